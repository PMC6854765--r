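test_that("single-leaf and ubiquitous characters reconstruct trivially", {
  tr <- parse_newick("((A,B),(C,D));")
  one <- reconstruct_character(tr, c(A = FALSE, B = FALSE, C = TRUE, D = FALSE))
  expect_identical(one$gain_node, match("C", leaf_labels(tr)))
  expect_length(one$losses, 0L)

  all_on <- reconstruct_character(tr, c(A = TRUE, B = TRUE, C = TRUE, D = TRUE))
  expect_identical(all_on$gain_branch, PRE_ROOT)
  expect_length(all_on$losses, 0L)

  none <- reconstruct_character(tr, c(A = FALSE, B = FALSE, C = FALSE, D = FALSE))
  expect_true(is.na(none$gain_branch))
  expect_length(none$losses, 0L)

  expect_error(reconstruct_character(tr, c(A = TRUE, B = TRUE, C = TRUE)),
               "missing for leaf: D")
})

test_that("loss count is minimal over all single-gain placements (exhaustive oracle)", {
  set.seed(99)
  for (k in 1:120) {
    tr <- random_tree(sample(4:12, 1L), seed = 300 + k)
    labs <- leaf_labels(tr)
    present <- sample(labs, sample(seq_along(labs), 1L))
    states <- setNames(labs %in% present, labs)
    sc <- reconstruct_character(tr, states)
    expect_identical(length(sc$losses),
                     as.integer(oracle_min_losses(tr, present)))
  }
})

test_that("loss branches are maximal (never nested) and below the gain", {
  set.seed(17)
  for (k in 1:40) {
    tr <- random_tree(sample(5:14, 1L), seed = 400 + k)
    labs <- leaf_labels(tr)
    present <- sample(labs, sample(seq_along(labs), 1L))
    sc <- reconstruct_character(tr, setNames(labs %in% present, labs))
    gain <- if (sc$gain_branch == PRE_ROOT) tr$root else sc$gain_node
    for (b in sc$losses) {
      # strict descendant of the gain node
      v <- b
      anc <- integer(0)
      while (!is.na(tr$parent[v])) {
        v <- tr$parent[v]
        anc <- c(anc, v)
      }
      expect_true(gain %in% anc)
      # no other loss is an ancestor of this one
      expect_length(intersect(anc, setdiff(sc$losses, b)), 0L)
    }
  }
})

test_that("unknown states locate the gain like absences but suppress losses", {
  tr <- parse_newick("((A,B),(C,D));")
  sc <- reconstruct_character(
    tr, c(A = "present", B = "present", C = "unknown", D = "unknown"))
  # gain at the (A,B) clade, and the all-unknown (C,D) subtree is no loss
  expect_identical(sc$gain_node, mrca_node(tr, c("A", "B")))
  expect_length(sc$losses, 0L)

  sc2 <- reconstruct_character(
    tr, c(A = "present", B = "present", C = "unknown", D = "present"))
  expect_identical(sc2$gain_branch, PRE_ROOT)
  # mixed unknown/absent subtree below the gain still counts one loss
  tr2 <- parse_newick("((A,B),(C,D),E);")
  sc3 <- reconstruct_character(
    tr2, c(A = "present", B = "present", C = "absent", D = "unknown",
           E = "present"))
  expect_length(sc3$losses, 1L)
  expect_identical(sc3$losses, mrca_node(tr2, c("C", "D")))
  # ... but an all-unknown one does not
  sc4 <- reconstruct_character(
    tr2, c(A = "present", B = "present", C = "unknown", D = "unknown",
           E = "present"))
  expect_length(sc4$losses, 0L)
})

test_that("reconstruction is invariant to row and column order", {
  fx <- apo_fixture()
  m <- fx$matrix
  set.seed(1)
  perm <- unclass(m)[sample(nrow(m)), sample(ncol(m))]
  rep1 <- reconstruct_all(fx$tree, m)
  rep2 <- reconstruct_all(fx$tree, phyletic_matrix(perm))
  expect_equal(rep1$gain_count, rep2$gain_count)
  expect_equal(rep1$loss_count, rep2$loss_count)
  for (ch in matrix_characters(m)) {
    expect_identical(rep1$scenarios[[ch]]$gain_node,
                     rep2$scenarios[[ch]]$gain_node)
    expect_identical(rep1$scenarios[[ch]]$losses,
                     rep2$scenarios[[ch]]$losses)
  }
})

test_that("reconstruct_all counts events and validates the taxon set", {
  tr <- parse_newick("((A,B),(C,D));")
  allp <- phyletic_matrix(matrix("present", 4, 2,
                                 dimnames = list(c("A", "B", "C", "D"),
                                                 c("x", "y"))))
  rep <- reconstruct_all(tr, allp)
  expect_equal(rep$gain_count, 0L)
  expect_equal(rep$gain_count_total, 2L)
  expect_equal(rep$loss_count, 0L)

  bad <- phyletic_matrix(matrix("present", 3, 1,
                                dimnames = list(c("A", "B", "Z"), "x")))
  expect_error(reconstruct_all(tr, bad), "only in matrix: \\{Z\\}")
})

test_that("per-branch aggregation matches the flat event table", {
  fx <- apo_fixture()
  rep <- reconstruct_all(fx$tree, fx$matrix)
  agg <- events_by_branch(rep)
  expect_equal(sum(agg$count), nrow(rep$events))
  aves <- agg[agg$branch == "Aves" & agg$event == "loss", ]
  expect_equal(aves$count, 3L)
  expect_equal(aves$characters, "ApoC-I,ApoC-II,ApoE")
})

test_that("emergence order groups by gain depth with pre-root first", {
  tr <- parse_newick("((A,B),(C,D));")
  single <- phyletic_matrix(matrix(c("present", "present", "absent", "absent"),
                                   ncol = 1,
                                   dimnames = list(c("A", "B", "C", "D"), "x")))
  ord <- emergence_order(tr, single)
  expect_equal(nrow(ord), 1L)
  expect_equal(ord$members, "x")

  # equal-depth gains on different nodes merge into one simultaneous group
  two <- phyletic_matrix(matrix(c("present", "present", "absent", "absent",
                                  "absent", "absent", "present", "present"),
                                ncol = 2,
                                dimnames = list(c("A", "B", "C", "D"),
                                                c("x", "y"))))
  ord2 <- emergence_order(tr, two)
  expect_equal(nrow(ord2), 1L)
  expect_equal(ord2$members, "x,y")
})
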