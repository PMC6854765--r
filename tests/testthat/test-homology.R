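test_that("self-alignment of a gapless hit sums the matrix diagonal", {
  sc <- default_scoring()
  s <- "MKVLITGAARWQ"
  chars <- strsplit(s, "")[[1]]
  expect_equal(local_align(s, s, sc)$score,
               sum(sc$matrix[cbind(chars, chars)]))
  res <- local_align(s, s, sc)
  expect_equal(res$a_range, c(0L, nchar(s)))
  expect_equal(res$b_range, c(0L, nchar(s)))
})

test_that("all-negative scoring floors the local score at zero", {
  m <- matrix(-1, 21, 21, dimnames = list(c(LETTERS[1:20], "X"),
                                          c(LETTERS[1:20], "X")))
  sc <- scoring(m, gap_open = 11, gap_extend = 1)
  res <- local_align("A", "C", sc)
  expect_equal(res$score, 0)
  expect_equal(res$a_range, c(0L, 0L))
})

test_that("illegal residues are rejected with their position", {
  expect_error(local_align("MKB1", "MK", default_scoring()),
               "illegal residue '1' at position 4")
})

test_that("local score is symmetric and nonnegative", {
  sc <- default_scoring()
  set.seed(31)
  for (k in 1:15) {
    a <- paste(sample(c("A", "C", "D", "E", "G", "K"), sample(3:20, 1),
                      replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "D", "E", "G", "K"), sample(3:20, 1),
                      replace = TRUE), collapse = "")
    s1 <- local_align(a, b, sc)$score
    expect_gte(s1, 0)
    expect_equal(s1, local_align(b, a, sc)$score)
  }
})

test_that("local alignment equals brute-force enumeration on short sequences", {
  blo <- test_blosum()
  sc <- scoring(blo, gap_open = 11, gap_extend = 1)
  alphabet <- c("A", "C", "D", "W") # reduced alphabet
  set.seed(77)
  for (k in 1:25) {
    a <- paste(sample(alphabet, sample(1:6, 1), replace = TRUE), collapse = "")
    b <- paste(sample(alphabet, sample(1:6, 1), replace = TRUE), collapse = "")
    expect_equal(local_align(a, b, sc)$score,
                 bf_local_score(a, b, blo, 11, 1),
                 label = paste(a, "vs", b))
  }
})

test_that("a candidate identical to a panel query is assigned that family at 1.0", {
  panel <- synthetic_panel(seed = 5)
  res <- assign_family(panel[["ApoE"]], panel)
  expect_equal(res$family, "ApoE")
  expect_equal(res$norm_score, 1.0)
})

test_that("assignment does not depend on panel order", {
  panel <- synthetic_panel(seed = 5)
  cand <- with_seed_test(8, mutate_seq_for_test(panel[["ApoC-II"]], 0.2))
  r1 <- assign_family(cand, panel)
  r2 <- assign_family(cand, rev(panel))
  expect_identical(r1, r2)
})

test_that("shuffled decoys fall below an assignment threshold of 0.3", {
  panel <- synthetic_panel(seed = 5)
  set.seed(123)
  n_none <- 0L
  for (k in 1:100) {
    src <- panel[[sample(length(panel), 1L)]]
    decoy <- paste(sample(strsplit(src, "")[[1]]), collapse = "")
    res <- assign_family(decoy, panel, threshold = 0.3)
    if (is.na(res$family)) n_none <- n_none + 1L
  }
  expect_gte(n_none, 95L)
})

test_that("members at 20% divergence are assigned to the right family", {
  panel <- synthetic_panel(seed = 5)
  correct <- 0L
  for (k in 1:100) {
    fam <- names(panel)[(k %% length(panel)) + 1L]
    cand <- with_seed_test(1000 + k, mutate_seq_for_test(panel[[fam]], 0.2))
    res <- assign_family(cand, panel)
    if (!is.na(res$family) && res$family == fam) correct <- correct + 1L
  }
  expect_gte(correct, 95L)
})

test_that("dedupe removes duplicates and contained partials, keeping the longest", {
  set.seed(55)
  base1 <- paste(sample(c("A", "C", "D", "E", "G", "K", "L"), 80,
                        replace = TRUE), collapse = "")
  base2 <- paste(sample(c("A", "C", "D", "E", "G", "K", "L"), 60,
                        replace = TRUE), collapse = "")
  recs <- protein_records(
    id = c("full1", "dup1", "half1", "full2", "other_taxon"),
    taxon = c("sp1", "sp1", "sp1", "sp1", "sp2"),
    sequence = c(base1, base1, substr(base1, 1, 40), base2, base1))
  out <- dedupe(recs, identity_threshold = 0.9)
  # equal-length duplicates keep the lexicographically first identifier
  expect_setequal(out$id, c("dup1", "full2", "other_taxon"))
  # idempotence
  expect_identical(dedupe(out, identity_threshold = 0.9), out)
})

test_that("dedupe output matches the constructed ground truth on random sets", {
  alphabet <- c("A", "C", "D", "E", "F", "G", "K", "L", "S", "T")
  set.seed(66)
  for (k in 1:8) {
    n_base <- sample(2:4, 1)
    ids <- character(0); seqs <- character(0)
    expected <- character(0)
    for (b in seq_len(n_base)) {
      base <- paste(sample(alphabet, sample(50:90, 1), replace = TRUE),
                    collapse = "")
      bid <- paste0("base", k, "_", b)
      ids <- c(ids, bid); seqs <- c(seqs, base)
      expected <- c(expected, bid)
      for (p in seq_len(sample(0:2, 1))) {
        ids <- c(ids, paste0(bid, "_part", p))
        seqs <- c(seqs, substr(base, 1, sample(10:(nchar(base) - 5), 1)))
      }
      if (sample(c(TRUE, FALSE), 1)) {
        ids <- c(ids, paste0(bid, "_dup"))
        seqs <- c(seqs, base)
      }
    }
    recs <- protein_records(ids, rep("sp1", length(ids)), seqs)
    out <- dedupe(recs, identity_threshold = 0.9)
    expect_setequal(out$id, expected)
  }
})

test_that("identify_members vectorizes assign_family over records", {
  panel <- synthetic_panel(seed = 5)
  recs <- protein_records(
    id = c("r1", "r2"), taxon = c("sp1", "sp1"),
    sequence = c(panel[["ApoA-II"]],
                 paste(rev(strsplit(panel[["ApoA-I"]], "")[[1]]), collapse = "")))
  res <- identify_members(recs, panel)
  expect_equal(res$family[1], "ApoA-II")
  expect_equal(res$norm_score[1], 1.0)
  one <- assign_family(recs$sequence[2], panel)
  expect_equal(res$norm_score[2], one$norm_score, tolerance = 1e-9)
})
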