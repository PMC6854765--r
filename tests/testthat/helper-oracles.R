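# Independent oracles used by the property-style tests. These deliberately
# avoid the package's own code paths.

# Exhaustive local-alignment score: enumerates every order-preserving set of
# aligned columns (including mismatches); unaligned stretches between
# consecutive columns are charged as affine gaps (open + ext per position)
# in each sequence. Local alignments have no terminal gaps. Floor at 0.
bf_local_score <- function(a, b, mat, open, ext) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  gap <- function(L) if (L > 0L) open + ext * L else 0
  best <- 0
  rec <- function(i, j, last_i, last_j, sc) {
    best <<- max(best, sc)
    if (i > n || j > m) return(invisible())
    for (ii in i:n) {
      for (jj in j:m) {
        g <- if (last_i == 0L) 0 else gap(ii - last_i - 1L) + gap(jj - last_j - 1L)
        rec(ii + 1L, jj + 1L, ii, jj, sc - g + mat[av[ii], bv[jj]])
      }
    }
  }
  rec(1L, 1L, 0L, 0L, 0)
  best
}

# Leaf set below each node, computed by label-path walking only.
oracle_leafsets <- function(tree) {
  labs <- leaf_labels(tree)
  n <- n_nodes(tree)
  sets <- vector("list", n)
  for (leaf in seq_along(labs)) {
    v <- leaf
    repeat {
      sets[[v]] <- union(sets[[v]], labs[leaf])
      v <- tree$parent[v]
      if (is.na(v)) break
    }
  }
  sets
}

# MRCA by scanning every node's leaf set: the node containing all taxa with
# the smallest leaf set.
oracle_mrca <- function(tree, taxa) {
  sets <- oracle_leafsets(tree)
  cand <- which(vapply(sets, function(s) all(taxa %in% s), logical(1L)))
  cand[which.min(lengths(sets[cand]))]
}

# Minimum loss count over every feasible single-gain placement, by
# exhaustive search: a gain node is feasible when its subtree holds every
# possessing leaf; its cost is the number of maximal all-absent subtrees
# below it.
oracle_min_losses <- function(tree, present_leaves) {
  sets <- oracle_leafsets(tree)
  labs <- leaf_labels(tree)
  absent_sub <- vapply(sets, function(s) !any(s %in% present_leaves), logical(1L))
  cost_below <- function(g) {
    cnt <- 0L
    stack <- tree$children[[g]]
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (absent_sub[v]) cnt <- cnt + 1L
      else if (!is_leaf(tree, v)) stack <- c(stack, tree$children[[v]])
    }
    cnt
  }
  feasible <- which(vapply(sets, function(s) all(present_leaves %in% s),
                           logical(1L)))
  min(vapply(feasible, cost_below, integer(1L)))
}

# Depth by explicit path walk.
oracle_depth <- function(tree, v) {
  d <- 0L
  while (!is.na(tree$parent[v])) {
    v <- tree$parent[v]
    d <- d + 1L
  }
  d
}

random_labels <- function(n) sprintf("t%02d", seq_len(n))

# Random phyletic matrix with all three states.
random_phyletic <- function(n_taxa, n_char, seed) {
  with_seed_test(seed, {
    states <- matrix(sample(c("present", "absent", "unknown"),
                            n_taxa * n_char, replace = TRUE,
                            prob = c(0.5, 0.4, 0.1)),
                     nrow = n_taxa,
                     dimnames = list(random_labels(n_taxa),
                                     paste0("c", seq_len(n_char))))
    phyletic_matrix(states)
  })
}

# Seed scoping for helpers (tests themselves may also use set.seed freely).
with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# BLOSUM62 with X zeroed, as used by default_scoring(), fetched directly.
test_blosum <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  m["X", ] <- 0
  m[, "X"] <- 0
  m
}

# Independent point-mutation helper (mirrors the generator's contract
# without calling it).
mutate_seq_for_test <- function(seq, divergence) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  chars <- strsplit(seq, "")[[1]]
  k <- round(divergence * length(chars))
  if (k > 0) {
    pos <- sample(length(chars), k)
    chars[pos] <- vapply(chars[pos], function(r) sample(setdiff(aa, r), 1L),
                         character(1L))
  }
  paste(chars, collapse = "")
}
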