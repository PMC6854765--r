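#' Random rooted tree
#'
#' Convenience wrapper around [ape::rtree()] returning a [rooted_tree]
#' with exponential-ish random branch lengths; used throughout the test
#' and simulation machinery.
#'
#' @param n_leaves Number of leaves (>= 2).
#' @param seed Integer seed.
#' @param labels Optional leaf labels (default `t1..tn` from ape).
#' @return A [rooted_tree].
#' @export
random_tree <- function(n_leaves, seed = 1L, labels = NULL) {
  stopifnot(n_leaves >= 2L)
  with_seed(seed, {
    phy <- ape::rtree(n_leaves)
    if (!is.null(labels)) phy$tip.label <- labels
    rooted_tree(phy)
  })
}

#' Simulate presence/absence characters under the single-gain model
#'
#' Each character originates exactly once: on its gain branch the state
#' switches to present, and on every branch below the gain node the
#' character is lost independently with probability `loss_prob` (loss is
#' absorbing - a lost lineage never regains the character). This is the
#' generative counterpart of the Dollo reconstruction: with
#' `loss_prob = 0` the leaf pattern determines the gain branch exactly.
#'
#' @param tree A [rooted_tree].
#' @param n_characters Number of characters to simulate.
#' @param loss_prob Per-branch loss probability in `[0, 1)`.
#' @param gain Either `"random"` (each character's gain branch drawn
#'   uniformly from all branches plus [PRE_ROOT]) or an integer vector of
#'   gain branches (child node ids; [PRE_ROOT] = present at the root),
#'   recycled to `n_characters`.
#' @param seed Integer seed; fixed seed gives a reproducible matrix.
#' @return List with `matrix` (a [phyletic_matrix], taxa x characters) and
#'   `scenarios` (list of the true scenarios: `character`, `gain_branch`,
#'   `gain_node`, `losses` - loss branches recorded only where the parent
#'   lineage still had the character, so they are maximal).
#' @examples
#' tr <- random_tree(6, seed = 2)
#' sim <- simulate_characters(tr, 5, loss_prob = 0.2, seed = 7)
#' sim$matrix
#' @export
simulate_characters <- function(tree, n_characters, loss_prob = 0,
                                gain = "random", seed = 1L) {
  stopifnot(inherits(tree, "rooted_tree"),
            n_characters >= 1L, loss_prob >= 0, loss_prob < 1)
  labs <- leaf_labels(tree)
  n <- n_nodes(tree)
  candidates <- c(PRE_ROOT, setdiff(seq_len(n), tree$root))
  with_seed(seed, {
    gains <- if (identical(gain, "random")) {
      sample(candidates, n_characters, replace = TRUE)
    } else {
      g <- as.integer(rep_len(gain, n_characters))
      bad <- !(g %in% candidates)
      if (any(bad)) stop("invalid gain branch: ", g[which(bad)[1L]], call. = FALSE)
      g
    }
    states <- matrix("absent", nrow = length(labs), ncol = n_characters,
                     dimnames = list(labs, paste0("char", seq_len(n_characters))))
    scenarios <- vector("list", n_characters)
    for (k in seq_len(n_characters)) {
      g <- gains[k]
      start <- if (g == PRE_ROOT) tree$root else g
      present <- logical(n)
      losses <- integer(0)
      # preorder walk from the gain node
      stack <- start
      present[start] <- TRUE
      while (length(stack)) {
        v <- stack[length(stack)]
        stack <- stack[-length(stack)]
        for (w in tree$children[[v]]) {
          if (loss_prob > 0 && stats::runif(1L) < loss_prob) {
            losses <- c(losses, w) # maximal: parent lineage had it
          } else {
            present[w] <- TRUE
            stack <- c(stack, w)
          }
        }
      }
      leaf_ids <- seq_len(tree$n_tip)
      states[present[leaf_ids], k] <- "present"
      scenarios[[k]] <- list(character = colnames(states)[k],
                             gain_branch = g,
                             gain_node = start,
                             losses = sort(losses))
    }
    list(matrix = phyletic_matrix(states), scenarios = scenarios)
  })
}

#' Simulate aligned sequences along a tree
#'
#' The root sequence evolves independently per site down the tree: along
#' a branch of length `t` (expected substitutions/site) a site substitutes
#' with probability `1 - exp(-t)`, drawing a uniformly random different
#' residue. No indels are produced, so the leaf sequences are returned as
#' an already-aligned [protein_alignment].
#'
#' @param tree A [rooted_tree] with branch lengths.
#' @param root_seq Root protein sequence; if `NULL`, a uniform random
#'   sequence of `length` residues is drawn.
#' @param length Root sequence length when `root_seq` is `NULL`.
#' @param seed Integer seed.
#' @return A [protein_alignment] over the leaf labels.
#' @export
simulate_sequences <- function(tree, root_seq = NULL, length = 200L,
                               seed = 1L) {
  stopifnot(inherits(tree, "rooted_tree"))
  bl <- branch_lengths(tree)
  non_root <- setdiff(seq_len(n_nodes(tree)), tree$root)
  if (anyNA(bl[non_root])) stop("tree must have branch lengths", call. = FALSE)
  if (any(bl[non_root] < 0)) stop("negative branch length", call. = FALSE)
  with_seed(seed, {
    root <- if (is.null(root_seq)) {
      sample(AA20, length, replace = TRUE)
    } else {
      check_protein(root_seq, AA20)
      strsplit(root_seq, "")[[1]]
    }
    L <- base::length(root)
    n <- n_nodes(tree)
    seqs <- vector("list", n)
    seqs[[tree$root]] <- root
    # preorder: parent sequence available before children
    for (v in rev(postorder_nodes(tree))) {
      if (v == tree$root) next
      parent_seq <- seqs[[tree$parent[v]]]
      p_sub <- 1 - exp(-bl[v])
      hit <- stats::runif(L) < p_sub
      child <- parent_seq
      if (any(hit)) {
        # uniform among the 19 other residues
        child[hit] <- vapply(parent_seq[hit], function(res) {
          sample(setdiff(AA20, res), 1L)
        }, character(1L))
      }
      seqs[[v]] <- child
    }
    leaves <- seq_len(tree$n_tip)
    out <- vapply(leaves, function(v) paste(seqs[[v]], collapse = ""),
                  character(1L))
    names(out) <- leaf_labels(tree)
    protein_alignment(out)
  })
}

#' Synthetic query panel with apolipoprotein-like lengths
#'
#' Ten independent random protein sequences named after the family
#' members, with lengths close to the human precursor proteins. Unrelated
#' random sequences stand in for the real query panel so identification
#' and recovery experiments can run without external sequence data.
#'
#' @param seed Integer seed.
#' @return Named character vector of 10 query sequences.
#' @export
synthetic_panel <- function(seed = 1L) {
  lengths <- c("ApoA-I" = 267L, "ApoA-II" = 100L, "ApoA-IV" = 396L,
               "ApoA-V" = 366L, "ApoC-I" = 83L, "ApoC-IA" = 83L,
               "ApoC-II" = 101L, "ApoC-III" = 99L, "ApoC-IV" = 127L,
               "ApoE" = 317L)
  with_seed(seed, {
    out <- vapply(lengths, function(L)
      paste(sample(AA20, L, replace = TRUE), collapse = ""), character(1L))
    names(out) <- names(lengths)
    out
  })
}

mutate_sequence <- function(seq, divergence) {
  chars <- strsplit(seq, "")[[1]]
  k <- round(divergence * length(chars))
  if (k > 0) {
    pos <- sample(length(chars), k)
    chars[pos] <- vapply(chars[pos], function(res) {
      sample(setdiff(AA20, res), 1L)
    }, character(1L))
  }
  paste(chars, collapse = "")
}

#' Simulate decoy-laden proteomes from a truth matrix
#'
#' For every taxon and every family member the truth matrix marks as
#' present, emits the panel query mutated at `divergence` of its
#' positions; adds `decoys_per_taxon` decoys per taxon, each a
#' composition-preserving shuffle of a random panel query (length-matched
#' to real proteins but with no local homology).
#'
#' @param panel Named character vector of query sequences.
#' @param truth A [phyletic_matrix] over taxa x panel names (the ground
#'   truth to emulate), or `NULL` for all-present over `taxa`.
#' @param taxa Taxa to simulate when `truth` is `NULL`.
#' @param divergence Fraction of positions to mutate, in `[0, 0.5]`.
#' @param decoys_per_taxon Nonnegative integer.
#' @param seed Integer seed.
#' @return List with `records` (protein records) and `truth` (data frame
#'   `id`, `taxon`, `family`; decoys have family `NA`).
#' @export
simulate_proteome <- function(panel, truth = NULL, taxa = NULL,
                              divergence = 0.2, decoys_per_taxon = 2L,
                              seed = 1L) {
  stopifnot(!is.null(names(panel)), divergence >= 0, divergence <= 0.5,
            decoys_per_taxon >= 0L)
  if (is.null(truth)) {
    stopifnot(!is.null(taxa))
    states <- matrix("present", nrow = length(taxa), ncol = length(panel),
                     dimnames = list(taxa, names(panel)))
    truth <- phyletic_matrix(states)
  }
  stopifnot(inherits(truth, "phyletic_matrix"),
            setequal(matrix_characters(truth), names(panel)))
  taxa <- matrix_taxa(truth)
  with_seed(seed, {
    ids <- character(0); txs <- character(0); seqs <- character(0)
    fams <- character(0)
    for (tx in taxa) {
      for (fam in matrix_characters(truth)) {
        if (unclass(truth)[tx, fam] != "present") next
        ids <- c(ids, paste0(tx, "|", fam))
        txs <- c(txs, tx)
        seqs <- c(seqs, mutate_sequence(panel[[fam]], divergence))
        fams <- c(fams, fam)
      }
      for (k in seq_len(decoys_per_taxon)) {
        src <- panel[[sample(length(panel), 1L)]]
        ids <- c(ids, paste0(tx, "|decoy", k))
        txs <- c(txs, tx)
        seqs <- c(seqs, paste(sample(strsplit(src, "")[[1]]), collapse = ""))
        fams <- c(fams, NA_character_)
      }
    }
    list(records = protein_records(ids, txs, seqs),
         truth = data.frame(id = ids, taxon = txs, family = fams,
                            stringsAsFactors = FALSE))
  })
}
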