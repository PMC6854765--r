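#' Multiple protein alignment container
#'
#' A thin container: a named character vector of equal-length aligned
#' sequences (gap symbol `-`). At least 3 rows are required for tree
#' building; 2 are allowed for distance computation.
#'
#' @param seqs Named character vector of aligned sequences.
#' @return Object of class `protein_alignment`.
#' @export
protein_alignment <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 2L, !is.null(names(seqs)))
  if (anyDuplicated(names(seqs))) stop("duplicate taxon names", call. = FALSE)
  w <- unique(nchar(seqs))
  if (length(w) != 1L) {
    stop("aligned sequences must have equal length; got lengths ",
         paste(sort(w), collapse = ", "), call. = FALSE)
  }
  structure(seqs, class = "protein_alignment")
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat("protein_alignment:", length(x), "sequences x", nchar(x[[1L]]),
      "columns\n")
  invisible(x)
}

alignment_matrix <- function(alignment) {
  m <- do.call(rbind, strsplit(unclass(alignment), ""))
  rownames(m) <- names(alignment)
  m
}

#' Number of columns of an alignment
#' @param alignment A [protein_alignment].
#' @export
alignment_ncol <- function(alignment) nchar(unclass(alignment)[[1L]])

MISSING_SYMBOLS <- c("-", ".", "X", "?")

#' Complete deletion of gapped columns
#'
#' Removes every column in which any row carries a gap or missing symbol
#' (`-`, `.`, `X`, `?`), the "complete deletion" option of distance
#' phylogenetics. Row order is preserved.
#'
#' @param alignment A [protein_alignment].
#' @return A [protein_alignment] with only the shared, fully resolved
#'   columns.
#' @export
complete_deletion <- function(alignment) {
  stopifnot(inherits(alignment, "protein_alignment"))
  m <- alignment_matrix(alignment)
  keep <- colSums(matrix(m %in% MISSING_SYMBOLS, nrow = nrow(m))) == 0L
  if (!any(keep)) stop("no shared positions", call. = FALSE)
  protein_alignment(apply(m[, keep, drop = FALSE], 1L, paste, collapse = ""))
}

#' Pairwise distances from an alignment
#'
#' The p-distance is the fraction of differing positions; the Poisson
#' correction `d = -ln(1 - p)` accounts for multiple substitutions at one
#' site. Run [complete_deletion()] first; gapped columns make the counts
#' incomparable between pairs.
#'
#' @param alignment A [protein_alignment] (gap-free).
#' @param model `"p"` or `"poisson"`.
#' @return Symmetric numeric matrix with zero diagonal, taxa as dimnames.
#' @export
pairwise_distance <- function(alignment, model = c("poisson", "p")) {
  stopifnot(inherits(alignment, "protein_alignment"))
  model <- match.arg(model)
  m <- alignment_matrix(alignment)
  if (ncol(m) < 1L) stop("alignment has no columns", call. = FALSE)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      p <- mean(m[i, ] != m[j, ])
      if (model == "poisson") {
        if (p >= 1) {
          stop("saturated pair: ", rownames(m)[i], " vs ", rownames(m)[j],
               " differ at every position", call. = FALSE)
        }
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

check_distance_matrix <- function(d) {
  if (!is.matrix(d) || !is.numeric(d) || nrow(d) != ncol(d)) {
    stop("distance matrix must be square and numeric", call. = FALSE)
  }
  if (is.null(rownames(d))) stop("distance matrix needs taxon dimnames", call. = FALSE)
  if (any(!is.finite(d))) stop("non-finite distance", call. = FALSE)
  if (any(abs(d - t(d)) > 1e-8)) stop("non-symmetric distance matrix", call. = FALSE)
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero", call. = FALSE)
  invisible(d)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical Saitou-Nei neighbor joining (or the variance-weighted BioNJ
#' variant). Taxa are ordered alphabetically before the agglomeration so
#' the tie-break between equally good joins is deterministic and
#' independent of input order. Negative branch-length estimates are
#' clamped to 0. The returned tree is arbitrarily rooted (NJ is an
#' unrooted method).
#'
#' @param d Symmetric distance matrix with taxon dimnames (3-64 taxa).
#' @param method `"nj"` (default) or `"bionj"`.
#' @return A [rooted_tree].
#' @export
neighbor_joining <- function(d, method = c("nj", "bionj")) {
  method <- match.arg(method)
  check_distance_matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa", call. = FALSE)
  if (n > 64L) stop("more than 64 taxa; distance trees this size are out of scope", call. = FALSE)
  ord <- order(rownames(d))
  d <- d[ord, ord, drop = FALSE]
  phy <- if (method == "nj") ape::nj(stats::as.dist(d)) else ape::bionj(stats::as.dist(d))
  phy$edge.length[phy$edge.length < 0] <- 0
  rooted_tree(phy)
}

#' Nontrivial bipartitions of a tree (unrooted semantics)
#'
#' Each internal edge splits the leaves in two; a bipartition is
#' nontrivial when both sides hold at least two leaves. Bipartitions are
#' canonicalized as the sorted, comma-joined leaf side containing the
#' alphabetically first taxon.
#'
#' @param tree A [rooted_tree].
#' @return Character vector of canonical bipartition keys (unique).
#' @export
bipartitions <- function(tree) {
  stopifnot(inherits(tree, "rooted_tree"))
  labs <- leaf_labels(tree)
  anchor <- sort(labs)[1L]
  out <- character(0)
  for (v in seq_len(n_nodes(tree))) {
    if (is_leaf(tree, v) || v == tree$root) next
    side <- sort(labs[subtree_leaves(tree, v)])
    other <- sort(setdiff(labs, side))
    if (length(side) < 2L || length(other) < 2L) next
    key <- if (anchor %in% side) paste(side, collapse = ",") else
      paste(other, collapse = ",")
    out <- c(out, key)
  }
  unique(out)
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric-difference count of nontrivial bipartitions, using unrooted
#' semantics (root placement is ignored).
#'
#' @param t1,t2 [rooted_tree]s over the same leaf set.
#' @return Nonnegative integer.
#' @export
robinson_foulds <- function(t1, t2) {
  stopifnot(inherits(t1, "rooted_tree"), inherits(t2, "rooted_tree"))
  if (!setequal(leaf_labels(t1), leaf_labels(t2))) {
    stop("leaf sets differ", call. = FALSE)
  }
  b1 <- bipartitions(t1)
  b2 <- bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the full-data NJ tree, then resamples alignment columns with
#' replacement `replicates` times, rebuilds a tree per replicate, and
#' annotates each internal edge of the full-data tree with the percentage
#' of replicates whose tree contains the same bipartition. Supports are
#' written as internal node labels (0-100).
#'
#' When all pairwise distances are zero (identical sequences) the data
#' carry no signal; a star tree with zero-length branches is returned, as
#' documented.
#'
#' @param alignment A [protein_alignment] (>= 3 rows; run
#'   [complete_deletion()] first if it has gaps).
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; same seed and input give identical supports.
#' @param model Distance model, `"poisson"` or `"p"`.
#' @param method `"nj"` or `"bionj"`.
#' @return A [rooted_tree] whose internal node labels are bootstrap
#'   percentages ([node_support()] reads them back).
#' @export
bootstrap_support <- function(alignment, replicates = 1000L, seed = 1L,
                              model = c("poisson", "p"),
                              method = c("nj", "bionj")) {
  stopifnot(inherits(alignment, "protein_alignment"), replicates >= 1L)
  model <- match.arg(model)
  method <- match.arg(method)
  if (length(alignment) < 3L) stop("need at least 3 taxa", call. = FALSE)
  d <- pairwise_distance(alignment, model)
  if (all(d == 0)) {
    # degenerate: no phylogenetic signal; star tree
    labs <- sort(names(alignment))
    star <- ape::read.tree(
      text = paste0("(", paste0(labs, ":0", collapse = ","), ");"))
    return(rooted_tree(star))
  }
  full <- neighbor_joining(d, method)
  target <- bipartitions(full)
  hits <- stats::setNames(numeric(length(target)), target)

  m <- alignment_matrix(alignment)
  ncol_a <- ncol(m)
  set.seed(seed)
  done <- 0L
  for (r in seq_len(replicates)) {
    cols <- sample.int(ncol_a, ncol_a, replace = TRUE)
    rep_aln <- protein_alignment(apply(m[, cols, drop = FALSE], 1L,
                                       paste, collapse = ""))
    rep_d <- tryCatch(pairwise_distance(rep_aln, model), error = function(e) NULL)
    if (is.null(rep_d)) next # saturated resample under poisson: skipped
    rep_tree <- neighbor_joining(rep_d, method)
    rb <- bipartitions(rep_tree)
    in_rep <- target %in% rb
    hits[in_rep] <- hits[in_rep] + 1
    done <- done + 1L
  }
  if (done == 0L) stop("all bootstrap replicates failed", call. = FALSE)
  support <- 100 * hits / done

  phy <- full$phy
  n_tip <- full$n_tip
  labs <- leaf_labels(full)
  node_lab <- character(phy$Nnode)
  for (v in (n_tip + 1L):n_nodes(full)) {
    if (v == full$root) { node_lab[v - n_tip] <- ""; next }
    side <- sort(labs[subtree_leaves(full, v)])
    other <- sort(setdiff(labs, side))
    if (length(side) < 2L || length(other) < 2L) {
      node_lab[v - n_tip] <- ""
      next
    }
    anchor <- sort(labs)[1L]
    key <- if (anchor %in% side) paste(side, collapse = ",") else
      paste(other, collapse = ",")
    node_lab[v - n_tip] <- format(round(support[[key]], 1L), trim = TRUE)
  }
  phy$node.label <- node_lab
  rooted_tree(phy)
}
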