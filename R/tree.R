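#' Rooted tree data model
#'
#' A `rooted_tree` wraps an [ape::read.tree()] style `phylo` object together
#' with parent/children lookup tables so that rooted traversals (ancestor
#' walks, subtree leaf sets, depths) are cheap. Node identifiers follow the
#' `phylo` convention: leaves are `1..n`, internal nodes `(n+1)..(n+m)` and
#' the root is `n+1`. Polytomies are allowed; the tree is never binarized.
#'
#' Branches are identified by their *child* node. The branch "above" the
#' root does not exist inside the tree; the sentinel [PRE_ROOT] stands for
#' an origin that predates the root (used by the Dollo reconstruction for
#' characters present in every sampled species).
#'
#' Internal node labels are interpreted as clade names (e.g. `"Aves"`,
#' `"Eutheria"`) when alphabetic and as support values when numeric; both
#' are retained.
#'
#' @param phy A rooted `phylo` object.
#' @return An object of class `rooted_tree` with elements `phy`, `n_tip`,
#'   `root`, `parent` (integer vector indexed by node id, `NA` at the root)
#'   and `children` (list indexed by node id).
#' @export
rooted_tree <- function(phy) {
  if (!inherits(phy, "phylo")) {
    stop("`phy` must be a 'phylo' object", call. = FALSE)
  }
  n_tip <- length(phy$tip.label)
  if (n_tip < 1L) stop("tree has no leaves", call. = FALSE)
  labs <- phy$tip.label
  if (anyDuplicated(labs)) {
    stop("duplicate leaf labels: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(labs))) stop("empty leaf label", call. = FALSE)
  n_node <- n_tip + phy$Nnode
  parent <- rep(NA_integer_, n_node)
  children <- vector("list", n_node)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]
    v <- phy$edge[i, 2L]
    if (!is.na(parent[v])) stop("node has two parents: not a tree", call. = FALSE)
    parent[v] <- p
    children[[p]] <- c(children[[p]], v)
  }
  root <- n_tip + 1L
  if (sum(is.na(parent)) != 1L || !is.na(parent[root])) {
    stop("tree must have exactly one root", call. = FALSE)
  }
  # reachability from the root (acyclicity comes with the single-parent check)
  seen <- rep(FALSE, n_node)
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    seen[v] <- TRUE
    stack <- c(stack, children[[v]])
  }
  if (!all(seen)) stop("tree contains nodes unreachable from the root", call. = FALSE)
  structure(
    list(phy = phy, n_tip = n_tip, root = root,
         parent = parent, children = children),
    class = "rooted_tree"
  )
}

#' Sentinel branch identifier for an origin before the root
#'
#' Used as the gain branch of characters that are present in every leaf:
#' their origin predates the sampled tree and is unobservable on it.
#' @export
PRE_ROOT <- 0L

#' @export
print.rooted_tree <- function(x, ...) {
  cat("rooted_tree:", x$n_tip, "leaves,", x$phy$Nnode, "internal nodes\n")
  lab <- leaf_labels(x)
  cat("  leaves:", paste(utils::head(lab, 6L), collapse = ", "),
      if (length(lab) > 6L) "..." else "", "\n")
  invisible(x)
}

#' Leaf labels of a rooted tree
#' @param tree A `rooted_tree`.
#' @return Character vector of taxon names in node-id order.
#' @export
leaf_labels <- function(tree) {
  stopifnot(inherits(tree, "rooted_tree"))
  tree$phy$tip.label
}

#' Total number of nodes (leaves + internal)
#' @param tree A `rooted_tree`.
#' @export
n_nodes <- function(tree) {
  stopifnot(inherits(tree, "rooted_tree"))
  tree$n_tip + tree$phy$Nnode
}

#' Is a node a leaf?
#' @param tree A `rooted_tree`.
#' @param node Integer node id(s).
#' @export
is_leaf <- function(tree, node) {
  stopifnot(inherits(tree, "rooted_tree"))
  node >= 1L & node <= tree$n_tip
}

#' Human-readable label for a node
#'
#' Leaves get their taxon name; internal nodes their node label when one is
#' present, otherwise `"node<id>"`. Used when reporting events on branches.
#' @param tree A `rooted_tree`.
#' @param node Integer node id(s), or [PRE_ROOT].
#' @return Character vector of labels.
#' @export
node_label <- function(tree, node) {
  stopifnot(inherits(tree, "rooted_tree"))
  vapply(as.integer(node), function(v) {
    if (v == PRE_ROOT) return("PRE_ROOT")
    check_node(tree, v)
    if (v <= tree$n_tip) return(tree$phy$tip.label[v])
    lab <- tree$phy$node.label
    if (!is.null(lab)) {
      l <- lab[v - tree$n_tip]
      if (!is.na(l) && nzchar(l)) return(l)
    }
    paste0("node", v)
  }, character(1L))
}

check_node <- function(tree, node) {
  if (length(node) != 1L || is.na(node) || node < 1L || node > n_nodes(tree)) {
    stop("unknown node: ", node, call. = FALSE)
  }
  invisible(as.integer(node))
}

#' Leaves descending from a node
#' @param tree A `rooted_tree`.
#' @param node Integer node id.
#' @return Integer vector of leaf node ids in the subtree rooted at `node`.
#' @export
subtree_leaves <- function(tree, node) {
  node <- check_node(tree, node)
  if (node <= tree$n_tip) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v <= tree$n_tip) out <- c(out, v) else stack <- c(stack, tree$children[[v]])
  }
  sort(out)
}

#' Nodes in postorder (children before parents)
#' @param tree A `rooted_tree`.
#' @return Integer vector over all node ids.
#' @export
postorder_nodes <- function(tree) {
  stopifnot(inherits(tree, "rooted_tree"))
  out <- integer(0)
  stack <- tree$root
  # reverse preorder then reverse = postorder
  pre <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    pre <- c(pre, v)
    stack <- c(stack, tree$children[[v]])
  }
  rev(pre)
}

#' Depth of a node
#'
#' Number of edges on the path from the root; the root has depth 0.
#' @param tree A `rooted_tree`.
#' @param node Integer node id.
#' @return Non-negative integer.
#' @export
node_depth <- function(tree, node) {
  node <- check_node(tree, node)
  d <- 0L
  v <- node
  while (!is.na(tree$parent[v])) {
    v <- tree$parent[v]
    d <- d + 1L
  }
  d
}

#' Most recent common ancestor of a set of taxa
#'
#' The deepest node whose descendant leaf set contains every taxon in
#' `taxa`.
#' @param tree A `rooted_tree`.
#' @param taxa Non-empty character vector of leaf labels.
#' @return Integer node id (a leaf id when `taxa` is a single taxon).
#' @export
mrca_node <- function(tree, taxa) {
  stopifnot(inherits(tree, "rooted_tree"))
  if (length(taxa) == 0L) stop("empty taxon set", call. = FALSE)
  idx <- match(taxa, tree$phy$tip.label)
  if (anyNA(idx)) {
    stop("unknown taxon: ", paste(taxa[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  idx <- unique(idx)
  if (length(idx) == 1L) return(idx)
  # intersect root-to-leaf ancestor paths
  path_of <- function(v) {
    p <- v
    while (!is.na(tree$parent[v])) {
      v <- tree$parent[v]
      p <- c(p, v)
    }
    rev(p) # root first
  }
  paths <- lapply(idx, path_of)
  shortest <- min(lengths(paths))
  mrca <- tree$root
  for (k in seq_len(shortest)) {
    nodes_k <- vapply(paths, `[[`, integer(1L), k)
    if (all(nodes_k == nodes_k[1L])) mrca <- nodes_k[1L] else break
  }
  mrca
}

#' Branch lengths indexed by child node
#' @param tree A `rooted_tree`.
#' @return Numeric vector over node ids (`NA` at the root and when the tree
#'   has no branch lengths).
#' @export
branch_lengths <- function(tree) {
  stopifnot(inherits(tree, "rooted_tree"))
  n <- n_nodes(tree)
  out <- rep(NA_real_, n)
  if (!is.null(tree$phy$edge.length)) {
    out[tree$phy$edge[, 2L]] <- tree$phy$edge.length
  }
  out
}

#' Support values of internal nodes
#'
#' Internal node labels that parse as numbers are reported as supports
#' (scale 0-100); alphabetic labels (clade names) give `NA`.
#' @param tree A `rooted_tree`.
#' @return Numeric vector indexed by node id; `NA` for leaves and unlabeled
#'   nodes.
#' @export
node_support <- function(tree) {
  stopifnot(inherits(tree, "rooted_tree"))
  n <- n_nodes(tree)
  out <- rep(NA_real_, n)
  lab <- tree$phy$node.label
  if (!is.null(lab)) {
    sup <- suppressWarnings(as.numeric(lab))
    out[(tree$n_tip + 1L):n] <- sup
  }
  out
}
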