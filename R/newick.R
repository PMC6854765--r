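#' Parse a Newick string into a rooted tree
#'
#' Accepts the standard Newick dialect: nested parentheses, optional branch
#' lengths after `:`, optional internal node labels, single-quoted labels,
#' and a terminating semicolon. Parsing itself is delegated to
#' [ape::read.tree()]; a pre-scan reports structural errors (unbalanced
#' parentheses, missing semicolon, empty input) with the 1-based character
#' offset at which they occur.
#'
#' @param text A single Newick string.
#' @return A [rooted_tree].
#' @examples
#' tr <- parse_newick("((A:1,B:1)ab:1,C:2);")
#' leaf_labels(tr)
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L) {
    stop("`text` must be a single string", call. = FALSE)
  }
  text <- trimws(text)
  if (!nzchar(text)) stop("Newick parse error at offset 1: empty input", call. = FALSE)
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  quoted <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") quoted <- !quoted
    if (quoted) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("Newick parse error at offset ", i,
             ": unmatched ')'", call. = FALSE)
      }
    }
  }
  if (depth != 0L) {
    stop("Newick parse error at offset ", length(chars),
         ": ", depth, " unclosed '('", call. = FALSE)
  }
  if (chars[length(chars)] != ";") {
    stop("Newick parse error at offset ", length(chars),
         ": missing terminating ';'", call. = FALSE)
  }
  phy <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(phy)) stop("Newick parse error: unparsable input", call. = FALSE)
  # ape keeps the quotes of quoted labels; strip them
  phy$tip.label <- gsub("^'(.*)'$", "\\1", phy$tip.label)
  rooted_tree(phy)
}

#' Serialize a rooted tree to Newick
#'
#' Branch lengths are written when present; internal node labels (clade
#' names or supports) are written as internal labels.
#'
#' @param tree A [rooted_tree].
#' @return A single Newick string with terminating semicolon.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "rooted_tree"))
  ape::write.tree(tree$phy)
}

#' Read a rooted tree from a Newick file
#' @param path Path to a Newick file (first tree is used).
#' @return A [rooted_tree].
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  parse_newick(txt)
}
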