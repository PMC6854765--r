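#' Phyletic presence/absence matrix
#'
#' A `phyletic_matrix` records, for every (taxon, family member) pair, one
#' of the states `"present"`, `"absent"` or `"unknown"`. It is stored as a
#' character matrix with taxa as rows and characters (family members) as
#' columns.
#'
#' @param states Character matrix with values in
#'   `c("present", "absent", "unknown")`, rownames = taxa, colnames =
#'   characters.
#' @return An object of class `phyletic_matrix`.
#' @export
phyletic_matrix <- function(states) {
  if (!is.matrix(states) || !is.character(states)) {
    stop("`states` must be a character matrix", call. = FALSE)
  }
  if (is.null(rownames(states)) || is.null(colnames(states))) {
    stop("`states` must have taxon rownames and character colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(states))) stop("duplicate taxon names", call. = FALSE)
  if (anyDuplicated(colnames(states))) stop("duplicate character names", call. = FALSE)
  bad <- !states %in% c("present", "absent", "unknown")
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop("illegal state '", states[bad][1L], "' at taxon '",
         rownames(states)[idx[1L]], "', character '",
         colnames(states)[idx[2L]], "'", call. = FALSE)
  }
  structure(states, class = c("phyletic_matrix", "matrix", "array"))
}

#' @export
print.phyletic_matrix <- function(x, ...) {
  cat("phyletic_matrix:", nrow(x), "taxa x", ncol(x), "characters\n")
  cat("  present:", sum(x == "present"),
      " absent:", sum(x == "absent"),
      " unknown:", sum(x == "unknown"), "\n")
  invisible(x)
}

#' Taxa (row names) of a phyletic matrix
#' @param matrix A [phyletic_matrix].
#' @export
matrix_taxa <- function(matrix) rownames(matrix)

#' Characters (column names) of a phyletic matrix
#' @param matrix A [phyletic_matrix].
#' @export
matrix_characters <- function(matrix) colnames(matrix)

STATE_TOKENS <- c(present = "1", absent = "0", unknown = "?")

#' Read a phyletic matrix from TSV
#'
#' Expected layout: the first row holds character names (first cell is a
#' corner label, conventionally `taxon`), the first column taxon names, and
#' the cells the tokens `1` (present), `0` (absent) or `?` (unknown).
#'
#' @param path Path to a tab-separated file.
#' @return A [phyletic_matrix].
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("matrix file needs a header and at least one row", call. = FALSE)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  n_char <- length(header) - 1L
  if (n_char < 1L) stop("matrix file has no character columns", call. = FALSE)
  chars <- header[-1L]
  taxa <- character(length(cells) - 1L)
  states <- matrix(NA_character_, nrow = length(cells) - 1L, ncol = n_char)
  for (r in seq_along(cells)[-1L]) {
    row <- cells[[r]]
    if (length(row) != n_char + 1L) {
      stop("ragged row ", r, ": expected ", n_char + 1L, " fields, got ",
           length(row), call. = FALSE)
    }
    taxa[r - 1L] <- row[1L]
    tok <- row[-1L]
    bad <- !tok %in% STATE_TOKENS
    if (any(bad)) {
      c1 <- which(bad)[1L]
      stop("illegal cell token '", tok[c1], "' at row ", r, ", column ",
           c1 + 1L, call. = FALSE)
    }
    states[r - 1L, ] <- names(STATE_TOKENS)[match(tok, STATE_TOKENS)]
  }
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon names: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(chars)) {
    stop("duplicate character names: ",
         paste(unique(chars[duplicated(chars)]), collapse = ", "), call. = FALSE)
  }
  dimnames(states) <- list(taxa, chars)
  phyletic_matrix(states)
}

#' Write a phyletic matrix to TSV
#'
#' Inverse of [read_matrix()]; row and column order are preserved.
#'
#' @param matrix A [phyletic_matrix].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "phyletic_matrix"))
  tok <- STATE_TOKENS[unclass(matrix)]
  dim(tok) <- dim(matrix)
  header <- paste(c("taxon", colnames(matrix)), collapse = "\t")
  rows <- vapply(seq_len(nrow(matrix)), function(r) {
    paste(c(rownames(matrix)[r], tok[r, ]), collapse = "\t")
  }, character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Build a presence/absence matrix from family assignments
#'
#' A cell is `"present"` when at least one assignment maps that taxon to
#' that family member, `"absent"` otherwise. This is the step that turns
#' the homology search output into the phyletic pattern analysed by the
#' gain/loss reconstruction.
#'
#' @param assignments A data frame with columns `taxon` and `family`
#'   (`NA` family rows, i.e. unassigned candidates, are ignored), as
#'   returned by [identify_members()].
#' @param taxa Ordered character vector of all taxa (rows).
#' @param characters Ordered character vector of all family members
#'   (columns).
#' @return A [phyletic_matrix].
#' @export
matrix_from_assignments <- function(assignments, taxa, characters) {
  stopifnot(is.data.frame(assignments),
            all(c("taxon", "family") %in% names(assignments)))
  hit <- assignments[!is.na(assignments$family), , drop = FALSE]
  if (nrow(hit)) {
    if (!all(hit$taxon %in% taxa)) {
      stop("assignment references unknown taxon: ",
           paste(setdiff(hit$taxon, taxa), collapse = ", "), call. = FALSE)
    }
    if (!all(hit$family %in% characters)) {
      stop("assignment references unknown character: ",
           paste(setdiff(hit$family, characters), collapse = ", "), call. = FALSE)
    }
  }
  states <- matrix("absent", nrow = length(taxa), ncol = length(characters),
                   dimnames = list(taxa, characters))
  if (nrow(hit)) {
    states[cbind(match(hit$taxon, taxa), match(hit$family, characters))] <- "present"
  }
  phyletic_matrix(states)
}
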