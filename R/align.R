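AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Default protein scoring scheme
#'
#' BLOSUM62 with affine gap penalties (opening 11, extension 1 per gapped
#' position), the standard protein-search default. The ambiguity residue
#' `X` scores 0 against everything.
#'
#' @param gap_open Gap opening penalty (>= 0).
#' @param gap_extend Gap extension penalty per gapped position (>= 0).
#' @return A list with elements `matrix`, `gap_open`, `gap_extend`.
#' @export
default_scoring <- function(gap_open = 11, gap_extend = 1) {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  m["X", ] <- 0
  m[, "X"] <- 0
  scoring(m, gap_open, gap_extend)
}

#' Build a scoring scheme from a substitution matrix
#' @param matrix Square numeric substitution matrix with residue dimnames.
#' @param gap_open,gap_extend Nonnegative affine gap penalties; a gap of
#'   length L costs `gap_open + L * gap_extend`.
#' @return A list with elements `matrix`, `gap_open`, `gap_extend`.
#' @export
scoring <- function(matrix, gap_open = 11, gap_extend = 1) {
  stopifnot(is.matrix(matrix), !is.null(dimnames(matrix)),
            gap_open >= 0, gap_extend >= 0)
  list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend)
}

check_protein <- function(seq, alphabet = c(AA20, "X")) {
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% alphabet)
  if (length(bad)) {
    stop("illegal residue '", chars[bad[1L]], "' at position ", bad[1L],
         call. = FALSE)
  }
  invisible(seq)
}

#' Optimal local (Smith-Waterman) alignment of two protein sequences
#'
#' Computes the maximum-scoring local alignment under affine gap costs.
#' The score is floored at 0 (the empty alignment); coordinates of the
#' aligned regions are reported 0-based, half-open.
#'
#' @param a,b Protein sequences (strings over the 20 amino acids plus X).
#' @param scoring A scoring scheme from [default_scoring()] or [scoring()].
#' @return List with elements `score` (numeric, >= 0), `a_range` and
#'   `b_range` (integer length-2 vectors, 0-based half-open; `c(0, 0)`
#'   for the empty alignment).
#' @examples
#' local_align("HEAGAWGHEE", "PAWHEAE")$score
#' @export
local_align <- function(a, b, scoring = default_scoring()) {
  stopifnot(is.character(a), length(a) == 1L, nzchar(a),
            is.character(b), length(b) == 1L, nzchar(b))
  alpha <- rownames(scoring$matrix)
  check_protein(a, alpha)
  check_protein(b, alpha)
  p <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "local",
    substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  sc <- Biostrings::score(p)
  if (sc <= 0) {
    return(list(score = 0, a_range = c(0L, 0L), b_range = c(0L, 0L)))
  }
  pr <- p@pattern@range
  sr <- p@subject@range
  list(score = sc,
       a_range = c(pr@start - 1L, pr@start + pr@width - 1L),
       b_range = c(sr@start - 1L, sr@start + sr@width - 1L))
}

local_align_scores <- function(seqs, query, scoring) {
  # vectorized score-only local alignment of many sequences against one query
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(seqs), subject = query, type = "local",
    substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
    scoreOnly = TRUE)
}

panel_self_scores <- function(panel, scoring) {
  vapply(panel, function(q) {
    Biostrings::pairwiseAlignment(
      pattern = q, subject = q, type = "local",
      substitutionMatrix = scoring$matrix,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
      scoreOnly = TRUE)
  }, numeric(1L))
}

#' Assign a candidate protein to a family member
#'
#' The candidate is locally aligned against every query of the panel; the
#' best-scoring query wins. The raw score is normalized by the winning
#' query's self-alignment score, so a candidate identical to a query
#' scores 1. The assignment is dropped (family `NA`) when the normalized
#' score falls below `threshold`. Ties are broken by family name
#' (alphabetical), making the result independent of panel order.
#'
#' @param candidate A protein sequence (string).
#' @param panel Named character vector of query sequences, one per family
#'   member.
#' @param scoring A scoring scheme.
#' @param threshold Minimum normalized score for an assignment (default
#'   0.25).
#' @return List with elements `family` (name or `NA`), `score` (raw) and
#'   `norm_score`.
#' @export
assign_family <- function(candidate, panel, scoring = default_scoring(),
                          threshold = 0.25) {
  stopifnot(length(panel) >= 1L, !is.null(names(panel)))
  panel <- panel[order(names(panel))]
  self <- panel_self_scores(panel, scoring)
  raw <- vapply(panel, function(q) {
    pmax(0, local_align_scores(candidate, q, scoring))
  }, numeric(1L))
  norm <- raw / self
  best <- which.max(norm) # first max = alphabetical tie-break
  if (norm[best] < threshold) {
    return(list(family = NA_character_, score = unname(raw[best]),
                norm_score = unname(norm[best])))
  }
  list(family = names(panel)[best], score = unname(raw[best]),
       norm_score = unname(norm[best]))
}

#' Construct a table of protein records
#'
#' @param id Character vector of sequence identifiers (unique).
#' @param taxon Character vector of taxon names.
#' @param sequence Character vector of protein sequences.
#' @return Data frame with columns `id`, `taxon`, `sequence`.
#' @export
protein_records <- function(id, taxon, sequence) {
  stopifnot(length(id) == length(taxon), length(id) == length(sequence))
  if (anyDuplicated(id)) stop("duplicate record identifiers", call. = FALSE)
  for (s in sequence) check_protein(s)
  data.frame(id = as.character(id), taxon = as.character(taxon),
             sequence = as.character(sequence), stringsAsFactors = FALSE)
}

#' Identify family members in a set of candidate proteins
#'
#' Runs [assign_family()] on every record, vectorizing the alignment per
#' panel query.
#'
#' @param records Protein records ([protein_records()]).
#' @param panel Named character vector of query sequences.
#' @param scoring A scoring scheme.
#' @param threshold Minimum normalized score.
#' @return Data frame with columns `id`, `taxon`, `family` (`NA` when no
#'   query reaches the threshold), `score`, `norm_score`.
#' @export
identify_members <- function(records, panel, scoring = default_scoring(),
                             threshold = 0.25) {
  stopifnot(is.data.frame(records), length(panel) >= 1L)
  panel <- panel[order(names(panel))]
  self <- panel_self_scores(panel, scoring)
  if (!nrow(records)) {
    return(data.frame(id = character(0), taxon = character(0),
                      family = character(0), score = numeric(0),
                      norm_score = numeric(0)))
  }
  for (s in records$sequence) check_protein(s, rownames(scoring$matrix))
  norm <- sapply(seq_along(panel), function(k) {
    pmax(0, local_align_scores(records$sequence, panel[[k]], scoring)) / self[k]
  })
  norm <- matrix(norm, nrow = nrow(records))
  best <- apply(norm, 1L, which.max)
  best_norm <- norm[cbind(seq_len(nrow(norm)), best)]
  fam <- names(panel)[best]
  fam[best_norm < threshold] <- NA_character_
  data.frame(id = records$id, taxon = records$taxon, family = fam,
             score = best_norm * self[best], norm_score = best_norm,
             stringsAsFactors = FALSE)
}

#' Remove redundant and partial sequences
#'
#' Within each taxon, drops exact duplicates and "partials": sequences
#' whose best local alignment to a longer kept sequence of the same taxon
#' covers at least `identity_threshold` of their own length at an identity
#' of at least `identity_threshold`. The longest representative is kept;
#' processing order (length descending, then identifier) makes the result
#' deterministic.
#'
#' @param records Protein records.
#' @param identity_threshold Fraction in (0, 1]; default 0.9.
#' @param scoring A scoring scheme.
#' @return The retained records, in the deterministic processing order.
#' @export
dedupe <- function(records, identity_threshold = 0.9,
                   scoring = default_scoring()) {
  stopifnot(is.data.frame(records), identity_threshold > 0,
            identity_threshold <= 1)
  if (!nrow(records)) return(records)
  ord <- order(-nchar(records$sequence), records$id)
  records <- records[ord, , drop = FALSE]
  keep <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    cand <- records$sequence[i]
    redundant <- FALSE
    for (j in which(keep & records$taxon == records$taxon[i])) {
      kept <- records$sequence[j]
      if (identical(cand, kept)) { redundant <- TRUE; break }
      p <- Biostrings::pairwiseAlignment(
        pattern = cand, subject = kept, type = "local",
        substitutionMatrix = scoring$matrix,
        gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
      alen <- Biostrings::nchar(p)
      if (alen == 0L) next
      coverage <- alen / nchar(cand)
      identity <- Biostrings::nmatch(p) / alen
      if (coverage >= identity_threshold && identity >= identity_threshold) {
        redundant <- TRUE
        break
      }
    }
    keep[i] <- !redundant
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a proteome FASTA file as protein records
#'
#' @param path FASTA file (plain headers; wrapped or unwrapped lines).
#' @param taxon Taxon name for all records; defaults to the file name
#'   without extension.
#' @return Protein records data frame.
#' @export
read_proteome <- function(path, taxon = NULL) {
  if (is.null(taxon)) {
    taxon <- sub("\\.[^.]*$", "", basename(path))
  }
  ss <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  protein_records(ids, rep(taxon, length(ss)), as.character(ss))
}

#' Read a query panel FASTA file
#'
#' Each record's header (first whitespace-delimited word) is the family
#' member name.
#'
#' @param path FASTA file.
#' @return Named character vector of query sequences.
#' @export
read_panel <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write sequences to a FASTA file
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
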