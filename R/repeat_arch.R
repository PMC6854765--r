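#' Apolipoprotein gene repeat-block architecture
#'
#' Exchangeable apolipoprotein genes share a modular mature-peptide
#' region: one 33-codon block plus a variable number of 22- and 11-codon
#' amphipathic repeat units, packaged in a gene model with a fixed
#' intron/exon count. An architecture records those counts; unit order is
#' not modeled (the event calculus works on unit multisets).
#'
#' @param name Gene name.
#' @param introns Nonnegative intron count.
#' @param exons Nonnegative exon count; for a linear gene model
#'   `exons == introns + 1` (violations error).
#' @param units Integer vector over `c(33, 22, 11)`: the repeat units of
#'   the mature-peptide region. Exactly one 33-codon block is the family
#'   rule; a different count triggers a warning, not an error.
#' @return Object of class `repeat_architecture`.
#' @examples
#' repeat_architecture("ApoA-I", 3, 4, c(33, rep(22, 3), rep(11, 12)))
#' @export
repeat_architecture <- function(name, introns, exons, units) {
  stopifnot(is.character(name), length(name) == 1L,
            introns >= 0, exons >= 0)
  units <- as.integer(units)
  if (!all(units %in% c(33L, 22L, 11L))) {
    stop("repeat units must be 33, 22 or 11 codons", call. = FALSE)
  }
  if (exons != introns + 1) {
    stop("linear gene model requires exons == introns + 1", call. = FALSE)
  }
  if (sum(units == 33L) != 1L) {
    warning("architecture '", name, "' has ", sum(units == 33L),
            " 33-codon blocks; the family rule is exactly one", call. = FALSE)
  }
  structure(list(name = name, introns = as.integer(introns),
                 exons = as.integer(exons), units = units),
            class = "repeat_architecture")
}

#' @export
print.repeat_architecture <- function(x, ...) {
  cat("repeat_architecture '", x$name, "': ", x$introns, " introns / ",
      x$exons, " exons; units 33x", sum(x$units == 33L),
      " 22x", sum(x$units == 22L), " 11x", sum(x$units == 11L), "\n", sep = "")
  invisible(x)
}

unit_counts <- function(arch) {
  c(`33` = sum(arch$units == 33L),
    `22` = sum(arch$units == 22L),
    `11` = sum(arch$units == 11L))
}

#' Minimal event list transforming one architecture into another
#'
#' Works per unit size on multisets: if `b` has more units of a size than
#' `a`, the difference is that many duplications; fewer, that many
#' deletions. Intron-count differences become intron gain/loss events.
#' Output order is fixed: 33-, 22-, then 11-codon unit events, then
#' intron events.
#'
#' @param a,b [repeat_architecture]s (transforming `a` into `b`).
#' @return Data frame with columns `kind` (`duplicate_unit`,
#'   `delete_unit`, `gain_intron`, `lose_intron`), `size` (33/22/11, `NA`
#'   for intron events) and `count` (positive integer); zero rows when the
#'   architectures match.
#' @examples
#' archs <- apo_architectures()
#' architecture_diff(archs[["Ancestral"]], archs[["ApoA-IV"]])
#' @export
architecture_diff <- function(a, b) {
  stopifnot(inherits(a, "repeat_architecture"),
            inherits(b, "repeat_architecture"))
  rows <- list()
  ca <- unit_counts(a)
  cb <- unit_counts(b)
  for (size in c(33L, 22L, 11L)) {
    delta <- cb[[as.character(size)]] - ca[[as.character(size)]]
    if (delta > 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "duplicate_unit", size = size, count = delta)
    } else if (delta < 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "delete_unit", size = size, count = -delta)
    }
  }
  di <- b$introns - a$introns
  if (di > 0) {
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "gain_intron", size = NA_integer_, count = di)
  } else if (di < 0) {
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "lose_intron", size = NA_integer_, count = -di)
  }
  if (!length(rows)) {
    return(data.frame(kind = character(0), size = integer(0),
                      count = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Total number of events in an event list
#' @param events Data frame from [architecture_diff()].
#' @return Nonnegative integer (sum of the `count` column).
#' @export
event_count <- function(events) {
  stopifnot(is.data.frame(events))
  if (!nrow(events)) return(0L)
  sum(as.integer(events$count))
}

#' Packaged apolipoprotein gene architectures
#'
#' The ten family-member architectures plus two reconstructed ancestors
#' (`Ancestral`, the ApoA-I-like primordial gene, and `ApoC-ancestral`,
#' the common ancestor of the ApoC genes), encoding the documented
#' duplication/deletion scenario: ApoA-I keeps the ancestral structure;
#' ApoA-IV lost the first intron and gained three 22- and one 11-codon
#' duplications; ApoE derives from the ApoA-I lineage by one 22- and one
#' 11-codon duplication; ApoA-V from the ApoA-IV lineage by one 11-codon
#' duplication (regaining the 3-intron layout); the ApoA-II/ApoC ancestor
#' underwent eleven 11-codon deletions (ten or eleven are equally
#' consistent; eleven is encoded, see the packaged file's comments); ApoC-II
#' and ApoC-I deleted one and two 22-codon repeats respectively after a
#' shared 11-codon duplication; ApoC-III deleted and ApoC-IV duplicated
#' an 11-codon unit. Intron counts follow the printed gene models: three
#' introns/four exons everywhere except ApoA-IV and ApoC-IV (two
#' introns/three exons).
#'
#' @return Named list of [repeat_architecture] objects.
#' @export
apo_architectures <- function() {
  path <- system.file("extdata", "apo_architectures.txt",
                      package = "apoevol", mustWork = TRUE)
  read_architectures(path)
}

#' Read architectures from a key-value text file
#'
#' Blocks separated by blank lines; keys `name`, `introns`, `exons`,
#' `units` (comma-separated 33/22/11 sizes). Lines starting with `#` are
#' comments.
#'
#' @param path Input file.
#' @return Named list of [repeat_architecture] objects.
#' @export
read_architectures <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  blocks <- split(lines, cumsum(!nzchar(trimws(lines))))
  out <- list()
  for (bl in blocks) {
    bl <- bl[nzchar(trimws(bl))]
    if (!length(bl)) next
    kv <- strsplit(bl, ":", fixed = TRUE)
    keys <- trimws(vapply(kv, `[[`, character(1L), 1L))
    vals <- trimws(vapply(kv, function(x) paste(x[-1L], collapse = ":"),
                          character(1L)))
    rec <- stats::setNames(vals, keys)
    need <- c("name", "introns", "exons", "units")
    if (!all(need %in% keys)) {
      stop("architecture block missing key(s): ",
           paste(setdiff(need, keys), collapse = ", "), call. = FALSE)
    }
    arch <- repeat_architecture(
      rec[["name"]], as.integer(rec[["introns"]]), as.integer(rec[["exons"]]),
      as.integer(strsplit(rec[["units"]], ",", fixed = TRUE)[[1L]]))
    out[[arch$name]] <- arch
  }
  out
}

#' Write architectures to the key-value text format
#' @param archs Named list of [repeat_architecture] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_architectures <- function(archs, path) {
  blocks <- vapply(archs, function(a) {
    paste0("name: ", a$name, "\n",
           "introns: ", a$introns, "\n",
           "exons: ", a$exons, "\n",
           "units: ", paste(a$units, collapse = ","))
  }, character(1L))
  writeLines(paste(blocks, collapse = "\n\n"), path)
  invisible(path)
}
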