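#' Round half away from zero
#'
#' Presentation rounding used for report tables: ties go away from zero
#' (2.345 -> 2.35), unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @export
#' @examples
#' roundHalfUp(c(0.125, -0.125), 2)
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

## amino-acid alphabet used throughout (20 standard residues)
.AA_LETTERS <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

## Validate a residue string; returns the string or stops with the first
## offending position named, e.g. "unknown residue 'B' at position 3".
.checkResidues <- function(x, what = "sequence") {
  if (length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop(what, " must be a single non-empty string", call. = FALSE)
  }
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% .AA_LETTERS))
  if (length(bad)) {
    stop(sprintf("unknown residue '%s' at position %d of %s",
                 chars[bad[1L]], bad[1L], what), call. = FALSE)
  }
  invisible(x)
}

.splitResidues <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

## path to a packaged data file
.extdata <- function(...) {
  path <- system.file("extdata", ..., package = "pepflux", mustWork = TRUE)
  path
}

## read a tabular file, dialect chosen from the extension (.csv vs .tsv/.txt)
.readTable <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    comment.char = "", quote = "\"")
}

.writeTable <- function(x, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(x, path, sep = sep, row.names = FALSE, quote = FALSE)
}
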