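#' Construct a ProteinSequence
#'
#' @param identifier sequence name.
#' @param residues 1-letter-code residue string (20 standard amino acids).
#' @param provenance free-text origin note.
#' @return a [ProteinSequence-class] object.
#' @export
#' @examples
#' ProteinSequence("toy", "AAFAA")
ProteinSequence <- function(identifier, residues,
                            provenance = NA_character_) {
  new("ProteinSequence",
      identifier = as.character(identifier),
      residues = toupper(as.character(residues)),
      provenance = as.character(provenance))
}

#' Read a protein sequence from a FASTA file
#'
#' Reads single- or multi-record FASTA; the first record is used unless a
#' record is named via `id` (matched against the FASTA headers).
#'
#' @param path path to a FASTA file.
#' @param id optional identifier (substring-matched against headers).
#' @return a [ProteinSequence-class].
#' @importFrom Biostrings readAAStringSet
#' @export
readProteinFasta <- function(path, id = NULL) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no records in FASTA file: ", path)
  idx <- 1L
  if (!is.null(id)) {
    hit <- grep(id, names(set), fixed = TRUE)
    if (!length(hit)) stop("no FASTA record matching identifier: ", id)
    idx <- hit[1L]
  }
  header <- names(set)[idx]
  ProteinSequence(identifier = strsplit(header, "\\s+")[[1L]][1L],
                  residues = as.character(set[[idx]]),
                  provenance = header)
}

#' The bundled mature bovine serum albumin chain
#'
#' Mature BSA (UniProt P02769 precursor residues 25-607): 583 residues and
#' hence 582 peptide bonds, the substrate arithmetic that all digestion
#' calibrations in this package rest on.
#'
#' @return a [ProteinSequence-class] of length 583.
#' @export
#' @examples
#' nBonds(bsaMature())
bsaMature <- function() {
  readProteinFasta(.extdata("bsa_mature.fasta"))
}

#' @rdname ProteinSequence-class
#' @export
setMethod("identifier", "ProteinSequence", function(x) x@identifier)

#' @rdname ProteinSequence-class
#' @export
setMethod("residues", "ProteinSequence", function(x) x@residues)

#' @rdname ProteinSequence-class
#' @export
setMethod("provenance", "ProteinSequence", function(x) x@provenance)

#' @rdname ProteinSequence-class
#' @export
setMethod("nBonds", "ProteinSequence", function(x) nchar(x@residues) - 1L)

#' @rdname ProteinSequence-class
#' @export
setMethod("length", "ProteinSequence", function(x) nchar(x@residues))

setMethod("show", "ProteinSequence", function(object) {
  n <- nchar(object@residues)
  head <- substr(object@residues, 1L, 12L)
  cat("ProteinSequence", object@identifier, "\n",
      "  ", n, " residues (", n - 1L, " peptide bonds): ",
      head, if (n > 12L) "..." else "", "\n", sep = "")
  if (!is.na(object@provenance))
    cat("  provenance: ", object@provenance, "\n", sep = "")
})
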