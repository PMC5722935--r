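#' Enumerate candidate peptides from a digested protein
#'
#' Produces the theoretical peptide pool used for FindPept-style mass
#' identification. Three specificity modes:
#' \describe{
#'   \item{specific}{fragments bounded by cleavage sites or chain termini,
#'     with at most `maxMissed` internal (missed) sites;}
#'   \item{semi-specific}{peptides with at least one terminus at a cleavage
#'     boundary;}
#'   \item{non-specific}{every substring of length >= `minLength`.}
#' }
#' Output is duplicate-free on (start, end) and sorted by start, then end.
#' Flanking residues are reported with "-" at the chain termini. Each row
#' carries the singly protonated monoisotopic mass.
#'
#' Non-specific and semi-specific enumeration is quadratic in chain length
#' and therefore refuses parents longer than `maxParent` residues.
#'
#' @param protein a [ProteinSequence-class].
#' @param map a [CleavageMap-class] for the same protein.
#' @param minLength minimum peptide length in residues (default 3).
#' @param mode specificity mode, see above.
#' @param maxMissed maximum missed cleavages (specific mode).
#' @param maxParent combinatorial guard for the quadratic modes.
#' @return data.frame: sequence, start, end, prev, foll, length, missed,
#'   specificity, mass.
#' @export
#' @examples
#' p <- ProteinSequence("toy", "AAFAA")
#' m <- findCleavageSites(p)
#' enumeratePeptides(p, m, minLength = 1, mode = "specific")
enumeratePeptides <- function(protein, map,
                              minLength = 3L,
                              mode = c("specific", "semi-specific",
                                       "non-specific"),
                              maxMissed = 0L,
                              maxParent = 1000L) {
  mode <- match.arg(mode)
  stopifnot(is(protein, "ProteinSequence"), is(map, "CleavageMap"))
  if (map@protein@residues != protein@residues)
    stop("cleavage map was computed for a different sequence")
  if (minLength < 1L) stop("minLength must be >= 1")
  if (maxMissed < 0L) stop("maxMissed must be >= 0")
  n <- nchar(protein@residues)
  if (mode != "specific" && n > maxParent)
    stop(sprintf(paste0(
      "%s enumeration of a %d-residue chain is quadratic; ",
      "raise maxParent (currently %d) to force it"),
      mode, n, maxParent))
  sites <- map@sites
  ## cumSites[i + 1] = number of cleavable bonds among bonds 1..i
  cumSites <- c(0L, cumsum(tabulate(sites, nbins = max(n - 1L, 1L))))

  if (mode == "specific") {
    b <- c(0L, sites, n)  # boundary "bonds": bond 0 and bond n are termini
    nb <- length(b)
    i <- rep(seq_len(nb - 1L), each = nb - 1L)
    j <- rep(seq_len(nb - 1L) + 1L, times = nb - 1L)
    keep <- j > i & (j - i - 1L) <= maxMissed & j <= nb
    i <- i[keep]; j <- j[keep]
    start <- b[i] + 1L
    end <- b[j]
  } else if (mode == "non-specific") {
    len <- minLength:n
    counts <- n - len + 1L
    start <- sequence(counts)
    end <- start + rep(len, counts) - 1L
  } else {
    startsAt <- c(0L, sites) + 1L           # starts licensed by a boundary
    endsAt <- c(sites, n)                   # ends licensed by a boundary
    s1 <- rep(startsAt, times = pmax(n - startsAt + 1L, 0L))
    e1 <- unlist(lapply(startsAt, function(s) seq.int(s, n)), use.names = FALSE)
    e2 <- rep(endsAt, times = endsAt)
    s2 <- unlist(lapply(endsAt, function(e) seq_len(e)), use.names = FALSE)
    start <- c(s1, s2)
    end <- c(e1, e2)
  }

  len <- end - start + 1L
  keep <- len >= minLength
  start <- start[keep]; end <- end[keep]
  key <- (start - 1) * (n + 1) + end
  dup <- duplicated(key)
  start <- start[!dup]; end <- end[!dup]
  ord <- order(start, end)
  start <- start[ord]; end <- end[ord]

  chars <- .splitResidues(protein@residues)
  cm <- .massCumsum(chars)
  missed <- cumSites[end] - cumSites[start]  # sites strictly inside [start,end]
  data.frame(
    sequence = substring(protein@residues, start, end),
    start = start, end = end,
    prev = ifelse(start == 1L, "-", chars[pmax(start - 1L, 1L)]),
    foll = ifelse(end == n, "-", chars[pmin(end + 1L, n)]),
    length = end - start + 1L,
    missed = as.integer(missed),
    specificity = mode,
    mass = cm[end + 1L] - cm[start] + .MASS_WATER_MONO + .MASS_PROTON,
    stringsAsFactors = FALSE)
}

#' Flank notation used in identification reports
#'
#' Renders "(X)/PEPTIDE/(Y)" with "-" for chain termini.
#'
#' @param prev,foll single flanking residues (or "-").
#' @param sequence peptide sequence.
#' @return character vector.
#' @export
flankNotation <- function(prev, sequence, foll) {
  sprintf("(%s)/%s/(%s)", prev, sequence, foll)
}
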