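## Kyte-Doolittle hydropathy scale
.KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Grand average of hydropathy (GRAVY)
#'
#' Arithmetic mean of Kyte-Doolittle hydropathy values over a peptide's
#' residues; bounded by the scale extremes [-4.5, 4.5]. Vectorised.
#'
#' @param sequence character vector of peptide sequences.
#' @return numeric vector of GRAVY scores.
#' @export
#' @examples
#' gravy(c("LLL", "IAF"))   # 3.80, 3.03
gravy <- function(sequence) {
  vapply(sequence, function(s) {
    .checkResidues(s)
    mean(.KYTE_DOOLITTLE[.splitResidues(s)])
  }, numeric(1L), USE.NAMES = FALSE)
}

#' Load a pKa table
#'
#' A pKa table names the ionisation constants of the free termini and the
#' seven ionisable side chains (D, E, C, Y, H, K, R). Packaged tables:
#' `"table1"` (the package default, calibrated so that net charges at pH 2
#' and pH 10 reproduce the bundled peptide reference table; see the
#' vignette), `"emboss"`, `"sillero"`, `"lehninger"`. A path to a YAML
#' file with the same schema is also accepted.
#'
#' @param name packaged table name or YAML path.
#' @return named numeric vector with elements nterm, cterm, D, E, C, Y,
#'   H, K, R.
#' @export
pkaTable <- function(name = "table1") {
  path <- if (file.exists(name)) name else .extdata("pka", paste0(name, ".yaml"))
  doc <- yaml::read_yaml(path)
  need <- c("nterm", "cterm", "D", "E", "C", "Y", "H", "K", "R")
  vals <- unlist(doc[need])
  if (length(vals) != length(need) || any(!is.finite(vals)))
    stop("pKa table must define: ", paste(need, collapse = ", "))
  if (any(vals <= 0 | vals >= 14))
    stop("pKa values must lie in (0, 14)")
  vals
}

## residue counts of the ionisable side chains
.ionisableCounts <- function(sequence) {
  chars <- .splitResidues(sequence)
  vapply(c("D", "E", "C", "Y", "H", "K", "R"),
         function(a) sum(chars == a), numeric(1L))
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch summation over ionisable groups: the N-terminus
#' and H/K/R side chains contribute `+1 / (1 + 10^(pH - pKa))`, the
#' C-terminus and D/E/C/Y side chains `-1 / (1 + 10^(pKa - pH))`. The
#' result is strictly decreasing in pH. `sequence` and `pH` recycle
#' against each other.
#'
#' @param sequence character vector of peptide sequences.
#' @param pH numeric vector of pH values in [0, 14].
#' @param pka a pKa table from [pkaTable()].
#' @return numeric vector of net charges (elementary charges).
#' @export
#' @examples
#' netCharge("IARRHPYF", 2)   # ~3.90 with the default table
netCharge <- function(sequence, pH, pka = pkaTable()) {
  if (any(pH < 0 | pH > 14)) stop("pH must lie in [0, 14]")
  n <- max(length(sequence), length(pH))
  sequence <- rep_len(sequence, n)
  pH <- rep_len(pH, n)
  vapply(seq_len(n), function(i) {
    .checkResidues(sequence[i])
    cnt <- .ionisableCounts(sequence[i])
    ph <- pH[i]
    pos <- 1 / (1 + 10^(ph - pka["nterm"])) +
      cnt["H"] / (1 + 10^(ph - pka["H"])) +
      cnt["K"] / (1 + 10^(ph - pka["K"])) +
      cnt["R"] / (1 + 10^(ph - pka["R"]))
    neg <- 1 / (1 + 10^(pka["cterm"] - ph)) +
      cnt["D"] / (1 + 10^(pka["D"] - ph)) +
      cnt["E"] / (1 + 10^(pka["E"] - ph)) +
      cnt["C"] / (1 + 10^(pka["C"] - ph)) +
      cnt["Y"] / (1 + 10^(pka["Y"] - ph))
    unname(pos - neg)
  }, numeric(1L))
}

#' Isoelectric point by bisection
#'
#' The pH at which the net charge crosses zero. Because both termini are
#' free, the charge is positive at pH 0 and negative at pH 14 and strictly
#' decreasing in between, so the crossing is unique; it is located by
#' bisection on [0, 14] to `tol` pH units.
#'
#' @param sequence character vector of peptide sequences.
#' @param pka a pKa table from [pkaTable()].
#' @param tol bisection tolerance in pH units (default 1e-3).
#' @return numeric vector of pI values.
#' @export
#' @examples
#' isoelectricPoint("LLL")   # midpoint of the terminal pKas
isoelectricPoint <- function(sequence, pka = pkaTable(), tol = 1e-3) {
  vapply(sequence, function(s) {
    lo <- 0; hi <- 14
    clo <- netCharge(s, lo, pka)
    chi <- netCharge(s, hi, pka)
    if (clo <= 0 || chi >= 0)
      stop("net charge of '", s, "' does not cross zero in [0, 14]")
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (netCharge(s, mid, pka) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1L), USE.NAMES = FALSE)
}

#' Classify a peptide by isoelectric point
#'
#' The grouping used for fractionation analysis: acid for pI < 5.0, basic
#' for pI > 8.0, neutral otherwise (the boundary values fall in the closed
#' neutral interval).
#'
#' @param pI numeric vector of isoelectric points in [0, 14].
#' @return character vector: "acid", "basic" or "neutral".
#' @export
classifyGroup <- function(pI) {
  if (any(pI < 0 | pI > 14)) stop("pI must lie in [0, 14]")
  ifelse(pI < 5, "acid", ifelse(pI > 8, "basic", "neutral"))
}

#' Annotate peptides with physicochemical descriptors
#'
#' Builds an identification-report row per peptide: [M+H]+ monoisotopic
#' mass, GRAVY, net charges at the requested pH values, pI, and the
#' acid/basic/neutral group.
#'
#' @param sequence character vector of peptide sequences.
#' @param prev,foll flanking residues ("-" at termini); optional.
#' @param ph numeric vector of pH values at which to report net charge.
#' @param pka a pKa table from [pkaTable()].
#' @param score optional numeric bioactivity scores in [0, 1], consumed as
#'   data (the package does not compute them).
#' @return data.frame: sequence, prev, foll, flanks, mass, gravy,
#'   `charge_ph<ph>` columns, pI, group, score.
#' @export
annotatePeptides <- function(sequence, prev = "-", foll = "-",
                             ph = c(2, 10), pka = pkaTable(),
                             score = NA_real_) {
  n <- length(sequence)
  if (n == 0L) {
    out <- data.frame(sequence = character(0), prev = character(0),
                      foll = character(0), flanks = character(0),
                      mass = numeric(0), gravy = numeric(0))
    for (p in ph) out[[sprintf("charge_ph%g", p)]] <- numeric(0)
    out$pI <- numeric(0); out$group <- character(0); out$score <- numeric(0)
    return(out)
  }
  prev <- rep_len(prev, n); foll <- rep_len(foll, n)
  score <- rep_len(score, n)
  out <- data.frame(sequence = sequence, prev = prev, foll = foll,
                    flanks = flankNotation(prev, sequence, foll),
                    mass = peptideMass(sequence),
                    gravy = gravy(sequence),
                    stringsAsFactors = FALSE)
  for (p in ph) {
    out[[sprintf("charge_ph%g", p)]] <- netCharge(sequence, p, pka)
  }
  out$pI <- isoelectricPoint(sequence, pka)
  out$group <- classifyGroup(out$pI)
  out$score <- score
  out
}

#' Per-group summary statistics
#'
#' Counts, composition fractions and mean masses per pI group, plus the
#' fraction of peptides whose bioactivity score exceeds a threshold.
#'
#' @param records data.frame with columns `group` and `mass` (and
#'   optionally `score`).
#' @param scoreThreshold bioactivity-score cut-off (default 0.5).
#' @return list with `groups` (data.frame: group, n, fraction (percent),
#'   meanMass) and `highScore` (list: n, fraction in percent; NA without a
#'   score column).
#' @export
groupSummary <- function(records, scoreThreshold = 0.5) {
  if (nrow(records) == 0L)
    return(list(groups = data.frame(group = character(0), n = integer(0),
                                    fraction = numeric(0),
                                    meanMass = numeric(0)),
                highScore = list(n = NA_integer_, fraction = NA_real_)))
  stopifnot(all(c("group", "mass") %in% names(records)))
  N <- nrow(records)
  grp <- split(records$mass, records$group)
  groups <- data.frame(group = names(grp),
                       n = vapply(grp, length, integer(1L)),
                       fraction = 100 * vapply(grp, length, integer(1L)) / N,
                       meanMass = vapply(grp, mean, numeric(1L)),
                       row.names = NULL, stringsAsFactors = FALSE)
  highScore <- list(n = NA_integer_, fraction = NA_real_)
  if ("score" %in% names(records) && any(!is.na(records$score))) {
    nHigh <- sum(records$score > scoreThreshold, na.rm = TRUE)
    highScore <- list(n = nHigh, fraction = 100 * nHigh / N)
  }
  list(groups = groups, highScore = highScore)
}

#' The bundled peptide reference table
#'
#' The 43 uniquely identified BSA peptic peptides with their printed
#' descriptors: [M+H]+ mass, flanking residues, net charges at pH 2 and
#' pH 10, acid/basic/neutral group, GRAVY and bioactivity score (scores
#' are external input data, not computed by this package).
#'
#' @return data.frame with 43 rows and columns mw, prev, sequence, foll,
#'   charge_ph2, charge_ph10, group, gravy, score.
#' @export
peptideReferenceTable <- function() {
  df <- utils::read.table(.extdata("table1_peptides.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE,
                          colClasses = c(group = "character",
                                         prev = "character",
                                         foll = "character",
                                         sequence = "character"))
  df
}
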