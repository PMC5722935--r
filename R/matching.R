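#' Match observed peak masses against a theoretical peptide pool
#'
#' FindPept-style identification: every pool peptide whose mass lies within
#' `tolerance` Da of an observed peak (and whose length is at least
#' `minLength`) is a candidate for that peak. A peak's status is "unique"
#' when its candidates reduce to exactly one distinct sequence (repeat
#' occurrences of the same sequence at different coordinates still count as
#' one), "ambiguous" for two or more distinct sequences and "unmatched"
#' for none. Candidates are sorted by absolute mass error, ties broken by
#' start coordinate. The pool masses must be in the same charge form as
#' the peak list (the package convention is [M+H]+ monoisotopic).
#'
#' @param peaks a [PeakTable-class], or a numeric vector of observed masses.
#' @param pool data.frame with columns `sequence` and `mass` (as produced
#'   by [enumeratePeptides()]; `start`/`end` used when present).
#' @param tolerance absolute mass tolerance in Da (default 0.3).
#' @param minLength minimum candidate sequence length (default 3).
#' @return a [MassMatches-class].
#' @export
matchMasses <- function(peaks, pool, tolerance = 0.3, minLength = 3L) {
  if (is.numeric(peaks)) peaks <- PeakTable(mass = peaks, area = 0)
  stopifnot(is(peaks, "PeakTable"))
  if (tolerance <= 0) stop("tolerance must be > 0")
  p <- peaks@peaks
  if (!is.data.frame(pool) || !all(c("sequence", "mass") %in% names(pool)))
    stop("pool must be a data.frame with columns sequence and mass")
  if (!"start" %in% names(pool)) pool$start <- rep(NA_integer_, nrow(pool))
  if (!"end" %in% names(pool)) pool$end <- rep(NA_integer_, nrow(pool))
  pool <- pool[nchar(pool$sequence) >= minLength, , drop = FALSE]
  if (nrow(pool) == 0L)
    warning("empty peptide pool: every peak is unmatched")

  ord <- order(pool$mass)
  pm <- pool$mass[ord]
  candList <- vector("list", nrow(p))
  status <- character(nrow(p))
  nseq <- integer(nrow(p))
  for (i in seq_len(nrow(p))) {
    obs <- p$mass[i]
    lo <- findInterval(obs - tolerance - 1e-9, pm) + 1L
    hi <- findInterval(obs + tolerance + 1e-9, pm)
    if (hi >= lo && nrow(pool)) {
      idx <- ord[lo:hi]
      delta <- abs(obs - pool$mass[idx])
      keep <- delta <= tolerance
      idx <- idx[keep]; delta <- delta[keep]
    } else {
      idx <- integer(0); delta <- numeric(0)
    }
    if (length(idx)) {
      o <- order(delta, pool$start[idx])
      idx <- idx[o]; delta <- delta[o]
      candList[[i]] <- data.frame(
        peak = i, observed = obs,
        sequence = pool$sequence[idx],
        start = pool$start[idx], end = pool$end[idx],
        mass = pool$mass[idx], delta = delta,
        stringsAsFactors = FALSE)
    }
    nseq[i] <- length(unique(pool$sequence[idx]))
    status[i] <- if (nseq[i] == 0L) "unmatched"
                 else if (nseq[i] == 1L) "unique" else "ambiguous"
  }
  cands <- do.call(rbind, candList)
  if (is.null(cands))
    cands <- data.frame(peak = integer(0), observed = numeric(0),
                        sequence = character(0), start = integer(0),
                        end = integer(0), mass = numeric(0),
                        delta = numeric(0), stringsAsFactors = FALSE)
  summ <- data.frame(
    peak = seq_len(nrow(p)), mass = p$mass, area = p$area,
    intensity = p$intensity, status = status, nSequences = nseq,
    topSequence = vapply(candList, function(d)
      if (is.null(d)) NA_character_ else d$sequence[1L], character(1L)),
    topDelta = vapply(candList, function(d)
      if (is.null(d)) NA_real_ else d$delta[1L], numeric(1L)),
    stringsAsFactors = FALSE)
  new("MassMatches", summary = summ, candidates = cands,
      tolerance = tolerance, minLength = as.integer(minLength))
}

#' @rdname MassMatches-class
#' @export
setMethod("matchSummary", "MassMatches", function(x) x@summary)

#' @rdname MassMatches-class
#' @export
setMethod("matchCandidates", "MassMatches", function(x) x@candidates)

setMethod("show", "MassMatches", function(object) {
  s <- object@summary$status
  cat("MassMatches: ", nrow(object@summary), " peaks (tolerance ",
      object@tolerance, " Da): ", sum(s == "unique"), " unique, ",
      sum(s == "ambiguous"), " ambiguous, ", sum(s == "unmatched"),
      " unmatched\n", sep = "")
})

#' Reconcile hydrolysate and permeate identifications
#'
#' Applies the acceptance rules for an identification campaign: only
#' uniquely matched hydrolysate masses are accepted; ambiguous hydrolysate
#' masses are excluded ("ambiguous"), and masses detected in any permeate
#' with no counterpart (within tolerance) among the hydrolysate peaks are
#' excluded ("permeate-only"). Unmatched hydrolysate masses are logged as
#' "unmatched". Both inputs must come from the same pool and tolerance.
#'
#' @param hydrolysate a [MassMatches-class] for the feed stream.
#' @param permeates a [MassMatches-class] or list of them, one per
#'   permeate condition.
#' @return list with elements `accepted` (data.frame of accepted unique
#'   identifications), `exclusions` (data.frame mass/reason), and `counts`
#'   (named integer vector per reason).
#' @export
reconcileStreams <- function(hydrolysate, permeates = list()) {
  stopifnot(is(hydrolysate, "MassMatches"))
  if (is(permeates, "MassMatches")) permeates <- list(permeates)
  for (p in permeates) {
    stopifnot(is(p, "MassMatches"))
    if (!isTRUE(all.equal(p@tolerance, hydrolysate@tolerance)))
      stop("hydrolysate and permeate matches used different tolerances")
  }
  hs <- hydrolysate@summary
  tol <- hydrolysate@tolerance
  accepted <- hs[hs$status == "unique", , drop = FALSE]
  accepted$sequence <- accepted$topSequence
  excl <- list()
  if (any(hs$status == "ambiguous"))
    excl$ambiguous <- data.frame(mass = hs$mass[hs$status == "ambiguous"],
                                 reason = "ambiguous")
  if (any(hs$status == "unmatched"))
    excl$unmatched <- data.frame(mass = hs$mass[hs$status == "unmatched"],
                                 reason = "unmatched")
  permOnly <- numeric(0)
  for (p in permeates) {
    pm <- p@summary$mass
    inFeed <- vapply(pm, function(m)
      length(hs$mass) > 0 && any(abs(hs$mass - m) <= tol), logical(1L))
    permOnly <- c(permOnly, pm[!inFeed])
  }
  if (length(permOnly))
    excl$permeateOnly <- data.frame(mass = unique(permOnly),
                                    reason = "permeate-only")
  exclusions <- if (length(excl)) do.call(rbind, unname(excl))
                else data.frame(mass = numeric(0), reason = character(0))
  rownames(exclusions) <- NULL
  counts <- c(accepted = nrow(accepted),
              ambiguous = sum(exclusions$reason == "ambiguous"),
              unmatched = sum(exclusions$reason == "unmatched"),
              `permeate-only` = sum(exclusions$reason == "permeate-only"))
  list(accepted = accepted, exclusions = exclusions, counts = counts)
}
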