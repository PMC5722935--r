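#' pH-stat degree-of-hydrolysis parameters
#'
#' Parameter bundle for converting titrant consumption into a degree of
#' hydrolysis: DH(%) = 100 * A * N_A / ((1 - alpha) * h_TOT * M_p), where
#' A is the cumulative titrant volume (mL), N_A the titrant normality
#' (meq/mL), alpha the average dissociation degree of the alpha-carboxylic
#' groups released at the working pH, h_TOT the total peptide-bond content
#' of the substrate (meq/g protein) and M_p the protein mass (g). The
#' defaults are the serum-albumin study conditions: N_A = 0.1 meq/mL,
#' alpha = 0.325, h_TOT = 8.8 meq/g, M_p = 3 g.
#'
#' @param nA titrant normality, meq/mL (> 0).
#' @param alpha average dissociation degree, in [0, 1).
#' @param hTot total peptide-bond content, meq/g protein (> 0).
#' @param mP protein mass, g (> 0).
#' @return a validated parameter list of class "DhParameters".
#' @export
dhParameters <- function(nA = 0.1, alpha = 0.325, hTot = 8.8, mP = 3) {
  if (nA <= 0) stop("titrant normality nA must be > 0")
  if (alpha < 0 || alpha >= 1)
    stop("alpha must lie in [0, 1): alpha = 1 makes DH undefined")
  if (hTot <= 0) stop("hTot must be > 0")
  if (mP <= 0) stop("protein mass mP must be > 0")
  structure(list(nA = nA, alpha = alpha, hTot = hTot, mP = mP),
            class = "DhParameters")
}

#' Degree of hydrolysis from titrant consumption
#'
#' Linear in A and N_A, inversely proportional to M_p. Vectorised over A.
#'
#' @param A cumulative titrant volume(s), mL (>= 0).
#' @param params a [dhParameters()] list.
#' @return DH in percent.
#' @export
#' @examples
#' dhFromTitration(10, dhParameters())   # 5.6117 %
dhFromTitration <- function(A, params = dhParameters()) {
  if (!inherits(params, "DhParameters")) params <- do.call(dhParameters, params)
  if (any(A < 0)) stop("titrant volume A must be >= 0")
  100 * (A * params$nA) / ((1 - params$alpha) * params$hTot * params$mP)
}

#' Degree of hydrolysis relative to the theoretical maximum
#'
#' @param dh DH in percent.
#' @param dhMax theoretical maximum DH in percent (> 0); a
#'   [CleavageMap-class] is also accepted and its DH_max used.
#' @return 100 * dh / dhMax, in percent of the attainable ceiling.
#' @export
relativeDh <- function(dh, dhMax) {
  if (is(dhMax, "CleavageMap")) dhMax <- dhMax(dhMax)
  if (!is.numeric(dhMax) || dhMax <= 0) stop("dhMax must be > 0")
  100 * dh / dhMax
}

#' Assemble a hydrolysis curve from a pH-stat series
#'
#' Maps each (time, cumulative volume) record through [dhFromTitration()]
#' and [relativeDh()]. A decreasing titrant volume between consecutive
#' points is instrument jitter: the series is clamped to its running
#' maximum with a warning, never silently. The plateau onset is the first
#' time after which every subsequent relative-DH gain, expressed per
#' `plateauInterval` minutes, stays below `plateauGain` percentage points.
#'
#' @param series data.frame with columns `time_min` (sorted ascending) and
#'   `volume_mL`.
#' @param params a [dhParameters()] list.
#' @param dhMax theoretical maximum DH (percent) or a [CleavageMap-class].
#' @param plateauGain plateau threshold, relative-DH points per interval
#'   (default 1).
#' @param plateauInterval interval length in minutes (default 15, the
#'   usual pH-stat sampling grid).
#' @return a [HydrolysisCurve-class].
#' @export
buildCurve <- function(series, params = dhParameters(), dhMax,
                       plateauGain = 1, plateauInterval = 15) {
  stopifnot(all(c("time_min", "volume_mL") %in% names(series)))
  if (is.unsorted(series$time_min))
    stop("series must be sorted by time")
  if (is(dhMax, "CleavageMap")) dhMax <- dhMax(dhMax)
  vol <- series$volume_mL
  if (any(diff(vol) < 0)) {
    warning("non-monotone titrant volumes clamped to their running maximum")
    vol <- cummax(vol)
  }
  dh <- dhFromTitration(vol, params)
  rel <- relativeDh(dh, dhMax)
  pts <- data.frame(time_min = series$time_min, volume_mL = vol,
                    dh = dh, relative_dh = rel)
  plateau <- NA_real_
  n <- nrow(pts)
  if (n >= 2L) {
    rate <- diff(rel) / diff(pts$time_min) * plateauInterval
    below <- rev(cumprod(rev(rate < plateauGain))) == 1  # all later rates below
    if (any(below)) plateau <- pts$time_min[which(below)[1L]]
  }
  new("HydrolysisCurve", points = pts,
      params = unclass(params), dhMax = dhMax, plateauTime = plateau)
}

#' @rdname HydrolysisCurve-class
#' @export
setMethod("curvePoints", "HydrolysisCurve", function(x) x@points)

#' @rdname HydrolysisCurve-class
#' @export
setMethod("plateauTime", "HydrolysisCurve", function(x) x@plateauTime)

setMethod("show", "HydrolysisCurve", function(object) {
  p <- object@points
  cat("HydrolysisCurve: ", nrow(p), " points over ",
      if (nrow(p)) max(p$time_min) else 0, " min; final DH ",
      if (nrow(p)) sprintf("%.2f%% (%.2f%% of DH_max %.2f%%)",
                           p$dh[nrow(p)], p$relative_dh[nrow(p)],
                           object@dhMax) else "NA", "\n",
      "  plateau onset: ",
      if (is.na(object@plateauTime)) "not reached"
      else paste0(object@plateauTime, " min"), "\n", sep = "")
})
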