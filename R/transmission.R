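#' Construct a MembraneSpec
#'
#' @param name membrane label, e.g. "PES5".
#' @param mwco nominal molecular weight cut-off in Da.
#' @param material membrane material (default polyethersulfone).
#' @return a [MembraneSpec-class].
#' @export
#' @examples
#' membraneSpec("PES5", 5000)
membraneSpec <- function(name, mwco, material = "polyethersulfone") {
  new("MembraneSpec", name = as.character(name), mwco = as.numeric(mwco),
      material = as.character(material))
}

#' @rdname MembraneSpec-class
#' @export
setMethod("mwco", "MembraneSpec", function(x) x@mwco)

setMethod("show", "MembraneSpec", function(object) {
  cat("MembraneSpec ", object@name, ": MWCO ", object@mwco, " Da (",
      object@material, ")\n", sep = "")
})

#' Observed transmission
#'
#' Tr_obs(%) = 100 * A_permeate / A_hydrolysate from paired peak areas of
#' the same peptide. Values above 100% are quantitation anomalies of
#' area-based chromatography; they are returned as-is (flag them
#' downstream rather than truncating). Vectorised.
#'
#' @param areaPermeate permeate peak area(s), >= 0.
#' @param areaHydrolysate feed peak area(s), > 0.
#' @return transmission in percent.
#' @export
#' @examples
#' trObserved(50, 100)   # 50 %
trObserved <- function(areaPermeate, areaHydrolysate) {
  if (any(areaHydrolysate <= 0))
    stop("peptide absent from feed: hydrolysate area must be > 0")
  if (any(areaPermeate < 0)) stop("permeate area must be >= 0")
  100 * areaPermeate / areaHydrolysate
}

#' Theoretical sieving transmission
#'
#' Steric (uncharged-sphere) sieving prediction from the solute-to-pore
#' size ratio lambda = (MW / MWCO)^0.4:
#' Tr(%) = 100 * (1 - (lambda * (lambda - 2))^2) * exp(-0.7146 * lambda^2)
#' for lambda < 1, and 0 for lambda >= 1. The clamp is physical: the raw
#' polynomial rebounds to positive values for 1 < lambda < 2, which a
#' sieving coefficient cannot do. Vectorised over `mw`.
#'
#' @param mw peptide molecular weight(s), Da (> 0).
#' @param membrane a [MembraneSpec-class], or the MWCO in Da.
#' @return transmission in percent, in [0, 100].
#' @export
#' @examples
#' trTheoretical(592.30, 5000)   # 48.33 %
trTheoretical <- function(mw, membrane) {
  cut <- if (is(membrane, "MembraneSpec")) membrane@mwco else as.numeric(membrane)
  if (any(mw <= 0)) stop("mw must be > 0")
  if (cut <= 0) stop("MWCO must be > 0")
  lambda <- (mw / cut)^0.4
  tr <- 100 * (1 - (lambda * (lambda - 2))^2) * exp(-0.7146 * lambda^2)
  tr[lambda >= 1] <- 0
  tr
}

#' Separation factor between two peptide groups
#'
#' S_x/y = mean(Tr of group x) / mean(Tr of group y). When the y group
#' mean is zero the factor is infinite; it is returned as `Inf` with
#' attribute `flagged = TRUE`. Undetected peptides should enter the
#' vectors as Tr = 0 when averaging over all group members (the default
#' convention elsewhere in the package).
#'
#' @param trX,trY transmissions (percent) of the peptides in groups x, y.
#' @return the ratio of group means; `Inf` (flagged) when mean(trY) == 0.
#' @export
#' @examples
#' separationFactor(c(50, 50), c(25, 25))   # 2
separationFactor <- function(trX, trY) {
  if (!length(trX) || !length(trY)) stop("both groups must be non-empty")
  mx <- mean(trX); my <- mean(trY)
  if (my == 0) return(structure(Inf, flagged = TRUE))
  mx / my
}

#' Build a per-peptide transmission table for one condition
#'
#' For each identified peptide, locates its feed and permeate peaks by
#' mass (nearest within `tolerance`), computes the observed transmission
#' from the area ratio and the theoretical sieving transmission from the
#' peptide mass and the membrane cut-off. Peptides present in the feed
#' but absent from the permeate get Tr_obs = 0 and `detected = FALSE`;
#' peptides absent from the feed are dropped with a warning.
#'
#' @param ids data.frame with columns `sequence`, `mass` and `group` (as
#'   from [annotatePeptides()]).
#' @param feed hydrolysate [PeakTable-class].
#' @param permeate permeate [PeakTable-class] of the condition.
#' @param membrane a [MembraneSpec-class].
#' @param tolerance mass tolerance (Da) for locating peaks (default 0.3).
#' @return data.frame: sequence, group, mass, membrane, pH, areaFeed,
#'   areaPermeate, trObs, trTheo, detected, anomalous.
#' @export
buildTransmissionTable <- function(ids, feed, permeate, membrane,
                                   tolerance = 0.3) {
  stopifnot(is(feed, "PeakTable"), is(permeate, "PeakTable"),
            is(membrane, "MembraneSpec"))
  stopifnot(all(c("sequence", "mass", "group") %in% names(ids)))
  nearest <- function(mass, tbl) {
    pm <- tbl@peaks$mass
    if (!length(pm)) return(NA_integer_)
    i <- which.min(abs(pm - mass))
    if (abs(pm[i] - mass) <= tolerance) i else NA_integer_
  }
  fi <- vapply(ids$mass, nearest, integer(1L), tbl = feed)
  if (any(is.na(fi)))
    warning(sum(is.na(fi)), " peptide(s) absent from the feed were dropped")
  keep <- !is.na(fi)
  ids <- ids[keep, , drop = FALSE]; fi <- fi[keep]
  pi <- vapply(ids$mass, nearest, integer(1L), tbl = permeate)
  areaFeed <- feed@peaks$area[fi]
  areaPerm <- ifelse(is.na(pi), 0, permeate@peaks$area[pi])
  trObs <- trObserved(areaPerm, areaFeed)
  data.frame(sequence = ids$sequence, group = ids$group, mass = ids$mass,
             membrane = membrane@name, pH = permeate@pH,
             areaFeed = areaFeed, areaPermeate = areaPerm,
             trObs = trObs,
             trTheo = trTheoretical(ids$mass, membrane),
             detected = !is.na(pi) & areaPerm > 0,
             anomalous = trObs > 100,
             stringsAsFactors = FALSE)
}

#' Group-wise separation factors per condition
#'
#' Computes S_x/y for the canonical pairs acid/neutral, acid/basic and
#' basic/neutral within every (membrane, pH) condition of a transmission
#' table. By default undetected peptides contribute Tr = 0 to their group
#' mean (averaging over all group members); `detectedOnly = TRUE` averages
#' over detected peptides only.
#'
#' @param table a transmission table from [buildTransmissionTable()]
#'   (several conditions may be row-bound).
#' @param pairs list of 2-element character vectors of groups.
#' @param detectedOnly average over detected peptides only.
#' @return data.frame: membrane, pH, pair, S, flagged.
#' @export
separationFactors <- function(table,
                              pairs = list(c("acid", "neutral"),
                                           c("acid", "basic"),
                                           c("basic", "neutral")),
                              detectedOnly = FALSE) {
  conds <- unique(table[, c("membrane", "pH")])
  out <- list()
  for (k in seq_len(nrow(conds))) {
    sub <- table[table$membrane == conds$membrane[k] &
                 table$pH == conds$pH[k], , drop = FALSE]
    if (detectedOnly) sub <- sub[sub$detected, , drop = FALSE]
    for (pr in pairs) {
      x <- sub$trObs[sub$group == pr[1L]]
      y <- sub$trObs[sub$group == pr[2L]]
      s <- if (length(x) && length(y)) separationFactor(x, y) else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        membrane = conds$membrane[k], pH = conds$pH[k],
        pair = paste(pr, collapse = "/"), S = as.numeric(s),
        flagged = isTRUE(attr(s, "flagged")), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Per-condition transmission summary
#'
#' Overall and per-group mean observed transmissions for every
#' (membrane, pH) condition, cross-membrane overall ratios at matching pH,
#' and per-peptide observed-minus-theoretical deltas. Row order of the
#' input does not affect any output.
#'
#' @param table a transmission table from [buildTransmissionTable()].
#' @return list with `overall` (membrane, pH, meanTrObs, meanTrTheo, n),
#'   `byGroup` (membrane, pH, group, meanTrObs, n), `membraneRatios`
#'   (pH, membraneX, membraneY, ratio of overall mean Tr_obs) and
#'   `deltas` (per peptide and condition, trObs - trTheo).
#' @export
conditionSummary <- function(table) {
  table <- table[order(table$membrane, table$pH, table$sequence), ,
                 drop = FALSE]
  key <- interaction(table$membrane, table$pH, drop = TRUE)
  overall <- do.call(rbind, lapply(split(table, key), function(d)
    data.frame(membrane = d$membrane[1L], pH = d$pH[1L],
               meanTrObs = mean(d$trObs), meanTrTheo = mean(d$trTheo),
               n = nrow(d), stringsAsFactors = FALSE)))
  rownames(overall) <- NULL
  byGroup <- do.call(rbind, lapply(split(table, key), function(d) {
    g <- split(d$trObs, d$group)
    data.frame(membrane = d$membrane[1L], pH = d$pH[1L], group = names(g),
               meanTrObs = vapply(g, mean, numeric(1L)),
               n = vapply(g, length, integer(1L)),
               stringsAsFactors = FALSE)
  }))
  rownames(byGroup) <- NULL
  ratios <- list()
  for (ph in unique(overall$pH)) {
    mem <- overall[overall$pH == ph, , drop = FALSE]
    if (nrow(mem) >= 2L) {
      cmb <- utils::combn(seq_len(nrow(mem)), 2L)
      for (c_ in seq_len(ncol(cmb))) {
        i <- cmb[1L, c_]; j <- cmb[2L, c_]
        ratios[[length(ratios) + 1L]] <- data.frame(
          pH = ph, membraneX = mem$membrane[i], membraneY = mem$membrane[j],
          ratio = mem$meanTrObs[i] / mem$meanTrObs[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  deltas <- data.frame(sequence = table$sequence, membrane = table$membrane,
                       pH = table$pH, delta = table$trObs - table$trTheo,
                       stringsAsFactors = FALSE)
  list(overall = overall, byGroup = byGroup,
       membraneRatios = if (length(ratios)) do.call(rbind, ratios)
                        else data.frame(pH = numeric(0),
                                        membraneX = character(0),
                                        membraneY = character(0),
                                        ratio = numeric(0)),
       deltas = deltas)
}
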