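#' Construct a PeakTable
#'
#' @param mass numeric vector of observed peak masses (Da, > 0).
#' @param area numeric vector of peak areas (>= 0).
#' @param intensity numeric vector of peak intensities; defaults to `area`
#'   when a peak list reports only areas.
#' @param stream "hydrolysate", "permeate" or "retentate".
#' @param membrane membrane label (NA for unfiltered streams).
#' @param pH numeric pH label.
#' @param replicate integer replicate index.
#' @return a [PeakTable-class].
#' @export
#' @examples
#' PeakTable(mass = c(350.21, 414.20), area = c(100, 40))
PeakTable <- function(mass, area, intensity = area,
                      stream = "hydrolysate", membrane = NA_character_,
                      pH = NA_real_, replicate = 1L) {
  new("PeakTable", stream = stream, membrane = as.character(membrane),
      pH = as.numeric(pH), replicate = as.integer(replicate),
      peaks = data.frame(mass = as.numeric(mass), area = as.numeric(area),
                         intensity = as.numeric(intensity)))
}

#' @rdname PeakTable-class
#' @export
setMethod("peaks", "PeakTable", function(x) x@peaks)

#' @rdname PeakTable-class
#' @export
setMethod("length", "PeakTable", function(x) nrow(x@peaks))

setMethod("show", "PeakTable", function(object) {
  cat("PeakTable: ", nrow(object@peaks), " peaks, stream ", object@stream,
      if (!is.na(object@membrane)) paste0(", membrane ", object@membrane),
      if (!is.na(object@pH)) paste0(", pH ", object@pH),
      "\n", sep = "")
})

#' Read / write peak lists
#'
#' CSV or TSV (chosen from the file extension) with columns `mass`, `area`
#' and optionally `intensity`, `stream`, `membrane`, `pH`, `replicate`.
#' A file must describe a single stream/condition.
#'
#' @param path file path (.csv for comma-, anything else tab-separated).
#' @return `readPeakTable` a [PeakTable-class]; `writePeakTable` the path,
#'   invisibly.
#' @export
readPeakTable <- function(path) {
  df <- .readTable(path)
  if (!all(c("mass", "area") %in% names(df)))
    stop("peak list needs at least columns mass and area: ", path)
  meta <- function(col, default) {
    if (!col %in% names(df)) return(default)
    u <- unique(df[[col]])
    if (length(u) != 1L)
      stop("peak list mixes several values of '", col, "': ", path)
    u
  }
  PeakTable(mass = df$mass, area = df$area,
            intensity = if ("intensity" %in% names(df)) df$intensity else df$area,
            stream = meta("stream", "hydrolysate"),
            membrane = meta("membrane", NA_character_),
            pH = meta("pH", NA_real_),
            replicate = as.integer(meta("replicate", 1L)))
}

#' @rdname readPeakTable
#' @param x a [PeakTable-class].
#' @export
writePeakTable <- function(x, path) {
  df <- x@peaks
  df$stream <- x@stream
  df$membrane <- x@membrane
  df$pH <- x@pH
  df$replicate <- x@replicate
  .writeTable(df, path)
  invisible(path)
}

#' Relative-intensity peak filtering
#'
#' Retains peaks whose intensity is strictly greater than
#' `threshold * max(intensity)` (the base peak itself is always retained),
#' the usual guard against quantifying sparse peptides.
#'
#' @param table a [PeakTable-class].
#' @param threshold relative intensity threshold in (0, 1); default 0.10.
#' @return the filtered [PeakTable-class].
#' @export
filterPeaks <- function(table, threshold = 0.10) {
  stopifnot(is(table, "PeakTable"))
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)")
  p <- table@peaks
  if (nrow(p) == 0L) stop("empty peak table")
  base <- max(p$intensity)
  if (base <= 0) stop("all intensities are zero: no base peak")
  keep <- p$intensity > threshold * base | p$intensity == base
  out <- table
  out@peaks <- p[keep, , drop = FALSE]
  rownames(out@peaks) <- NULL
  out
}

#' Merge peaks within instrument precision
#'
#' Peaks whose masses lie within `tol` of their neighbour (single-linkage
#' on the sorted mass axis) are integrated into one record: areas and
#' intensities are summed and the merged mass is the area-weighted mean
#' (plain mean when the group has zero total area). Emulates chromatogram
#' integration before matching.
#'
#' @param table a [PeakTable-class].
#' @param tol merge tolerance in Da (default 0.005).
#' @return the merged [PeakTable-class].
#' @export
mergePeaks <- function(table, tol = 0.005) {
  stopifnot(is(table, "PeakTable"))
  p <- table@peaks
  if (nrow(p) <= 1L) return(table)
  ord <- order(p$mass)
  p <- p[ord, , drop = FALSE]
  grp <- cumsum(c(1L, as.integer(diff(p$mass) > tol)))
  agg <- function(f, col) as.numeric(tapply(p[[col]], grp, f))
  area <- agg(sum, "area")
  wmass <- vapply(split(seq_len(nrow(p)), grp), function(i) {
    a <- p$area[i]
    if (sum(a) > 0) sum(p$mass[i] * a) / sum(a) else mean(p$mass[i])
  }, numeric(1L))
  out <- table
  out@peaks <- data.frame(mass = unname(wmass), area = area,
                          intensity = agg(sum, "intensity"))
  out
}
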