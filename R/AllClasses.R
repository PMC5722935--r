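#' @import methods
NULL

#' ProteinSequence: a substrate polypeptide
#'
#' Holds a single protein chain as a 1-letter-code residue string together
#' with an identifier and a free-text provenance note. Validity requires at
#' least two residues, all drawn from the 20 standard amino acids, so that
#' the chain has `length - 1 >= 1` peptide bonds.
#'
#' @slot identifier single character, sequence name.
#' @slot residues single character string of 1-letter residue codes.
#' @slot provenance single character, free-text origin note.
#' @export
setClass("ProteinSequence",
  representation(identifier = "character",
                 residues = "character",
                 provenance = "character"))

setValidity("ProteinSequence", function(object) {
  if (length(object@identifier) != 1L || !nzchar(object@identifier))
    return("identifier must be a single non-empty string")
  res <- tryCatch({ .checkResidues(object@residues, "residues"); NULL },
                  error = function(e) conditionMessage(e))
  if (!is.null(res)) return(res)
  if (nchar(object@residues) < 2L)
    return("sequence must contain at least 2 residues (1 peptide bond)")
  TRUE
})

#' CleavageRuleSet: declarative protease specificity
#'
#' A rule set is a list of positional constraints over the P4..P4' context
#' window of a peptide bond. Each rule carries an `action` ("license" or
#' "veto") and a data.frame of constraints with columns `position` (one of
#' P4, P3, P2, P1, P1p, P2p, P3p, P4p), `match` ("in" or "not_in") and
#' `residues` (a string of 1-letter codes). A bond is cleavable when at
#' least one license rule matches and no veto rule matches; veto rules take
#' precedence. The `termini` policy decides how a constraint referring to a
#' position beyond the chain evaluates: under "permissive" a missing
#' position satisfies "not_in" constraints (an absent residue cannot be a
#' forbidden one), under "blocking" it fails every constraint. "in"
#' constraints always require an actual residue.
#'
#' @slot enzyme single character, enzyme name.
#' @slot variant single character, rule-table variant label.
#' @slot termini "permissive" or "blocking".
#' @slot rules list of rules (see description).
#' @export
setClass("CleavageRuleSet",
  representation(enzyme = "character",
                 variant = "character",
                 termini = "character",
                 rules = "list"))

.RULE_POSITIONS <- c("P4", "P3", "P2", "P1", "P1p", "P2p", "P3p", "P4p")

setValidity("CleavageRuleSet", function(object) {
  if (!object@termini %in% c("permissive", "blocking"))
    return("termini must be 'permissive' or 'blocking'")
  if (length(object@rules) == 0L) return("rule set must contain rules")
  for (r in object@rules) {
    if (!is.list(r) || is.null(r$action) || is.null(r$constraints))
      return("each rule needs an action and constraints")
    if (!r$action %in% c("license", "veto"))
      return("rule action must be 'license' or 'veto'")
    cst <- r$constraints
    if (!is.data.frame(cst) ||
        !all(c("position", "match", "residues") %in% names(cst)))
      return("constraints need columns position, match, residues")
    if (!all(cst$position %in% .RULE_POSITIONS))
      return("constraint positions must lie within P4..P4'")
    if (!all(cst$match %in% c("in", "not_in")))
      return("constraint match must be 'in' or 'not_in'")
  }
  TRUE
})

#' CleavageMap: cleavable bonds of a sequence under a rule set
#'
#' Bond i (1-based) joins residues i and i+1, so a chain of n residues has
#' n - 1 bonds. The map stores the cleavable bond indices and houses the
#' theoretical maximum degree of hydrolysis,
#' DH_max = 100 * |sites| / n_bonds.
#'
#' @slot protein the digested [ProteinSequence-class].
#' @slot sites integer vector of cleavable bond indices (sorted, unique).
#' @slot enzyme,variant character, provenance of the rule set used.
#' @export
setClass("CleavageMap",
  representation(protein = "ProteinSequence",
                 sites = "integer",
                 enzyme = "character",
                 variant = "character"))

setValidity("CleavageMap", function(object) {
  nb <- nchar(object@protein@residues) - 1L
  s <- object@sites
  if (any(s < 1L | s > nb)) return("bond indices must lie in [1, n_bonds]")
  if (is.unsorted(s, strictly = TRUE)) return("sites must be sorted and unique")
  TRUE
})

#' PeakTable: one stream's chromatographic peak list
#'
#' Records (mass, area, intensity) triples for one stream of one filtration
#' condition. Mass is the reported (singly protonated) peak mass in Da;
#' area and intensity are arbitrary chromatogram units.
#'
#' @slot stream "hydrolysate", "permeate" or "retentate".
#' @slot membrane membrane label (NA for unfiltered streams).
#' @slot pH numeric pH label (NA when not applicable).
#' @slot replicate integer replicate index.
#' @slot peaks data.frame with columns mass, area, intensity.
#' @export
setClass("PeakTable",
  representation(stream = "character",
                 membrane = "character",
                 pH = "numeric",
                 replicate = "integer",
                 peaks = "data.frame"))

setValidity("PeakTable", function(object) {
  if (!object@stream %in% c("hydrolysate", "permeate", "retentate"))
    return("stream must be hydrolysate, permeate or retentate")
  p <- object@peaks
  if (!all(c("mass", "area", "intensity") %in% names(p)))
    return("peaks need columns mass, area, intensity")
  if (nrow(p)) {
    if (any(!is.finite(p$mass)) || any(p$mass <= 0))
      return("all peak masses must be positive")
    if (any(p$area < 0) || any(p$intensity < 0))
      return("areas and intensities must be non-negative")
  }
  TRUE
})

#' MassMatches: result of matching observed masses against a peptide pool
#'
#' One row of `summary` per observed peak with its match status: "unique"
#' (exactly one distinct candidate sequence within tolerance), "ambiguous"
#' (two or more distinct sequences) or "unmatched". `candidates` holds one
#' row per (peak, candidate peptide) pair, sorted by absolute mass error.
#'
#' @slot summary data.frame: peak, mass, area, intensity, status,
#'   nSequences, topSequence, topDelta.
#' @slot candidates data.frame: peak, observed, sequence, start, end,
#'   mass, delta.
#' @slot tolerance absolute mass tolerance in Da.
#' @slot minLength minimum candidate length in residues.
#' @export
setClass("MassMatches",
  representation(summary = "data.frame",
                 candidates = "data.frame",
                 tolerance = "numeric",
                 minLength = "integer"))

#' MembraneSpec: an ultrafiltration membrane
#'
#' @slot name membrane label, e.g. "PES5".
#' @slot mwco nominal molecular weight cut-off in Da (> 0).
#' @slot material free-text membrane material.
#' @export
setClass("MembraneSpec",
  representation(name = "character", mwco = "numeric", material = "character"))

setValidity("MembraneSpec", function(object) {
  if (length(object@mwco) != 1L || !is.finite(object@mwco) || object@mwco <= 0)
    return("mwco must be a single positive number")
  TRUE
})

#' HydrolysisCurve: a pH-stat degree-of-hydrolysis time course
#'
#' @slot points data.frame: time_min, volume_mL, dh, relative_dh.
#' @slot params the DH parameter list used (see [dhParameters()]).
#' @slot dhMax reference maximum DH in percent.
#' @slot plateauTime first time (min) after which the relative DH gain per
#'   interval stays below the plateau threshold; NA when never reached.
#' @export
setClass("HydrolysisCurve",
  representation(points = "data.frame",
                 params = "list",
                 dhMax = "numeric",
                 plateauTime = "numeric"))
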