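#' @rdname ProteinSequence-class
#' @param object,x an object.
#' @export
setGeneric("identifier", function(x) standardGeneric("identifier"))

#' @rdname ProteinSequence-class
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))

#' @rdname ProteinSequence-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname ProteinSequence-class
#' @export
setGeneric("nBonds", function(x) standardGeneric("nBonds"))

#' @rdname CleavageMap-class
#' @export
setGeneric("cleavageSites", function(x) standardGeneric("cleavageSites"))

#' @rdname CleavageMap-class
#' @export
setGeneric("dhMax", function(x) standardGeneric("dhMax"))

#' @rdname PeakTable-class
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))

#' @rdname MassMatches-class
#' @export
setGeneric("matchSummary", function(x) standardGeneric("matchSummary"))

#' @rdname MassMatches-class
#' @export
setGeneric("matchCandidates", function(x) standardGeneric("matchCandidates"))

#' @rdname MembraneSpec-class
#' @export
setGeneric("mwco", function(x) standardGeneric("mwco"))

#' @rdname HydrolysisCurve-class
#' @export
setGeneric("curvePoints", function(x) standardGeneric("curvePoints"))

#' @rdname HydrolysisCurve-class
#' @export
setGeneric("plateauTime", function(x) standardGeneric("plateauTime"))
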