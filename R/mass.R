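## Residue (monomer) masses in Da. Monoisotopic values to >= 4 decimals;
## a peptide's neutral mass adds one water, the [M+H]+ form one proton.
.MONO_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931)

.AVG_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594,
  N = 114.1038, D = 115.0886, Q = 128.1307, K = 128.1741,
  E = 129.1155, M = 131.1926, H = 137.1411, F = 147.1766,
  R = 156.1875, Y = 163.1760, W = 186.2132)

.MASS_WATER_MONO <- 18.0105646
.MASS_WATER_AVG <- 18.01528
.MASS_PROTON <- 1.0072765

#' Peptide mass
#'
#' Sum of residue masses plus one water, optionally plus one proton for the
#' singly protonated [M+H]+ form that ESI peak lists report. Vectorised
#' over sequences.
#'
#' @param sequence character vector of 1-letter-code peptide sequences.
#' @param kind "monoisotopic" or "average" residue masses.
#' @param form "protonated" ([M+H]+, the default used throughout the
#'   package because identification tables print that form) or "neutral".
#' @return numeric vector of masses in Da.
#' @export
#' @examples
#' peptideMass("IAF")                      # 350.21 at 2 decimals
#' peptideMass("G", form = "neutral")      # glycine + water = 75.0320
peptideMass <- function(sequence,
                        kind = c("monoisotopic", "average"),
                        form = c("protonated", "neutral")) {
  kind <- match.arg(kind)
  form <- match.arg(form)
  tab <- if (kind == "monoisotopic") .MONO_MASS else .AVG_MASS
  water <- if (kind == "monoisotopic") .MASS_WATER_MONO else .MASS_WATER_AVG
  extra <- water + if (form == "protonated") .MASS_PROTON else 0
  vapply(sequence, function(s) {
    .checkResidues(s)
    sum(tab[.splitResidues(s)]) + extra
  }, numeric(1L), USE.NAMES = FALSE)
}

## cumulative residue-mass vector for fast substring masses
.massCumsum <- function(chars, kind = "monoisotopic") {
  tab <- if (kind == "monoisotopic") .MONO_MASS else .AVG_MASS
  c(0, cumsum(tab[chars]))
}
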