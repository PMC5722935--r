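#' Load a cleavage rule set
#'
#' Rule sets are declarative YAML documents (see the packaged pepsin files
#' under `extdata/enzymes/`). `name` may be a packaged rule-set name
#' ("pepsin-ph2", "pepsin-ph1.3") or a path to a YAML file with the same
#' schema.
#'
#' @param name packaged rule-set name or path to a YAML rule file.
#' @return a [CleavageRuleSet-class].
#' @export
#' @examples
#' readCleavageRules("pepsin-ph2")
readCleavageRules <- function(name = "pepsin-ph2") {
  path <- if (file.exists(name)) name else .extdata("enzymes", paste0(name, ".yaml"))
  doc <- yaml::read_yaml(path)
  rules <- lapply(doc$rules, function(r) {
    cst <- do.call(rbind, lapply(r$constraints, function(cc)
      data.frame(position = cc$position, match = cc$match,
                 residues = cc$residues, stringsAsFactors = FALSE)))
    list(action = r$action, constraints = cst)
  })
  new("CleavageRuleSet",
      enzyme = as.character(doc$enzyme),
      variant = as.character(doc$variant),
      termini = if (is.null(doc$termini)) "permissive" else doc$termini,
      rules = rules)
}

#' @rdname readCleavageRules
#' @param variant pepsin rule-table variant.
#' @export
pepsinRules <- function(variant = c("pH>2", "pH1.3")) {
  variant <- match.arg(variant)
  readCleavageRules(if (variant == "pH>2") "pepsin-ph2" else "pepsin-ph1.3")
}

## residue at offset off from bond b: P1 = off 0 maps to residue b,
## P1' = residue b + 1, etc. Returns NA beyond the chain.
.POSITION_OFFSET <- c(P4 = -3L, P3 = -2L, P2 = -1L, P1 = 0L,
                      P1p = 1L, P2p = 2L, P3p = 3L, P4p = 4L)

## Evaluate one constraint for all bonds; `chars` is the residue vector.
.evalConstraint <- function(cst, chars, bonds, permissive) {
  idx <- bonds + .POSITION_OFFSET[[cst$position]]
  res <- rep(NA_character_, length(bonds))
  ok <- idx >= 1L & idx <= length(chars)
  res[ok] <- chars[idx[ok]]
  set <- .splitResidues(cst$residues)
  if (cst$match == "in") {
    out <- res %in% set           # NA (missing residue) never satisfies "in"
  } else {
    out <- !(res %in% set)
    out[is.na(res)] <- permissive # missing residue: policy decides
  }
  out
}

.ruleMatches <- function(rule, chars, bonds, permissive) {
  m <- rep(TRUE, length(bonds))
  for (k in seq_len(nrow(rule$constraints))) {
    m <- m & .evalConstraint(rule$constraints[k, ], chars, bonds, permissive)
    if (!any(m)) break
  }
  m
}

#' Locate cleavable peptide bonds
#'
#' Applies a declarative rule set over every peptide bond of a protein.
#' A bond is cleavable when at least one license rule matches its P4..P4'
#' context and no veto rule matches (veto precedence). Deterministic and
#' idempotent for fixed inputs.
#'
#' @param protein a [ProteinSequence-class].
#' @param rules a [CleavageRuleSet-class] (default: calibrated pepsin pH>2).
#' @return a [CleavageMap-class].
#' @export
#' @examples
#' findCleavageSites(ProteinSequence("toy", "AAFAA"))
findCleavageSites <- function(protein, rules = pepsinRules()) {
  stopifnot(is(protein, "ProteinSequence"), is(rules, "CleavageRuleSet"))
  validObject(protein)
  validObject(rules)
  chars <- .splitResidues(protein@residues)
  bonds <- seq_len(length(chars) - 1L)
  permissive <- rules@termini == "permissive"
  lic <- rep(FALSE, length(bonds))
  veto <- rep(FALSE, length(bonds))
  for (r in rules@rules) {
    m <- .ruleMatches(r, chars, bonds, permissive)
    if (r$action == "license") lic <- lic | m else veto <- veto | m
  }
  new("CleavageMap", protein = protein,
      sites = as.integer(bonds[lic & !veto]),
      enzyme = rules@enzyme, variant = rules@variant)
}

#' @rdname CleavageMap-class
#' @export
setMethod("cleavageSites", "CleavageMap", function(x) x@sites)

#' @rdname CleavageMap-class
#' @export
setMethod("nBonds", "CleavageMap", function(x) nBonds(x@protein))

#' @rdname CleavageMap-class
#' @export
setMethod("dhMax", "CleavageMap", function(x) {
  nb <- nBonds(x@protein)
  if (nb == 0L) stop("protein has no peptide bonds; DH_max undefined")
  100 * length(x@sites) / nb
})

#' Theoretical maximum degree of hydrolysis
#'
#' DH_max(%) = 100 * |cleavable bonds| / n_bonds: the ceiling that a
#' protease of given specificity can reach on a substrate. Unrounded;
#' round only at presentation time.
#'
#' @param map a [CleavageMap-class].
#' @return percent in [0, 100].
#' @export
maxDegreeOfHydrolysis <- function(map) dhMax(map)

setMethod("show", "CleavageMap", function(object) {
  cat("CleavageMap: ", object@enzyme, " (", object@variant, ") on ",
      object@protein@identifier, "\n",
      "  ", length(object@sites), " cleavable of ", nBonds(object),
      " bonds; DH_max = ", sprintf("%.2f", dhMax(object)), "%\n", sep = "")
})

setMethod("show", "CleavageRuleSet", function(object) {
  nl <- sum(vapply(object@rules, function(r) r$action == "license", TRUE))
  cat("CleavageRuleSet: ", object@enzyme, " (", object@variant, "), ",
      nl, " license / ", length(object@rules) - nl, " veto rules, termini ",
      object@termini, "\n", sep = "")
})
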