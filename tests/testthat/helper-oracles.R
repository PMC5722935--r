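## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths: plain loops and direct formula evaluation.

## Pepsin-style site finder: direct per-bond conditional logic, independent
## of the declarative rule engine.
oracleSites <- function(sequence, hydrophobic = "FLWY", permissive = TRUE) {
  chars <- strsplit(sequence, "")[[1L]]
  hyd <- strsplit(hydrophobic, "")[[1L]]
  n <- length(chars)
  at <- function(i) if (i >= 1 && i <= n) chars[i] else NA_character_
  notIn <- function(res, bad) {
    if (is.na(res)) return(permissive)
    !(res %in% strsplit(bad, "")[[1L]])
  }
  out <- integer(0)
  for (b in seq_len(n - 1L)) {
    p1 <- at(b); p2 <- at(b - 1L); p3 <- at(b - 2L)
    p1p <- at(b + 1L); p2p <- at(b + 2L)
    exc <- notIn(p3, "HKR") && notIn(p2, "P") && notIn(p2p, "P")
    licA <- !is.na(p1) && p1 %in% hyd && exc
    licB <- !is.na(p1p) && p1p %in% hyd && notIn(p1, "R") && exc
    if (licA || licB) out <- c(out, b)
  }
  out
}

## Brute-force enumeration of specific-cleavage fragments: test every
## substring against the boundary/missed-cleavage definition.
oracleFragments <- function(sequence, sites, minLength, maxMissed) {
  n <- nchar(sequence)
  boundaries <- c(0L, sites, n)
  rows <- list()
  for (s in seq_len(n)) {
    for (e in s:n) {
      if (e - s + 1L < minLength) next
      if (!((s - 1L) %in% boundaries) || !(e %in% boundaries)) next
      internal <- sum(sites > (s - 1L) & sites < e)
      if (internal > maxMissed) next
      rows[[length(rows) + 1L]] <- data.frame(start = s, end = e,
                                              missed = internal)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$end), , drop = FALSE]
}

## Random peptide sequences over the 20 standard residues.
randPeptide <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               n, replace = TRUE), collapse = "")
}

## Direct Henderson-Hasselbalch evaluation from residue counts, written
## long-hand as the charge oracle.
oracleCharge <- function(sequence, pH, pka) {
  chars <- strsplit(sequence, "")[[1L]]
  cnt <- function(a) sum(chars == a)
  pos <- function(pk, k = 1) k / (1 + 10^(pH - pk))
  neg <- function(pk, k = 1) -k / (1 + 10^(pk - pH))
  pos(pka[["nterm"]]) + pos(pka[["H"]], cnt("H")) +
    pos(pka[["K"]], cnt("K")) + pos(pka[["R"]], cnt("R")) +
    neg(pka[["cterm"]]) + neg(pka[["D"]], cnt("D")) +
    neg(pka[["E"]], cnt("E")) + neg(pka[["C"]], cnt("C")) +
    neg(pka[["Y"]], cnt("Y"))
}

## The sieving model evaluated directly, clamp included.
oracleSieving <- function(mw, mwcoDa) {
  lam <- (mw / mwcoDa)^0.4
  if (lam >= 1) return(0)
  100 * (1 - (lam * (lam - 2))^2) * exp(-0.7146 * lam^2)
}
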