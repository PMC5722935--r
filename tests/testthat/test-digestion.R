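test_that("protein validation rejects malformed sequences", {
  expect_error(ProteinSequence("bad", "AAXBA"), "unknown residue 'X' at position 3")
  expect_error(ProteinSequence("short", "A"), "at least 2 residues")
  p <- ProteinSequence("ok", "ACDEFG")
  expect_s4_class(p, "ProteinSequence")
  expect_identical(nBonds(p), 5L)
})

test_that("bundled mature BSA has the expected chain arithmetic", {
  p <- bsaMature()
  expect_identical(length(p), 583L)
  expect_identical(nBonds(p), 582L)
  ## Table 1 peptides that do occur in the chain appear with their flanks
  expect_true(grepl("LVLIAFSQY", residues(p)))   # (L)/IAF/(S)
  expect_true(grepl("EIARRHPYFY", residues(p)))  # (E)/IARRHPYF/(Y)
})

test_that("pepsin rules give no sites without hydrophobic residues", {
  m <- findCleavageSites(ProteinSequence("g", "GGGGG"))
  expect_identical(cleavageSites(m), integer(0))
  expect_identical(dhMax(m), 0)
})

test_that("hand-derived site set for AAFAA", {
  ## bond-by-bond application of the pH>2 table (permissive termini):
  ## bond 2 (A-F): P1' = F licenses; P1 = A != R; P3 absent (permissive),
  ##   P2 = A, P2' = A -> site
  ## bond 3 (F-A): P1 = F licenses; P3 = A, P2 = A, P2' = A -> site
  ## bonds 1 and 4 have no F/L/W/Y at P1 or P1' -> no site
  m <- findCleavageSites(ProteinSequence("toy", "AAFAA"))
  expect_identical(cleavageSites(m), c(2L, 3L))
})

test_that("blocking termini veto sites whose exception window leaves the chain", {
  rules <- pepsinRules()
  rules@termini <- "blocking"
  m <- findCleavageSites(ProteinSequence("toy", "AAFAA"), rules)
  expect_identical(cleavageSites(m), 3L)  # bond 2 loses its absent P3
})

test_that("site finding matches an independent conditional-logic oracle", {
  set.seed(42)
  rules <- pepsinRules()
  for (i in 1:25) {
    s <- randPeptide(sample(6:40, 1))
    m <- findCleavageSites(ProteinSequence("r", s), rules)
    expect_identical(cleavageSites(m), as.integer(oracleSites(s)),
                     info = s)
    ## idempotent and in range
    expect_identical(cleavageSites(findCleavageSites(ProteinSequence("r", s),
                                                     rules)),
                     cleavageSites(m))
    expect_true(all(cleavageSites(m) >= 1 & cleavageSites(m) <= nchar(s) - 1))
  }
})

test_that("dh_max arithmetic covers the degenerate limits", {
  p <- ProteinSequence("p", "AAFAAFAA")
  m <- new("CleavageMap", protein = p, sites = integer(0),
           enzyme = "e", variant = "v")
  expect_identical(maxDegreeOfHydrolysis(m), 0)
  m@sites <- seq_len(nBonds(p))
  expect_identical(maxDegreeOfHydrolysis(m), 100)
})

test_that("specific enumeration partitions the chain at a single site", {
  p <- ProteinSequence("toy", "AAFAA")
  m <- new("CleavageMap", protein = p, sites = 3L, enzyme = "e", variant = "v")
  out <- enumeratePeptides(p, m, minLength = 1, mode = "specific",
                           maxMissed = 0)
  expect_identical(out$sequence, c("AAF", "AA"))
  expect_identical(out$prev, c("-", "F"))
  expect_identical(out$foll, c("A", "-"))
  expect_identical(out$missed, c(0L, 0L))
})

test_that("non-specific enumeration counts all qualifying substrings", {
  p <- ProteinSequence("toy", "AAFAA")
  m <- findCleavageSites(p)
  out <- enumeratePeptides(p, m, minLength = 3, mode = "non-specific")
  expect_identical(nrow(out), 6L)  # sum over L=3..5 of (5 - L + 1)
  expect_false(any(duplicated(out[, c("start", "end")])))
  expect_false(is.unsorted(out$start))
})

test_that("specific enumeration equals brute force on short chains", {
  set.seed(7)
  for (i in 1:12) {
    s <- randPeptide(sample(8:30, 1))
    p <- ProteinSequence("r", s)
    m <- findCleavageSites(p)
    for (mm in c(0L, 1L, 3L)) {
      got <- enumeratePeptides(p, m, minLength = 1, mode = "specific",
                               maxMissed = mm)
      want <- oracleFragments(s, cleavageSites(m), 1L, mm)
      expect_identical(got$start, want$start, info = paste(s, mm))
      expect_identical(got$end, want$end)
      expect_identical(got$missed, as.integer(want$missed))
      expect_identical(got$sequence, substring(s, want$start, want$end))
    }
    ## unlimited missed cleavages = all boundary pairs
    sites <- cleavageSites(m)
    all1 <- enumeratePeptides(p, m, minLength = 1, mode = "specific",
                              maxMissed = length(sites))
    want <- oracleFragments(s, sites, 1L, length(sites))
    expect_identical(nrow(all1), nrow(want))
  }
})

test_that("zero-missed specific fragments tile the parent exactly once", {
  set.seed(11)
  for (i in 1:8) {
    s <- randPeptide(sample(10:40, 1))
    p <- ProteinSequence("r", s)
    m <- findCleavageSites(p)
    out <- enumeratePeptides(p, m, minLength = 1, mode = "specific",
                             maxMissed = 0)
    expect_identical(paste(out$sequence, collapse = ""), s)
    expect_identical(out$start[1L], 1L)
    expect_identical(out$end[nrow(out)], nchar(s))
    expect_identical(out$start[-1L], out$end[-nrow(out)] + 1L)
  }
})

test_that("semi-specific peptides carry one cleavage-consistent terminus", {
  s <- "AAFAAWAAA"
  p <- ProteinSequence("r", s)
  m <- findCleavageSites(p)
  out <- enumeratePeptides(p, m, minLength = 3, mode = "semi-specific")
  b <- c(0L, cleavageSites(m), nchar(s))
  expect_true(all((out$start - 1L) %in% b | out$end %in% b))
  ## every fully specific fragment is also semi-specific
  spec <- enumeratePeptides(p, m, minLength = 3, mode = "specific",
                            maxMissed = length(cleavageSites(m)))
  expect_true(all(paste(spec$start, spec$end) %in% paste(out$start, out$end)))
})

test_that("quadratic enumeration refuses oversized parents", {
  p <- bsaMature()
  m <- findCleavageSites(p)
  expect_error(enumeratePeptides(p, m, mode = "non-specific", maxParent = 100),
               "quadratic")
})
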