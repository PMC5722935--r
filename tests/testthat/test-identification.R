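test_that("relative-intensity filter applies the strict 10% rule", {
  t1 <- PeakTable(mass = c(500, 600, 700), area = 1,
                  intensity = c(100, 9, 11))
  f1 <- filterPeaks(t1, 0.10)
  expect_equal(peaks(f1)$intensity, c(100, 11))
  ## singleton: the base peak survives its own threshold
  t2 <- PeakTable(mass = 500, area = 1, intensity = 50)
  expect_equal(peaks(filterPeaks(t2, 0.10))$intensity, 50)
  t3 <- PeakTable(mass = c(1, 2), area = 0, intensity = 0)
  expect_error(filterPeaks(t3), "no base peak")
  expect_error(filterPeaks(t1, 1.2), "threshold")
})

test_that("filtering matches a brute-force comparison on a large table", {
  set.seed(8)
  int <- rlnorm(1000, 3, 1.5)
  tbl <- PeakTable(mass = sort(runif(1000, 300, 3000)), area = 1,
                   intensity = int)
  got <- peaks(filterPeaks(tbl, 0.10))$intensity
  want <- int[int > 0.10 * max(int) | int == max(int)]
  expect_equal(sort(got), sort(want))
})

test_that("peaks within instrument precision merge with summed areas", {
  tbl <- PeakTable(mass = c(500.000, 500.004, 500.020), area = c(10, 30, 5))
  m <- peaks(mergePeaks(tbl, 0.005))
  expect_identical(nrow(m), 2L)
  expect_equal(m$area, c(40, 5))
  expect_equal(m$mass[1L], (500.000 * 10 + 500.004 * 30) / 40)
})

test_that("exact pool matches are unique with zero error", {
  pool <- data.frame(sequence = c("IAF", "FTF"), mass = peptideMass(c("IAF", "FTF")),
                     start = c(1L, 10L), end = c(3L, 12L))
  mm <- matchMasses(peptideMass("IAF"), pool, tolerance = 0.3)
  s <- matchSummary(mm)
  expect_identical(s$status, "unique")
  expect_identical(s$topSequence, "IAF")
  expect_equal(s$topDelta, 0)
})

test_that("repeat occurrences of one sequence still count as one candidate", {
  pool <- data.frame(sequence = c("IAF", "IAF"), mass = peptideMass("IAF"),
                     start = c(1L, 50L), end = c(3L, 52L))
  mm <- matchMasses(peptideMass("IAF"), pool)
  expect_identical(matchSummary(mm)$status, "unique")
  expect_identical(nrow(matchCandidates(mm)), 2L)
})

test_that("an empty pool warns and leaves every peak unmatched", {
  pool <- data.frame(sequence = character(0), mass = numeric(0))
  expect_warning(mm <- matchMasses(c(400, 500), pool), "empty")
  expect_identical(matchSummary(mm)$status, c("unmatched", "unmatched"))
})

test_that("matching equals an exhaustive all-pairs comparison", {
  set.seed(9)
  pool <- data.frame(sequence = vapply(1:200, function(i)
                       randPeptide(sample(3:12, 1)), ""),
                     start = sample.int(500, 200), end = NA_integer_)
  pool$mass <- peptideMass(pool$sequence)
  obs <- runif(50, min(pool$mass) - 1, max(pool$mass) + 1)
  mm <- matchMasses(obs, pool, tolerance = 0.3, minLength = 3)
  s <- matchSummary(mm)
  for (i in seq_along(obs)) {
    hits <- pool$sequence[abs(pool$mass - obs[i]) <= 0.3]
    nseq <- length(unique(hits))
    want <- if (nseq == 0) "unmatched" else if (nseq == 1) "unique"
            else "ambiguous"
    expect_identical(s$status[i], want, info = paste("peak", i))
    expect_identical(s$nSequences[i], nseq)
  }
  ## candidates sorted by |delta| with ties by start coordinate
  cands <- matchCandidates(mm)
  for (pk in unique(cands$peak)) {
    d <- cands$delta[cands$peak == pk]
    expect_true(!is.unsorted(d))
  }
})

test_that("shrinking the tolerance never resurrects unmatched peaks", {
  set.seed(10)
  pool <- data.frame(sequence = vapply(1:100, function(i)
                       randPeptide(sample(3:10, 1)), ""))
  pool$mass <- peptideMass(pool$sequence)
  obs <- runif(40, 300, 1500)
  wide <- matchSummary(matchMasses(obs, pool, tolerance = 0.3))$status
  narrow <- matchSummary(matchMasses(obs, pool, tolerance = 0.05))$status
  expect_true(all(narrow[wide == "unmatched"] == "unmatched"))
  ## and matched sets can only shrink
  expect_true(all(which(narrow != "unmatched") %in% which(wide != "unmatched")))
})

test_that("stream reconciliation applies the exclusion rules", {
  pool <- data.frame(
    sequence = c("IAF", "FTF", "LLL", "ILL"),
    mass = peptideMass(c("IAF", "FTF", "LLL", "ILL")))
  ## hydrolysate sees IAF (unique) and the LLL/ILL isobars (ambiguous);
  ## the permeate adds FTF, which the feed never showed
  hyd <- matchMasses(peptideMass(c("IAF", "LLL")), pool, tolerance = 0.3)
  perm <- matchMasses(peptideMass(c("IAF", "FTF")), pool, tolerance = 0.3)
  rec <- reconcileStreams(hyd, perm)
  expect_identical(rec$accepted$sequence, "IAF")
  expect_setequal(rec$exclusions$reason, c("ambiguous", "permeate-only"))
  expect_identical(unname(rec$counts["accepted"]), 1L)
  expect_identical(unname(rec$counts["ambiguous"]), 1L)
  expect_identical(unname(rec$counts["permeate-only"]), 1L)
  ## every excluded mass appears in exactly one category
  expect_false(any(duplicated(rec$exclusions$mass)))
  ## mismatched tolerances are a contract violation
  perm2 <- matchMasses(peptideMass("FTF"), pool, tolerance = 0.2)
  expect_error(reconcileStreams(hyd, perm2), "tolerance")
})

test_that("peak tables round-trip through CSV and TSV", {
  tbl <- PeakTable(mass = c(350.21, 414.20), area = c(10, 20),
                   stream = "permeate", membrane = "PES5", pH = 10)
  for (ext in c(".csv", ".tsv")) {
    f <- tempfile(fileext = ext)
    writePeakTable(tbl, f)
    back <- readPeakTable(f)
    expect_equal(peaks(back), peaks(tbl))
    expect_identical(back@stream, "permeate")
    expect_identical(back@membrane, "PES5")
    expect_equal(back@pH, 10)
    unlink(f)
  }
})
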