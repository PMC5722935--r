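cfgSmall <- function(...) {
  simulationConfig(nPeptides = 40L, ...)
}

test_that("hydrolysate simulation is seed-deterministic", {
  a <- simulateHydrolysate(cfgSmall(seed = 21))
  b <- simulateHydrolysate(cfgSmall(seed = 21))
  expect_identical(peaks(a$feed), peaks(b$feed))
  expect_identical(a$truth, b$truth)
  c_ <- simulateHydrolysate(cfgSmall(seed = 22))
  expect_false(identical(peaks(a$feed)$area, peaks(c_$feed)$area))
  ## ground-truth structure (sampled sequences) is seed-dependent, but the
  ## underlying digest pool is not: every truth row maps into the pool
  expect_true(all(a$truth$sequence %in%
                    enumeratePeptides(bsaMature(), findCleavageSites(bsaMature()),
                                      mode = "specific", maxMissed = 2)$sequence))
})

test_that("noise-free areas equal ground-truth abundances", {
  sim <- simulateHydrolysate(cfgSmall(seed = 23, areaSigma = 0,
                                      massJitterSd = 0))
  expect_equal(peaks(sim$feed)$area, sim$truth$abundance)
  expect_equal(peaks(sim$feed)$mass, sim$truth$massTrue)
})

test_that("area noise is centred multiplicative lognormal", {
  cfg <- simulationConfig(seed = 24, nPeptides = 1000L, areaSigma = 0.2,
                          maxMissed = 8L)
  sim <- simulateHydrolysate(cfg)
  n <- nrow(sim$truth)
  expect_gt(n, 500)  # the digest pool is deep enough for the draw
  r <- log(peaks(sim$feed)$area / sim$truth$abundance)
  se <- 0.2 / sqrt(n)
  expect_lt(abs(mean(r)), 3 * se)
  expect_equal(sd(r), 0.2, tolerance = 0.05)
})

test_that("pure-sieving filtration reproduces the theoretical transmission", {
  cfg <- cfgSmall(seed = 25, areaSigma = 0, massJitterSd = 0,
                  chargeAttenuation = 0, hydrophobicRetention = 0)
  sim <- simulateHydrolysate(cfg)
  fl <- simulateFiltration(sim$feed, sim$truth, cfg, "PES5", 10)
  ## permeate rows preserve feed order; pair positionally (isobaric
  ## peptides make mass-based pairing ambiguous)
  idx <- which(fl$truth$transmission > 0)
  trObs <- trObserved(peaks(fl$permeate)$area, peaks(sim$feed)$area[idx])
  trTheo <- trTheoretical(sim$truth$massTrue[idx], 5000)
  expect_equal(trObs, trTheo, tolerance = 1e-9)
  expect_error(simulateFiltration(sim$feed, sim$truth, cfg, "PES9", 10),
               "MWCO missing")
})

test_that("strong charge attenuation suppresses transmission", {
  cfg <- cfgSmall(seed = 26, areaSigma = 0, chargeAttenuation = 50)
  sim <- simulateHydrolysate(cfg)
  fl <- simulateFiltration(sim$feed, sim$truth, cfg, "PES5", 2)
  ## at pH 2 every peptide carries positive charge, so the logistic factor
  ## collapses all transmissions towards zero
  expect_true(all(fl$truth$transmission < 1))
})

test_that("recovered transmissions track ground truth within noise", {
  cfg <- simulationConfig(seed = 27, nPeptides = 150L, areaSigma = 0.1,
                          massJitterSd = 0)
  sim <- simulateHydrolysate(cfg)
  fl <- simulateFiltration(sim$feed, sim$truth, cfg, "PES5", 10)
  idx <- which(fl$truth$transmission > 0)
  trObs <- trObserved(peaks(fl$permeate)$area, peaks(sim$feed)$area[idx])
  trTrue <- fl$truth$transmission[idx]
  relErr <- abs(log(trObs / trTrue))
  ## mean |log error| of exp(N(0, 0.1)) noise is below 2 sigma
  expect_lt(mean(relErr), 2 * 0.1)
})

test_that("pH-stat simulation hits its analytic limits", {
  cfg <- cfgSmall(seed = 28, phstatSigma = 0, phstatDuration = 600)
  sim <- simulatePhstat(cfg)
  expect_equal(sim$series$volume_mL[1L], 0)
  expect_equal(tail(sim$series$volume_mL, 1L),
               cfg$phstatAinf * (1 - exp(-cfg$phstatK * 600)),
               tolerance = 1e-12)
  expect_true(all(diff(sim$series$volume_mL) > 0))
})

test_that("replicate fits recover the generating kinetics", {
  cfg <- simulationConfig(seed = 29)
  fits <- t(vapply(1:50, function(r) {
    s <- simulatePhstat(cfg, replicate = r)$series
    fit <- minpack.lm::nlsLM(volume_mL ~ aInf * (1 - exp(-k * time_min)),
                             data = s,
                             start = list(aInf = max(s$volume_mL), k = 0.02))
    coef(fit)
  }, c(aInf = 0, k = 0)))
  for (p in c("aInf", "k")) {
    est <- fits[, p]
    se <- sd(est) / sqrt(length(est))
    truth <- if (p == "aInf") cfg$phstatAinf else cfg$phstatK
    expect_lt(abs(mean(est) - truth), 2 * se + 0.01 * truth)
  }
})

test_that("identification on simulated data recovers the generating peptides", {
  cfg <- simulationConfig(seed = 30, nPeptides = 80L, massJitterSd = 0.01)
  sim <- simulateHydrolysate(cfg)
  pool <- enumeratePeptides(cfg$substrate, findCleavageSites(cfg$substrate),
                            mode = "specific", maxMissed = cfg$maxMissed)
  mm <- matchMasses(sim$feed, pool, tolerance = 0.3, minLength = 3)
  s <- matchSummary(mm)
  uniq <- s$status == "unique"
  ## every unique assignment names the generating peptide (tolerance is
  ## 30x the mass jitter, so misses would indicate matching defects)
  expect_true(all(s$topSequence[uniq] == sim$truth$sequence[uniq]))
  expect_gt(mean(uniq), 0.3)  # the BSA peptic pool has many isobars
})
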