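#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the simulators with defaults that mirror the
#' serum-albumin study design: the bundled mature BSA substrate digested
#' by the calibrated pepsin rule set, lognormal peptide abundances,
#' multiplicative chromatographic noise, two polyethersulfone membranes
#' (1 and 5 kDa cut-offs) operated at pH 2 and pH 10, and a first-order
#' saturating pH-stat titrant curve sampled every 15 min over 180 min.
#' The transmission ground truth is the steric sieving term modulated by
#' a logistic attenuation in |net charge| and a hydrophobic-retention
#' penalty above a GRAVY threshold - a synthetic construction for testing
#' (it encodes charge dominance qualitatively), not a literature model.
#'
#' All draws are governed by `seed`; the individual simulators advance
#' documented sub-seeds from it, so ground-truth structure is shared and
#' only noise realisations change between seeds.
#'
#' @param seed integer random seed.
#' @param substrate a [ProteinSequence-class].
#' @param enzyme packaged rule-set name or YAML path.
#' @param nPeptides number of distinct peptides sampled into the
#'   hydrolysate.
#' @param minLength,maxMissed digestion-pool settings (specific mode).
#' @param abundanceMeanlog,abundanceSdlog lognormal abundance model.
#' @param areaSigma multiplicative lognormal noise sigma on peak areas.
#' @param massJitterSd additive Gaussian jitter (Da) on observed masses.
#' @param membranes named numeric vector of MWCOs in Da.
#' @param phValues operating pH values for filtration.
#' @param chargeAttenuation logistic coefficient on |net charge|
#'   (0 = pure sieving).
#' @param hydrophobicRetention exponential penalty per GRAVY unit above
#'   `gravyThreshold` (0 disables).
#' @param gravyThreshold GRAVY level above which retention sets in.
#' @param pka pKa table name for the operating-pH net charge.
#' @param phstatK first-order rate constant, 1/min.
#' @param phstatAinf asymptotic titrant volume, mL.
#' @param phstatSigma additive Gaussian noise on titrant volumes, mL.
#' @param phstatInterval,phstatDuration sampling grid, min.
#' @return a validated list of class "SimulationConfig".
#' @export
simulationConfig <- function(seed = 1L,
                             substrate = bsaMature(),
                             enzyme = "pepsin-ph2",
                             nPeptides = 60L,
                             minLength = 3L,
                             maxMissed = 2L,
                             abundanceMeanlog = log(1e5),
                             abundanceSdlog = 1,
                             areaSigma = 0.2,
                             massJitterSd = 0.01,
                             membranes = c(PES1 = 1000, PES5 = 5000),
                             phValues = c(2, 10),
                             chargeAttenuation = 1.2,
                             hydrophobicRetention = 0.5,
                             gravyThreshold = 1,
                             pka = "table1",
                             phstatK = 0.03,
                             phstatAinf = 29.5,
                             phstatSigma = 0.3,
                             phstatInterval = 15,
                             phstatDuration = 180) {
  stopifnot(is(substrate, "ProteinSequence"))
  if (areaSigma < 0 || massJitterSd < 0 || phstatSigma < 0)
    stop("noise sigmas must be >= 0")
  if (phstatK <= 0) stop("phstatK must be > 0")
  if (phstatAinf <= 0) stop("phstatAinf must be > 0")
  if (is.null(names(membranes)) || any(membranes <= 0))
    stop("membranes must be a named vector of positive MWCOs")
  structure(as.list(environment()), class = "SimulationConfig")
}

## run fn under a sub-seed without disturbing the caller's RNG stream
.withSeed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
         else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fn()
}

#' Simulate a hydrolysate peak table
#'
#' Digests the substrate with the configured rule set (specific mode),
#' samples `nPeptides` distinct peptides, draws lognormal ground-truth
#' abundances and emits one peak per peptide at its [M+H]+ monoisotopic
#' mass (plus optional Gaussian jitter) with multiplicatively noisy area.
#' Deterministic for a fixed seed. A substrate without cleavage sites
#' degenerates, with a warning, to one whole-protein peak.
#'
#' @param config a [simulationConfig()].
#' @return list: `feed` (a hydrolysate [PeakTable-class]) and `truth`
#'   (data.frame: sequence, start, end, massTrue, abundance).
#' @export
simulateHydrolysate <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "SimulationConfig"))
  rules <- readCleavageRules(config$enzyme)
  map <- findCleavageSites(config$substrate, rules)
  if (length(map@sites) == 0L) {
    warning("substrate has no cleavage sites: emitting whole-protein peak")
    seqs <- config$substrate@residues
    pool <- data.frame(sequence = seqs, start = 1L,
                       end = nchar(seqs), mass = peptideMass(seqs),
                       stringsAsFactors = FALSE)
  } else {
    pool <- enumeratePeptides(config$substrate, map,
                              minLength = config$minLength,
                              mode = "specific",
                              maxMissed = config$maxMissed)
    pool <- pool[!duplicated(pool$sequence), , drop = FALSE]
  }
  .withSeed(config$seed, function() {
    n <- min(config$nPeptides, nrow(pool))
    pick <- pool[sample.int(nrow(pool), n), , drop = FALSE]
    abundance <- stats::rlnorm(n, config$abundanceMeanlog,
                               config$abundanceSdlog)
    area <- abundance * exp(stats::rnorm(n, 0, config$areaSigma))
    massObs <- pick$mass + stats::rnorm(n, 0, config$massJitterSd)
    ord <- order(massObs)
    truth <- data.frame(sequence = pick$sequence, start = pick$start,
                        end = pick$end, massTrue = pick$mass,
                        massObserved = massObs, abundance = abundance,
                        stringsAsFactors = FALSE)[ord, ]
    rownames(truth) <- NULL
    list(feed = PeakTable(mass = massObs[ord], area = area[ord],
                          stream = "hydrolysate"),
         truth = truth)
  })
}

## ground-truth transmission fraction of one peptide under the synthetic
## sieving x charge x hydrophobicity model
.trueTransmission <- function(sequence, massTrue, mwcoDa, pH, config,
                              pka = pkaTable(config$pka)) {
  sieve <- trTheoretical(massTrue, mwcoDa) / 100
  z <- netCharge(sequence, pH, pka)
  fCharge <- 2 / (1 + exp(config$chargeAttenuation * abs(z)))
  g <- gravy(sequence)
  fHydro <- exp(-config$hydrophobicRetention *
                  pmax(0, g - config$gravyThreshold))
  sieve * fCharge * fHydro
}

#' Simulate a permeate peak table for one filtration condition
#'
#' Per feed peptide the true transmission is the sieving coefficient of
#' the membrane modulated by the logistic charge-attenuation factor at
#' the operating pH and the hydrophobic-retention penalty; the permeate
#' area is the feed area times that transmission times multiplicative
#' noise. With `chargeAttenuation = 0`, `hydrophobicRetention = 0` and
#' `areaSigma = 0` the recomputed observed transmissions equal the
#' theoretical sieving transmissions exactly.
#'
#' @param feed the hydrolysate [PeakTable-class] from
#'   [simulateHydrolysate()].
#' @param truth its ground-truth data.frame.
#' @param config the same [simulationConfig()].
#' @param membrane membrane name; must be one of `names(config$membranes)`.
#' @param pH operating pH.
#' @return list: `permeate` (a [PeakTable-class]) and `truth` (data.frame:
#'   sequence, transmission in percent).
#' @export
simulateFiltration <- function(feed, truth, config, membrane, pH) {
  stopifnot(inherits(config, "SimulationConfig"), is(feed, "PeakTable"))
  if (!membrane %in% names(config$membranes))
    stop("membrane MWCO missing from config: ", membrane)
  mwcoDa <- config$membranes[[membrane]]
  tr <- .trueTransmission(truth$sequence, truth$massTrue, mwcoDa, pH, config)
  sub <- match(membrane, names(config$membranes)) * 100L + round(pH)
  .withSeed(config$seed + sub, function() {
    noise <- exp(stats::rnorm(nrow(truth), 0, config$areaSigma))
    areaP <- feed@peaks$area * tr * noise
    keep <- areaP > 0
    list(permeate = PeakTable(mass = feed@peaks$mass[keep],
                              area = areaP[keep], stream = "permeate",
                              membrane = membrane, pH = pH),
         truth = data.frame(sequence = truth$sequence,
                            transmission = 100 * tr,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a pH-stat titration series
#'
#' First-order saturating titrant consumption
#' A(t) = A_inf * (1 - exp(-k t)) plus additive Gaussian noise, sampled on
#' the configured grid and clamped non-negative. A(0) is exactly 0 in the
#' noise-free case.
#'
#' @param config a [simulationConfig()].
#' @param replicate integer replicate index; advances the sub-seed so that
#'   replicate experiments are independent but reproducible.
#' @return list: `series` (data.frame time_min, volume_mL) and `truth`
#'   (list k, aInf).
#' @export
simulatePhstat <- function(config = simulationConfig(), replicate = 1L) {
  stopifnot(inherits(config, "SimulationConfig"))
  t <- seq(0, config$phstatDuration, by = config$phstatInterval)
  a <- config$phstatAinf * (1 - exp(-config$phstatK * t))
  .withSeed(config$seed + 7000L + as.integer(replicate), function() {
    if (config$phstatSigma > 0)
      a <- pmax(0, a + stats::rnorm(length(t), 0, config$phstatSigma))
    list(series = data.frame(time_min = t, volume_mL = a),
         truth = list(k = config$phstatK, aInf = config$phstatAinf))
  })
}
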