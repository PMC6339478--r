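## Forward simulator: seasonal (nonhomogeneous Poisson) births, individual
## Michaelis-Menten growth with lognormal variability, mortality by maximal
## age, and uneven monthly sampling. Gives every pipeline stage ground truth.

#' Construct a simulation configuration
#'
#' Defaults describe a shallow-station-like population: chamber growth
#' reaching ~73 chambers with half-asymptote near day 36 (initial rate
#' ~2 chambers/day), sigmoid diameter growth from a ~294 um nepiont, a
#' maximal age of 450 days, and a seasonal birth intensity with a dominant
#' summer pulse and a weaker winter pulse over a 15-month span sampled at 17
#' roughly monthly, jittered dates. See [simulationScenario()] for the two
#' shipped scenarios.
#'
#' @param cbrParams,dirParams ground-truth growth parameters.
#' @param individualCV relative sd of the lognormal per-individual asymptote
#'   multiplier.
#' @param birthOffset baseline birth intensity (births/day).
#' @param birthSinusoids data.frame `period`, `amplitude`, `phase`.
#' @param spanDays study span in days.
#' @param samplingDays sampling days since study start.
#' @param sampleFraction fraction of the living population caught per
#'   sampling.
#' @param maxAgeDays maximal age (death/removal).
#' @param warmupDays pre-study interval from which births are also drawn
#'   (default: the maximal age), so that mature generations are present at
#'   the first sampling; set 0 to start from an empty habitat.
#' @param nocNoiseProb probability of a +/-1 chamber miscount.
#' @param tdNoiseSD sdlog of the multiplicative lognormal noise on TD.
#' @return a validated [SimulationConfig-class] object.
#' @export
simulationConfig <- function(cbrParams = c(mmax = 72.6, b = 36),
                             dirParams = c(m0 = 293.7, mmax = 5000, b = 250, c = 1.6),
                             individualCV = 0.1,
                             birthOffset = 1.2,
                             birthSinusoids = data.frame(
                               period = c(365, 182.5),
                               amplitude = c(0.7, 0.4),
                               phase = c(0, 0)),
                             spanDays = 450,
                             samplingDays = NULL,
                             sampleFraction = 0.05,
                             maxAgeDays = 450,
                             warmupDays = NULL,
                             nocNoiseProb = 0.1,
                             tdNoiseSD = 0.05) {
  if (is.null(samplingDays))
    samplingDays <- round(seq(5, spanDays - 5, length.out = 17))
  if (is.null(warmupDays)) warmupDays <- maxAgeDays
  new("SimulationConfig", cbrParams = cbrParams, dirParams = dirParams,
      individualCV = individualCV, birthOffset = birthOffset,
      birthSinusoids = birthSinusoids, spanDays = spanDays,
      samplingDays = as.numeric(samplingDays), sampleFraction = sampleFraction,
      maxAgeDays = maxAgeDays, warmupDays = warmupDays,
      nocNoiseProb = nocNoiseProb,
      tdNoiseSD = tdNoiseSD)
}

#' Shipped simulation scenarios
#'
#' `"20m"`: dominant summer reproduction pulse about three times the winter
#' pulse, as observed in shallow (schizont-dominated) populations. `"50m"`:
#' balanced, slightly winter-leaning pulses, as in the deeper
#' (gamont-dominated) populations. Day 0 corresponds to a late-April study
#' start; phases place the annual intensity maximum in late July and the
#' semiannual component adds the winter pulse.
#'
#' @param scenario `"20m"` or `"50m"`.
#' @param ... overrides passed to [simulationConfig()].
#' @return a [SimulationConfig-class] object.
#' @export
simulationScenario <- function(scenario = c("20m", "50m"), ...) {
  scenario <- match.arg(scenario)
  startDoy <- 113                 # late April (day-of-year of study start)
  peakDoy <- 208                  # late July
  phi365 <- pi / 2 - 2 * pi * (peakDoy - startDoy) / 365
  phi182 <- pi / 2 - 2 * pi * (peakDoy - startDoy) / 182.5
  base <- switch(scenario,
    "20m" = list(birthOffset = 1.2,
                 birthSinusoids = data.frame(period = c(365, 182.5),
                                             amplitude = c(0.7, 0.4),
                                             phase = c(phi365, phi182))),
    "50m" = list(birthOffset = 1.0,
                 birthSinusoids = data.frame(period = c(365, 182.5),
                                             amplitude = c(-0.15, 0.55),
                                             phase = c(phi365, phi182))))
  args <- utils::modifyList(base, list(...))
  do.call(simulationConfig, args)
}

#' Draw birth days from the seasonal intensity
#'
#' Nonhomogeneous Poisson process simulated by thinning: candidate events
#' are drawn homogeneously at the intensity maximum and accepted with
#' probability `lambda(t) / lambda_max`. Deterministic given the seed.
#' Births are drawn on `[-warmupDays, spanDays]` so that the first sampling
#' already sees an ongoing population.
#'
#' @param cfg a [SimulationConfig-class] object.
#' @param seed RNG seed.
#' @return sorted numeric vector of birth days on `[-warmupDays, spanDays]`.
#' @export
simulateBirths <- function(cfg, seed = 1L) {
  stopifnot(is(cfg, "SimulationConfig"))
  lo <- -cfg@warmupDays
  grid <- seq(lo, cfg@spanDays, by = 0.25)
  lamMax <- max(birthIntensity(cfg, grid))
  if (lamMax <= 0) return(numeric())
  .withSeed(seed, {
    n <- stats::rpois(1, lamMax * (cfg@spanDays - lo))
    cand <- sort(runif(n, lo, cfg@spanDays))
    keep <- runif(n) < birthIntensity(cfg, cand) / lamMax
    cand[keep]
  })
}

#' Grow the simulated individuals and sample them
#'
#' Each individual carries a lognormal asymptote multiplier (relative sd
#' `individualCV`) applied to both growth asymptotes. At every sampling day
#' the living individuals (age in `(0, maxAgeDays)`) are subsampled with
#' probability `sampleFraction`; the observed chamber number is the rounded
#' CBR value at age (clamped to at least 2, with a +/-1 miscount at
#' probability `nocNoiseProb`) and the observed diameter is the DIR value
#' times lognormal noise.
#'
#' @param births birth days from [simulateBirths()].
#' @param cfg a [SimulationConfig-class] object.
#' @param seed RNG seed.
#' @return a [SimulatedPopulation-class] object.
#' @export
growAndSample <- function(births, cfg, seed = 1L) {
  stopifnot(is(cfg, "SimulationConfig"))
  nInd <- length(births)
  sdlog <- sqrt(log(1 + cfg@individualCV^2))
  .withSeed(seed + 1L, {
    scale <- if (nInd) rlnorm(nInd, -sdlog^2 / 2, sdlog) else numeric()
    truth <- data.frame(id = seq_len(nInd), birth_day = births, scale = scale)
    obs <- NULL
    for (d in sort(cfg@samplingDays)) {
      age <- d - births
      alive <- which(age > 0 & age < cfg@maxAgeDays)
      if (!length(alive)) next
      take <- alive[runif(length(alive)) < cfg@sampleFraction]
      if (!length(take)) next
      a <- d - births[take]
      cbr <- cfg@cbrParams; dir <- cfg@dirParams
      noc <- numeric(length(take)); td <- numeric(length(take))
      for (i in seq_along(take)) {
        pc <- c(mmax = cbr[["mmax"]] * scale[take[i]], b = cbr[["b"]])
        pd <- c(m0 = dir[["m0"]], mmax = dir[["mmax"]] * scale[take[i]],
                b = dir[["b"]], c = dir[["c"]])
        noc[i] <- round(mmEval(pc, a[i]))
        td[i] <- gmmEval(pd, a[i])
      }
      flip <- runif(length(take)) < cfg@nocNoiseProb
      noc[flip] <- noc[flip] + sample(c(-1, 1), sum(flip), replace = TRUE)
      noc <- pmax(noc, 2)
      if (cfg@tdNoiseSD > 0)
        td <- td * rlnorm(length(take), -cfg@tdNoiseSD^2 / 2, cfg@tdNoiseSD)
      obs <- rbind(obs, data.frame(
        specimen_id = sprintf("d%03d_i%05d", as.integer(d), take),
        sampling_day = d, birth_day = births[take],
        chamber_count = noc, test_diameter = td))
    }
    if (is.null(obs))
      obs <- data.frame(specimen_id = character(), sampling_day = numeric(),
                        birth_day = numeric(), chamber_count = numeric(),
                        test_diameter = numeric())
    ns <- table(obs$sampling_day)
    obs$sample_size <- as.integer(ns[as.character(obs$sampling_day)])
    rownames(obs) <- NULL
    new("SimulatedPopulation", truth = truth, observed = obs, config = cfg)
  })
}

#' Simulate a population end to end
#'
#' @param cfg a [SimulationConfig-class] object.
#' @param seed RNG seed; births and observation noise derive from it.
#' @return a [SimulatedPopulation-class] object.
#' @export
simulatePopulation <- function(cfg, seed = 1L) {
  growAndSample(simulateBirths(cfg, seed), cfg, seed)
}

#' Convert a simulated population to a ForamSamples object
#'
#' @param pop a [SimulatedPopulation-class] object.
#' @param origin calendar date of simulation day 0.
#' @param depth nominal station depth recorded in the records (m).
#' @return a [ForamSamples-class] object.
#' @export
asForamSamples <- function(pop, origin = as.Date("2014-04-23"), depth = 20) {
  stopifnot(is(pop, "SimulatedPopulation"))
  obs <- pop@observed
  if (!nrow(obs)) stop("the simulated population was never sampled", call. = FALSE)
  foramSamples(data.frame(
    specimen_id = obs$specimen_id,
    sampling_date = origin + obs$sampling_day,
    station_depth = depth,
    chamber_count = obs$chamber_count,
    test_diameter = obs$test_diameter))
}
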