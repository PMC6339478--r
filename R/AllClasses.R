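#' @import methods
#' @importFrom stats coef dnorm lm lm.wfit median optim pchisq pnorm qnorm
#'   rbinom rlnorm rnorm runif sd setNames complete.cases anova aggregate
#' @importFrom utils read.table write.table head tail
NULL

## ---------------------------------------------------------------------------
## ForamSamples: per-specimen morphometric records of one sampling campaign
## ---------------------------------------------------------------------------

#' Per-specimen samples of a foraminiferal population
#'
#' Container for the raw observations of a 'natural laboratory' campaign:
#' one row per specimen with its sampling date, water-depth station, chamber
#' number (NoC, counted including the nepiont) and maximal test diameter
#' (TD, in micrometres through the proloculus centre). A specimen may carry
#' only one of the two characters; it is then used only for analyses of the
#' character it has.
#'
#' @slot specimens data.frame with columns `specimen_id`, `sampling_date`
#'   (`Date`), `station_depth` (m), `chamber_count`, `test_diameter`.
#' @slot sedimentWeight named numeric, grams of sediment per sampling date
#'   (optional; typically available only for soft-bottom stations).
#' @slot studyStart,studyEnd study window; all sampling dates must fall inside.
#'
#' @seealso [readSpecimenTable()], [foramSamples()]
#' @export
setClass("ForamSamples",
  representation(
    specimens      = "data.frame",
    sedimentWeight = "numeric",
    studyStart     = "Date",
    studyEnd       = "Date"
  )
)

setValidity("ForamSamples", function(object) {
  sp <- object@specimens
  need <- c("specimen_id", "sampling_date", "station_depth",
            "chamber_count", "test_diameter")
  miss <- setdiff(need, names(sp))
  if (length(miss))
    return(sprintf("missing specimen column(s): %s", paste(miss, collapse = ", ")))
  if (!inherits(sp$sampling_date, "Date"))
    return("sampling_date must be of class Date")
  bad <- which(!is.na(sp$chamber_count) & sp$chamber_count < 2)
  if (length(bad))
    return(sprintf("chamber_count < 2 (nepiont has 2 chambers) in row(s) %s",
                   paste(head(bad, 5), collapse = ", ")))
  bad <- which(!is.na(sp$test_diameter) & sp$test_diameter <= 0)
  if (length(bad))
    return(sprintf("test_diameter <= 0 in row(s) %s", paste(head(bad, 5), collapse = ", ")))
  bad <- which(is.na(sp$chamber_count) & is.na(sp$test_diameter))
  if (length(bad))
    return(sprintf("row(s) %s carry neither character", paste(head(bad, 5), collapse = ", ")))
  if (nrow(sp) && (any(sp$sampling_date < object@studyStart) ||
                   any(sp$sampling_date > object@studyEnd)))
    return("sampling_date outside the study window")
  TRUE
})

## ---------------------------------------------------------------------------
## ForamHistogram: fixed-interval frequency distribution of one sample
## ---------------------------------------------------------------------------

#' Fixed-interval size-frequency histogram
#'
#' One monthly sample binned on a fixed grid. Chamber numbers are binned as
#' natural numbers; test diameters are binned on the natural-log scale
#' (character `"lnTD"`), reflecting the logarithmic test growth.
#'
#' @slot edges strictly increasing, equally spaced bin edges.
#' @slot counts nonnegative counts per bin; `sum(counts)` equals the sample
#'   size used.
#' @slot character `"NoC"` or `"lnTD"`.
#' @slot samplingDate date of the sample.
#' @export
setClass("ForamHistogram",
  representation(
    edges        = "numeric",
    counts       = "numeric",
    character    = "character",
    samplingDate = "Date"
  )
)

setValidity("ForamHistogram", function(object) {
  e <- object@edges
  if (length(e) < 2 || any(diff(e) <= 0))
    return("bin edges must be strictly increasing")
  w <- diff(e)
  if (max(w) - min(w) > 1e-8 * mean(w))
    return("bins must have equal widths")
  if (length(object@counts) != length(e) - 1L)
    return("counts must have one entry per bin")
  if (any(object@counts < 0))
    return("counts must be nonnegative")
  if (!object@character %in% c("NoC", "lnTD"))
    return("character must be 'NoC' or 'lnTD'")
  TRUE
})

## ---------------------------------------------------------------------------
## ComponentDecomposition: Gaussian components of one monthly histogram
## ---------------------------------------------------------------------------

#' Normal components decomposed from a monthly size-frequency histogram
#'
#' Result of fitting a sum of up to three scaled Gaussian curves to the bin
#' counts of one monthly sample. Each component is interpreted as one cohort
#' (generation). The `density` of a component is its peak height in count
#' units, i.e. the expected count in the bin at the component mean; the
#' implied component total is `density * sd * sqrt(2*pi) / binwidth`.
#'
#' @slot samplingDate date of the decomposed sample.
#' @slot character `"NoC"` or `"lnTD"`.
#' @slot components data.frame with columns `density`, `mean`, `sd`, sorted
#'   by decreasing mean. For `"lnTD"` the ln-scale fit is kept here; see
#'   [components()] for the micrometre-scale report.
#' @slot reducedChi2 reduced chi-square of the selected fit.
#' @slot normalityP p-value of the chi-square normality pre-test.
#' @slot binWidth bin width of the underlying histogram.
#' @slot sampleSize number of specimens behind the histogram.
#' @export
setClass("ComponentDecomposition",
  representation(
    samplingDate = "Date",
    character    = "character",
    components   = "data.frame",
    reducedChi2  = "numeric",
    normalityP   = "numeric",
    binWidth     = "numeric",
    sampleSize   = "numeric"
  )
)

setValidity("ComponentDecomposition", function(object) {
  cp <- object@components
  if (!all(c("density", "mean", "sd") %in% names(cp)))
    return("components need columns density, mean, sd")
  if (nrow(cp) < 1 || nrow(cp) > 3)
    return("between 1 and 3 components are allowed")
  if (any(cp$density <= 0)) return("component density must be > 0")
  if (any(cp$sd <= 0)) return("component sd must be > 0")
  if (is.unsorted(rev(cp$mean), strictly = FALSE))
    return("components must be sorted by decreasing mean")
  if (nrow(cp) > 1 && min(abs(diff(cp$mean))) < object@binWidth)
    return("component means must be separated by at least one bin width")
  TRUE
})

## ---------------------------------------------------------------------------
## GenerationTracks: monthly components linked into generations
## ---------------------------------------------------------------------------

#' Monthly components linked into generation tracks
#'
#' Time-ordered assignment of decomposed components to generations. Along a
#' track the component means must grow, up to a configurable slack for
#' sampling noise (default 15% relative decrease).
#'
#' @slot entries data.frame with columns `generation`, `date`, `density`,
#'   `mean`, `sd`.
#' @slot character `"NoC"` or `"TD"` (means on the measurement scale).
#' @slot slack tolerated relative decrease of the mean along a track.
#' @export
setClass("GenerationTracks",
  representation(
    entries   = "data.frame",
    character = "character",
    slack     = "numeric"
  )
)

setValidity("GenerationTracks", function(object) {
  en <- object@entries
  need <- c("generation", "date", "density", "mean", "sd")
  if (!all(need %in% names(en)))
    return(sprintf("entries need columns %s", paste(need, collapse = ", ")))
  for (g in unique(en$generation)) {
    tr <- en[en$generation == g, ]
    tr <- tr[order(tr$date), ]
    if (any(duplicated(tr$date)))
      return(sprintf("generation %s has two components on one date", g))
    if (nrow(tr) > 1) {
      rel <- diff(tr$mean) / head(tr$mean, -1)
      if (any(rel < -object@slack))
        return(sprintf("generation %s mean decreases by more than the slack", g))
    }
  }
  TRUE
})

## ---------------------------------------------------------------------------
## GrowthFit: fitted MM / generalized-MM curve for one generation
## ---------------------------------------------------------------------------

#' Fitted growth curve of one generation
#'
#' Michaelis-Menten chamber-building rate (CBR, parameters `mmax`, `b`) or
#' generalized Michaelis-Menten diameter-increase rate (DIR, parameters
#' `m0`, `mmax`, `b`, `c`), with the onset interval selected by grid search.
#' Time `t` is measured in days since birth; the first observed component of
#' the generation sits at `t = onsetDays`.
#'
#' @slot kind `"CBR"` or `"DIR"`.
#' @slot trajectoryKind `"max"` (means inflated to cohort maxima) or `"mean"`.
#' @slot parameters named numeric vector of curve parameters.
#' @slot onsetDays fitted onset (days between birth and first appearance).
#' @slot onsetReference date of the generation's first observed component;
#'   birth date of the cohort is `onsetReference - onsetDays`.
#' @slot reducedChi2 reduced chi-square of the selected fit.
#' @slot cvMean pooled coefficient of variation used to build the maxima.
#' @slot generation generation identifier.
#' @slot character `"NoC"` or `"TD"`.
#' @export
setClass("GrowthFit",
  representation(
    kind           = "character",
    trajectoryKind = "character",
    parameters     = "numeric",
    onsetDays      = "numeric",
    onsetReference = "Date",
    reducedChi2    = "numeric",
    cvMean         = "numeric",
    generation     = "numeric",
    character      = "character"
  )
)

setValidity("GrowthFit", function(object) {
  p <- object@parameters
  if (object@kind == "CBR") {
    if (!all(c("mmax", "b") %in% names(p)))
      return("CBR parameters must be named mmax, b")
    if (p[["mmax"]] <= 0 || p[["b"]] <= 0)
      return("mmax and b must be positive")
  } else if (object@kind == "DIR") {
    if (!all(c("m0", "mmax", "b", "c") %in% names(p)))
      return("DIR parameters must be named m0, mmax, b, c")
    if (p[["m0"]] <= 0 || p[["m0"]] >= p[["mmax"]])
      return("need 0 < m0 < mmax")
    if (p[["b"]] <= 0) return("b must be positive")
    if (p[["c"]] <= 1) return("shape exponent c must exceed 1 (sigmoid)")
  } else return("kind must be 'CBR' or 'DIR'")
  if (object@onsetDays < 0) return("onsetDays must be nonnegative")
  TRUE
})

## ---------------------------------------------------------------------------
## Simulation classes
## ---------------------------------------------------------------------------

#' Configuration of the forward population simulator
#'
#' Defines the ground-truth growth curves, the seasonal birth intensity
#' (offset plus sinusoids, a nonhomogeneous Poisson rate in births/day), the
#' sampling design and the observation noise of a simulated population.
#'
#' @slot cbrParams named numeric `mmax`, `b` of the chamber-number curve.
#' @slot dirParams named numeric `m0`, `mmax`, `b`, `c` of the diameter curve.
#' @slot individualCV relative sd of the per-individual asymptote multiplier.
#' @slot birthOffset baseline birth intensity (births/day).
#' @slot birthSinusoids data.frame `period`, `amplitude`, `phase` added to the
#'   baseline.
#' @slot spanDays length of the simulated study (days).
#' @slot samplingDays days (since study start) on which samples are taken.
#' @slot sampleFraction fraction of the living population caught per sampling.
#' @slot maxAgeDays age at which individuals die/leave the population.
#' @slot warmupDays births are drawn from `-warmupDays` so that the study
#'   samples an ongoing population with mature generations.
#' @slot nocNoiseProb probability of a +/-1 chamber miscount.
#' @slot tdNoiseSD sdlog of the multiplicative lognormal noise on TD.
#' @export
setClass("SimulationConfig",
  representation(
    cbrParams      = "numeric",
    dirParams      = "numeric",
    individualCV   = "numeric",
    birthOffset    = "numeric",
    birthSinusoids = "data.frame",
    spanDays       = "numeric",
    samplingDays   = "numeric",
    sampleFraction = "numeric",
    maxAgeDays     = "numeric",
    warmupDays     = "numeric",
    nocNoiseProb   = "numeric",
    tdNoiseSD      = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  if (object@individualCV < 0) return("individualCV must be >= 0")
  if (object@sampleFraction <= 0 || object@sampleFraction > 1)
    return("sampleFraction must lie in (0, 1]")
  if (object@maxAgeDays <= 0) return("maxAgeDays must be positive")
  if (object@birthOffset < 0) return("birth offset must be nonnegative")
  bs <- object@birthSinusoids
  if (nrow(bs) && !all(c("period", "amplitude", "phase") %in% names(bs)))
    return("birthSinusoids needs columns period, amplitude, phase")
  if (object@warmupDays < 0) return("warmupDays must be >= 0")
  ## the intensity must be nonnegative everywhere births are drawn
  tt <- seq(-object@warmupDays, object@spanDays, by = 0.25)
  if (any(birthIntensity(object, tt) < -1e-9))
    return("birth intensity is negative somewhere on the span")
  if (any(object@samplingDays < 0 | object@samplingDays > object@spanDays))
    return("samplingDays must lie within the span")
  TRUE
})

#' Simulated population with ground truth
#'
#' @slot truth data.frame per individual: `id`, `birth_day`, `scale`
#'   (individual asymptote multiplier).
#' @slot observed data.frame of sampled records: `specimen_id`, `sampling_day`,
#'   `birth_day`, `chamber_count`, `test_diameter`, `sample_size`.
#' @slot config the [SimulationConfig-class] that produced it.
#' @export
setClass("SimulatedPopulation",
  representation(
    truth    = "data.frame",
    observed = "data.frame",
    config   = "SimulationConfig"
  )
)

## ---------------------------------------------------------------------------
## StudyConfig
## ---------------------------------------------------------------------------

#' Run configuration of the analysis pipeline
#'
#' @slot studyStart,studyEnd study window (dates).
#' @slot binWidthNoC histogram bin width for chamber numbers (chambers).
#' @slot binWidthLnTD histogram bin width for ln test diameter.
#' @slot onsetGrid numeric `(min, max, step)` of the coarse onset grid, days.
#' @slot maxComponents maximum number of normal components (1-3).
#' @slot seed RNG seed for the seeded multistart fits.
#' @slot sStarRule `"product"` (normalized sd = CV_mean * mean) or
#'   `"as-printed"` (CV_mean / mean; dimensionally inconsistent, kept for
#'   sensitivity checks).
#' @slot pseudoDays days of life at which the two nepiont pseudo-observations
#'   are placed.
#' @slot pseudoWeight least-squares weight of the pseudo-observations.
#' @slot slack tolerated relative mean decrease along a generation track.
#' @slot overrides data.frame `date`, `component`, `generation` forcing the
#'   generation assignment of individual components.
#' @export
setClass("StudyConfig",
  representation(
    studyStart    = "Date",
    studyEnd      = "Date",
    binWidthNoC   = "numeric",
    binWidthLnTD  = "numeric",
    onsetGrid     = "numeric",
    maxComponents = "numeric",
    seed          = "numeric",
    sStarRule     = "character",
    pseudoDays    = "numeric",
    pseudoWeight  = "numeric",
    slack         = "numeric",
    overrides     = "data.frame"
  )
)

setValidity("StudyConfig", function(object) {
  g <- object@onsetGrid
  if (length(g) != 3 || g[1] <= 0 || g[2] < g[1] || g[3] <= 0)
    return("onsetGrid must be (min, max, step) with 0 < min <= max, step > 0")
  if (!object@maxComponents %in% 1:3)
    return("maxComponents must be 1, 2 or 3")
  if (!object@sStarRule %in% c("product", "as-printed"))
    return("sStarRule must be 'product' or 'as-printed'")
  if (length(object@pseudoDays) != 2 || any(object@pseudoDays <= 0))
    return("pseudoDays must be two positive days")
  TRUE
})
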