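---
title: "Growth, reproduction timing and longevity from size-frequency samples"
author: "foramDynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth, reproduction timing and longevity from size-frequency samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foramDynamics)
```

## The problem

Larger benthic foraminifera of the mesophotic zone cannot be observed
continuously in the field and grow differently in culture. The "natural
laboratory" approach replaces direct observation with repeated monthly
sampling of one population: every sample yields a size-frequency
distribution of chamber numbers (NoC) and maximal test diameters (TD, µm),
and the month-to-month displacement of cohort modes carries the growth
signal. This vignette documents the model, the numerical choices, and what
the accompanying simulator does and does not establish.

## From histograms to cohorts

NoC is binned as counted; TD is binned on the natural-log scale because
test growth is multiplicative. Default bin widths are 5 chambers and 0.15
ln-units — coarse enough that a monthly sample of 10–50 specimens fills
bins, fine enough to separate co-occurring cohorts; both are arguments of
`studyConfig()`. All months of one analysis share one edge grid
(`histogramEdges()`), so distributions are comparable along the abscissa.

Samples are first screened with a Pearson chi-square test against a normal
distribution whose moments come from the binned data (`testNormality()`;
bins pooled inward until every expected count reaches 1, df = bins − 3).
Samples with fewer than 10 specimens are skipped by the pipeline: below
that, the screen and the decomposition are both uninformative.

`decomposeHistogram()` fits a sum of *k* scaled Gaussian curves to the bin
counts by seeded multistart nonlinear least squares (`minpack.lm::nls.lm`,
10 restarts, means seeded at histogram modes with the later restarts
sampling modes in proportion to the counts). The component `density` is
its peak height in count units — the expected count in the bin at the
component mean — so a component's implied total is
`density · sd · √(2π) / binwidth`; the fit conserves the sample size in
that sense to within sampling noise. Constraints keep the optimization on
the science: component means stay on the histogram axis, a component sd is
at least a quarter and at most the pooled sample sd plus one bin width
(anything wider is a pedestal, not a cohort), and components whose implied
total falls below one specimen, whose sd falls below half a bin width, or
whose means collide within one bin width are dropped and the fit repeated
with fewer components. The number of components is the smallest *k* whose
reduced chi-square is not improved by more than 20% by *k* + 1 — ties go
to fewer components, and at most three are allowed, matching how many
cohorts ever co-occur in these populations. The reduced chi-square
denominator floors expected counts at 0.5 so empty tail bins cannot
dominate. Given the seed the result is deterministic.

## Generations and trajectories

`assignGenerations()` links components across months greedily: within a
month (components in decreasing-mean order) each component joins the open
track whose last mean is nearest, provided growth is non-negative within a
slack of 15% relative decrease (sampling noise); otherwise it opens a new
generation. Tracks that can no longer be matched are closed. Two
admissible tracks trigger a warning and resolve to the smaller gap.
Real campaigns need judgment calls the greedy rule cannot make — an old
generation fading out in the same month a young one passes through the
same size class — so a manual override map `(date, component) →
generation` is honoured first; the shipped Sesoko tables
(`sesokoComponents()`) carry such an identification. One entry there
deserves a note: at the 50 m station the September component at 38.2 mean
chambers is placed in the third generation, because the second generation
had already reached that size three months earlier (a cohort does not stop
growing for a hundred days), while the third generation — present since
August at 29.2 chambers — reaches exactly that size by September under its
own early growth, mirroring the shallow station where the third generation
first appears in September at 36.6 chambers.

For a track, `pooledCV()` averages the component CVs (sd/mean); pooling is
per generation and character, so truncated neighbouring generations do not
contaminate it. The cohort maximum used for growth fitting is
`m = x̄ (1 + 3 CV_mean)`, i.e. the normalized sd is `s* = CV_mean · x̄`.
The alternative form `s* = CV_mean / x̄` is dimensionally inconsistent
(a standard deviation must carry the character's units) and would make the
"maximum" indistinguishable from the mean; it remains available as
`sStarRule = "as-printed"` for sensitivity checks. Mean trajectories
(`meanTrajectory()`) are first-class as well, since both maximal and mean
growth curves are of interest.

## Growth curves and the onset search

Chamber building follows the Michaelis–Menten curve `m_max t / (b + t)`
through the origin; diameter growth follows the generalized logistic MM
`(m0 b^c + m_max t^c) / (b^c + t^c)` with shape exponent `c > 1`, because
the tight early whorls add diameter slowly. `fitGrowth()` is
deterministic: the linear parameters (`m_max`; or `m0` and `m_max`) are
profiled out exactly on a grid over the nonlinear ones (`b`; or `b` and
`c`, with `c` scanned in 1.01–8), then a Levenberg–Marquardt polish runs
under bounds (`m_max` at most 10× the largest observation, `m0` at most
1.5× the smallest, `c` in (1, 12], `b` positive) that keep truncated,
nearly flat trajectories from driving the asymptote to infinity. Fit
quality is the reduced chi-square `Σ (obs − fit)² / fit / (n − k)`.

A cohort is born an *onset* interval before its first appearance as a
component. `onsetSearch()` scans onsets of 10–70 days in 5-day steps and
then day-wise around the best candidate, mapping sample dates to
`t = days since first appearance + onset`. Two nepiont pseudo-observations
anchor the origin region with double weight: chamber numbers 2 and 3 (for
diameters, the population's measured mean diameters at those chamber
counts), placed at days 1 and 2 of life. The placement follows the
species' biology — freshly released juveniles build their first chambers
within days, and the fitted day-table itself reaches ~33 chambers by day
30, so placing the 3-chamber stage weeks into life would contradict the
very curve being fitted and, worse, make every onset equally (im)plausible;
the days remain configurable (`pseudoDays`). Candidates are scored by the
reduced chi-square over all points, pseudo-observations included —
scoring the trajectory alone lets the chi-square decrease monotonically
with the onset and the search run to the grid edge. The diameter fit
reuses the chamber fit's onset for the same generation, since one cohort
has one birth. On noiseless data with the pseudo-observations disabled
(`pseudoWeight = 0`) the search recovers the generating onset exactly;
the test suite asserts this.

Birthdate inversion uses the exact algebraic inverses of the two curves
(`invertCBR()`, `invertDIR()`). Specimens at or beyond the fitted
asymptote have no finite model age; they are excluded and counted rather
than clamped, which would fabricate arbitrarily large ages. Diameters
below the nepiont size get age 0 and a flag. The pipeline inverts the
generation whose component means span the widest observed range — the
generation whose growth was actually watched from juvenile to near-adult —
with ties resolved to the higher fitted asymptote; `inversionGeneration`
overrides the choice. Monthly histograms weight specimens by 1 (stations
where sampled volumes are comparable) or by `1/sample size` (stations with
strongly varying sample sizes), and longevity is the largest
birth-to-sampling difference among included specimens.

## Periodicity

`lombPeriodogram()` implements the classical normalized Lomb periodogram
(no installed package provides one), scanning frequencies from 1/span to
the Nyquist frequency of the median sampling interval at 4× oversampling;
peak significance uses the standard exponential false-alarm approximation
with the independent-frequency count set to the scanned range over the
oversampling factor — adequate for flagging dominant peaks at α = 0.05,
and cross-checked in the tests against planted sinusoids. The series
analysed are the monthly birthdate densities placed at month midpoints.
`nyquistScan()` greedily selects up to three frequencies by explained
variance, but refits all selected sinusoids jointly after each selection
and then refines each frequency by coordinate descent against the joint
model — a plain fit-and-subtract scheme leaves leakage bias on every
frequency after the first. `harmonicPeriods()` gives the annual series
365/k; sums of sinusoids over harmonic periods are exactly year-periodic,
which makes them the only basis suited to extrapolation beyond the
sampled window. `fitSinusoidSum()` solves the fixed-period problem by
linear least squares (sine/cosine pairs plus offset), so amplitudes and
phases are exact given the periods.

## The simulator and what it shows

`simulationScenario()` ships two configurations emulating the study
conditions. Both use chamber growth with `m_max = 72.6`, `b = 36` days
(initial rate ~2 chambers/day) and sigmoid diameter growth from a 293.7 µm
nepiont toward 5,000 µm (`b = 250` d, `c = 1.6`), a 450-day maximal age
matching the observed longevity scale, lognormal individual variation of
the asymptotes at CV 0.1, a 450-day span with 17 near-monthly samplings,
and observation noise of ±1 chamber at probability 0.1 and 5% lognormal
diameter noise (all configurable; the noise levels are deliberately small,
of the order of measurement repeatability). The `"20m"` scenario has a
dominant summer birth pulse about three times the winter pulse; `"50m"` is
balanced with a winter lean. Births are a nonhomogeneous Poisson process
(offset plus sinusoids, simulated by thinning) drawn also over a pre-study
warm-up of one maximal age, so the first sample already contains mature
generations, as any real campaign does.

The simulator establishes that the machinery is correct: growth-curve
fitting recovers the generating parameters from noisy per-specimen records,
inversion plus histogramming locates the planted reproduction pulses, and
the pipeline is seed-reproducible end to end. It does **not** establish
field accuracy of the full decomposition–tracking chain under continuous
background reproduction: when births never cease, monthly mixtures of ages
pile up near the growth asymptote, decomposed components blend neighbouring
cohorts, and tracks near the asymptote are intrinsically ambiguous (two
cohorts within one bin width are one component by construction). The same
limitation affects real data and is why the manual override map exists.
The simulator also omits spatial patchiness, sediment-weight effects, the
microspheric (sexual) part of the trimorphic life cycle, and any feedback
of environment on growth.

## Problem sizes and determinism

The shipped tests run the decomposition on samples of 120–280 specimens,
parameter-recovery and pulse-recovery properties on 50 seeded replicates
each, and the full pipeline on a simulated campaign of ~300 records —
sizes chosen to match the real campaign's scale while keeping a complete
run in a few minutes. Every stochastic step (multistart seeding, simulator
draws) flows from an explicit seed through an RNG-state-preserving wrapper,
so repeated calls are byte-identical and independent of the caller's RNG
state.

## Known limitations

* Fits to the published component tables inherit the uncertainty of the
  generation identification, which for two months cannot be derived
  mechanically from the printed parameters alone.
* The onset and `b` are partially confounded when a trajectory lacks early
  points; the chi-square surface is then flat over several days of onset,
  and the reported onset should be read with that width in mind.
* The 50 m diameter analysis requires raw per-specimen data (the published
  50 m diameter component block is a printing erratum); the package
  therefore ships chamber components only for that station.
* Reduced chi-square with floored expected counts is a pragmatic, not
  exact, small-count statistic; it ranks fits, which is all the selection
  rules need.
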