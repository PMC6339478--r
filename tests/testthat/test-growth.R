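test_that("the MM curve obeys its defining identities", {
  p <- c(mmax = 70, b = 35)
  expect_equal(mmEval(p, 0), 0)
  expect_equal(mmEval(p, 35), 35)             # half-asymptote at t = b
  expect_error(mmEval(p, -1), "nonnegative")
  ## parameters solved from two tabulated points (day 30 -> 33, day 360 -> 66)
  ## reproduce a third: day 90 rounds to 52
  b <- 36; mmax <- 72.6
  expect_equal(round(mmEval(c(mmax = mmax, b = b), 30)), 33)
  expect_equal(round(mmEval(c(mmax = mmax, b = b), 360)), 66)
  expect_equal(round(mmEval(c(mmax = mmax, b = b), 90)), 52)
})

test_that("the MM derivative is exact and strictly decreasing", {
  p <- c(mmax = 72.6, b = 36)
  expect_equal(mmDerivative(p, 0), 72.6 / 36)
  tt <- seq(0, 400, by = 7)
  expect_true(all(diff(mmDerivative(p, tt)) < 0))
  ## central finite differences of the curve
  hh <- 1e-4
  num <- (mmEval(p, tt + hh) - mmEval(p, pmax(tt - hh, 0))) /
    (tt + hh - pmax(tt - hh, 0))
  expect_equal(mmDerivative(p, tt), num, tolerance = 1e-6)
})

test_that("the generalized MM starts at m0, halves at b and saturates at mmax", {
  p <- c(m0 = 293.7, mmax = 6000, b = 250, c = 1.7)
  expect_equal(gmmEval(p, 0), 293.7)
  expect_equal(gmmEval(p, 250), (293.7 + 6000) / 2)
  expect_lt(abs(gmmEval(p, 1e6 * 250) - 6000) / 6000, 1e-3)
  expect_error(gmmEval(p, -2), "nonnegative")
})

test_that("exact MM data are recovered to numerical precision", {
  t <- c(1, 2, 20, 50, 90, 150, 250, 380)
  m <- mmEval(c(mmax = 72.6, b = 36), t)
  fit <- fitGrowth(t, m, "CBR")
  expect_equal(unname(fit$parameters[["mmax"]]), 72.6, tolerance = 1e-7)
  expect_equal(unname(fit$parameters[["b"]]), 36, tolerance = 1e-7)
  expect_lt(fit$reducedChi2, 1e-12)
})

test_that("exact generalized-MM data are recovered", {
  p <- c(m0 = 293.7, mmax = 5200, b = 260, c = 1.8)
  t <- c(1, 2, 30, 60, 120, 180, 260, 340, 420)
  fit <- fitGrowth(t, gmmEval(p, t), "DIR")
  expect_equal(unname(fit$parameters), unname(p), tolerance = 1e-4)
  expect_lt(fit$reducedChi2, 1e-8)
})

test_that("a noiseless onset is recovered exactly by the grid search", {
  traj <- noiselessTrajectory(mmax = 70, b = 35, onset = 42)
  fit <- onsetSearch(traj, "CBR", pseudoWeight = 0)
  expect_equal(onsetDays(fit), 42)
  expect_equal(unname(growthParams(fit)[["mmax"]]), 70, tolerance = 1e-6)
  expect_equal(unname(growthParams(fit)[["b"]]), 35, tolerance = 1e-6)
  expect_equal(birthDate(fit), min(traj$date) - 42)
})

test_that("the selected onset beats every rejected candidate", {
  traj <- maximumTrajectory(sesokoTracks(20, "NoC"), 2)
  best <- onsetSearch(traj, "CBR")
  expect_gte(onsetDays(best), 10)
  expect_lte(onsetDays(best), 70)
  for (L in c(10, 25, 40, 55, 70)) {
    alt <- onsetSearch(traj, "CBR", fixedOnset = L)
    expect_gte(reducedChi2(alt), reducedChi2(best) - 1e-9)
  }
})

test_that("growth-fit parameters are recovered from noisy simulated specimens", {
  ## per-specimen (age, NoC) pairs from the simulator's truth, >= 150 records
  ok <- 0
  nRep <- 10
  for (i in seq_len(nRep)) {
    cfg <- simulationScenario("20m", sampleFraction = 0.12)
    pop <- simulatePopulation(cfg, seed = 2000 + i)
    obs <- pop@observed
    expect_gte(nrow(obs), 150)
    age <- obs$sampling_day - obs$birth_day
    fit <- fitGrowth(age, obs$chamber_count, "CBR")
    relM <- abs(fit$parameters[["mmax"]] - 72.6) / 72.6
    relB <- abs(fit$parameters[["b"]] - 36) / 36
    if (relM < 0.05 && relB < 0.10) ok <- ok + 1
  }
  expect_gte(ok / nRep, 0.8)
})

test_that("chamber growth reaches half its asymptote before diameter growth", {
  cfg <- simulationScenario("20m")
  tHalfNoC <- cfg@cbrParams[["b"]]
  tHalfTD <- cfg@dirParams[["b"]]
  expect_lt(tHalfNoC, tHalfTD)
  ## and the same ordering holds for curves fitted to one simulated cohort
  t <- c(1, 2, seq(20, 420, by = 40))
  mN <- mmEval(cfg@cbrParams, t)
  mT <- gmmEval(cfg@dirParams, t)
  fN <- fitGrowth(t, mN, "CBR")$parameters
  fT <- fitGrowth(t, mT, "DIR")$parameters
  expect_lt(fN[["b"]], fT[["b"]])
})

test_that("growth tables telescope and never decrease", {
  fit <- onsetSearch(noiselessTrajectory(), "CBR", pseudoWeight = 0)
  tab <- growthTable(fit)
  expect_true(all(diff(tab$value) >= 0))
  daily <- growthTable(fit, days = 0:60)
  expect_equal(sum(daily$rate[-1]),
               mmEval(fit, 60) - mmEval(fit, 0), tolerance = 0.6)
  expect_equal(tab$day, c(1:7, 10, 15, 30, 60, 90, 120, 150, 180, 210, 240,
                          270, 300, 330, 360))
})

test_that("degenerate trajectories are rejected with a diagnostic", {
  expect_error(fitGrowth(c(1, 2), c(3, 4), "CBR"), "at least 3")
  expect_error(fitGrowth(c(1, 2, 3, 4), c(5, 6, 7, 8), "DIR"), "at least 5")
  expect_error(onsetSearch(noiselessTrajectory()[1:3, ], "CBR"),
               "at least 4")
})
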