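test_that("constant intensity gives Poisson birth counts", {
  cfg <- simulationConfig(birthOffset = 1.5,
                          birthSinusoids = data.frame(period = numeric(),
                                                      amplitude = numeric(),
                                                      phase = numeric()),
                          spanDays = 400, warmupDays = 0)
  b <- simulateBirths(cfg, seed = 10)
  expect_true(all(b >= 0 & b <= 400))
  lam <- 1.5 * 400
  expect_lt(abs(length(b) - lam), 4 * sqrt(lam))
})

test_that("zero intensity yields no births; negative intensity is rejected", {
  cfg <- simulationConfig(birthOffset = 0,
                          birthSinusoids = data.frame(period = numeric(),
                                                      amplitude = numeric(),
                                                      phase = numeric()))
  expect_length(simulateBirths(cfg, seed = 1), 0)
  expect_error(simulationConfig(birthOffset = 0.2,
                                birthSinusoids = data.frame(period = 365,
                                                            amplitude = 1,
                                                            phase = 0)),
               "negative")
})

test_that("birth histograms peak at the intensity maximum", {
  ## amplitude equal to the offset: the intensity vanishes at the trough and
  ## peaks once a year; the phase puts the maximum mid-month (day 76) so the
  ## target month is unambiguous
  phase <- pi / 2 - 2 * pi * 76 / 365
  cfg <- simulationConfig(birthOffset = 1,
                          birthSinusoids = data.frame(period = 365,
                                                      amplitude = 1,
                                                      phase = phase),
                          spanDays = 365, warmupDays = 0)
  ok <- 0; nRep <- 50
  for (i in seq_len(nRep)) {
    b <- simulateBirths(cfg, seed = 3000 + i)
    mo <- floor(b / 30.42)
    peakMo <- as.integer(names(which.max(table(mo))))
    if (abs(peakMo - 2) <= 1) ok <- ok + 1
  }
  expect_gte(ok / nRep, 0.9)
})

test_that("the simulator is byte-identical under a fixed seed", {
  cfg <- simulationScenario("20m")
  p1 <- simulatePopulation(cfg, seed = 77)
  p2 <- simulatePopulation(cfg, seed = 77)
  expect_identical(p1@truth, p2@truth)
  expect_identical(p1@observed, p2@observed)
  p3 <- simulatePopulation(cfg, seed = 78)
  expect_false(identical(p1@observed, p3@observed))
})

test_that("full sampling without mortality captures every living individual", {
  cfg <- simulationConfig(sampleFraction = 1, maxAgeDays = 1e6,
                          warmupDays = 0, spanDays = 200,
                          samplingDays = c(60, 120, 190),
                          birthOffset = 0.4,
                          birthSinusoids = data.frame(period = numeric(),
                                                      amplitude = numeric(),
                                                      phase = numeric()))
  b <- simulateBirths(cfg, seed = 5)
  pop <- growAndSample(b, cfg, seed = 5)
  obs <- pop@observed
  for (d in cfg@samplingDays) {
    expect_equal(sum(obs$sampling_day == d), sum(b < d))
  }
})

test_that("mortality removes individuals older than the maximal age", {
  cfg <- simulationConfig(sampleFraction = 1, maxAgeDays = 100,
                          warmupDays = 300, spanDays = 100,
                          samplingDays = c(50),
                          birthOffset = 0.5,
                          birthSinusoids = data.frame(period = numeric(),
                                                      amplitude = numeric(),
                                                      phase = numeric()))
  pop <- simulatePopulation(cfg, seed = 6)
  age <- pop@observed$sampling_day - pop@observed$birth_day
  expect_true(all(age > 0 & age < 100))
})

test_that("noiseless growth reproduces the curve exactly", {
  cfg <- simulationConfig(individualCV = 0, nocNoiseProb = 0, tdNoiseSD = 0,
                          sampleFraction = 1, warmupDays = 0)
  b <- simulateBirths(cfg, seed = 8)
  pop <- growAndSample(b, cfg, seed = 8)
  obs <- pop@observed
  age <- obs$sampling_day - obs$birth_day
  expect_equal(obs$chamber_count,
               pmax(round(mmEval(cfg@cbrParams, age)), 2))
  expect_equal(obs$test_diameter, gmmEval(cfg@dirParams, age))
})

test_that("simulated populations convert to valid specimen tables", {
  pop <- simulatePopulation(simulationScenario("50m"), seed = 9)
  fs <- asForamSamples(pop, origin = as.Date("2014-04-23"), depth = 50)
  expect_s4_class(fs, "ForamSamples")
  expect_equal(nrow(specimens(fs)), nrow(pop@observed))
  expect_true(all(specimens(fs)$chamber_count >= 2))
  ## the scenario emulates the campaign scale (hundreds of specimens)
  expect_gt(nrow(specimens(fs)), 100)
})
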