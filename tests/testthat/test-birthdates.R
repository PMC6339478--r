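.rec <- function(noc = NA, td = NA, date = "2014-08-19") {
  data.frame(specimen_id = sprintf("s%02d", seq_along(date)),
             sampling_date = as.Date(date),
             chamber_count = noc, test_diameter = td)
}

test_that("CBR inversion is the exact algebraic inverse of the curve", {
  p <- c(mmax = 72.6, b = 36)
  tstar <- c(5, 30, 120, 390)
  rec <- .rec(noc = mmEval(p, tstar), date = rep("2014-08-19", 4))
  out <- invertCBR(p, rec)
  expect_equal(out$age_days, tstar, tolerance = 1e-10)
  ## hand-checkable case: NoC 33 -> 33 * 36 / 39.6 = 30 days
  out1 <- invertCBR(p, .rec(noc = 33))
  expect_equal(out1$age_days, 30)
  expect_equal(out1$birth_date, as.Date("2014-08-19") - 30)
})

test_that("CBR age grows monotonically and diverges toward the asymptote", {
  p <- c(mmax = 72.6, b = 36)
  noc <- seq(2, 72, by = 0.5)
  ages <- invertCBR(p, .rec(noc = noc, date = rep("2014-08-19", length(noc))))$age_days
  expect_true(all(diff(ages) > 0))
  expect_gt(max(ages), 2000)   # near the pole the age explodes
})

test_that("specimens beyond the asymptote are excluded and counted", {
  p <- c(mmax = 60, b = 30)
  rec <- .rec(noc = c(30, 60, 65), date = rep("2014-08-19", 3))
  expect_warning(out <- invertCBR(p, rec), "2 specimen")
  expect_equal(nrow(out), 1)
  expect_equal(attr(out, "excluded"), 2)
})

test_that("DIR inversion roundtrips and flags sub-nepiont diameters", {
  p <- c(m0 = 293.7, mmax = 6000, b = 250, c = 1.7)
  tstar <- c(3, 40, 200, 420)
  rec <- .rec(td = gmmEval(p, tstar), date = rep("2014-08-19", 4))
  out <- invertDIR(p, rec)
  expect_equal(out$age_days, tstar, tolerance = 1e-9)
  expect_false(any(out$flagged))
  ## TD = m0 gives age 0; TD below m0 is flagged at age 0
  out0 <- invertDIR(p, .rec(td = c(293.7, 250), date = rep("2014-08-19", 2)))
  expect_equal(out0$age_days, c(0, 0))
  expect_equal(out0$flagged, c(FALSE, TRUE))
  ## age strictly increasing across the admissible diameter range
  td <- seq(294, 5990, by = 12)
  ages <- invertDIR(p, .rec(td = td, date = rep("2014-08-19", length(td))))$age_days
  expect_true(all(diff(ages) > 0))
})

test_that("inversion then evaluation is the identity over random parameters", {
  set.seed(9)
  for (i in 1:25) {
    pc <- c(mmax = runif(1, 40, 120), b = runif(1, 10, 80))
    tt <- runif(6, 1, 400)
    rec <- .rec(noc = mmEval(pc, tt), date = rep("2014-08-19", 6))
    expect_equal(invertCBR(pc, rec)$age_days, tt, tolerance = 1e-6)
    m0 <- runif(1, 200, 400)
    pd <- c(m0 = m0, mmax = m0 + runif(1, 2000, 9000),
            b = runif(1, 80, 500), c = runif(1, 1.1, 3))
    rec <- .rec(td = gmmEval(pd, tt), date = rep("2014-08-19", 6))
    expect_equal(invertDIR(pd, rec)$age_days, tt, tolerance = 1e-6)
  }
})

test_that("birthdate histograms weight specimens as configured", {
  p <- c(mmax = 72.6, b = 36)
  rec <- invertCBR(p, .rec(noc = rep(33, 42), date = rep("2014-08-19", 42)))
  hb <- birthdateHistogram(rec, "per_sample")
  expect_equal(sum(hb$density), 1)                   # 42 specimens at 1/42
  expect_equal(max(hb$density), 1)
  hb2 <- birthdateHistogram(rec, "simple")
  expect_equal(sum(hb2$density), 42)
  expect_equal(nrow(hb2[hb2$density > 0, ]), 1)      # all born the same month
})

test_that("fully included samples contribute weight one each", {
  p <- c(mmax = 72.6, b = 36)
  rec <- invertCBR(p, .rec(noc = c(20, 30, 40, 25, 35),
                           date = c(rep("2014-08-19", 3), rep("2014-09-10", 2))))
  hb <- birthdateHistogram(rec, "per_sample")
  expect_equal(sum(hb$density), 2)                   # one per sample
})

test_that("longevity is the maximum birth-to-sampling difference", {
  rec <- data.frame(age_days = c(10, 100, 55))
  expect_equal(estimateLongevity(rec), 100)
  p <- c(mmax = 60, b = 30)
  suppressWarnings(out <- invertCBR(p, .rec(noc = c(30, 61), date = rep("2014-08-19", 2))))
  ## the beyond-asymptote specimen cannot dominate the longevity
  expect_equal(estimateLongevity(out), 30)
})

test_that("histogram peak months recover planted reproduction pulses", {
  ## simulate, invert with the true curve, and locate the histogram peak
  ok <- 0; nRep <- 50
  for (i in seq_len(nRep)) {
    cfg <- simulationScenario("20m", sampleFraction = 0.08)
    pop <- simulatePopulation(cfg, seed = 500 + i)
    fs <- asForamSamples(pop, origin = as.Date("2014-04-23"))
    rec <- suppressWarnings(invertCBR(cfg@cbrParams, fs))
    hb <- birthdateHistogram(rec, "simple")
    peak <- hb$month[which.max(hb$density)]
    ## planted intensity peaks in late July of either year
    targets <- as.Date(c("2014-07-01", "2015-07-01"))
    off <- min(abs(vapply(targets, function(tg)
      (as.POSIXlt(peak)$year * 12 + as.POSIXlt(peak)$mon) -
        (as.POSIXlt(tg)$year * 12 + as.POSIXlt(tg)$mon), 0)))
    if (off <= 1) ok <- ok + 1
  }
  expect_gte(ok / nRep, 0.8)
})
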