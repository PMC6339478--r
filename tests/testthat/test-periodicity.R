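## uneven monthly-ish sampling grid used throughout
.tgrid <- function(n = 16, seed = 3) {
  set.seed(seed)
  sort(cumsum(runif(n, 20, 40)))
}

test_that("a planted sinusoid dominates the Lomb periodogram", {
  t <- .tgrid(16)
  y <- 3 + 2 * sin(2 * pi * t / 130 + 0.7)
  pg <- lombPeriodogram(t, y)
  top <- pg$period[which.max(pg$power)]
  grid_step <- max(abs(diff(pg$period[seq(which.max(pg$power) - 1,
                                          which.max(pg$power) + 1)])))
  expect_lt(abs(top - 130), grid_step + 1e-9)
  expect_lt(min(pg$fap), 0.05)
})

test_that("constant series carry no spectral power", {
  t <- .tgrid(12)
  pg <- lombPeriodogram(t, rep(4.2, length(t)))
  expect_true(all(pg$power == 0))
  expect_equal(nrow(periodogramPeaks(pg)), 0)
})

test_that("the periodogram is invariant to adding a constant", {
  t <- .tgrid(14, seed = 8)
  y <- sin(2 * pi * t / 200) + rnorm(length(t), 0, 0.1)
  p1 <- lombPeriodogram(t, y)
  p2 <- lombPeriodogram(t, y + 57.3)
  expect_equal(p1$power, p2$power, tolerance = 1e-12)
})

test_that("harmonic periods divide the year", {
  expect_equal(harmonicPeriods(3), c(365, 182.5, 121.7))
  expect_equal(harmonicPeriods(1), 365)
  expect_true(all(diff(harmonicPeriods(6)) < 0))
})

test_that("the Nyquist scan respects the sampling limit and finds planted periods", {
  t <- .tgrid(16, seed = 5)
  med <- median(diff(t))
  y <- 2 * sin(2 * pi * t / 300 + 1) + 1.2 * sin(2 * pi * t / 130 + 2)
  sc <- nyquistScan(t, y, k = 3)
  expect_true(all(sc$period >= 2 * med - 1e-9))
  ## both planted periods recovered within one grid step
  span <- diff(range(t))
  fstep <- (1 / (2 * med) - 1 / span) / (2000 - 1)
  for (P in c(300, 130)) {
    hit <- min(abs(1 / sc$period - 1 / P))
    expect_lt(hit, fstep * 1.5)
  }
})

test_that("a single planted sinusoid leaves little residual variance to others", {
  t <- .tgrid(18, seed = 9)
  y <- 5 + 3 * sin(2 * pi * t / 250 + 0.3)
  sc <- nyquistScan(t, y, k = 3)
  expect_gt(sc$r2[1], 0.9)
  expect_lt(abs(1 / sc$period[1] - 1 / 250), 1e-3)
  expect_true(all(sc$r2[-1] < 0.999))   # later steps act on near-noise residue
})

test_that("sums of sinusoids are fitted by exact linear algebra", {
  t <- .tgrid(20, seed = 2)
  fit0 <- fitSinusoidSum(t, rep(0, length(t)), c(365, 182.5))
  expect_true(all(fit0$components$amplitude < 1e-12))
  y <- 1 + 2.5 * sin(2 * pi * t / 310 + 1.1)
  fit1 <- fitSinusoidSum(t, y, 310)
  expect_equal(fit1$components$amplitude, 2.5, tolerance = 1e-8)
  expect_equal(fit1$components$phase, 1.1, tolerance = 1e-8)
  expect_equal(fit1$offset, 1, tolerance = 1e-8)
  expect_error(fitSinusoidSum(t, y, c(310, 310)), "collinear")
})

test_that("noisy three-sinusoid series recover their amplitudes", {
  set.seed(4)
  t <- sort(runif(60, 0, 900))
  true <- data.frame(period = c(365, 137, 80), amplitude = c(10, 6, 3),
                     phase = c(0.5, 1.5, 2.5))
  y <- 20
  for (i in 1:3) y <- y + true$amplitude[i] * sin(2 * pi * t / true$period[i] + true$phase[i])
  y <- y + rnorm(length(t), 0, 1)          # sd = 10% of the largest amplitude
  fit <- fitSinusoidSum(t, y, true$period)
  expect_equal(fit$components$amplitude, true$amplitude, tolerance = 0.15)
})

test_that("adding a sinusoid never increases the residual sum of squares", {
  set.seed(6)
  t <- .tgrid(18, seed = 6)
  y <- 2 + sin(2 * pi * t / 400) + rnorm(length(t), 0, 0.5)
  r1 <- fitSinusoidSum(t, y, 365)$rss
  r2 <- fitSinusoidSum(t, y, c(365, 182.5))$rss
  r3 <- fitSinusoidSum(t, y, c(365, 182.5, 121.7))$rss
  expect_lte(r2, r1 + 1e-10)
  expect_lte(r3, r2 + 1e-10)
})

test_that("harmonic sums repeat exactly after one year", {
  t <- .tgrid(20, seed = 12)
  y <- 3 + 2 * sin(2 * pi * t / 365) + sin(2 * pi * t / 182.5)
  fit <- fitSinusoidSum(t, y, c(365, 182.5, 365 / 3))
  probe <- seq(0, 700, by = 13)
  expect_equal(fit$predict(probe), fit$predict(probe + 365), tolerance = 1e-6)
})
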