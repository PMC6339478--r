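test_that("values are binned on fixed left-closed intervals", {
  h <- buildHistogram(c(3, 3, 7), "NoC", edges = c(0, 5, 10))
  expect_equal(binCounts(h), c(2, 1))
  expect_equal(sum(binCounts(h)), 3)
  expect_error(buildHistogram(c(3, 12), "NoC", edges = c(0, 5, 10)),
               "outside the bin range")
})

test_that("diameters are binned on the natural-log scale", {
  df <- data.frame(specimen_id = "x", sampling_date = as.Date("2014-05-02"),
                   station_depth = 20, chamber_count = 10,
                   test_diameter = exp(7))
  fs <- foramSamples(df)
  h <- buildHistogram(fs, "TD", edges = seq(6.05, 7.55, by = 0.1))
  expect_equal(h@character, "lnTD")
  mids <- binMids(h)
  expect_equal(mids[binCounts(h) == 1], 7)   # ln-bin [6.95, 7.05)
})

test_that("shared edges conserve every month's sample size", {
  fs <- foramSamples(tinySpecimenFrame())
  edges <- histogramEdges(specimens(fs)$chamber_count, 5)
  for (d in as.list(sampleDates(fs))) {
    h <- buildHistogram(fs, "NoC", edges = edges, date = d)
    expect_equal(sum(binCounts(h)), unname(sampleSizes(fs)[format(d)]))
  }
})

test_that("the normality screen accepts its own expected counts", {
  edges <- seq(10, 70, by = 5)
  mids <- edges[-length(edges)] + 2.5
  counts <- 200 * diff(pnorm(edges, 40, 8))
  ## iterate to the fixed point where estimated moments reproduce the counts
  for (i in 1:60) {
    n <- sum(counts)
    mu <- sum(mids * counts) / n
    s <- sqrt(sum(counts * (mids - mu)^2) / (n - 1))
    counts <- foramDynamics:::.expectedNormal(edges, n, mu, s)
  }
  h <- new("ForamHistogram", edges = edges, counts = counts,
           character = "NoC", samplingDate = as.Date("2014-05-02"))
  res <- testNormality(h)
  expect_lt(res[["statistic"]], 1e-4)
  expect_equal(res[["p"]], 1, tolerance = 1e-6)
})

test_that("the normality screen keeps its nominal size on normal samples", {
  set.seed(11)
  reject <- vapply(1:100, function(i) {
    x <- rnorm(200, 45, 7)
    h <- buildHistogram(x, "NoC", width = 5)
    testNormality(h)[["p"]] < 0.05
  }, TRUE)
  ## calibration: about alpha = 5%, certainly not more than ~10%
  expect_lte(mean(reject), 0.10)
})

test_that("too small samples raise an insufficient-data signal", {
  h <- buildHistogram(c(12, 13, 14), "NoC", width = 5)
  expect_error(testNormality(h), class = "foramInsufficientData")
})

test_that("planted two-component mixtures are recovered", {
  errHi <- errLo <- kk <- numeric(10)
  for (s in 1:10) {
    h <- mixtureHistogram(n = 200, seed = s)
    dec <- decomposeHistogram(h, seed = 1)
    cp <- components(dec)
    kk[s] <- nrow(cp)
    errHi[s] <- abs(cp$mean[1] - 55)   # sorted by decreasing mean
    errLo[s] <- abs(cp$mean[nrow(cp)] - 30)
    ## implied component totals track the sample size
    total <- sum(cp$density * cp$sd * sqrt(2 * pi) / binWidth(dec))
    expect_lt(abs(total - 200) / 200, 0.15)
  }
  expect_gte(mean(kk == 2), 0.9)
  expect_lt(median(errHi), 1.5)
  expect_lt(median(errLo), 1.5)
})

test_that("decomposition is deterministic given the seed", {
  h <- mixtureHistogram(n = 200, seed = 3)
  d1 <- decomposeHistogram(h, seed = 42)
  d2 <- decomposeHistogram(h, seed = 42)
  expect_identical(components(d1), components(d2))
})

test_that("all mass in one bin yields one component at the bin midpoint", {
  h <- buildHistogram(rep(12, 25), "NoC", edges = c(0, 5, 10, 15, 20))
  dec <- decomposeHistogram(h)
  expect_equal(nrow(components(dec)), 1)
  expect_equal(components(dec)$mean, 12.5)
})

test_that("single-normal samples select one component in most replicates", {
  k1 <- vapply(1:12, function(i) {
    set.seed(100 + i)
    x <- rnorm(150, 45, 7)
    h <- buildHistogram(x, "NoC", width = 5)
    nrow(components(decomposeHistogram(h, seed = i)))
  }, 0L)
  expect_gte(mean(k1 == 1), 0.9)
})

test_that("lnTD components are reported back-transformed to micrometres", {
  set.seed(5)
  td <- exp(rnorm(120, 7.3, 0.12))
  df <- data.frame(specimen_id = sprintf("s%03d", 1:120),
                   sampling_date = as.Date("2014-05-02"), station_depth = 20,
                   chamber_count = 30, test_diameter = td)
  h <- buildHistogram(foramSamples(df), "TD", width = 0.15)
  dec <- decomposeHistogram(h, seed = 2)
  rep <- components(dec)              # micrometres
  fitted <- components(dec, "fitted") # ln scale
  expect_equal(rep$mean, exp(fitted$mean))
  expect_equal(rep$sd, fitted$sd * exp(fitted$mean))
  expect_lt(abs(rep$mean[1] - exp(7.3)) / exp(7.3), 0.05)
})
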