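test_that("two interleaved growth sequences are recovered exactly", {
  tab <- interleavedComponentTable()
  tr <- assignGenerations(tab, character = "NoC")
  en <- trackTable(tr)
  g1 <- en$mean[en$generation == 1]
  g2 <- en$mean[en$generation == 2]
  expect_equal(sort(g1), c(10, 20, 30))
  expect_equal(sort(g2), c(5, 15, 25))
})

test_that("assignment is invariant to component order within a month", {
  tab <- interleavedComponentTable()
  set.seed(1)
  shuf <- tab[sample(nrow(tab)), ]
  a <- trackTable(assignGenerations(tab, character = "NoC"))
  b <- trackTable(assignGenerations(shuf, character = "NoC"))
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("components from two simulated generations are assigned to their cohort", {
  ## two cohorts 160 days apart, observed monthly with mild noise
  set.seed(21)
  hits <- 0; tot <- 0
  for (rep in 1:5) {
    tab <- twoCohortComponents()
    tr <- suppressWarnings(assignGenerations(tab[, 1:4], character = "NoC"))
    en <- trackTable(tr)
    en <- en[order(en$date, -en$mean), ]
    tab2 <- tab[order(tab$date, -tab$mean), ]
    ## map assigned generation to majority truth label
    for (g in unique(en$generation)) {
      lab <- tab2$truth[en$generation == g]
      hits <- hits + max(table(lab))
      tot <- tot + length(lab)
    }
  }
  expect_gte(hits / tot, 0.9)
})

test_that("early large components form one generation, small ones another (shallow station)", {
  tab <- sesokoComponents(20, "NoC")
  tr <- assignGenerations(tab[, c("date", "density", "mean", "sd")],
                          character = "NoC")
  en <- trackTable(tr)
  mayAug <- en[en$date <= as.Date("2014-08-19"), ]
  big <- mayAug$generation[mayAug$mean > 50]
  small <- mayAug$generation[mayAug$mean < 45]
  expect_equal(length(unique(big)), 1L)
  expect_equal(length(unique(small)), 1L)
  expect_true(unique(big) != unique(small))
  expect_equal(sort(mayAug$mean[mayAug$generation == unique(big)]),
               sort(c(54.6, 56.3, 52.4, 52.0)))
})

test_that("manual overrides force the published generation structure", {
  tr <- sesokoTracks(20, "NoC")
  en <- trackTable(tr, 2)
  expect_equal(en$mean, c(33.2, 39.5, 37.3, 40.8, 50.8, 50.8, 45.4, 54.1, 53.4))
  expect_equal(range(en$date), as.Date(c("2014-05-02", "2015-03-03")))
})

test_that("pooled CV is the mean of component CVs", {
  tab <- data.frame(date = as.Date("2014-05-01") + c(0, 30, 60),
                    density = 1, mean = c(10, 20, 20), sd = c(1, 2, 2))
  tr <- assignGenerations(tab, character = "NoC")
  expect_equal(pooledCV(tr, 1), 0.1)
  ## a single component: the direct quotient
  expect_equal(9.79 / 54.6, 0.1793, tolerance = 2e-4)
  ## identical CVs pool to that CV
  tab$sd <- tab$mean * 0.07
  expect_equal(pooledCV(assignGenerations(tab, character = "NoC"), 1), 0.07)
})

test_that("maximum trajectories scale the means by 1 + 3 CV", {
  tab <- data.frame(date = as.Date("2014-05-01") + c(0, 30, 60),
                    density = 1, mean = c(20, 30, 40), sd = c(2, 3, 4))
  tr <- assignGenerations(tab, character = "NoC")   # CV = 0.1
  traj <- maximumTrajectory(tr, 1)
  expect_equal(traj$m, traj$mean * 1.3)
  expect_equal(traj$m[traj$mean == 40], 52)
  ## constant ratio along the track, increasing in the mean
  expect_equal(unique(round(traj$m / traj$mean, 12)), 1.3)
  expect_true(all(diff(traj$m[order(traj$mean)]) > 0))
  ## zero CV collapses the maximum onto the mean
  tab$sd <- 1e-12
  expect_equal(maximumTrajectory(assignGenerations(tab, character = "NoC"), 1)$m,
               tab$mean)
  ## mean trajectory leaves the means untouched
  expect_equal(meanTrajectory(tr, 1)$m, traj$mean)
})

test_that("trajectory offsets are days since first appearance", {
  traj <- maximumTrajectory(sesokoTracks(20, "NoC"), 2)
  expect_equal(traj$offset[1:4], c(0, 28, 77, 109))
})
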