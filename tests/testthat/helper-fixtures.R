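## Shared fixtures, built in code at test time.

## a small specimen table spanning two sampling dates
tinySpecimenFrame <- function() {
  data.frame(
    specimen_id = c("a", "b", "c"),
    sampling_date = c("02.05.2014", "02.05.2014", "30.05.2014"),
    station_depth = 20,
    chamber_count = c(30, 45, 50),
    test_diameter = c(1500, 2500, 2800))
}

## two interleaved cohorts observed as one component each per month
interleavedComponentTable <- function() {
  dates <- as.Date("2014-05-01") + c(0, 30, 60)
  rbind(
    data.frame(date = dates, density = 5, mean = c(10, 20, 30), sd = 1),
    data.frame(date = dates, density = 5, mean = c(5, 15, 25), sd = 1))
}

## monthly components of two noisy MM cohorts with known membership; months
## where the cohort means fall within one bin width are dropped, since the
## decomposition stage only ever emits components at least one bin apart
twoCohortComponents <- function(binWidth = 5) {
  dates <- as.Date("2014-05-01") + seq(0, 330, by = 30)
  mk <- function(birth, lab) {
    age <- as.numeric(dates - as.Date("2014-05-01")) - birth + 40
    ok <- age > 0
    data.frame(date = dates[ok], density = 5,
               mean = mmEval(c(mmax = 72, b = 36), age[ok]) *
                 rlnorm(sum(ok), 0, 0.03),
               sd = 3, truth = lab)
  }
  tab <- rbind(mk(0, 1), mk(160, 2))
  drop <- vapply(as.list(tab$date), function(d) {
    mu <- tab$mean[tab$date == d]
    length(mu) == 2 && abs(diff(mu)) < binWidth
  }, TRUE)
  tab[!drop, ]
}

## histogram sampled from a two-component normal mixture
mixtureHistogram <- function(n = 200, seed = 7, w = 0.6,
                             mu = c(30, 55), s = c(4, 6), width = 5) {
  set.seed(seed)
  n1 <- rbinom(1, n, w)
  x <- c(rnorm(n1, mu[1], s[1]), rnorm(n - n1, mu[2], s[2]))
  buildHistogram(x, "NoC", width = width)
}

## noiseless generation trajectory from a known MM curve and onset
noiselessTrajectory <- function(mmax = 70, b = 35, onset = 42,
                                offsets = c(0, 28, 60, 95, 130, 170, 220, 300)) {
  structure(
    data.frame(date = as.Date("2014-05-01") + offsets,
               offset = offsets,
               mean = mmEval(c(mmax = mmax, b = b), offsets + onset),
               m = mmEval(c(mmax = mmax, b = b), offsets + onset)),
    generation = 2, character = "NoC", cvMean = 0, trajectoryKind = "max")
}
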