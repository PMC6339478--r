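## Periodicity of reproduction: Lomb periodogram for unevenly sampled
## birthdate series, Nyquist-bounded sinusoid scans, harmonic series, and
## sums of sinusoids. No installed package provides the Lomb periodogram, so
## the classical normalized form is implemented here and cross-checked in
## the test suite against direct sinusoid least squares.

#' Lomb periodogram of an unevenly sampled series
#'
#' Classical normalized Lomb periodogram: for angular frequency `w` the
#' power is
#' `P(w) = { [sum y' cos w(t - tau)]^2 / sum cos^2 w(t - tau) +
#'           [sum y' sin w(t - tau)]^2 / sum sin^2 w(t - tau) } / (2 s^2)`
#' with `y'` the mean-subtracted series, `s^2` its variance and `tau` the
#' usual phase origin making the power invariant to time shifts. Peak
#' significance uses the standard exponential false-alarm approximation
#' `FAP = 1 - (1 - exp(-P))^M` with `M` the number of independent
#' frequencies (the scanned range divided by the oversampling factor).
#'
#' @param time sampling times (days); need not be evenly spaced.
#' @param density series values (e.g. monthly birthdate densities at month
#'   midpoints).
#' @param periods optional period grid (days); by default frequencies are
#'   scanned from `1 / span` to the Nyquist frequency of the median spacing
#'   (periods from twice the median spacing to the series span).
#' @param ofac oversampling factor of the default frequency grid.
#' @return data.frame `period`, `power`, `fap`, sorted by decreasing period,
#'   with attribute `M` (independent-frequency count).
#' @export
lombPeriodogram <- function(time, density, periods = NULL, ofac = 4) {
  stopifnot(length(time) == length(density))
  if (length(time) < 8) stop("need at least 8 points", call. = FALSE)
  if (diff(range(time)) == 0) stop("times must not all be equal", call. = FALSE)
  o <- order(time); time <- time[o]; density <- density[o]
  span <- diff(range(time))
  med <- median(diff(time))
  if (is.null(periods)) {
    fmin <- 1 / span
    fmax <- 1 / (2 * med)
    freq <- seq(fmin, fmax, by = fmin / ofac)
    periods <- 1 / freq
  } else {
    freq <- 1 / periods
  }
  y <- density - mean(density)
  s2 <- sum(y^2) / (length(y) - 1)
  power <- vapply(freq, function(f) {
    if (s2 == 0) return(0)
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * time)), sum(cos(2 * w * time))) / (2 * w)
    ct <- cos(w * (time - tau)); st <- sin(w * (time - tau))
    (sum(y * ct)^2 / sum(ct^2) + sum(y * st)^2 / sum(st^2)) / (2 * s2)
  }, 0)
  M <- max(length(freq) / ofac, 1)
  fap <- 1 - (1 - exp(-power))^M
  out <- data.frame(period = periods, power = power, fap = fap)
  out <- out[order(-out$period), ]
  rownames(out) <- NULL
  structure(out, M = M)
}

#' Significant periodogram peaks
#'
#' Local maxima of the Lomb power whose false-alarm probability is below
#' `alpha`, strongest first.
#'
#' @param pg periodogram data.frame from [lombPeriodogram()].
#' @param alpha false-alarm threshold (default 0.05).
#' @param k maximum number of peaks returned.
#' @return data.frame of peak rows (possibly empty).
#' @export
periodogramPeaks <- function(pg, alpha = 0.05, k = 3) {
  p <- pg$power
  n <- length(p)
  isPeak <- vapply(seq_len(n), function(i) {
    (i == 1 || p[i] >= p[i - 1]) && (i == n || p[i] >= p[i + 1])
  }, TRUE)
  peaks <- pg[isPeak & pg$fap < alpha, , drop = FALSE]
  peaks <- peaks[order(-peaks$power), , drop = FALSE]
  head(peaks, k)
}

#' Harmonic series of the annual period
#'
#' Periods `365 / 1, 365 / 2, ..., 365 / k` days, rounded to one decimal.
#'
#' @param k number of harmonics.
#' @return numeric vector of strictly decreasing periods.
#' @export
harmonicPeriods <- function(k) {
  stopifnot(k >= 1)
  round(365 / seq_len(k), 1)
}

#' Greedy Nyquist-bounded sinusoid scan
#'
#' Scans a frequency grid bounded above by the Nyquist frequency for the
#' median sampling interval; at each step the frequency explaining the most
#' residual variance (by least-squares sine/cosine fit) is added to the
#' model, all selected sinusoids are refitted jointly (which removes the
#' bias a plain fit-and-subtract scheme leaves on later frequencies), and
#' the scan repeats on the joint residual, returning the top `k` periods.
#'
#' @param time,density the series.
#' @param k number of periods returned.
#' @param nFreq size of the frequency grid.
#' @return data.frame `period`, `amplitude`, `phase` (from the final joint
#'   fit), `r2` (fraction of the residual variance explained at selection
#'   time), in selection order.
#' @export
nyquistScan <- function(time, density, k = 3, nFreq = 2000) {
  stopifnot(length(time) == length(density))
  if (length(time) < 8) stop("need at least 8 points", call. = FALSE)
  o <- order(time); time <- time[o]; density <- density[o]
  span <- diff(range(time))
  med <- median(diff(time))
  freq <- seq(1 / span, 1 / (2 * med), length.out = nFreq)
  chosen <- numeric()
  r2 <- numeric()
  resid <- density - mean(density)
  for (step in seq_len(k)) {
    tv <- sum((resid - mean(resid))^2)
    if (tv <= 0) break
    ssr <- vapply(freq, function(f) {
      X <- cbind(1, cos(2 * pi * f * time), sin(2 * pi * f * time))
      sum(lm.wfit(X, resid, rep(1, length(resid)))$residuals^2)
    }, 0)
    iBest <- which.min(ssr)
    chosen <- c(chosen, 1 / freq[iBest])
    r2 <- c(r2, 1 - ssr[iBest] / tv)
    joint <- fitSinusoidSum(time, density, chosen)
    resid <- density - joint$predict(time)
    freq <- freq[-iBest]
  }
  ## coordinate refinement: re-scan each chosen frequency over the full grid
  ## with the other sinusoids held in the model, so that early selections are
  ## revisited once the later ones are known
  fullFreq <- seq(1 / span, 1 / (2 * med), length.out = nFreq)
  ones <- rep(1, length(time))
  for (sweep in 1:2) {
    for (j in seq_along(chosen)) {
      others <- chosen[-j]
      Xo <- cbind(1, do.call(cbind, c(list(NULL), lapply(others, function(P)
        cbind(cos(2 * pi * time / P), sin(2 * pi * time / P))))))
      ssr <- vapply(fullFreq, function(f) {
        if (any(abs(1 / f - others) < 1e-9)) return(Inf)
        X <- cbind(Xo, cos(2 * pi * f * time), sin(2 * pi * f * time))
        sum(lm.wfit(X, density, ones)$residuals^2)
      }, 0)
      chosen[j] <- 1 / fullFreq[which.min(ssr)]
    }
  }
  joint <- fitSinusoidSum(time, density, chosen)
  comp <- joint$components
  out <- comp[match(chosen, comp$period), ]
  out$r2 <- r2
  rownames(out) <- NULL
  out
}

#' Fit a sum of sinusoids with fixed periods
#'
#' Linear least squares on a sine/cosine pair per period plus an offset:
#' `y = offset + sum_i A_i sin(2 pi t / P_i + phi_i)`.
#'
#' @param time,density the series.
#' @param periods up to 3 distinct periods (days).
#' @return list of class `sinusoidSumFit`: `components` data.frame
#'   (`period`, `amplitude`, `phase`, sorted by decreasing period), `offset`,
#'   `rss`, and the model function `predict(t)`.
#' @export
fitSinusoidSum <- function(time, density, periods) {
  stopifnot(length(time) == length(density), length(periods) >= 1,
            length(periods) <= 3)
  if (anyDuplicated(periods))
    stop("duplicate periods give a collinear design", call. = FALSE)
  X <- cbind(offset = rep(1, length(time)))
  for (P in periods)
    X <- cbind(X, cos(2 * pi * time / P), sin(2 * pi * time / P))
  cf <- lm.wfit(X, density, rep(1, length(density)))$coefficients
  cf[is.na(cf)] <- 0
  comp <- data.frame(period = periods,
                     amplitude = NA_real_, phase = NA_real_)
  for (i in seq_along(periods)) {
    a <- cf[2 * i]; b <- cf[2 * i + 1]
    comp$amplitude[i] <- sqrt(a^2 + b^2)
    comp$phase[i] <- atan2(a, b) %% (2 * pi)
  }
  comp <- comp[order(-comp$period), ]
  rownames(comp) <- NULL
  offset <- unname(cf[1])
  predictFun <- function(t) {
    y <- rep(offset, length(t))
    for (i in seq_len(nrow(comp)))
      y <- y + comp$amplitude[i] *
        sin(2 * pi * t / comp$period[i] + comp$phase[i])
    y
  }
  rss <- sum((density - predictFun(time))^2)
  structure(list(components = comp, offset = offset, rss = rss,
                 predict = predictFun),
            class = "sinusoidSumFit")
}

#' @export
print.sinusoidSumFit <- function(x, ...) {
  cat(sprintf("Sum of %d sinusoid(s), offset %.4g, rss %.4g\n",
              nrow(x$components), x$offset, x$rss))
  print(x$components, row.names = FALSE)
  invisible(x)
}
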