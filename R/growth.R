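## Michaelis-Menten chamber-building rate (CBR) and generalized
## Michaelis-Menten diameter-increase rate (DIR): evaluation, derivatives,
## weighted fitting, and the onset grid search.

#' Michaelis-Menten growth curve and derivative
#'
#' The chamber-building curve `m(t) = mmax * t / (b + t)` intersects the
#' origin; `mmax` is the growth asymptote (maximal chamber number) and `b`
#' the time at which half of it is reached. Its derivative
#' `mmax * b / (b + t)^2` is the continuously decreasing number of chambers
#' built per day.
#'
#' @param p named numeric with `mmax` and `b` (or a [GrowthFit-class]).
#' @param t days since birth, `t >= 0`.
#' @return curve value (chambers) or per-day rate (chambers/day).
#' @export
mmEval <- function(p, t) {
  p <- .growthPars(p, c("mmax", "b"))
  if (any(t < 0)) stop("t must be nonnegative", call. = FALSE)
  p[["mmax"]] * t / (p[["b"]] + t)
}

#' @rdname mmEval
#' @export
mmDerivative <- function(p, t) {
  p <- .growthPars(p, c("mmax", "b"))
  if (any(t < 0)) stop("t must be nonnegative", call. = FALSE)
  p[["mmax"]] * p[["b"]] / (p[["b"]] + t)^2
}

#' Generalized (logistic) Michaelis-Menten curve
#'
#' `m(t) = (m0 * b^c + mmax * t^c) / (b^c + t^c)`: starts at the nepiontic
#' diameter `m0`, reaches `(m0 + mmax)/2` at `t = b` and approaches the
#' maximal diameter `mmax`; the shape exponent `c > 1` gives the sigmoid
#' course of the initially slow, maturo-evolute diameter growth.
#'
#' @param p named numeric with `m0`, `mmax`, `b`, `c` (or a
#'   [GrowthFit-class]).
#' @param t days since birth, `t >= 0`.
#' @return curve value (micrometres).
#' @export
gmmEval <- function(p, t) {
  p <- .growthPars(p, c("m0", "mmax", "b", "c"))
  if (any(t < 0)) stop("t must be nonnegative", call. = FALSE)
  bc <- p[["b"]]^p[["c"]]
  tc <- t^p[["c"]]
  (p[["m0"]] * bc + p[["mmax"]] * tc) / (bc + tc)
}

.growthPars <- function(p, need) {
  if (is(p, "GrowthFit")) p <- p@parameters
  if (!all(need %in% names(p)))
    stop("parameters must be named: ", paste(need, collapse = ", "), call. = FALSE)
  p
}

## reduced chi-square of observed vs fitted values
.growthChi2 <- function(obs, fit, nPar) {
  ok <- fit > 0
  sum((obs[ok] - fit[ok])^2 / fit[ok]) / max(sum(ok) - nPar, 1)
}

#' Fit a growth curve to trajectory points
#'
#' Weighted least squares of the Michaelis-Menten (`kind = "CBR"`) or
#' generalized Michaelis-Menten (`kind = "DIR"`) curve. Fitting is
#' deterministic: a profile grid over the nonlinear parameters (`b`; or
#' `b` and `c`) with the linear parameters (`mmax`; or `m0` and `mmax`)
#' profiled out exactly, followed by a Levenberg-Marquardt polish. The
#' quality of fit is reported as the reduced chi-square
#' `sum((obs - fit)^2 / fit) / (n - k)`.
#'
#' @param t days since birth of each point.
#' @param m observed trajectory values.
#' @param kind `"CBR"` or `"DIR"`.
#' @param weights least-squares weights (default 1).
#' @return list with `parameters` (named numeric), `reducedChi2`, `fitted`.
#' @export
fitGrowth <- function(t, m, kind = c("CBR", "DIR"), weights = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(t) == length(m), all(t >= 0))
  if (is.null(weights)) weights <- rep(1, length(m))
  if (kind == "CBR") {
    if (length(m) < 3) stop("need at least 3 points to fit the CBR", call. = FALSE)
    fit <- .fitMM(t, m, weights)
    k <- 2
  } else {
    if (length(m) < 5) stop("need at least 5 points to fit the DIR", call. = FALSE)
    fit <- .fitGMM(t, m, weights)
    k <- 4
  }
  fitted <- if (kind == "CBR") mmEval(fit, t) else gmmEval(fit, t)
  list(parameters = fit, reducedChi2 = .growthChi2(m, fitted, k), fitted = fitted)
}

.fitMM <- function(t, m, w) {
  ## profile: for fixed b, the weighted LS mmax is closed-form
  bGrid <- exp(seq(log(0.5), log(max(t) * 4), length.out = 400))
  ss <- vapply(bGrid, function(b) {
    x <- t / (b + t)
    mmax <- sum(w * x * m) / sum(w * x^2)
    sum(w * (m - mmax * x)^2)
  }, 0)
  b0 <- bGrid[which.min(ss)]
  x <- t / (b0 + t)
  mmax0 <- sum(w * x * m) / sum(w * x^2)
  fit <- try(minpack.lm::nlsLM(m ~ mmax * t / (b + t),
                               start = list(mmax = mmax0, b = b0),
                               weights = w, lower = c(1e-8, 1e-8),
                               upper = c(10 * max(m), 50 * max(t)),
                               control = minpack.lm::nls.lm.control(maxiter = 500)),
             silent = TRUE)
  if (inherits(fit, "try-error")) return(c(mmax = mmax0, b = b0))
  cf <- coef(fit)
  c(mmax = unname(cf[["mmax"]]), b = unname(cf[["b"]]))
}

.fitGMM <- function(t, m, w) {
  ## profile: for fixed (b, c) the model is linear in (m0, mmax)
  cGrid <- seq(1.01, 8, by = 0.07)
  bGrid <- exp(seq(log(max(min(t[t > 0]), 1)), log(max(t) * 8), length.out = 80))
  best <- NULL
  for (cc in cGrid) for (bb in bGrid) {
    u <- t^cc / (bb^cc + t^cc)
    X <- cbind(m0 = 1 - u, mmax = u)
    cf <- try(lm.wfit(X, m, w)$coefficients, silent = TRUE)
    if (inherits(cf, "try-error") || any(!is.finite(cf))) next
    if (cf[1] <= 0 || cf[2] <= cf[1] || cf[2] > 10 * max(m)) next
    ss <- sum(w * (m - drop(X %*% cf))^2)
    if (is.null(best) || ss < best$ss)
      best <- list(ss = ss, par = c(m0 = unname(cf[1]), mmax = unname(cf[2]),
                                    b = bb, c = cc))
  }
  if (is.null(best))
    stop("generalized MM fit did not converge (degenerate trajectory?)", call. = FALSE)
  p0 <- best$par
  fit <- try(minpack.lm::nlsLM(
    m ~ (m0 * b^c + mmax * t^c) / (b^c + t^c),
    start = as.list(p0), weights = w,
    lower = c(m0 = 1e-8, mmax = 1e-8, b = 1e-8, c = 1.000001),
    upper = c(m0 = 1.5 * min(m), mmax = 10 * max(m), b = 50 * max(t), c = 12),
    control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
  if (inherits(fit, "try-error")) return(p0)
  cf <- coef(fit)
  out <- c(m0 = unname(cf[["m0"]]), mmax = unname(cf[["mmax"]]),
           b = unname(cf[["b"]]), c = unname(cf[["c"]]))
  if (out[["m0"]] <= 0 || out[["mmax"]] <= out[["m0"]] || out[["c"]] <= 1) p0 else out
}

#' Onset grid search for a generation trajectory
#'
#' The onset is the interval between a generation's birth and its first
#' appearance as a decomposed component. Each candidate onset `L` of the
#' coarse grid maps the sampling dates to `t = days since first appearance +
#' L`, prepends the two nepiont pseudo-observations (chamber numbers 2 and 3
#' for the CBR; the measured mean diameters at chambers 2 and 3 for the DIR)
#' at the configured days of life, fits the growth curve by weighted least
#' squares, and scores the candidate by the reduced chi-square over all
#' points. The best coarse candidate is then refined in day-wise steps
#' (within the grid limits). The DIR reuses the onset selected for the CBR
#' of the same generation (`fixedOnset`).
#'
#' @param traj trajectory data.frame from [maximumTrajectory()] /
#'   [meanTrajectory()] (columns `offset`, `m`; attributes `generation`,
#'   `character`, `cvMean`, `trajectoryKind`), or any data.frame with those
#'   columns.
#' @param kind `"CBR"` or `"DIR"`.
#' @param onsetGrid numeric `(min, max, step)` in days.
#' @param pseudoValues the two pseudo-observation values; defaults to
#'   chambers `c(2, 3)` for the CBR and must be supplied for the DIR (the
#'   population's measured nepiont diameters).
#' @param pseudoDays days of life of the two pseudo-observations.
#' @param pseudoWeight least-squares weight of the pseudo-observations
#'   (trajectory points have weight 1); 0 fits the trajectory points alone.
#' @param fixedOnset skip the search and use this onset (days).
#' @param refine half-width (days) of the day-wise refinement window.
#' @return a [GrowthFit-class] object.
#' @export
onsetSearch <- function(traj, kind = c("CBR", "DIR"),
                        onsetGrid = c(10, 70, 5),
                        pseudoValues = NULL, pseudoDays = c(1, 2),
                        pseudoWeight = 2, fixedOnset = NULL, refine = 5) {
  kind <- match.arg(kind)
  stopifnot(all(c("offset", "m") %in% names(traj)))
  if (nrow(traj) < 4)
    stop("need at least 4 trajectory points for the onset search", call. = FALSE)
  if (is.null(pseudoValues))
    pseudoValues <- if (kind == "CBR") c(2, 3) else
      stop("DIR needs measured nepiont diameters as pseudoValues", call. = FALSE)
  stopifnot(length(pseudoValues) == 2, length(pseudoDays) == 2)
  fit1 <- function(L) {
    if (pseudoWeight > 0) {
      pd <- ifelse(pseudoDays > L, L, pseudoDays)  # pseudo-obs live in the onset
      tt <- c(pd, traj$offset + L)
      yy <- c(pseudoValues, traj$m)
      ww <- c(pseudoWeight, pseudoWeight, rep(1, nrow(traj)))
    } else {
      tt <- traj$offset + L
      yy <- traj$m
      ww <- rep(1, nrow(traj))
    }
    f <- fitGrowth(tt, yy, kind, weights = ww)
    f$onset <- L
    f
  }
  if (is.null(fixedOnset)) {
    grid <- seq(onsetGrid[1], onsetGrid[2], by = onsetGrid[3])
    coarse <- lapply(grid, fit1)
    bestL <- grid[which.min(vapply(coarse, `[[`, 0, "reducedChi2"))]
    fineGrid <- seq(max(onsetGrid[1], bestL - refine),
                    min(onsetGrid[2], bestL + refine), by = 1)
    fine <- lapply(fineGrid, fit1)
    best <- fine[[which.min(vapply(fine, `[[`, 0, "reducedChi2"))]]
  } else {
    best <- fit1(fixedOnset)
  }
  gen <- attr(traj, "generation", exact = TRUE)
  cv <- attr(traj, "cvMean", exact = TRUE)
  tk <- attr(traj, "trajectoryKind", exact = TRUE)
  ch <- attr(traj, "character", exact = TRUE)
  ref <- if ("date" %in% names(traj)) min(traj$date) else as.Date("1970-01-01")
  new("GrowthFit", kind = kind,
      trajectoryKind = if (is.null(tk)) "max" else tk,
      parameters = best$parameters, onsetDays = best$onset,
      onsetReference = ref, reducedChi2 = best$reducedChi2,
      cvMean = if (is.null(cv)) NA_real_ else cv,
      generation = if (is.null(gen)) NA_real_ else as.numeric(gen),
      character = if (is.null(ch)) ifelse(kind == "CBR", "NoC", "TD") else ch)
}

#' Tabulate a fitted growth curve on a day grid
#'
#' @param fit a [GrowthFit-class] object.
#' @param days day grid; default matches the conventional report (daily for
#'   the first week, then widening intervals to one year).
#' @return data.frame `day`, `value` (curve value rounded to integer),
#'   `rate` (per-day increase `value(t) - value(t - 1)` of the unrounded
#'   curve, to 1 decimal).
#' @export
growthTable <- function(fit, days = c(1:7, 10, 15, 30, 60, 90, 120, 150, 180,
                                      210, 240, 270, 300, 330, 360)) {
  stopifnot(is(fit, "GrowthFit"))
  evalf <- if (fit@kind == "CBR") mmEval else gmmEval
  value <- evalf(fit@parameters, days)
  rate <- value - evalf(fit@parameters, pmax(days - 1, 0))
  data.frame(day = days, value = round(value), rate = round(rate, 1))
}

#' Initial per-day growth rate of a fitted curve
#'
#' For the Michaelis-Menten CBR this is the curve's derivative at the
#' origin, `mmax / b` (chambers/day); for the generalized MM DIR the
#' increase over the first day of life, `m(1) - m(0)`.
#'
#' @param fit a [GrowthFit-class] object.
#' @return rate in character units per day.
#' @export
initialRate <- function(fit) {
  stopifnot(is(fit, "GrowthFit"))
  p <- fit@parameters
  if (fit@kind == "CBR") unname(p[["mmax"]] / p[["b"]])
  else unname(gmmEval(p, 1) - p[["m0"]])
}
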