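## Size-frequency histograms, normality screen, decomposition into normal
## components. Chamber numbers are binned as counted; test diameters on the
## natural-log scale.

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Equal-width bin edges covering a set of values
#'
#' Edges are aligned to multiples of the bin width so that all monthly
#' samples of one analysis share identical intervals along the abscissa.
#'
#' @param values numeric values (already ln-transformed for diameters).
#' @param width bin width.
#' @return numeric vector of edges; `min(values)` falls in the first bin and
#'   `max(values)` in the last (edges are left-closed, right-open).
#' @export
histogramEdges <- function(values, width) {
  stopifnot(width > 0, length(values) > 0, all(is.finite(values)))
  lo <- floor(min(values) / width) * width
  hi <- ceiling((max(values) + width * 1e-9) / width) * width
  if (hi <= max(values)) hi <- hi + width
  seq(lo, hi, by = width)
}

#' Build a fixed-interval frequency histogram of one monthly sample
#'
#' Chamber numbers (`"NoC"`) are processed as natural numbers; test diameters
#' (`"TD"`) are transformed with the natural logarithm before binning, giving
#' a `"lnTD"` histogram.
#'
#' @param object a [ForamSamples-class] object or a numeric vector of values
#'   (already transformed in the latter case).
#' @param character `"NoC"` or `"TD"` (ignored for numeric input, where it
#'   labels the histogram).
#' @param edges bin edges shared across months; computed from the data via
#'   [histogramEdges()] when `NULL`.
#' @param width bin width used when `edges` is `NULL`.
#' @param date sampling date to select (for `ForamSamples` input).
#' @param ... unused.
#' @return a [ForamHistogram-class] object; bin counts conserve the sample
#'   size.
#' @export
setGeneric("buildHistogram",
  function(object, character = c("NoC", "TD"), edges = NULL, width = NULL,
           date = NULL, ...) standardGeneric("buildHistogram"))

#' @rdname buildHistogram
#' @export
setMethod("buildHistogram", "numeric",
  function(object, character = c("NoC", "TD"), edges = NULL, width = NULL,
           date = NULL, ...) {
    character <- match.arg(character)
    hchar <- if (character == "TD") "lnTD" else "NoC"
    if (is.null(width)) width <- if (hchar == "NoC") 5 else 0.15
    if (is.null(edges)) edges <- histogramEdges(object, width)
    .binValues(object, edges, hchar,
               if (is.null(date)) as.Date(NA) else as.Date(date),
               ids = names(object))
  })

#' @rdname buildHistogram
#' @export
setMethod("buildHistogram", "ForamSamples",
  function(object, character = c("NoC", "TD"), edges = NULL, width = NULL,
           date = NULL, ...) {
    character <- match.arg(character)
    sp <- object@specimens
    if (!is.null(date)) sp <- sp[sp$sampling_date == as.Date(date), , drop = FALSE]
    vals <- if (character == "NoC") sp$chamber_count else sp$test_diameter
    keep <- !is.na(vals)
    vals <- vals[keep]
    if (!length(vals)) stop("no specimens carry character ", character, call. = FALSE)
    if (character == "TD") vals <- log(vals)
    hchar <- if (character == "TD") "lnTD" else "NoC"
    if (is.null(width)) width <- if (hchar == "NoC") 5 else 0.15
    if (is.null(edges)) edges <- histogramEdges(vals, width)
    .binValues(vals, edges, hchar,
               if (is.null(date)) min(sp$sampling_date) else as.Date(date),
               ids = sp$specimen_id[keep])
  })

.binValues <- function(vals, edges, hchar, date, ids = NULL) {
  out <- vals < edges[1] | vals >= edges[length(edges)]
  if (any(out)) {
    who <- if (!is.null(ids) && length(ids) == length(vals)) ids[which(out)[1]]
           else sprintf("value %.4g", vals[which(out)[1]])
    stop(sprintf("specimen %s falls outside the bin range [%.4g, %.4g)",
                 who, edges[1], edges[length(edges)]), call. = FALSE)
  }
  idx <- findInterval(vals, edges, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  new("ForamHistogram", edges = edges, counts = as.numeric(counts),
      character = hchar, samplingDate = date)
}

## expected normal bin counts with the tail mass folded into the end bins,
## so that sum(expected) == n
.expectedNormal <- function(edges, n, mu, s) {
  p <- pnorm(edges, mu, s)
  probs <- diff(p)
  probs[1] <- probs[1] + p[1]
  probs[length(probs)] <- probs[length(probs)] + (1 - p[length(p)])
  n * probs
}

#' Chi-square goodness-of-fit screen for normality
#'
#' Pearson chi-square of the observed bin counts against the counts expected
#' under a normal distribution whose mean and sd are estimated from the
#' binned data. Bins are pooled inwards from both ends until every expected
#' count is at least 1; the degrees of freedom are `bins - 3` (two estimated
#' parameters plus the total).
#'
#' @param hist a [ForamHistogram-class] object.
#' @return named numeric `c(statistic, p, df)`.
#' @section Errors: fewer than 4 usable bins after pooling raises a
#'   condition of class `foramInsufficientData`; callers typically skip the
#'   sample (small samples carry no decomposable signal).
#' @export
testNormality <- function(hist) {
  stopifnot(is(hist, "ForamHistogram"))
  counts <- hist@counts
  edges <- hist@edges
  n <- sum(counts)
  mids <- edges[-length(edges)] + diff(edges) / 2
  if (n < 2) .insufficient("fewer than 2 specimens")
  mu <- sum(mids * counts) / n
  s <- sqrt(sum(counts * (mids - mu)^2) / (n - 1))
  if (s == 0) .insufficient("zero variance")
  expected <- .expectedNormal(edges, n, mu, s)
  ## pool inwards from both ends until every expected count >= 1
  grp <- seq_along(counts)
  repeat {
    eg <- tapply(expected, grp, sum)
    if (all(eg >= 1) || length(eg) <= 2) break
    small <- which(eg < 1)
    i <- small[1]
    ## merge with the inward neighbour
    from <- as.integer(names(eg)[i])
    to <- if (i < length(eg) / 2 || i == 1) as.integer(names(eg)[min(i + 1, length(eg))])
          else as.integer(names(eg)[max(i - 1, 1)])
    grp[grp == from] <- to
  }
  og <- as.numeric(tapply(counts, grp, sum))
  eg <- as.numeric(tapply(expected, grp, sum))
  if (length(og) < 4) .insufficient("fewer than 4 usable bins after pooling")
  stat <- sum((og - eg)^2 / eg)
  df <- length(og) - 3
  c(statistic = stat, p = pchisq(stat, df, lower.tail = FALSE), df = df)
}

.insufficient <- function(msg) {
  cond <- structure(class = c("foramInsufficientData", "error", "condition"),
                    list(message = paste0("insufficient data: ", msg),
                         call = sys.call(-1)))
  stop(cond)
}

## sum of k scaled Gaussian curves, amplitude parameterization:
## par = (d_1, mu_1, s_1, d_2, ...), d_j = peak expected count per bin
.mixtureCurve <- function(par, x) {
  k <- length(par) / 3
  y <- numeric(length(x))
  for (j in seq_len(k)) {
    d <- par[3 * j - 2]; mu <- par[3 * j - 1]; s <- par[3 * j]
    y <- y + d * exp(-(x - mu)^2 / (2 * s^2))
  }
  y
}

.mixtureChi2 <- function(counts, fitted, nPar, floor = 0.5) {
  sum((counts - fitted)^2 / pmax(fitted, floor)) / max(length(counts) - nPar, 1)
}

.fitMixtureK <- function(mids, counts, k, width, seed, restarts = 10) {
  n <- sum(counts)
  datSd <- sqrt(sum(counts * (mids - sum(mids * counts) / n)^2) / max(n - 1, 1))
  ord <- order(counts, decreasing = TRUE)
  best <- NULL
  .withSeed(seed, {
    for (r in seq_len(restarts)) {
      ## mode seeding: first restart takes the k highest bins; later restarts
      ## sample starting means weighted by the counts
      mu0 <- if (r == 1) mids[ord[seq_len(min(k, length(mids)))]]
             else sample(mids, k, replace = TRUE, prob = pmax(counts, 0.25))
      mu0 <- mu0 + runif(k, -width / 4, width / 4)
      s0 <- rep(max(datSd / k, width), k)
      d0 <- pmax(counts[vapply(mu0, function(m) which.min(abs(mids - m)), 1L)], 1)
      par0 <- as.numeric(rbind(d0, mu0, s0))
      ## component means stay on the histogram axis; a component cannot be
      ## wider than the pooled sample
      lower <- rep(c(1e-4, min(mids) - width, width / 4), k)
      upper <- rep(c(2 * max(counts) + 5, max(mids) + width, datSd + width), k)
      fit <- try(minpack.lm::nls.lm(
        par = par0,
        lower = lower, upper = upper,
        fn = function(p) counts - .mixtureCurve(p, mids),
        control = minpack.lm::nls.lm.control(maxiter = 400)), silent = TRUE)
      if (inherits(fit, "try-error")) next
      par <- fit$par
      chi2 <- .mixtureChi2(counts, .mixtureCurve(par, mids), 3 * k)
      if (is.null(best) || chi2 < best$chi2) best <- list(par = par, chi2 = chi2)
    }
  })
  best
}

#' Decompose a size-frequency histogram into normal components
#'
#' Fits a sum of `k` scaled Gaussian curves to the bin counts by nonlinear
#' least squares (seeded multistart), for `k = 1, 2, ...` up to `kMax`, and
#' selects the smallest `k` whose reduced chi-square is not improved by more
#' than 20% by `k + 1` (ties break toward fewer components). Component
#' `density` is the peak height in count units. Degenerate components
#' (implied total below one specimen, sd below half a bin width, mean outside
#' the populated range, or two means closer than one bin width) are dropped
#' and the fit repeated with fewer components.
#'
#' @param hist a [ForamHistogram-class] object.
#' @param kMax maximum number of components (1-3).
#' @param seed RNG seed for the multistart initialization; the result is
#'   deterministic given the seed.
#' @param improve relative reduced-chi-square improvement required to accept
#'   an additional component (default 0.2).
#' @return a [ComponentDecomposition-class] object.
#' @export
decomposeHistogram <- function(hist, kMax = 3, seed = 1L, improve = 0.2) {
  stopifnot(is(hist, "ForamHistogram"), kMax >= 1, kMax <= 3)
  counts <- hist@counts
  edges <- hist@edges
  width <- diff(edges[1:2])
  mids <- edges[-length(edges)] + diff(edges) / 2
  if (sum(counts > 0) < 2 && kMax > 1) kMax <- 1
  normP <- tryCatch(unname(testNormality(hist)["p"]),
                    foramInsufficientData = function(e) NA_real_)
  if (sum(counts > 0) == 1) {
    ## all mass in one bin: a single component at the bin midpoint
    j <- which(counts > 0)
    cp <- data.frame(density = counts[j], mean = mids[j], sd = width / 2)
    return(new("ComponentDecomposition", samplingDate = hist@samplingDate,
               character = hist@character, components = cp,
               reducedChi2 = 0, normalityP = if (is.na(normP)) 1 else normP,
               binWidth = width, sampleSize = sum(counts)))
  }
  fits <- vector("list", kMax)
  for (k in seq_len(kMax))
    fits[[k]] <- .fitMixtureK(mids, counts, k, width, seed + 1000 * k)
  ok <- !vapply(fits, is.null, TRUE)
  if (!any(ok)) stop("decomposition failed to converge for any k", call. = FALSE)
  ## smallest k whose chi2 is not improved by > `improve` by k+1
  kSel <- 1L
  for (k in seq_len(kMax - 1)) {
    if (is.null(fits[[k]]) ||
        (!is.null(fits[[k + 1]]) &&
         fits[[k + 1]]$chi2 < (1 - improve) * fits[[k]]$chi2))
      kSel <- k + 1L else break
  }
  par <- fits[[kSel]]$par
  cp <- data.frame(density = par[seq(1, length(par), 3)],
                   mean = par[seq(2, length(par), 3)],
                   sd = par[seq(3, length(par), 3)])
  ## degeneracy screen; drop and refit with fewer components
  populated <- range(mids[counts > 0])
  repeat {
    total <- cp$density * cp$sd * sqrt(2 * pi) / width
    degen <- total < 1 | cp$sd < width / 2 |
      cp$mean < populated[1] - 3 * cp$sd | cp$mean > populated[2] + 3 * cp$sd
    if (nrow(cp) > 1) {
      ordm <- order(cp$mean)
      close <- which(diff(cp$mean[ordm]) < width)
      if (length(close)) {
        pair <- ordm[c(close[1], close[1] + 1)]
        degen[pair[which.min(cp$density[pair])]] <- TRUE
      }
    }
    if (!any(degen) || nrow(cp) == 1) break
    kNew <- nrow(cp) - sum(degen)
    if (kNew < 1) kNew <- 1
    fitNew <- .fitMixtureK(mids, counts, kNew, width, seed + 7000 + kNew)
    par <- fitNew$par
    cp <- data.frame(density = par[seq(1, length(par), 3)],
                     mean = par[seq(2, length(par), 3)],
                     sd = par[seq(3, length(par), 3)])
  }
  cp <- cp[order(cp$mean, decreasing = TRUE), , drop = FALSE]
  rownames(cp) <- NULL
  chi2 <- .mixtureChi2(counts, .mixtureCurve(as.numeric(t(as.matrix(cp))), mids),
                       3 * nrow(cp))
  new("ComponentDecomposition", samplingDate = hist@samplingDate,
      character = hist@character, components = cp, reducedChi2 = chi2,
      normalityP = if (is.na(normP)) NA_real_ else normP,
      binWidth = width, sampleSize = sum(counts))
}
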