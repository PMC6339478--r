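## Per-sample descriptive screens: correlation between chamber number and
## ln test diameter, and an equal-slopes (ANCOVA) test across samples.

#' Screen one monthly sample: NoC vs ln TD regression
#'
#' Ordinary least squares of `ln(TD)` on `NoC`; reports the squared Pearson
#' correlation and the two-sided p-value of the slope.
#'
#' @param sample data.frame with columns `chamber_count` and `test_diameter`
#'   (rows lacking either are dropped), or a [ForamSamples-class] with
#'   `date`.
#' @param date sampling date to select for `ForamSamples` input.
#' @return named numeric `c(n, r_squared, p_slope)`; `r_squared` is `NA`
#'   (with a warning) when the chamber numbers have zero variance.
#' @export
screenSample <- function(sample, date = NULL) {
  if (is(sample, "ForamSamples")) {
    sp <- sample@specimens
    if (!is.null(date)) sp <- sp[sp$sampling_date == as.Date(date), , drop = FALSE]
    sample <- sp
  }
  keep <- !is.na(sample$chamber_count) & !is.na(sample$test_diameter)
  noc <- sample$chamber_count[keep]
  lntd <- log(sample$test_diameter[keep])
  n <- length(noc)
  if (n < 3) stop("need at least 3 complete specimens", call. = FALSE)
  if (stats::var(noc) == 0) {
    warning("zero variance in chamber number: correlation undefined", call. = FALSE)
    return(c(n = n, r_squared = NA_real_, p_slope = NA_real_))
  }
  fit <- lm(lntd ~ noc)
  sm <- summary(fit)
  c(n = n, r_squared = unname(sm$r.squared),
    p_slope = unname(sm$coefficients["noc", "Pr(>|t|)"]))
}

#' Screen all monthly samples of a campaign
#'
#' @param samples a [ForamSamples-class] object.
#' @param minN samples with fewer complete specimens are skipped.
#' @return data.frame `date`, `n`, `r_squared`, `p_slope`, one row per
#'   retained sampling date.
#' @export
screenSamples <- function(samples, minN = 3) {
  stopifnot(is(samples, "ForamSamples"))
  out <- NULL
  for (d in as.list(sampleDates(samples))) {
    sp <- samples@specimens[samples@specimens$sampling_date == d, , drop = FALSE]
    if (sum(!is.na(sp$chamber_count) & !is.na(sp$test_diameter)) < minN) next
    sc <- screenSample(sp)
    out <- rbind(out, data.frame(date = d, n = as.integer(sc[["n"]]),
                                 r_squared = sc[["r_squared"]],
                                 p_slope = sc[["p_slope"]]))
  }
  out
}

#' Equal-slopes test across monthly samples
#'
#' Analysis-of-covariance F-test of slope homogeneity: the `NoC x sample`
#' interaction term of `ln(TD) ~ NoC * sample` against the common-slope
#' model.
#'
#' @param samples a [ForamSamples-class] object.
#' @param minN samples with fewer complete specimens are excluded.
#' @return named numeric `c(F, p, df1, df2)`.
#' @export
equalSlopesTest <- function(samples, minN = 3) {
  stopifnot(is(samples, "ForamSamples"))
  sp <- samples@specimens
  sp <- sp[!is.na(sp$chamber_count) & !is.na(sp$test_diameter), , drop = FALSE]
  keep <- names(which(table(format(sp$sampling_date)) >= minN))
  sp <- sp[format(sp$sampling_date) %in% keep, , drop = FALSE]
  if (length(unique(sp$sampling_date)) < 2)
    stop("need at least two samples for the equal-slopes test", call. = FALSE)
  grp <- factor(format(sp$sampling_date))
  lntd <- log(sp$test_diameter)
  noc <- sp$chamber_count
  full <- lm(lntd ~ noc * grp)
  null <- lm(lntd ~ noc + grp)
  av <- anova(null, full)
  c(F = av$F[2], p = av$`Pr(>F)`[2], df1 = av$Df[2], df2 = av$Res.Df[2])
}
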