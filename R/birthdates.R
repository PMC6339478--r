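## Inversion of fitted growth curves to per-specimen birthdates, weighted
## monthly birthdate histograms, and longevity.

#' Invert the chamber-building curve to specimen ages and birthdates
#'
#' The Michaelis-Menten curve is inverted exactly:
#' `age = NoC * b / (mmax - NoC)`, and the birthdate is the sampling date
#' minus the age. Specimens whose chamber number reaches or exceeds the
#' asymptote have no finite age under the model; they are excluded with a
#' warning (their number is recorded in the `excluded` attribute).
#'
#' @param fit a [GrowthFit-class] of kind `"CBR"` (or a named vector with
#'   `mmax`, `b`).
#' @param records a [ForamSamples-class] object or a data.frame with columns
#'   `specimen_id`, `sampling_date`, `chamber_count`.
#' @return data.frame `specimen_id`, `basis` (`"CBR"`), `sampling_date`,
#'   `birth_date`, `age_days`; attribute `excluded` counts the specimens
#'   beyond the asymptote.
#' @export
invertCBR <- function(fit, records) {
  p <- .growthPars(fit, c("mmax", "b"))
  rec <- .asRecordFrame(records, "chamber_count")
  x <- rec$value
  if (any(x < 2)) stop("chamber_count < 2 cannot be inverted", call. = FALSE)
  beyond <- x >= p[["mmax"]]
  if (any(beyond))
    warning(sprintf("%d specimen(s) at or beyond the CBR asymptote excluded",
                    sum(beyond)), call. = FALSE)
  age <- x[!beyond] * p[["b"]] / (p[["mmax"]] - x[!beyond])
  .birthdateFrame(rec[!beyond, , drop = FALSE], age, "CBR", sum(beyond))
}

#' Invert the diameter-increase curve to specimen ages and birthdates
#'
#' Exact algebraic inverse of the generalized Michaelis-Menten curve:
#' `age = ((TD - m0) * b^c / (mmax - TD))^(1/c)`. Diameters below the
#' nepiontic diameter `m0` get age 0 (flagged in column `flagged`);
#' diameters at or beyond the asymptote are excluded with a warning.
#'
#' @param fit a [GrowthFit-class] of kind `"DIR"` (or a named vector with
#'   `m0`, `mmax`, `b`, `c`).
#' @param records a [ForamSamples-class] object or a data.frame with columns
#'   `specimen_id`, `sampling_date`, `test_diameter`.
#' @return data.frame as in [invertCBR()] with `basis = "DIR"` plus a
#'   logical `flagged` column for sub-nepiont diameters.
#' @export
invertDIR <- function(fit, records) {
  p <- .growthPars(fit, c("m0", "mmax", "b", "c"))
  rec <- .asRecordFrame(records, "test_diameter")
  x <- rec$value
  beyond <- x >= p[["mmax"]]
  if (any(beyond))
    warning(sprintf("%d specimen(s) at or beyond the DIR asymptote excluded",
                    sum(beyond)), call. = FALSE)
  rec <- rec[!beyond, , drop = FALSE]
  x <- x[!beyond]
  small <- x < p[["m0"]]
  age <- numeric(length(x))
  xi <- pmax(x, p[["m0"]])
  age <- ((xi - p[["m0"]]) * p[["b"]]^p[["c"]] / (p[["mmax"]] - xi))^(1 / p[["c"]])
  out <- .birthdateFrame(rec, age, "DIR", 0L)
  attr(out, "excluded") <- sum(beyond)
  out$flagged <- small
  out
}

.asRecordFrame <- function(records, col) {
  if (is(records, "ForamSamples")) records <- records@specimens
  stopifnot(all(c("specimen_id", "sampling_date", col) %in% names(records)))
  rec <- records[!is.na(records[[col]]), , drop = FALSE]
  data.frame(specimen_id = as.character(rec$specimen_id),
             sampling_date = as.Date(rec$sampling_date),
             value = rec[[col]], stringsAsFactors = FALSE)
}

.birthdateFrame <- function(rec, age, basis, excluded) {
  out <- data.frame(specimen_id = rec$specimen_id,
                    basis = basis,
                    sampling_date = rec$sampling_date,
                    birth_date = rec$sampling_date - round(age),
                    age_days = age,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Monthly birthdate histogram
#'
#' Sums specimen weights per civil month of the inferred birth date.
#' `weighting = "simple"` gives every specimen weight 1 (used where sampled
#' volumes are comparable); `weighting = "per_sample"` gives each specimen
#' of sample k weight `1 / sample_size_k`, removing the bias of differing
#' sample sizes (then a fully included sample contributes total weight 1).
#'
#' @param records birthdate data.frame from [invertCBR()]/[invertDIR()] (or
#'   a concatenation of both for combined histograms).
#' @param weighting `"simple"` or `"per_sample"`.
#' @param sampleSizes optional named numeric of sample sizes keyed by
#'   `"YYYY-MM-DD"` sampling date; defaults to the record counts per
#'   sampling date.
#' @return data.frame `month` (first day of month), `mid_day` (numeric day
#'   of the month midpoint, for periodicity analyses), `density`; the total
#'   density equals the summed weights.
#' @export
birthdateHistogram <- function(records, weighting = c("simple", "per_sample"),
                               sampleSizes = NULL) {
  weighting <- match.arg(weighting)
  stopifnot(nrow(records) > 0)
  if (weighting == "per_sample") {
    key <- format(records$sampling_date)
    if (is.null(sampleSizes)) {
      tab <- table(key)
      sampleSizes <- setNames(as.numeric(tab), names(tab))
    }
    w <- 1 / sampleSizes[key]
    if (anyNA(w)) stop("sampleSizes lacks entries for some sampling dates", call. = FALSE)
  } else {
    w <- rep(1, nrow(records))
  }
  month <- as.Date(format(records$birth_date, "%Y-%m-01"))
  months <- seq(min(month), max(month), by = "month")
  dens <- vapply(months, function(mo) sum(w[month == mo]), 0)
  nxt <- seq(min(month), by = "month", length.out = length(months) + 1)[-1]
  data.frame(month = months,
             mid_day = as.numeric(months) + as.numeric(nxt - months) / 2,
             density = unname(dens))
}

#' Maximal longevity from birthdate records
#'
#' The maximum difference in days between a specimen's sampling date and its
#' inferred reproduction (birth) date; specimens excluded as beyond the
#' asymptote never enter the records and therefore do not contribute.
#'
#' @param records birthdate data.frame from [invertCBR()]/[invertDIR()].
#' @return longevity in days.
#' @export
estimateLongevity <- function(records) {
  stopifnot(nrow(records) > 0, "age_days" %in% names(records))
  max(records$age_days)
}
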