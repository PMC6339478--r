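## Generics and accessors. Slot access from user code goes through these.

#' Specimen table of a ForamSamples object
#'
#' @param object a [ForamSamples-class] object.
#' @return data.frame with one row per specimen.
#' @export
setGeneric("specimens", function(object) standardGeneric("specimens"))

#' @rdname specimens
#' @export
setMethod("specimens", "ForamSamples", function(object) object@specimens)

#' Sampling dates present in an object
#'
#' @param object a [ForamSamples-class] or [GenerationTracks-class] object.
#' @return sorted vector of `Date`s.
#' @export
setGeneric("sampleDates", function(object) standardGeneric("sampleDates"))

#' @rdname sampleDates
#' @export
setMethod("sampleDates", "ForamSamples", function(object)
  sort(unique(object@specimens$sampling_date)))

#' @rdname sampleDates
#' @export
setMethod("sampleDates", "GenerationTracks", function(object)
  sort(unique(object@entries$date)))

#' Number of specimens per sampling date
#'
#' @param object a [ForamSamples-class] object.
#' @param character count only specimens carrying this character
#'   (`"NoC"`, `"TD"`) or `"any"` (default).
#' @return named integer vector, one entry per sampling date.
#' @export
setGeneric("sampleSizes", function(object, character = "any")
  standardGeneric("sampleSizes"))

#' @rdname sampleSizes
#' @export
setMethod("sampleSizes", "ForamSamples", function(object, character = "any") {
  sp <- object@specimens
  keep <- switch(match.arg(character, c("any", "NoC", "TD")),
    any = rep(TRUE, nrow(sp)),
    NoC = !is.na(sp$chamber_count),
    TD  = !is.na(sp$test_diameter))
  tab <- table(format(sp$sampling_date[keep]))
  setNames(as.integer(tab), names(tab))
})

#' Bin edges, counts and width of a histogram
#'
#' @param object a [ForamHistogram-class] object.
#' @return `binEdges`: numeric edges; `binCounts`: counts per bin;
#'   `binWidth`: common bin width; `binMids`: bin midpoints.
#' @export
setGeneric("binEdges", function(object) standardGeneric("binEdges"))
#' @rdname binEdges
#' @export
setMethod("binEdges", "ForamHistogram", function(object) object@edges)

#' @rdname binEdges
#' @export
setGeneric("binCounts", function(object) standardGeneric("binCounts"))
#' @rdname binEdges
#' @export
setMethod("binCounts", "ForamHistogram", function(object) object@counts)

#' @rdname binEdges
#' @export
setGeneric("binWidth", function(object) standardGeneric("binWidth"))
#' @rdname binEdges
#' @export
setMethod("binWidth", "ForamHistogram", function(object) diff(object@edges[1:2]))
#' @rdname binEdges
#' @export
setMethod("binWidth", "ComponentDecomposition", function(object) object@binWidth)

#' @rdname binEdges
#' @export
setGeneric("binMids", function(object) standardGeneric("binMids"))
#' @rdname binEdges
#' @export
setMethod("binMids", "ForamHistogram", function(object)
  object@edges[-length(object@edges)] + diff(object@edges) / 2)

#' Component table of a decomposition
#'
#' For `"lnTD"` decompositions the component means are back-transformed to
#' micrometres (`exp` of the ln-scale mean) and the ln-scale sds are mapped to
#' micrometres by the delta method (`sd_um = sd_ln * exp(mean_ln)`), matching
#' how diameter components are conventionally reported; set `scale =
#' "fitted"` for the raw ln-scale parameters.
#'
#' @param object a [ComponentDecomposition-class] object.
#' @param scale `"report"` (default, micrometres for lnTD) or `"fitted"`.
#' @return data.frame with columns `density`, `mean`, `sd`.
#' @export
setGeneric("components", function(object, scale = "report")
  standardGeneric("components"))

#' @rdname components
#' @export
setMethod("components", "ComponentDecomposition",
  function(object, scale = "report") {
    scale <- match.arg(scale, c("report", "fitted"))
    cp <- object@components
    if (scale == "report" && object@character == "lnTD") {
      cp <- data.frame(density = cp$density,
                       mean = exp(cp$mean),
                       sd = cp$sd * exp(cp$mean))
    }
    cp
  })

#' Reduced chi-square of a fitted object
#'
#' @param object a [ComponentDecomposition-class] or [GrowthFit-class] object.
#' @return the reduced chi-square statistic, `sum((obs - fit)^2 / fit)`
#'   divided by the residual degrees of freedom.
#' @export
setGeneric("reducedChi2", function(object) standardGeneric("reducedChi2"))
#' @rdname reducedChi2
#' @export
setMethod("reducedChi2", "ComponentDecomposition", function(object) object@reducedChi2)
#' @rdname reducedChi2
#' @export
setMethod("reducedChi2", "GrowthFit", function(object) object@reducedChi2)

#' Table of generation-track entries
#'
#' @param object a [GenerationTracks-class] object.
#' @param generation optional generation id to subset to.
#' @return data.frame `generation`, `date`, `density`, `mean`, `sd`, ordered
#'   by generation and date.
#' @export
setGeneric("trackTable", function(object, generation = NULL)
  standardGeneric("trackTable"))

#' @rdname trackTable
#' @export
setMethod("trackTable", "GenerationTracks", function(object, generation = NULL) {
  en <- object@entries
  if (!is.null(generation)) en <- en[en$generation %in% generation, ]
  en[order(en$generation, en$date), , drop = FALSE]
})

#' Fitted growth-curve parameters and onset
#'
#' @param object a [GrowthFit-class] object.
#' @return `growthParams`: named numeric parameter vector (`mmax`, `b` for
#'   CBR; `m0`, `mmax`, `b`, `c` for DIR); `onsetDays`: the fitted onset in
#'   days; `birthDate`: the cohort birth date implied by the onset.
#' @export
setGeneric("growthParams", function(object) standardGeneric("growthParams"))
#' @rdname growthParams
#' @export
setMethod("growthParams", "GrowthFit", function(object) object@parameters)

#' @rdname growthParams
#' @export
setGeneric("onsetDays", function(object) standardGeneric("onsetDays"))
#' @rdname growthParams
#' @export
setMethod("onsetDays", "GrowthFit", function(object) object@onsetDays)

#' @rdname growthParams
#' @export
setGeneric("birthDate", function(object) standardGeneric("birthDate"))
#' @rdname growthParams
#' @export
setMethod("birthDate", "GrowthFit", function(object)
  object@onsetReference - round(object@onsetDays))

#' Seasonal birth intensity of a simulation configuration
#'
#' Evaluates the nonhomogeneous Poisson birth rate (births/day) at the given
#' days since study start.
#'
#' @param object a [SimulationConfig-class] object.
#' @param t days since study start.
#' @return numeric vector of intensities.
#' @export
setGeneric("birthIntensity", function(object, t) standardGeneric("birthIntensity"))

#' @rdname birthIntensity
#' @export
setMethod("birthIntensity", "SimulationConfig", function(object, t) {
  lam <- rep(object@birthOffset, length(t))
  bs <- object@birthSinusoids
  if (nrow(bs)) for (i in seq_len(nrow(bs)))
    lam <- lam + bs$amplitude[i] * sin(2 * pi * t / bs$period[i] + bs$phase[i])
  lam
})

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "ForamSamples", function(object) {
  sp <- object@specimens
  cat(sprintf("ForamSamples: %d specimens, %d sampling dates (%s .. %s)\n",
              nrow(sp), length(unique(sp$sampling_date)),
              format(min(sp$sampling_date)), format(max(sp$sampling_date))))
  cat(sprintf("  depths (m): %s | NoC on %d, TD on %d specimens\n",
              paste(sort(unique(sp$station_depth)), collapse = ", "),
              sum(!is.na(sp$chamber_count)), sum(!is.na(sp$test_diameter))))
})

setMethod("show", "ForamHistogram", function(object) {
  cat(sprintf("ForamHistogram (%s, %s): %d bins of width %.3g, n = %d\n",
              object@character, format(object@samplingDate),
              length(object@counts), diff(object@edges[1:2]),
              as.integer(sum(object@counts))))
})

setMethod("show", "ComponentDecomposition", function(object) {
  cat(sprintf("ComponentDecomposition (%s, %s): %d component(s), reduced chi2 = %.3g, normality p = %.3g\n",
              object@character, format(object@samplingDate),
              nrow(object@components), object@reducedChi2, object@normalityP))
  print(components(object), row.names = FALSE)
})

setMethod("show", "GenerationTracks", function(object) {
  en <- object@entries
  cat(sprintf("GenerationTracks (%s): %d generation(s), %d components\n",
              object@character, length(unique(en$generation)), nrow(en)))
  for (g in sort(unique(en$generation))) {
    tr <- en[en$generation == g, ]
    cat(sprintf("  generation %d: %d components, %s .. %s, mean %.4g .. %.4g\n",
                g, nrow(tr), format(min(tr$date)), format(max(tr$date)),
                tr$mean[which.min(tr$date)], tr$mean[which.max(tr$date)]))
  }
})

setMethod("show", "GrowthFit", function(object) {
  cat(sprintf("GrowthFit: %s (%s trajectory), generation %d\n",
              object@kind, object@trajectoryKind, object@generation))
  cat("  parameters:",
      paste(sprintf("%s = %.4g", names(object@parameters), object@parameters),
            collapse = ", "), "\n")
  cat(sprintf("  onset = %d days (birth %s), reduced chi2 = %.3g\n",
              as.integer(round(object@onsetDays)), format(birthDate(object)),
              object@reducedChi2))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: span %d days, %d samplings, max age %d days\n",
              as.integer(object@spanDays), length(object@samplingDays),
              as.integer(object@maxAgeDays)))
  cat(sprintf("  births: offset %.3g/day + %d sinusoid(s); individual CV %.3g\n",
              object@birthOffset, nrow(object@birthSinusoids), object@individualCV))
})

setMethod("show", "SimulatedPopulation", function(object) {
  cat(sprintf("SimulatedPopulation: %d individuals born, %d records observed over %d samplings\n",
              nrow(object@truth), nrow(object@observed),
              length(unique(object@observed$sampling_day))))
})
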