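## Published component-parameter tables of the Sesoko-Jima Heterostegina
## depressa campaign (17 monthly samplings, April 2014 - July 2015, stations
## at ~20 m and ~50 m), shipped as plain text under inst/extdata. The 50 m
## table carries chamber numbers only: the published diameter block for that
## station duplicates the chamber-number values (a printing erratum), and
## diameter components for 50 m must be re-derived from raw data.

#' Published monthly component parameters of the Sesoko populations
#'
#' Decomposed normal components (peak density in count units, mean, sd) of
#' the monthly chamber-number and test-diameter frequency distributions,
#' together with the generation structure of the campaign (generation 1
#' present from the study start into summer/autumn 2014; generations 2 and 3
#' spanning most of the period; generation 4 appearing in June 2015). The
#' generation column reflects the published identification and feeds
#' [assignGenerations()] as an override map.
#'
#' @param depth 20 or 50 (metres).
#' @param character optional filter, `"NoC"` or `"TD"`.
#' @return data.frame `date`, `character`, `component`, `density`, `mean`,
#'   `sd`, `generation`.
#' @export
sesokoComponents <- function(depth = 20, character = NULL) {
  stopifnot(depth %in% c(20, 50))
  path <- system.file("extdata", sprintf("components_%dm.csv", depth),
                      package = "foramDynamics", mustWork = TRUE)
  tab <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  tab$date <- as.Date(tab$date)
  if (!is.null(character)) {
    stopifnot(character %in% c("NoC", "TD"))
    tab <- tab[tab$character == character, , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}

#' Generation tracks of the published Sesoko component tables
#'
#' Builds a [GenerationTracks-class] object from [sesokoComponents()], using
#' the published generation identification as the override map of
#' [assignGenerations()].
#'
#' @param depth 20 or 50.
#' @param character `"NoC"` or `"TD"`.
#' @return a [GenerationTracks-class] object.
#' @export
sesokoTracks <- function(depth = 20, character = c("NoC", "TD")) {
  character <- match.arg(character)
  tab <- sesokoComponents(depth, character)
  if (!nrow(tab))
    stop(sprintf("no published %s components at %d m", character, depth),
         call. = FALSE)
  assignGenerations(tab[, c("date", "density", "mean", "sd", "generation")],
                    character = character)
}

#' Measured nepiont diameters of the Sesoko populations
#'
#' Mean maximal test diameter over all specimens at chamber numbers 2 and 3,
#' used as the diameter pseudo-observations of the onset interval.
#'
#' @param depth 20 or 50.
#' @return numeric `c(atNoC2, atNoC3)` in micrometres.
#' @export
nepiontDiameters <- function(depth = 20) {
  stopifnot(depth %in% c(20, 50))
  if (depth == 20) c(293.7, 346.5) else c(296.4, 347.6)
}
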