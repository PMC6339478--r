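## Linking of monthly components into generations, pooled CV, trajectories.

#' Link monthly components into generation tracks
#'
#' Greedy nearest-trajectory linking: within each month (processed in order
#' of decreasing component mean) a component is matched to the open track
#' whose last mean is closest, provided the implied growth is non-negative
#' within the slack tolerance for sampling noise. Components no admissible
#' track can claim open a new track (a new generation, numbered in order of
#' appearance). Tracks whose last mean exceeds every component of a month by
#' more than the slack can no longer be matched and are closed. A manual
#' override map `(date, component index) -> generation` is honoured first;
#' ambiguous matches (two admissible tracks) go to the smaller mean gap with
#' a warning.
#'
#' @param decomps list of [ComponentDecomposition-class] objects (one
#'   character), or a data.frame with columns `date`, `density`, `mean`,
#'   `sd` and optionally `generation` (used as override where non-`NA`).
#' @param character measurement character of the resulting tracks
#'   (`"NoC"` or `"TD"`); inferred from the decompositions when missing.
#' @param slack tolerated relative decrease of the mean along a track.
#' @param overrides data.frame `date`, `component`, `generation`; `component`
#'   indexes the month's components in decreasing-mean order.
#' @return a [GenerationTracks-class] object.
#' @export
assignGenerations <- function(decomps, character = NULL, slack = 0.15,
                              overrides = NULL) {
  if (is.data.frame(decomps)) {
    tab <- decomps
    stopifnot(all(c("date", "density", "mean", "sd") %in% names(tab)))
    if (is.null(character)) character <- attr(decomps, "character", exact = TRUE)
    if (is.null(character)) character <- "NoC"
  } else {
    stopifnot(length(decomps) >= 1, all(vapply(decomps, is, TRUE, "ComponentDecomposition")))
    if (is.null(character)) {
      hchar <- decomps[[1]]@character
      character <- if (hchar == "lnTD") "TD" else hchar
    }
    tab <- do.call(rbind, lapply(decomps, function(d) {
      cp <- components(d)          # report scale (um for diameters)
      data.frame(date = d@samplingDate, density = cp$density,
                 mean = cp$mean, sd = cp$sd)
    }))
  }
  if (length(unique(tab$date)) < 3)
    stop("need components from at least 3 months to link generations", call. = FALSE)
  ovr <- overrides
  if (is.null(ovr) && "generation" %in% names(tab)) {
    tab2 <- tab[order(tab$date, -tab$mean), ]
    idx <- unlist(lapply(split(seq_len(nrow(tab2)), format(tab2$date)),
                         seq_along), use.names = FALSE)
    ovr <- data.frame(date = tab2$date, component = idx,
                      generation = tab2$generation)
    ovr <- ovr[!is.na(ovr$generation), , drop = FALSE]
  }
  tracks <- list()   # keyed by as.character(id): list(id, lastMean, open)
  entries <- NULL
  nextId <- 1L
  for (d in as.list(sort(unique(tab$date)))) {
    comps <- tab[tab$date == d, , drop = FALSE]
    comps <- comps[order(comps$mean, decreasing = TRUE), , drop = FALSE]
    matchedIds <- integer()
    for (i in seq_len(nrow(comps))) {
      m <- comps$mean[i]
      gid <- NA_integer_
      if (!is.null(ovr)) {
        hit <- ovr$date == d & ovr$component == i
        if (any(hit)) gid <- as.integer(ovr$generation[which(hit)[1]])
      }
      if (is.na(gid)) {
        cand <- Filter(function(tr) tr$open && !(tr$id %in% matchedIds) &&
                         (m - tr$lastMean) / tr$lastMean >= -slack, tracks)
        if (length(cand)) {
          gaps <- vapply(cand, function(tr) abs(m - tr$lastMean), 0)
          if (sum(gaps <= min(gaps) * (1 + slack)) > 1)
            warning(sprintf("ambiguous assignment on %s (mean %.4g): choosing the smaller gap",
                            format(d), m), call. = FALSE)
          gid <- cand[[which.min(gaps)]]$id
        }
      }
      if (is.na(gid)) { gid <- nextId; nextId <- nextId + 1L }
      key <- as.character(gid)
      if (is.null(tracks[[key]])) {
        tracks[[key]] <- list(id = gid, lastMean = m, open = TRUE)
        nextId <- max(nextId, gid + 1L)
      } else {
        tracks[[key]]$lastMean <- m
      }
      matchedIds <- c(matchedIds, gid)
      entries <- rbind(entries, data.frame(generation = gid, date = d,
                                           density = comps$density[i],
                                           mean = m, sd = comps$sd[i]))
    }
    ## close tracks whose expected next value exceeds all observed components
    mTop <- max(comps$mean)
    for (key in names(tracks)) {
      tr <- tracks[[key]]
      if (tr$open && !(tr$id %in% matchedIds) && tr$lastMean * (1 - slack) > mTop)
        tracks[[key]]$open <- FALSE
    }
  }
  entries <- entries[order(entries$generation, entries$date), ]
  rownames(entries) <- NULL
  new("GenerationTracks", entries = entries, character = character,
      slack = max(slack, .requiredSlack(entries)))
}

## smallest slack under which the entries are valid (printed component tables
## can carry somewhat larger month-to-month sampling noise)
.requiredSlack <- function(entries) {
  req <- 0
  for (g in unique(entries$generation)) {
    tr <- entries[entries$generation == g, ]
    tr <- tr[order(tr$date), ]
    if (nrow(tr) > 1)
      req <- max(req, -min(diff(tr$mean) / head(tr$mean, -1)))
  }
  req + 1e-9
}

#' Pooled coefficient of variation of a generation track
#'
#' Arithmetic mean of `sd / mean` over the components assigned to one
#' generation. Pooling is per generation and character, keeping generations
#' independent.
#'
#' @param tracks a [GenerationTracks-class] object.
#' @param generation generation id.
#' @return the pooled CV (dimensionless).
#' @export
pooledCV <- function(tracks, generation) {
  stopifnot(is(tracks, "GenerationTracks"))
  tr <- tracks@entries[tracks@entries$generation == generation, ]
  if (!nrow(tr)) stop("no components in generation ", generation, call. = FALSE)
  if (any(tr$mean <= 0)) stop("component mean <= 0: CV undefined", call. = FALSE)
  mean(tr$sd / tr$mean)
}

#' Maximum and mean trajectories of a generation
#'
#' The cohort maximum at time t is `m = mean * (1 + 3 * CV_mean)` under the
#' default rule `s* = CV_mean * mean` (the normalized sd carries the
#' character's units). `sStarRule = "as-printed"` uses `s* = CV_mean / mean`
#' instead, for sensitivity checks. The mean trajectory uses the component
#' means unchanged.
#'
#' @param tracks a [GenerationTracks-class] object.
#' @param generation generation id.
#' @param sStarRule `"product"` (default) or `"as-printed"`.
#' @return data.frame with columns `date`, `offset` (days since the
#'   generation's first appearance), `mean`, `m` (the trajectory value), with
#'   attributes `generation`, `character`, `cvMean` and `trajectoryKind`.
#' @export
maximumTrajectory <- function(tracks, generation, sStarRule = "product") {
  sStarRule <- match.arg(sStarRule, c("product", "as-printed"))
  cv <- pooledCV(tracks, generation)
  tr <- trackTable(tracks, generation)
  sStar <- switch(sStarRule, product = cv * tr$mean, `as-printed` = cv / tr$mean)
  out <- data.frame(date = tr$date,
                    offset = as.numeric(tr$date - min(tr$date)),
                    mean = tr$mean,
                    m = tr$mean + 3 * sStar)
  structure(out, generation = generation, character = tracks@character,
            cvMean = cv, trajectoryKind = "max")
}

#' @rdname maximumTrajectory
#' @export
meanTrajectory <- function(tracks, generation) {
  cv <- pooledCV(tracks, generation)
  tr <- trackTable(tracks, generation)
  out <- data.frame(date = tr$date,
                    offset = as.numeric(tr$date - min(tr$date)),
                    mean = tr$mean,
                    m = tr$mean)
  structure(out, generation = generation, character = tracks@character,
            cvMean = cv, trajectoryKind = "mean")
}
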