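## Reading and writing of specimen tables and stage outputs.

.parseDates <- function(x) {
  x <- trimws(as.character(x))
  out <- as.Date(rep(NA_integer_, length(x)), origin = "1970-01-01")
  iso <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[iso] <- as.Date(x[iso], format = "%Y-%m-%d")
  dot <- grepl("^\\d{1,2}\\.\\d{1,2}\\.\\d{4}$", x)
  out[dot] <- as.Date(x[dot], format = "%d.%m.%Y")
  if (anyNA(out[!is.na(x) & nzchar(x)])) {
    bad <- which(is.na(out) & nzchar(x))
    stop(sprintf("unparseable date(s), e.g. '%s' (row %d); use DD.MM.YYYY or ISO 8601",
                 x[bad[1]], bad[1]), call. = FALSE)
  }
  out
}

## decimal commas ("0,74") are accepted alongside decimal points
.parseNumeric <- function(x) {
  if (is.numeric(x)) return(x)
  x <- trimws(as.character(x))
  x[!nzchar(x)] <- NA
  suppressWarnings(as.numeric(sub(",", ".", x, fixed = TRUE)))
}

#' Construct a ForamSamples object from a specimen data.frame
#'
#' @param specimens data.frame with columns `sampling_date`, `station_depth`,
#'   `chamber_count`, `test_diameter` and optionally `specimen_id` (generated
#'   when absent). Dates may be `Date` or text (`DD.MM.YYYY` or ISO 8601);
#'   numbers may use decimal commas.
#' @param sedimentWeight optional named numeric of sample weights (g) keyed by
#'   `"YYYY-MM-DD"` sampling date.
#' @param studyStart,studyEnd study window; defaults to the observed date range.
#' @return a validated [ForamSamples-class] object, rows sorted by date.
#' @export
foramSamples <- function(specimens, sedimentWeight = numeric(),
                         studyStart = NULL, studyEnd = NULL) {
  need <- c("sampling_date", "station_depth", "chamber_count", "test_diameter")
  miss <- setdiff(need, names(specimens))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  sp <- data.frame(
    specimen_id = if ("specimen_id" %in% names(specimens))
      as.character(specimens$specimen_id) else sprintf("sp%04d", seq_len(nrow(specimens))),
    sampling_date = if (inherits(specimens$sampling_date, "Date"))
      specimens$sampling_date else .parseDates(specimens$sampling_date),
    station_depth = .parseNumeric(specimens$station_depth),
    chamber_count = .parseNumeric(specimens$chamber_count),
    test_diameter = .parseNumeric(specimens$test_diameter),
    stringsAsFactors = FALSE)
  bad <- which(!is.na(sp$chamber_count) & sp$chamber_count < 2)
  if (length(bad))
    stop(sprintf("chamber_count < 2 in row %d (specimen %s)", bad[1],
                 sp$specimen_id[bad[1]]), call. = FALSE)
  bad <- which(!is.na(sp$test_diameter) & sp$test_diameter <= 0)
  if (length(bad))
    stop(sprintf("test_diameter <= 0 in row %d (specimen %s)", bad[1],
                 sp$specimen_id[bad[1]]), call. = FALSE)
  sp <- sp[order(sp$sampling_date, sp$specimen_id), , drop = FALSE]
  rownames(sp) <- NULL
  new("ForamSamples", specimens = sp,
      sedimentWeight = sedimentWeight,
      studyStart = if (is.null(studyStart)) min(sp$sampling_date) else as.Date(studyStart),
      studyEnd   = if (is.null(studyEnd)) max(sp$sampling_date) else as.Date(studyEnd))
}

#' Read a delimited specimen table
#'
#' Reads a comma- or tab-delimited text file with one row per specimen and
#' groups the rows into monthly samples. The expected columns are
#' `date`, `depth`, `chamber_count`, `test_diameter`; alternative
#' names can be supplied through `columns` because deposited raw-data layouts
#' differ. Dates may be `DD.MM.YYYY` or ISO 8601; decimal commas are accepted.
#'
#' @param path file path.
#' @param columns named character vector mapping the canonical names
#'   `date`, `depth`, `chamber_count`, `test_diameter` (and optionally
#'   `specimen_id`) to the column names present in the file.
#' @param sep field separator; guessed from the header line when `NULL`.
#' @param ... passed on to [foramSamples()] (e.g. the study window).
#' @return a [ForamSamples-class] object.
#' @export
readSpecimenTable <- function(path,
                              columns = c(date = "date", depth = "depth",
                                          chamber_count = "chamber_count",
                                          test_diameter = "test_diameter"),
                              sep = NULL, ...) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  raw <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "\"", comment.char = "")
  need <- c("date", "depth", "chamber_count", "test_diameter")
  if (any(!need %in% names(columns)))
    stop("column mapping must name: ", paste(need, collapse = ", "), call. = FALSE)
  miss <- setdiff(unname(columns[need]), names(raw))
  if (length(miss))
    stop("file lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  sp <- data.frame(sampling_date = raw[[columns[["date"]]]],
                   station_depth = raw[[columns[["depth"]]]],
                   chamber_count = raw[[columns[["chamber_count"]]]],
                   test_diameter = raw[[columns[["test_diameter"]]]],
                   stringsAsFactors = FALSE)
  if ("specimen_id" %in% names(columns) && columns[["specimen_id"]] %in% names(raw))
    sp$specimen_id <- raw[[columns[["specimen_id"]]]]
  foramSamples(sp, ...)
}

#' Write a stage output table
#'
#' Writes any stage output (component tables, generation tracks, growth fits,
#' birthdate records, periodogram rows) as UTF-8 delimited text with a header,
#' deterministic column order and plain decimal points, so that every stage
#' is re-loadable independently.
#'
#' @param rows data.frame (possibly empty: a header-only file is written).
#' @param path output file path.
#' @param sep field separator (default comma).
#' @return invisibly, the path.
#' @export
writeStageTable <- function(rows, path, sep = ",") {
  stopifnot(is.data.frame(rows))
  rows <- as.data.frame(lapply(rows, function(col) {
    if (inherits(col, "Date")) format(col) else col
  }), stringsAsFactors = FALSE, check.names = FALSE)
  names(rows) <- names(rows)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  write.table(rows, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a stage output table
#'
#' Counterpart of [writeStageTable()]; date-like columns (named `date`,
#' `sampling_date` or `birth_date`) are restored to `Date`.
#'
#' @param path file path.
#' @param sep field separator.
#' @return data.frame.
#' @export
readStageTable <- function(path, sep = ",") {
  out <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (nm in intersect(c("date", "sampling_date", "birth_date"), names(out)))
    out[[nm]] <- as.Date(out[[nm]])
  out
}

#' Build a study configuration
#'
#' Collects the tunable settings of the analysis pipeline. Defaults follow
#' the study design: an onset grid from 10 to 70 days in 5-day steps with
#' day-wise refinement, up to three normal components per monthly sample,
#' histogram bin widths of 5 chambers (NoC) and 0.15 (ln TD).
#'
#' @param studyStart,studyEnd study window (dates); may be `NULL` to adopt
#'   the data range when the configuration is applied.
#' @param binWidthNoC,binWidthLnTD histogram bin widths.
#' @param onsetGrid numeric `(min, max, step)` in days.
#' @param maxComponents maximum number of components (1-3).
#' @param seed RNG seed for seeded multistart fits.
#' @param sStarRule rule mapping the pooled CV to the normalized sd, see
#'   [StudyConfig-class].
#' @param pseudoDays,pseudoWeight placement (days of life) and weight of the
#'   two nepiont pseudo-observations used in growth fitting.
#' @param slack tolerated relative mean decrease along a generation track.
#' @param overrides data.frame `date`, `component`, `generation` of manual
#'   generation assignments.
#' @return a validated [StudyConfig-class] object.
#' @export
studyConfig <- function(studyStart = as.Date("2014-04-23"),
                        studyEnd = as.Date("2015-07-14"),
                        binWidthNoC = 5, binWidthLnTD = 0.15,
                        onsetGrid = c(10, 70, 5), maxComponents = 3,
                        seed = 1L, sStarRule = "product",
                        pseudoDays = c(1, 2), pseudoWeight = 2,
                        slack = 0.15,
                        overrides = data.frame(date = as.Date(character()),
                                               component = integer(),
                                               generation = integer())) {
  new("StudyConfig",
      studyStart = as.Date(studyStart), studyEnd = as.Date(studyEnd),
      binWidthNoC = binWidthNoC, binWidthLnTD = binWidthLnTD,
      onsetGrid = as.numeric(onsetGrid), maxComponents = as.numeric(maxComponents),
      seed = as.numeric(seed), sStarRule = sStarRule,
      pseudoDays = as.numeric(pseudoDays), pseudoWeight = pseudoWeight,
      slack = slack, overrides = overrides)
}
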