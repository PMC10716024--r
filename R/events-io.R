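## Reading/writing landing-event tables, species sheets, sample sheets and
## study reports. CSV dialect: comma separator, dot decimal, UTF-8, header
## row required, one landing event per row.

.EVENT_COLUMNS <- c("measurement_id", "day_id", "sample_id", "contrast")
.SPECIES_COLUMNS <- c("name", "material_class", "size_value", "size_unit")

#' Normalize the sign convention of an event list
#'
#' The canonical sign for ratiometric contrast is negative (mass binding).
#' Vendor exports sometimes report magnitudes; this normalizes them.
#'
#' @param m a [ContrastMeasurement-class].
#' @param policy `"as_is"` keeps the values; `"force_negative"` maps every
#'   event to `-|event|`; `"auto"` negates all events when more than half
#'   are positive. All policies are idempotent.
#' @return The measurement with normalized events.
#' @export
normalizeSign <- function(m, policy = c("auto", "as_is", "force_negative")) {
  policy <- match.arg(policy)
  ev <- m@events
  if (length(ev)) {
    if (policy == "force_negative") ev <- -abs(ev)
    else if (policy == "auto" && mean(ev > 0) > 0.5) ev <- -ev
  }
  methods::initialize(m, events = ev)
}

#' Read a landing-event CSV into ContrastMeasurement objects
#'
#' Expects columns `measurement_id, day_id, sample_id, contrast`, one
#' detected landing event per row. Rows are grouped by `measurement_id`
#' (order of first appearance preserved; event order within a measurement
#' is row order).
#'
#' @param source path to a CSV file (or a connection).
#' @param signPolicy see [normalizeSign()]; applied per measurement.
#' @return A named list of [ContrastMeasurement-class] objects (possibly
#'   empty, with a warning, for a header-only file).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("measurement_id,day_id,sample_id,contrast",
#'              "m1,day1,aav2,-0.105", "m1,day1,aav2,-0.146"), f)
#' ms <- readEventsCSV(f)
#' events(ms[["m1"]])
#' @export
readEventsCSV <- function(source,
                          signPolicy = c("auto", "as_is", "force_negative")) {
  signPolicy <- match.arg(signPolicy)
  df <- utils::read.csv(source, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(.EVENT_COLUMNS, names(df))
  if (length(missing))
    stop("events CSV is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(df) == 0L) {
    warning("events CSV contains no event rows")
    return(list())
  }
  contrast <- suppressWarnings(as.numeric(df$contrast))
  bad <- which(is.na(contrast) | !is.finite(contrast))
  if (length(bad))
    stop("non-numeric contrast value(s) at line(s) ",
         paste(bad + 1L, collapse = ", "), " of the events CSV")
  out <- list()
  for (mid in unique(df$measurement_id)) {
    idx <- which(df$measurement_id == mid)
    m <- ContrastMeasurement(measurementId = mid,
                             events = contrast[idx],
                             dayId = df$day_id[idx[1]],
                             sampleId = df$sample_id[idx[1]])
    out[[mid]] <- normalizeSign(m, signPolicy)
  }
  out
}

#' Write ContrastMeasurement objects to a landing-event CSV
#'
#' Inverse of [readEventsCSV()]: `readEventsCSV(writeEventsCSV(x, f))` is
#' the identity on the identifier and event fields.
#'
#' @param measurements a list of [ContrastMeasurement-class] objects (or a
#'   single one).
#' @param dest output path (or connection).
#' @return `dest`, invisibly.
#' @export
writeEventsCSV <- function(measurements, dest) {
  if (methods::is(measurements, "ContrastMeasurement"))
    measurements <- list(measurements)
  rows <- lapply(measurements, function(m) {
    data.frame(measurement_id = m@measurementId, day_id = m@dayId,
               sample_id = m@sampleId, contrast = m@events,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(df))
    df <- data.frame(measurement_id = character(0), day_id = character(0),
                     sample_id = character(0), contrast = numeric(0))
  utils::write.csv(df, dest, row.names = FALSE, quote = FALSE)
  invisible(dest)
}

#' Read / write a species sheet
#'
#' A species sheet declares the calibrant identities: columns
#' `name, material_class, size_value, size_unit`.
#'
#' @param source,dest CSV path (or connection).
#' @return `readSpeciesSheet`: a named list of [SpeciesSpec-class].
#' @export
readSpeciesSheet <- function(source) {
  df <- utils::read.csv(source, stringsAsFactors = FALSE)
  missing <- setdiff(.SPECIES_COLUMNS, names(df))
  if (length(missing))
    stop("species sheet is missing required column(s): ",
         paste(missing, collapse = ", "))
  out <- list()
  for (i in seq_len(nrow(df)))
    out[[df$name[i]]] <- SpeciesSpec(df$name[i], df$material_class[i],
                                     df$size_value[i], df$size_unit[i])
  out
}

#' @rdname readSpeciesSheet
#' @param species list of [SpeciesSpec-class] objects.
#' @export
writeSpeciesSheet <- function(species, dest) {
  df <- do.call(rbind, lapply(species, function(s) {
    data.frame(name = s@name, material_class = s@materialClass,
               size_value = s@sizeValue, size_unit = s@sizeUnit,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, dest, row.names = FALSE, quote = FALSE)
  invisible(dest)
}

#' Read a sample sheet of AAV samples
#'
#' Columns: `sample_id, serotype, expected_genome_length` where the
#' expected length is in bases, `0` means an empty capsid, and the literal
#' string `unknown` (or an empty field) means not known.
#'
#' @param source CSV path.
#' @return A named list of [AAVSampleSpec-class].
#' @export
readSampleSheet <- function(source) {
  df <- utils::read.csv(source, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("sample_id", "expected_genome_length")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("sample sheet is missing required column(s): ",
         paste(missing, collapse = ", "))
  out <- list()
  for (i in seq_len(nrow(df))) {
    raw <- trimws(df$expected_genome_length[i])
    egl <- if (raw %in% c("", "unknown", "NA")) NA_real_ else as.numeric(raw)
    sero <- if ("serotype" %in% names(df)) df$serotype[i] else ""
    out[[df$sample_id[i]]] <- AAVSampleSpec(df$sample_id[i], egl, sero)
  }
  out
}

## ---- report JSON ----------------------------------------------------------

.checkFiniteDeep <- function(x, where = "report") {
  if (is.list(x)) {
    for (i in seq_along(x))
      .checkFiniteDeep(x[[i]], where)
  } else if (is.numeric(x)) {
    bad <- !is.na(x) & !is.finite(x)
    if (any(bad))
      stop("non-finite number in ", where, "; refusing to serialize")
  }
  invisible(TRUE)
}

.estimateToList <- function(e) {
  days <- names(e@perDayMean)
  per_day <- lapply(days, function(d) {
    list(day_id = d, mean_bases = unname(e@perDayMean[[d]]),
         n = sum(e@perMeasurement$dayId == d))
  })
  list(sample_id = e@sampleId, approach = e@approach, per_day = per_day,
       mean_bases = e@meanBases, sd_bases = e@sdBases,
       cv_percent = e@cvPercent, accuracy_percent = e@accuracyPercent,
       reference_label = e@referenceLabel)
}

.estimateFromList <- function(x) {
  days <- vapply(x$per_day, `[[`, character(1), "day_id")
  perDay <- vapply(x$per_day, function(d) as.numeric(d$mean_bases),
                   numeric(1))
  names(perDay) <- days
  n <- vapply(x$per_day, function(d) as.integer(d$n), integer(1))
  pm <- data.frame(measurementId = rep(NA_character_, sum(n)),
                   dayId = rep(days, times = n),
                   bases = rep(perDay, times = n),
                   stringsAsFactors = FALSE)
  new("GenomeLengthEstimate", sampleId = x$sample_id, approach = x$approach,
      perMeasurement = pm, perDayMean = perDay,
      meanBases = as.numeric(x$mean_bases),
      sdBases = if (is.null(x$sd_bases)) NA_real_ else as.numeric(x$sd_bases),
      cvPercent = if (is.null(x$cv_percent)) NA_real_
                  else as.numeric(x$cv_percent),
      accuracyPercent = if (is.null(x$accuracy_percent)) NA_real_
                        else as.numeric(x$accuracy_percent),
      referenceLabel = if (is.null(x$reference_label)) "none"
                       else x$reference_label)
}

#' Write / read a study report as JSON
#'
#' Serializes a [StudyReport-class] with deterministic key order and full
#' numeric precision; `readReport(writeReport(x, f))` restores an equal
#' report. `NA` statistics (e.g. SD for a single measurement day) are
#' written as JSON `null`; genuinely non-finite numbers (NaN, Inf) are
#' refused.
#'
#' @param report a [StudyReport-class].
#' @param dest,source file path.
#' @return `writeReport`: `dest` invisibly. `readReport`: a
#'   [StudyReport-class].
#' @export
writeReport <- function(report, dest) {
  methods::validObject(report)
  x <- list(samples = lapply(report@estimates, .estimateToList),
            calibrations = lapply(report@calibrations, .calibrationToList),
            provenance = report@provenance)
  .checkFiniteDeep(x)
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = I(17), null = "null",
                           na = "null", pretty = TRUE)
  writeLines(json, dest, useBytes = TRUE)
  invisible(dest)
}

#' @rdname writeReport
#' @export
readReport <- function(source) {
  x <- jsonlite::fromJSON(source, simplifyVector = FALSE)
  new("StudyReport",
      estimates = lapply(x$samples, .estimateFromList),
      calibrations = lapply(x$calibrations, .calibrationFromList),
      provenance = if (is.null(x$provenance)) list() else x$provenance)
}
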