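## Run configuration and the end-to-end pipeline tying events, peaks,
## calibration and sizing together. The command-line entry point
## (inst/scripts/mpsize) is a thin wrapper around these functions.

#' RunConfig: configuration of one pipeline run
#'
#' @slot events path to the landing-event CSV.
#' @slot species path to the species sheet (calibrant identities), or "".
#' @slot samples path to the AAV sample sheet, or "".
#' @slot out path for the report JSON, or "" to skip writing.
#' @slot approach `a1`, `a2_delta`, `a2_abs` or `a3`.
#' @slot family calibration family for the run.
#' @slot referenceLabel reference population for delta-contrast sizing.
#' @slot includeEmpty include the empty-AAV zero-base point
#'   (aav_abs_bases).
#' @slot seed integer seed recorded in provenance.
#' @slot verbosity 0 = quiet, 1 = stage log, 2 = detail.
#' @slot regions classification bounds (see [regionDefaults()]).
#' @slot bandwidths list: `intact_kda` (default 40), `intact_bases`
#'   (default 120, for AAV-family analyses), `released_bases` (default 50).
#' @export
setClass("RunConfig",
         representation(events = "character", species = "character",
                        samples = "character", out = "character",
                        approach = "character", family = "character",
                        referenceLabel = "character",
                        includeEmpty = "logical", seed = "integer",
                        verbosity = "integer", regions = "list",
                        bandwidths = "list"))

.CONFIG_DEFAULTS <- list(
  events = "", species = "", samples = "", out = "",
  approach = "a1", family = "protein_mass", reference_label = "aav_empty",
  include_empty = FALSE, seed = 1L, verbosity = 1L,
  regions = NULL,  # filled from regionDefaults()
  bandwidths = list(intact_kda = 40, intact_bases = 120,
                    released_bases = 50))

.VALID_PAIRINGS <- list(
  a1 = c("protein_mass", "dsDNA_bp", "RNA_bases", "ssDNA_plasmid_bases"),
  a2_delta = "aav_delta_bases",
  a2_abs = "aav_abs_bases",
  a3 = c("RNA_bases", "ssDNA_plasmid_bases"))

.checkPairing <- function(approach, family) {
  ok <- .VALID_PAIRINGS[[approach]]
  if (is.null(ok)) stop("unknown approach '", approach, "'")
  if (!family %in% ok)
    stop("approach '", approach, "' is incompatible with calibration ",
         "family '", family, "' (expected one of: ",
         paste(ok, collapse = ", "), ")")
  invisible(TRUE)
}

#' Parse a pipeline configuration file
#'
#' Reads a YAML key-value file, fills all documented defaults and rejects
#' unknown keys. Region bounds are magnitudes and must be nonnegative.
#'
#' @param path path to a YAML config file.
#' @return A validated [RunConfig-class].
#' @seealso [writeRunConfig()] for the serializing inverse.
#' @export
parseConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), names(.CONFIG_DEFAULTS))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(.CONFIG_DEFAULTS, raw)
  regions <- regionDefaults()
  if (!is.null(cfg$regions)) {
    unknownR <- setdiff(names(cfg$regions), names(regions))
    if (length(unknownR))
      stop("unknown regions key(s): ", paste(unknownR, collapse = ", "))
    regions <- utils::modifyList(regions, cfg$regions)
  }
  regions$released <- as.numeric(regions$released)
  regions$aav <- as.numeric(regions$aav)
  .checkRegions(regions)
  bw <- cfg$bandwidths
  unknownB <- setdiff(names(bw), names(.CONFIG_DEFAULTS$bandwidths))
  if (length(unknownB))
    stop("unknown bandwidths key(s): ", paste(unknownB, collapse = ", "))
  bw <- utils::modifyList(.CONFIG_DEFAULTS$bandwidths, bw)
  if (any(unlist(bw) <= 0)) stop("bandwidths must be > 0")
  new("RunConfig", events = cfg$events, species = cfg$species,
      samples = cfg$samples, out = cfg$out, approach = cfg$approach,
      family = cfg$family, referenceLabel = cfg$reference_label,
      includeEmpty = isTRUE(cfg$include_empty),
      seed = as.integer(cfg$seed), verbosity = as.integer(cfg$verbosity),
      regions = regions, bandwidths = bw)
}

#' Serialize a RunConfig back to YAML
#'
#' `parseConfig(writeRunConfig(cfg, f))` is the identity.
#'
#' @param config a [RunConfig-class].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
writeRunConfig <- function(config, path) {
  x <- list(events = config@events, species = config@species,
            samples = config@samples, out = config@out,
            approach = config@approach, family = config@family,
            reference_label = config@referenceLabel,
            include_empty = config@includeEmpty, seed = config@seed,
            verbosity = config@verbosity, regions = config@regions,
            bandwidths = config@bandwidths)
  yaml::write_yaml(x, path)
  invisible(path)
}

.logStage <- function(config, ...) {
  if (config@verbosity >= 1L) message("[mpsize] ", ...)
}

## material classes contributing calibrant points to each standard family
.FAMILY_CLASSES <- list(protein_mass = c("protein", "aav_capsid"),
                        dsDNA_bp = "dsDNA", RNA_bases = "ssRNA",
                        ssDNA_plasmid_bases = "ssDNA_circular")

## peak contrast of one calibrant species, averaged over its measurements
.speciesPeakContrast <- function(ms, bwContrast) {
  mean(vapply(ms, .calibrantPeakMu, numeric(1),
              bandwidthContrast = bwContrast))
}

.buildStandardCalibration <- function(config, measurements, species) {
  fam <- config@family
  classes <- .FAMILY_CLASSES[[fam]]
  cal_species <- Filter(function(s) s@materialClass %in% classes, species)
  if (!length(cal_species))
    stop("species sheet has no calibrants of class ",
         paste(classes, collapse = "/"), " for family ", fam)
  bwContrast <- config@bandwidths$intact_kda * 3e-5  # provisional pass
  pts <- do.call(rbind, lapply(cal_species, function(s) {
    ms <- Filter(function(m) m@sampleId == s@name, measurements)
    if (!length(ms)) return(NULL)
    data.frame(name = s@name,
               contrast = .speciesPeakContrast(ms, bwContrast),
               response = s@sizeValue, stringsAsFactors = FALSE)
  }))
  if (is.null(pts) || nrow(pts) < 2L)
    stop("not enough calibrant measurements for family ", fam)
  buildLinearCalibration(pts, fam)
}

.measurementDelta <- function(m, config) {
  peaks <- fitMeasurementPeaks(m, bandwidth = config@bandwidths$intact_kda,
                               bandwidthUnit = "kDa", slopeHint = 3e-5,
                               regions = config@regions)
  filled <- .findPeak(peaks, "aav_filled")
  empty <- .findPeak(peaks, "aav_empty")
  if (is.null(filled) || is.null(empty))
    stop("empty/filled pair not resolved in measurement ", m@measurementId)
  filled@mu - empty@mu
}

.measurementFilledMu <- function(m, config) {
  peaks <- fitMeasurementPeaks(m, bandwidth = config@bandwidths$intact_kda,
                               bandwidthUnit = "kDa", slopeHint = 3e-5,
                               regions = config@regions)
  filled <- .findPeak(peaks, "aav_filled")
  if (is.null(filled))
    stop("no filled-AAV peak in measurement ", m@measurementId)
  filled@mu
}

.buildAAVCalibration <- function(config, sampleRuns, sampleSheet,
                                 excludeSample = NULL) {
  known <- Filter(function(s) !is.na(s@expectedGenomeLength) &&
                    s@expectedGenomeLength > 0, sampleSheet)
  known <- Filter(function(s) !identical(s@sampleId, excludeSample), known)
  known <- Filter(function(s) length(sampleRuns[[s@sampleId]]) > 0, known)
  if (length(known) < 2L)
    stop("an AAV calibration needs at least 2 samples of known genome ",
         "length (excluding the sample under analysis)")
  fam <- config@family
  pts <- do.call(rbind, lapply(known, function(s) {
    ms <- sampleRuns[[s@sampleId]]
    val <- if (fam == "aav_delta_bases")
      mean(vapply(ms, .measurementDelta, numeric(1), config = config))
    else
      mean(vapply(ms, .measurementFilledMu, numeric(1), config = config))
    data.frame(name = s@sampleId, contrast = val,
               response = s@expectedGenomeLength, stringsAsFactors = FALSE)
  }))
  if (fam == "aav_abs_bases" && config@includeEmpty) {
    emptyS <- Filter(function(s) !is.na(s@expectedGenomeLength) &&
                       s@expectedGenomeLength == 0, sampleSheet)
    if (length(emptyS)) {
      s <- emptyS[[1]]
      ms <- sampleRuns[[s@sampleId]]
      if (length(ms)) {
        bwContrast <- config@bandwidths$intact_kda * 3e-5
        pts <- rbind(pts, data.frame(
          name = s@sampleId,
          contrast = .speciesPeakContrast(ms, bwContrast),
          response = 0, stringsAsFactors = FALSE))
      }
    }
  }
  buildLinearCalibration(pts, fam, includeEmpty = config@includeEmpty,
                         referenceLabel = if (fam == "aav_delta_bases")
                           config@referenceLabel else "none")
}

.sizeOne <- function(m, config, curve) {
  switch(config@approach,
         a1 = sizeApproach1(m, curve,
                            bandwidth = config@bandwidths$intact_kda,
                            bandwidthUnit = "kDa",
                            regions = config@regions),
         a2_delta = sizeApproach2Delta(m, curve, config@referenceLabel,
                                       bandwidth =
                                         config@bandwidths$intact_kda,
                                       bandwidthUnit = "kDa",
                                       regions = config@regions),
         a2_abs = sizeApproach2Abs(m, curve,
                                   bandwidth = config@bandwidths$intact_kda,
                                   bandwidthUnit = "kDa",
                                   regions = config@regions),
         a3 = sizeApproach3(m, curve,
                            bandwidth = config@bandwidths$released_bases,
                            bandwidthUnit = "bases",
                            regions = config@regions))
}

#' Run the full sizing pipeline from a configuration
#'
#' Reads the landing-event CSV (and the species / sample sheets when
#' given), builds the configured calibration from the calibrant
#' measurements, sizes every sample measurement with the configured
#' approach, aggregates per sample across measurement days, and writes
#' the report JSON when an output path is configured. The run is
#' deterministic given identical inputs. For the AAV-based families the
#' calibration set is the samples of known genome length; a sample that
#' is itself part of the set is sized against a curve built from the
#' remaining samples (leave-one-out).
#'
#' @param config a [RunConfig-class] (see [parseConfig()]).
#' @return A [StudyReport-class], invisibly when written to file.
#' @export
runPipeline <- function(config) {
  .checkPairing(config@approach, config@family)
  if (!nzchar(config@events)) stop("config: 'events' path is required")
  .logStage(config, "reading events from ", config@events)
  measurements <- readEventsCSV(config@events)
  .logStage(config, length(measurements), " measurements read")
  species <- if (nzchar(config@species)) readSpeciesSheet(config@species)
             else list()
  sampleSheet <- if (nzchar(config@samples)) readSampleSheet(config@samples)
                 else list()
  speciesNames <- names(species)
  isCalibrant <- vapply(measurements, function(m)
    m@sampleId %in% speciesNames, logical(1))
  calRuns <- measurements[isCalibrant]
  sampleMs <- measurements[!isCalibrant]
  if (!length(sampleMs)) stop("no sample measurements found")
  if (!length(sampleSheet)) {
    ids <- unique(vapply(sampleMs, function(m) m@sampleId, character(1)))
    sampleSheet <- lapply(ids, AAVSampleSpec)
    names(sampleSheet) <- ids
  }
  sampleRuns <- split(sampleMs, vapply(sampleMs, function(m) m@sampleId,
                                       character(1)))
  aavFamily <- config@family %in% c("aav_delta_bases", "aav_abs_bases")
  sharedCurve <- NULL
  if (!aavFamily) {
    sharedCurve <- .buildStandardCalibration(config, calRuns, species)
    .logStage(config, sprintf(
      "calibration %s: slope %.4g, intercept %.4g, r2 %.5f",
      sharedCurve@family, sharedCurve@slope, sharedCurve@intercept,
      sharedCurve@rSquared))
  }
  calibrations <- list()
  estimates <- list()
  for (sid in names(sampleRuns)) {
    spec <- sampleSheet[[sid]]
    expected <- if (is.null(spec)) NA_real_ else spec@expectedGenomeLength
    if (!is.na(expected) && expected == 0) next  # empty reference sample
    curve <- if (aavFamily)
      .buildAAVCalibration(config, sampleRuns, sampleSheet,
                           excludeSample = sid)
    else sharedCurve
    calibrations[[sid]] <- curve
    pm <- do.call(rbind, lapply(sampleRuns[[sid]], function(m) {
      data.frame(measurementId = m@measurementId, dayId = m@dayId,
                 bases = .sizeOne(m, config, curve),
                 stringsAsFactors = FALSE)
    }))
    est <- aggregateStudy(pm, expected = expected, sampleId = sid,
                          approach = config@approach,
                          referenceLabel = if (config@approach == "a2_delta")
                            config@referenceLabel else "none")
    .logStage(config, sprintf("%s: %d bases (n=%d)", sid,
                              round(est@meanBases), nrow(pm)))
    estimates[[sid]] <- est
  }
  if (!length(estimates)) stop("no sizable sample measurements found")
  uniqueCurves <- calibrations[!duplicated(vapply(calibrations,
                                                  function(cv) cv@family,
                                                  character(1))) |
                                 aavFamily]
  report <- StudyReport(
    estimates = unname(estimates),
    calibrations = unname(uniqueCurves),
    provenance = list(seed = config@seed,
                      versions = list(
                        mpsize = as.character(
                          utils::packageVersion("mpsize")))))
  if (nzchar(config@out)) {
    writeReport(report, config@out)
    .logStage(config, "report written to ", config@out)
    return(invisible(report))
  }
  report
}
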