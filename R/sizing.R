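## The three sizing approaches, study-level aggregation, the within-sample
## resolution estimate and the approach-recommendation decision tree.

.A1_FAMILIES <- c("protein_mass", "dsDNA_bp", "RNA_bases",
                  "ssDNA_plasmid_bases")
.A3_FAMILIES <- c("RNA_bases", "ssDNA_plasmid_bases")

.findPeak <- function(peaks, label) {
  hit <- Filter(function(p) p@label == label, peaks)
  if (length(hit) == 0L) return(NULL)
  ## tie-break: the dominant population defines the sample
  hit[[which.max(vapply(hit, function(p) p@nEvents, integer(1)))]]
}

.peaksFor <- function(m, bandwidth, bandwidthUnit, slopeHint, regions,
                      singleAAVLabel = "aav_filled") {
  fitMeasurementPeaks(m, bandwidth = bandwidth, bandwidthUnit = bandwidthUnit,
                      slopeHint = slopeHint, regions = regions,
                      singleAAVLabel = singleAAVLabel)
}

#' Approach 1: size the genome from the empty/filled contrast difference
#'
#' Fits and classifies the peaks of an intact-AAV measurement, takes the
#' contrast difference between the filled and the empty capsid population,
#' and converts it into a genome length through a protein, dsDNA, RNA or
#' ssDNA-plasmid calibration (see [deltaContrastToBases()]).
#'
#' The measurement must contain both populations; if the sample has no
#' empty capsids, spike empty-AAV reference material into it.
#'
#' @param m a [ContrastMeasurement-class] of an intact AAV sample.
#' @param curve a [CalibrationCurve-class] of family `protein_mass`,
#'   `dsDNA_bp`, `RNA_bases` or `ssDNA_plasmid_bases`.
#' @param bandwidth,bandwidthUnit smoothing bandwidth for the intact-AAV
#'   analysis (default 40 kDa).
#' @param slopeHint |contrast per bandwidth unit|; defaults to the curve's
#'   slope when its unit matches, else a provisional 3e-5 per kDa.
#' @param regions classification bounds, see [regionDefaults()].
#' @param singleAAVLabel how to read a lone capsid-band peak (see
#'   [classifyPeaks()]); set `"aav_empty"` for a sample known to hold
#'   only empty capsids.
#' @return Genome length in bases (positive).
#' @export
sizeApproach1 <- function(m, curve, bandwidth = 40, bandwidthUnit = "kDa",
                          slopeHint = NULL, regions = regionDefaults(),
                          singleAAVLabel = "aav_filled") {
  if (!curve@family %in% .A1_FAMILIES)
    stop("approach 1 needs a protein/dsDNA/RNA/ssDNA-plasmid calibration, got ",
         curve@family)
  if (is.null(slopeHint))
    slopeHint <- if (curve@responseUnit == bandwidthUnit)
      slopeHintFromCalibration(curve) else 3e-5
  peaks <- .peaksFor(m, bandwidth, bandwidthUnit, slopeHint, regions,
                     singleAAVLabel = singleAAVLabel)
  filled <- .findPeak(peaks, "aav_filled")
  empty <- .findPeak(peaks, "aav_empty")
  if (is.null(empty))
    stop("no empty-AAV peak found; spike empty AAV reference material ",
         "into the sample so both populations are present")
  if (is.null(filled))
    stop("no filled-AAV peak found in the intact-AAV band")
  deltaContrastToBases(curve, filled@mu - empty@mu)
}

#' Approach 2 (delta contrast): size against an AAV delta-contrast calibration
#'
#' Takes the contrast difference between the filled population and a
#' reference population (empty AAV, or the HMW standard when the sample
#' was spiked with it) and applies the delta-contrast-vs-bases calibration
#' line (slope and intercept). Additive per-measurement drift cancels in
#' the difference.
#'
#' @param m a [ContrastMeasurement-class] of an intact AAV sample
#'   containing the reference population.
#' @param curve a [CalibrationCurve-class] of family `aav_delta_bases`,
#'   built with the same `referenceLabel`.
#' @param referenceLabel `"aav_empty"` or `"hmw_standard"`.
#' @inheritParams sizeApproach1
#' @return Genome length in bases.
#' @export
sizeApproach2Delta <- function(m, curve,
                               referenceLabel = c("aav_empty",
                                                  "hmw_standard"),
                               bandwidth = 40, bandwidthUnit = "kDa",
                               slopeHint = 3e-5,
                               regions = regionDefaults()) {
  referenceLabel <- match.arg(referenceLabel)
  if (curve@family != "aav_delta_bases")
    stop("approach 2 (delta) needs an aav_delta_bases calibration, got ",
         curve@family)
  if (curve@referenceLabel != referenceLabel)
    stop("reference mismatch: curve was built against '",
         curve@referenceLabel, "', requested '", referenceLabel, "'")
  peaks <- .peaksFor(m, bandwidth, bandwidthUnit, slopeHint, regions)
  filled <- .findPeak(peaks, "aav_filled")
  ## both the empty capsid and the HMW standard land in the intact band;
  ## the smaller-|contrast| peak is the reference either way
  ref <- .findPeak(peaks, "aav_empty")
  if (is.null(ref))
    stop("no reference peak (", referenceLabel, ") found; spike the ",
         "reference into the sample")
  if (is.null(filled))
    stop("no filled-AAV peak found in the intact-AAV band")
  deltaContrastToBases(curve, filled@mu - ref@mu)
}

#' Approach 2 (absolute contrast): size the filled peak directly
#'
#' Converts the absolute contrast of the filled-AAV peak into a genome
#' length by inverting an `aav_abs_bases` calibration. Needs no reference
#' population, but inherits any additive measurement drift: an offset
#' `d` added to all events shifts the estimate by `-d / slope`.
#'
#' @param m a [ContrastMeasurement-class] of an intact AAV sample.
#' @param curve a [CalibrationCurve-class] of family `aav_abs_bases`.
#' @inheritParams sizeApproach1
#' @return Genome length in bases.
#' @export
sizeApproach2Abs <- function(m, curve, bandwidth = 40,
                             bandwidthUnit = "kDa", slopeHint = 3e-5,
                             regions = regionDefaults()) {
  if (curve@family != "aav_abs_bases")
    stop("approach 2 (abs) needs an aav_abs_bases calibration, got ",
         curve@family)
  peaks <- .peaksFor(m, bandwidth, bandwidthUnit, slopeHint, regions)
  filled <- .findPeak(peaks, "aav_filled")
  if (is.null(filled))
    stop("no filled-AAV peak found in the intact-AAV band")
  predictResponse(curve, filled@mu)
}

#' Approach 3: size the released genome
#'
#' For a measurement taken after genome release (heating, or heating in
#' SDS followed by SDS removal), finds the released-genome peak and
#' converts its contrast into bases with a single-stranded nucleic acid
#' calibration (slope and intercept). Sizing is refused when an
#' intact-AAV peak is still present (incomplete disassembly) and fragment
#' and aggregate events never enter the fit window.
#'
#' @param m a [ContrastMeasurement-class] of a release workflow product.
#' @param curve a [CalibrationCurve-class] of family `RNA_bases` or
#'   `ssDNA_plasmid_bases`.
#' @param bandwidth,bandwidthUnit smoothing bandwidth for released-genome
#'   analysis (default 50 bases).
#' @param slopeHint |contrast per base|; defaults to the curve's slope.
#' @param regions classification bounds, see [regionDefaults()].
#' @return Genome length in bases.
#' @export
sizeApproach3 <- function(m, curve, bandwidth = 50, bandwidthUnit = "bases",
                          slopeHint = NULL, regions = regionDefaults()) {
  if (!curve@family %in% .A3_FAMILIES)
    stop("approach 3 needs an RNA_bases or ssDNA_plasmid_bases calibration, ",
         "got ", curve@family)
  if (is.null(slopeHint))
    slopeHint <- if (bandwidthUnit %in% c("bases", "bp"))
      slopeHintFromCalibration(curve) else 3e-5
  peaks <- .peaksFor(m, bandwidth, bandwidthUnit, slopeHint, regions)
  labels <- vapply(peaks, function(p) p@label, character(1))
  if (any(labels %in% c("aav_empty", "aav_filled")))
    stop("incomplete disassembly: an intact-AAV peak is still present; ",
         "sizing of the released genome refused")
  released <- .findPeak(peaks, "released_genome")
  if (is.null(released))
    stop("no released-genome peak found")
  predictResponse(curve, released@mu)
}

#' Aggregate per-measurement estimates into a study-level result
#'
#' Measurements are first averaged within each measurement day; the
#' headline statistics are then computed across the day means: mean, SD,
#' %CV = 100 * SD / mean, and accuracy = 100 * mean / expected when the
#' expected genome length is known and positive. With a single day, SD
#' and %CV are reported as not applicable (`NA`), not zero.
#'
#' @param perMeasurement data.frame with columns `measurementId`, `dayId`,
#'   `bases` (one row per measurement).
#' @param expected expected genome length in bases, or `NA` when unknown
#'   (accuracy is then omitted).
#' @param sampleId,approach,referenceLabel metadata stored on the result.
#' @return A [GenomeLengthEstimate-class].
#' @examples
#' pm <- data.frame(measurementId = paste0("m", 1:3),
#'                  dayId = paste0("day", 1:3),
#'                  bases = c(3900, 3991, 4082))
#' est <- aggregateStudy(pm, expected = 3793)
#' est@accuracyPercent  # ~105
#' @export
aggregateStudy <- function(perMeasurement, expected = NA_real_,
                           sampleId = "", approach = "a1",
                           referenceLabel = "none") {
  stopifnot(all(c("measurementId", "dayId", "bases") %in%
                names(perMeasurement)),
            nrow(perMeasurement) >= 1L)
  dayMeans <- tapply(perMeasurement$bases, perMeasurement$dayId, mean)
  dayMeans <- dayMeans[unique(perMeasurement$dayId)]  # keep day order
  perDay <- as.numeric(dayMeans)
  names(perDay) <- names(dayMeans)
  meanBases <- mean(perDay)
  if (length(perDay) >= 2L) {
    sdBases <- stats::sd(perDay)
    cvPercent <- 100 * sdBases / meanBases
  } else {
    sdBases <- NA_real_
    cvPercent <- NA_real_
  }
  accuracy <- if (!is.na(expected) && expected > 0)
    100 * meanBases / expected else NA_real_
  new("GenomeLengthEstimate", sampleId = sampleId, approach = approach,
      perMeasurement = perMeasurement, perDayMean = perDay,
      meanBases = meanBases, sdBases = sdBases, cvPercent = cvPercent,
      accuracyPercent = accuracy, referenceLabel = referenceLabel)
}

#' Display-rounded summary of a study estimate
#'
#' Table-style rounding: bases and accuracy to integers, %CV to one
#' decimal.
#'
#' @param est a [GenomeLengthEstimate-class].
#' @return A one-row data.frame.
#' @export
formatEstimate <- function(est) {
  data.frame(sample_id = est@sampleId, approach = est@approach,
             mean_bases = round(est@meanBases),
             sd_bases = if (is.na(est@sdBases)) NA else round(est@sdBases),
             cv_percent = if (is.na(est@cvPercent)) NA
                          else round(est@cvPercent, 1),
             accuracy_percent = if (is.na(est@accuracyPercent)) NA
                                else round(est@accuracyPercent),
             stringsAsFactors = FALSE)
}

#' Minimum resolvable within-sample genome-length difference
#'
#' Two equal Gaussian peaks of width `sigma` merge into a single mode when
#' closer than about one full width at half maximum; the minimal
#' resolvable contrast separation is therefore `k * sigma` with
#' `k = 2.355` (configurable), which the calibration slope converts into
#' bases: `delta_bases = k * sigma / |slope_bases|`.
#'
#' @param sigmaContrast peak width (SD) in contrast units.
#' @param curve a [CalibrationCurve-class]; its slope is converted to
#'   contrast-per-base through the family's chain (309 kDa/1,000 bases for
#'   protein mass, x2 for bp).
#' @param k resolvability criterion in units of sigma (default 2.355, the
#'   FWHM of a unit Gaussian).
#' @return Minimal resolvable genome-length difference in bases.
#' @examples
#' cal <- buildLinearCalibration(
#'   data.frame(contrast = c(-0.0334, -0.0352, -0.0370),
#'              response = c(3793, 4000, 4207)), "aav_delta_bases")
#' estimateResolutionLimit(0.0015, cal)
#' @export
estimateResolutionLimit <- function(sigmaContrast, curve, k = 2.355) {
  stopifnot(is.finite(sigmaContrast), sigmaContrast >= 0)
  if (!is.finite(curve@slope) || curve@slope == 0)
    stop("degenerate calibration curve: zero slope")
  slopeBases <- switch(curve@family,
                       protein_mass = abs(curve@slope) * 309 / 1000,
                       dsDNA_bp = abs(curve@slope) / 2,
                       abs(curve@slope))
  k * sigmaContrast / slopeBases
}

#' Recommend a sizing approach from available material
#'
#' Encodes the decision tree for picking the most suitable method given
#' the calibration and reference material at hand, in priority order:
#' the AAV delta-contrast calibration (most accurate) when an AAV
#' calibration set plus a reference (empty AAV or HMW standard) exist;
#' the absolute-contrast AAV calibration when an AAV set exists but no
#' reference can be spiked; the empty/filled contrast difference with a
#' protein or nucleic calibration (fastest) when a reference plus such
#' calibrants exist; and sizing after genome release (needs no AAV
#' calibration material) when single-stranded nucleic calibrants are
#' available and the genome can be released.
#'
#' @param hasEmptyReference empty-AAV material available (inherent or for
#'   spiking).
#' @param hasHmwStandard HMW standard available as reference.
#' @param hasAavCalibrationSet AAVs of known genome length available.
#' @param hasProteinCalibrants protein calibrants available.
#' @param hasSsNucleicCalibrants single-stranded nucleic acid calibrants
#'   (RNA ladder or ssDNA plasmids) available.
#' @param canReleaseGenome a genome-release workflow is applicable.
#' @return A list with elements `approach` (`a2_delta`, `a2_abs`, `a1` or
#'   `a3`) and `rationale` (character).
#' @export
recommendApproach <- function(hasEmptyReference = FALSE,
                              hasHmwStandard = FALSE,
                              hasAavCalibrationSet = FALSE,
                              hasProteinCalibrants = FALSE,
                              hasSsNucleicCalibrants = FALSE,
                              canReleaseGenome = FALSE) {
  hasReference <- hasEmptyReference || hasHmwStandard
  if (hasAavCalibrationSet && hasReference)
    return(list(approach = "a2_delta",
                rationale = paste("AAV calibration set and a reference",
                                  "population are available; the",
                                  "delta-contrast AAV calibration gives the",
                                  "most accurate and precise results.")))
  if (hasAavCalibrationSet)
    return(list(approach = "a2_abs",
                rationale = paste("AAV calibration set available but no",
                                  "reference can be spiked; size the filled",
                                  "peak's absolute contrast directly.")))
  if (hasReference && (hasProteinCalibrants || hasSsNucleicCalibrants))
    return(list(approach = "a1",
                rationale = paste("Reference population plus standard",
                                  "calibrants available; converting the",
                                  "empty/filled contrast difference is the",
                                  "fastest route (protein calibration",
                                  "preferred for accuracy).")))
  if (hasSsNucleicCalibrants && canReleaseGenome)
    return(list(approach = "a3",
                rationale = paste("No AAV reference or calibration material",
                                  "needed: release the genome and size it",
                                  "against a single-stranded nucleic acid",
                                  "calibration.")))
  stop("no sizing route available with the declared material")
}
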