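## S4 classes for mass-photometry landing-event data and genome sizing.
## Ratiometric contrasts are dimensionless; the canonical sign is NEGATIVE
## (a landing particle reduces the local reflectivity signal), so "larger"
## particles have larger |contrast|.

.MATERIAL_CLASSES <- c("protein", "aav_capsid", "dsDNA", "ssRNA",
                       "ssDNA_circular", "ssDNA_linear", "hmw_standard")

## unit required for each material class
.CLASS_UNIT <- c(protein = "kDa", aav_capsid = "kDa", hmw_standard = "kDa",
                 dsDNA = "bp", ssRNA = "bases",
                 ssDNA_circular = "bases", ssDNA_linear = "bases")

.CAL_FAMILIES <- c("protein_mass", "dsDNA_bp", "RNA_bases",
                   "ssDNA_plasmid_bases", "aav_delta_bases", "aav_abs_bases")

.FAMILY_UNIT <- c(protein_mass = "kDa", dsDNA_bp = "bp", RNA_bases = "bases",
                  ssDNA_plasmid_bases = "bases", aav_delta_bases = "bases",
                  aav_abs_bases = "bases")

.PEAK_LABELS <- c("unlabeled", "aav_empty", "aav_filled", "released_genome",
                  "fragment", "aggregate", "calibrant")

#' ContrastMeasurement: one MP acquisition
#'
#' Holds the signed ratiometric contrast of every landing event detected in
#' one mass-photometry acquisition (by default a 60 s video), together with
#' measurement / day / sample identifiers.
#'
#' @slot measurementId character(1), unique measurement identifier.
#' @slot dayId character(1), measurement-day identifier.
#' @slot sampleId character(1), sample identifier.
#' @slot events numeric vector of ratiometric contrasts (canonically <= 0).
#' @slot durationS acquisition duration in seconds.
#' @slot metadata free-form list (e.g. simulation truth, `allowEmpty` flag).
#'
#' @export
setClass("ContrastMeasurement",
         representation(measurementId = "character", dayId = "character",
                        sampleId = "character", events = "numeric",
                        durationS = "numeric", metadata = "list"),
         prototype(measurementId = "", dayId = "", sampleId = "",
                   events = numeric(0), durationS = 60,
                   metadata = list(allowEmpty = TRUE)))

setValidity("ContrastMeasurement", function(object) {
  msg <- character(0)
  for (s in c("measurementId", "dayId", "sampleId"))
    if (length(slot(object, s)) != 1L)
      msg <- c(msg, sprintf("'%s' must be a single string", s))
  if (anyNA(object@events) || any(!is.finite(object@events)))
    msg <- c(msg, "all events must be finite")
  if (length(object@events) == 0L && !isTRUE(object@metadata$allowEmpty))
    msg <- c(msg, "empty event list requires allowEmpty = TRUE")
  if (length(object@durationS) != 1L || object@durationS <= 0)
    msg <- c(msg, "durationS must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Create a ContrastMeasurement
#'
#' @param measurementId,dayId,sampleId identifiers (single strings).
#' @param events numeric vector of signed ratiometric contrasts.
#' @param durationS acquisition duration in seconds (default 60).
#' @param metadata list of free-form metadata.
#' @param allowEmpty logical; permit an empty event list (flagged in
#'   `metadata`).
#' @return A [ContrastMeasurement-class] object.
#' @examples
#' m <- ContrastMeasurement("m1", c(-0.105, -0.146, -0.041))
#' events(m)
#' @export
ContrastMeasurement <- function(measurementId, events, dayId = "day1",
                                sampleId = "", durationS = 60,
                                metadata = list(), allowEmpty = FALSE) {
  if (allowEmpty) metadata$allowEmpty <- TRUE
  new("ContrastMeasurement", measurementId = as.character(measurementId),
      dayId = as.character(dayId), sampleId = as.character(sampleId),
      events = as.numeric(events), durationS = durationS, metadata = metadata)
}

#' SpeciesSpec: a calibrant or reference species
#'
#' Declares the identity of one calibration species: its material class and
#' its known size (molecular mass in kDa for proteins, capsids and the HMW
#' standard; length in bp for dsDNA; length in bases for RNA and ssDNA).
#'
#' @slot name character(1) species name.
#' @slot materialClass one of `protein`, `aav_capsid`, `dsDNA`, `ssRNA`,
#'   `ssDNA_circular`, `ssDNA_linear`, `hmw_standard`.
#' @slot sizeValue positive size in `sizeUnit`.
#' @slot sizeUnit one of `kDa`, `bases`, `bp` (must match the class).
#' @export
setClass("SpeciesSpec",
         representation(name = "character", materialClass = "character",
                        sizeValue = "numeric", sizeUnit = "character"))

setValidity("SpeciesSpec", function(object) {
  msg <- character(0)
  if (!object@materialClass %in% .MATERIAL_CLASSES)
    msg <- c(msg, sprintf("unknown material class '%s'", object@materialClass))
  else if (object@sizeUnit != .CLASS_UNIT[[object@materialClass]])
    msg <- c(msg, sprintf("class '%s' requires size unit '%s', got '%s'",
                          object@materialClass,
                          .CLASS_UNIT[[object@materialClass]],
                          object@sizeUnit))
  if (length(object@sizeValue) != 1L || !is.finite(object@sizeValue) ||
      object@sizeValue <= 0)
    msg <- c(msg, "sizeValue must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' @rdname SpeciesSpec-class
#' @param name,materialClass,sizeValue,sizeUnit see slot descriptions.
#' @return A [SpeciesSpec-class] object.
#' @examples
#' SpeciesSpec("thyroglobulin", "protein", 670, "kDa")
#' @export
SpeciesSpec <- function(name, materialClass, sizeValue, sizeUnit) {
  new("SpeciesSpec", name = as.character(name),
      materialClass = as.character(materialClass),
      sizeValue = as.numeric(sizeValue), sizeUnit = as.character(sizeUnit))
}

#' AAVSampleSpec: an AAV sample under analysis
#'
#' @slot sampleId character(1).
#' @slot serotype character(1) (free text, e.g. "AAV9").
#' @slot expectedGenomeLength expected genome length in bases; `NA` encodes
#'   "unknown" (0 is meaningful: an empty capsid).
#' @slot spikedReference a [SpeciesSpec-class] (empty AAV or HMW standard)
#'   or `NULL`.
#' @export
setClass("AAVSampleSpec",
         representation(sampleId = "character", serotype = "character",
                        expectedGenomeLength = "numeric",
                        spikedReference = "ANY"),
         prototype(serotype = "", expectedGenomeLength = NA_real_,
                   spikedReference = NULL))

setValidity("AAVSampleSpec", function(object) {
  msg <- character(0)
  egl <- object@expectedGenomeLength
  if (length(egl) != 1L || (!is.na(egl) && (!is.finite(egl) || egl < 0)))
    msg <- c(msg, "expectedGenomeLength must be NA (unknown) or >= 0 bases")
  if (!is.null(object@spikedReference) &&
      !methods::is(object@spikedReference, "SpeciesSpec"))
    msg <- c(msg, "spikedReference must be NULL or a SpeciesSpec")
  if (length(msg)) msg else TRUE
})

#' @rdname AAVSampleSpec-class
#' @param sampleId,serotype,expectedGenomeLength,spikedReference see slots.
#' @return An [AAVSampleSpec-class] object.
#' @export
AAVSampleSpec <- function(sampleId, expectedGenomeLength = NA_real_,
                          serotype = "", spikedReference = NULL) {
  new("AAVSampleSpec", sampleId = as.character(sampleId),
      serotype = as.character(serotype),
      expectedGenomeLength = as.numeric(expectedGenomeLength),
      spikedReference = spikedReference)
}

#' SmoothedDistribution: kernel density estimate of an event list
#'
#' @slot grid strictly increasing contrast grid.
#' @slot density nonnegative KDE values on the grid.
#' @slot bandwidthContrast kernel SD in contrast units (> 0).
#' @slot bandwidthDeclared list(value=, unit=) as declared by the user
#'   (e.g. 40 kDa), before conversion to contrast units.
#' @slot slopeUsed |contrast per declared unit| used for the conversion
#'   (NA when the bandwidth was given directly in contrast units).
#' @slot nEvents number of events the density was estimated from.
#' @export
setClass("SmoothedDistribution",
         representation(grid = "numeric", density = "numeric",
                        bandwidthContrast = "numeric",
                        bandwidthDeclared = "list", slopeUsed = "numeric",
                        nEvents = "integer"))

setValidity("SmoothedDistribution", function(object) {
  msg <- character(0)
  if (length(object@grid) != length(object@density))
    msg <- c(msg, "grid and density lengths differ")
  if (any(diff(object@grid) <= 0))
    msg <- c(msg, "grid must be strictly increasing")
  if (any(object@density < 0)) msg <- c(msg, "density must be >= 0")
  if (object@bandwidthContrast <= 0)
    msg <- c(msg, "bandwidthContrast must be > 0")
  if (length(msg)) msg else TRUE
})

#' PeakFit: one fitted Gaussian population
#'
#' @slot mu fitted peak contrast (signed).
#' @slot sigma fitted peak width in contrast units (> 0).
#' @slot nEvents raw events inside the final fit window.
#' @slot window numeric(2), final fit window (lo, hi) in contrast units.
#' @slot rmsResidual RMS of density residuals of the fit.
#' @slot label population label (see [classifyPeaks()]).
#' @slot lowConfidence TRUE when fewer events than the minimum supported
#'   the fit.
#' @slot degenerate TRUE when the events had (near) zero spread and sigma
#'   was floored.
#' @export
setClass("PeakFit",
         representation(mu = "numeric", sigma = "numeric",
                        nEvents = "integer", window = "numeric",
                        rmsResidual = "numeric", label = "character",
                        lowConfidence = "logical", degenerate = "logical"),
         prototype(label = "unlabeled", lowConfidence = FALSE,
                   degenerate = FALSE, rmsResidual = NA_real_))

setValidity("PeakFit", function(object) {
  msg <- character(0)
  if (length(object@window) != 2L || object@window[1] >= object@window[2])
    msg <- c(msg, "window must be (lo, hi) with lo < hi")
  else if (object@mu <= object@window[1] || object@mu >= object@window[2])
    msg <- c(msg, "mu must lie strictly inside the window")
  if (object@sigma <= 0) msg <- c(msg, "sigma must be > 0")
  if (!object@label %in% .PEAK_LABELS)
    msg <- c(msg, sprintf("unknown label '%s'", object@label))
  if (length(msg)) msg else TRUE
})

#' CalibrationCurve: one linear contrast-vs-size calibration
#'
#' A straight line `contrast = slope * response + intercept` fitted by
#' ordinary least squares to the calibration points of one family, plus the
#' conversion chain that turns predicted responses into bases.
#'
#' @slot family one of `protein_mass`, `dsDNA_bp`, `RNA_bases`,
#'   `ssDNA_plasmid_bases`, `aav_delta_bases`, `aav_abs_bases`.
#' @slot slope contrast per response unit (negative: heavier/longer species
#'   produce more negative contrast).
#' @slot intercept contrast at zero response.
#' @slot responseUnit `kDa`, `bp` or `bases`.
#' @slot points data.frame with columns `name`, `contrast`, `response`.
#' @slot rSquared coefficient of determination of the fit.
#' @slot includeEmpty whether the empty-AAV zero-base point was included
#'   (aav_abs_bases family only).
#' @slot referenceLabel reference population for delta-contrast use:
#'   `aav_empty`, `hmw_standard` or `none`.
#' @export
setClass("CalibrationCurve",
         representation(family = "character", slope = "numeric",
                        intercept = "numeric", responseUnit = "character",
                        points = "data.frame", rSquared = "numeric",
                        includeEmpty = "logical", referenceLabel = "character"),
         prototype(includeEmpty = FALSE, referenceLabel = "none"))

setValidity("CalibrationCurve", function(object) {
  msg <- character(0)
  if (!object@family %in% .CAL_FAMILIES)
    msg <- c(msg, sprintf("unknown calibration family '%s'", object@family))
  if (!is.finite(object@slope) || object@slope >= 0)
    msg <- c(msg, "slope must be finite and negative")
  if (nrow(object@points) < 2L)
    msg <- c(msg, "a calibration needs at least 2 points")
  if (!all(c("name", "contrast", "response") %in% names(object@points)))
    msg <- c(msg, "points must have columns name, contrast, response")
  if (!object@referenceLabel %in% c("aav_empty", "hmw_standard", "none"))
    msg <- c(msg, "referenceLabel must be aav_empty, hmw_standard or none")
  if (length(msg)) msg else TRUE
})

#' GenomeLengthEstimate: per-study sizing result for one sample
#'
#' @slot sampleId sample identifier.
#' @slot approach `a1`, `a2_delta`, `a2_abs` or `a3`.
#' @slot perMeasurement data.frame(measurementId, dayId, bases).
#' @slot perDayMean named numeric, mean bases per day.
#' @slot meanBases mean across day means.
#' @slot sdBases SD across day means (`NA` for a single day).
#' @slot cvPercent 100 * sdBases / meanBases (`NA` for a single day).
#' @slot accuracyPercent 100 * meanBases / expected (`NA` when the expected
#'   length is unknown or zero).
#' @slot referenceLabel reference population used (or `none`).
#' @export
setClass("GenomeLengthEstimate",
         representation(sampleId = "character", approach = "character",
                        perMeasurement = "data.frame",
                        perDayMean = "numeric", meanBases = "numeric",
                        sdBases = "numeric", cvPercent = "numeric",
                        accuracyPercent = "numeric",
                        referenceLabel = "character"),
         prototype(referenceLabel = "none", accuracyPercent = NA_real_,
                   sdBases = NA_real_, cvPercent = NA_real_))

setValidity("GenomeLengthEstimate", function(object) {
  msg <- character(0)
  if (!object@approach %in% c("a1", "a2_delta", "a2_abs", "a3"))
    msg <- c(msg, sprintf("unknown approach '%s'", object@approach))
  if (!all(c("measurementId", "dayId", "bases") %in%
           names(object@perMeasurement)))
    msg <- c(msg, "perMeasurement needs columns measurementId, dayId, bases")
  if (!is.na(object@cvPercent) && object@cvPercent < 0)
    msg <- c(msg, "cvPercent must be >= 0")
  if (!all(names(object@perDayMean) %in% object@perMeasurement$dayId))
    msg <- c(msg, "perDayMean keys must be day ids seen in perMeasurement")
  if (length(msg)) msg else TRUE
})

#' StudyReport: the result bundle of one sizing study
#'
#' @slot estimates list of [GenomeLengthEstimate-class].
#' @slot calibrations list of [CalibrationCurve-class] used.
#' @slot provenance list (seed, package version, config hash, ...).
#' @export
setClass("StudyReport",
         representation(estimates = "list", calibrations = "list",
                        provenance = "list"),
         prototype(estimates = list(), calibrations = list(),
                   provenance = list()))

setValidity("StudyReport", function(object) {
  ok_e <- all(vapply(object@estimates, methods::is, logical(1),
                     "GenomeLengthEstimate"))
  ok_c <- all(vapply(object@calibrations, methods::is, logical(1),
                     "CalibrationCurve"))
  msg <- character(0)
  if (!ok_e) msg <- c(msg, "estimates must be GenomeLengthEstimate objects")
  if (!ok_c) msg <- c(msg, "calibrations must be CalibrationCurve objects")
  if (length(msg)) msg else TRUE
})

#' @rdname StudyReport-class
#' @param estimates,calibrations,provenance see slots.
#' @return A [StudyReport-class] object.
#' @export
StudyReport <- function(estimates = list(), calibrations = list(),
                        provenance = list()) {
  new("StudyReport", estimates = estimates, calibrations = calibrations,
      provenance = provenance)
}

#' SimConfig: generative parameters of the landing-event simulator
#'
#' The simulator draws each population's events from a Gaussian around
#' `-(coefficient x size)`, adds a per-measurement additive drift offset,
#' and (for genome-release workflows) mixes in fragment and aggregate
#' artifact events. See [simConfig()] for the defaults and their meaning.
#'
#' @slot alphaCapsid contrast per kDa for capsid-like particles (> 0,
#'   applied with negative sign).
#' @slot perBaseMass kDa per base of encapsidated ssDNA (default 0.309).
#' @slot alphaFreeSS contrast per base for free linear ssDNA (default
#'   0.041/4658).
#' @slot classRatio named numeric: factor by which sizing an encapsidated
#'   genome with each family over-estimates.
#' @slot sigmaEvent per-event contrast SD.
#' @slot driftSd SD of the per-measurement additive offset.
#' @slot nPerPeak default events per population.
#' @slot emptyCapsidMass kDa (default 3700).
#' @slot hmwMass kDa (default 3643).
#' @slot fragmentFraction named numeric, per release workflow.
#' @slot aggregateFraction named numeric, per release workflow.
#' @slot seed integer RNG seed.
#' @export
setClass("SimConfig",
         representation(alphaCapsid = "numeric", perBaseMass = "numeric",
                        alphaFreeSS = "numeric", classRatio = "numeric",
                        sigmaEvent = "numeric", driftSd = "numeric",
                        nPerPeak = "integer", emptyCapsidMass = "numeric",
                        hmwMass = "numeric", fragmentFraction = "numeric",
                        aggregateFraction = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  pos <- c("alphaCapsid", "perBaseMass", "alphaFreeSS", "emptyCapsidMass",
           "hmwMass")
  for (s in pos)
    if (slot(object, s) <= 0) msg <- c(msg, sprintf("%s must be > 0", s))
  if (any(object@classRatio <= 0)) msg <- c(msg, "class ratios must be > 0")
  need <- c("ssRNA", "ssDNA_circular", "dsDNA_per_2bases",
            "protein_mass_route")
  if (!all(need %in% names(object@classRatio)))
    msg <- c(msg, "classRatio must name ssRNA, ssDNA_circular, dsDNA_per_2bases, protein_mass_route")
  if (object@sigmaEvent < 0 || object@driftSd < 0)
    msg <- c(msg, "sigmaEvent and driftSd must be >= 0")
  for (s in c("fragmentFraction", "aggregateFraction")) {
    fr <- slot(object, s)
    if (!all(c("heat", "sds") %in% names(fr)) || any(fr < 0) || any(fr >= 1))
      msg <- c(msg, sprintf("%s must name heat and sds, each in [0, 1)", s))
  }
  if (length(msg)) msg else TRUE
})
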