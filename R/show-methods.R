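## Accessors and show() methods.

#' @rdname mpsize-accessors
setMethod("events", "ContrastMeasurement", function(object) object@events)
#' @rdname mpsize-accessors
setMethod("measurementId", "ContrastMeasurement",
          function(object) object@measurementId)
#' @rdname mpsize-accessors
setMethod("dayId", "ContrastMeasurement", function(object) object@dayId)
#' @rdname mpsize-accessors
setMethod("sampleId", "ContrastMeasurement",
          function(object) object@sampleId)
#' @rdname mpsize-accessors
setMethod("sampleId", "AAVSampleSpec", function(object) object@sampleId)

#' @rdname mpsize-accessors
setMethod("peakContrast", "PeakFit", function(object) object@mu)
#' @rdname mpsize-accessors
setMethod("peakWidth", "PeakFit", function(object) object@sigma)
#' @rdname mpsize-accessors
setMethod("eventCount", "PeakFit", function(object) object@nEvents)
#' @rdname mpsize-accessors
setMethod("eventCount", "ContrastMeasurement",
          function(object) length(object@events))
#' @rdname mpsize-accessors
setMethod("peakLabel", "PeakFit", function(object) object@label)

#' @rdname mpsize-accessors
setMethod("slope", "CalibrationCurve", function(object) object@slope)
#' @rdname mpsize-accessors
setMethod("intercept", "CalibrationCurve", function(object) object@intercept)
#' @rdname mpsize-accessors
setMethod("calibrationFamily", "CalibrationCurve",
          function(object) object@family)
#' @rdname mpsize-accessors
setMethod("calibrationPoints", "CalibrationCurve",
          function(object) object@points)
#' @rdname mpsize-accessors
setMethod("rSquared", "CalibrationCurve", function(object) object@rSquared)

#' @rdname mpsize-accessors
setMethod("estimates", "StudyReport", function(object) object@estimates)

setMethod("show", "ContrastMeasurement", function(object) {
  n <- length(object@events)
  cat(sprintf("ContrastMeasurement '%s' (day %s, sample '%s'): %d events\n",
              object@measurementId, object@dayId, object@sampleId, n))
  if (n)
    cat(sprintf("  contrast range [%.4f, %.4f], median %.4f\n",
                min(object@events), max(object@events),
                stats::median(object@events)))
})

setMethod("show", "SpeciesSpec", function(object) {
  cat(sprintf("SpeciesSpec '%s': %s, %g %s\n", object@name,
              object@materialClass, object@sizeValue, object@sizeUnit))
})

setMethod("show", "AAVSampleSpec", function(object) {
  egl <- if (is.na(object@expectedGenomeLength)) "unknown"
         else sprintf("%g bases", object@expectedGenomeLength)
  cat(sprintf("AAVSampleSpec '%s'%s: expected genome length %s\n",
              object@sampleId,
              if (nzchar(object@serotype))
                sprintf(" (%s)", object@serotype) else "",
              egl))
})

setMethod("show", "SmoothedDistribution", function(object) {
  cat(sprintf(paste0("SmoothedDistribution: %d grid points on ",
                     "[%.4f, %.4f], bandwidth %.3g contrast (%g %s), ",
                     "%d events\n"),
              length(object@grid), min(object@grid), max(object@grid),
              object@bandwidthContrast, object@bandwidthDeclared$value,
              object@bandwidthDeclared$unit, object@nEvents))
})

setMethod("show", "PeakFit", function(object) {
  flags <- c(if (object@lowConfidence) "low-confidence",
             if (object@degenerate) "degenerate")
  cat(sprintf("PeakFit [%s]: mu %.4f, sigma %.4g, %d events%s\n",
              object@label, object@mu, object@sigma, object@nEvents,
              if (length(flags)) paste0(" (", paste(flags, collapse = ", "),
                                        ")") else ""))
})

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf(paste0("CalibrationCurve '%s': contrast = %.4g x %s %+.4g ",
                     "(r2 %.5f, %d points)\n"),
              object@family, object@slope, object@responseUnit,
              object@intercept, object@rSquared, nrow(object@points)))
  if (object@family == "aav_abs_bases")
    cat(sprintf("  empty-AAV point included: %s\n", object@includeEmpty))
  if (object@referenceLabel != "none")
    cat(sprintf("  delta-contrast reference: %s\n", object@referenceLabel))
})

setMethod("show", "GenomeLengthEstimate", function(object) {
  f <- formatEstimate(object)
  cat(sprintf("GenomeLengthEstimate '%s' (%s): %d bases",
              object@sampleId, object@approach, f$mean_bases))
  if (!is.na(f$sd_bases))
    cat(sprintf(" +/- %d (CV %.1f%%)", f$sd_bases, f$cv_percent))
  if (!is.na(f$accuracy_percent))
    cat(sprintf(", accuracy %d%%", f$accuracy_percent))
  cat(sprintf("; %d measurements over %d day(s)\n",
              nrow(object@perMeasurement), length(object@perDayMean)))
})

setMethod("show", "StudyReport", function(object) {
  cat(sprintf("StudyReport: %d sample estimate(s), %d calibration(s)\n",
              length(object@estimates), length(object@calibrations)))
  for (e in object@estimates) show(e)
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0("SimConfig: alphaCapsid %.3g/kDa, alphaFreeSS ",
                     "%.3g/base, sigmaEvent %.3g, driftSd %.3g, ",
                     "nPerPeak %d, seed %d\n"),
              object@alphaCapsid, object@alphaFreeSS, object@sigmaEvent,
              object@driftSd, object@nPerPeak, object@seed))
})
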