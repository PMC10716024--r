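## Linear contrast-vs-size calibrations, conversion chains to bases, and
## leverage diagnostics.
##
## Orientation: contrast is regressed on the response (mass or length), so
## the slope carries units of contrast per kDa / bp / base -- the same
## orientation in which instrument-style calibration slopes are quoted.
## Prediction inverts the fitted line analytically.

## minimum point counts per family: families with a declared calibrant set
## of three or more species need at least 3 points.
.FAMILY_MIN_POINTS <- c(protein_mass = 3L, dsDNA_bp = 3L, RNA_bases = 3L,
                        ssDNA_plasmid_bases = 3L, aav_delta_bases = 2L,
                        aav_abs_bases = 2L)

#' Mean ssDNA chain-residue mass, per 1,000 bases
#'
#' The mass added per base of a ssDNA chain is the monophosphate monomer
#' mass minus one water (lost on phosphodiester-bond formation). Averaged
#' over the four deoxynucleoside monophosphates (dAMP 331.22, dCMP 307.20,
#' dGMP 347.22, dTMP 322.21 Da; water 18.02 Da) this gives ~308.9 Da per
#' base, i.e. ~309 kDa per 1,000 bases -- the factor used to convert a
#' mass difference into a genome length.
#'
#' @return Mean residue mass scaled to 1,000 bases, in kDa.
#' @examples
#' dnaResidueMassPer1000Bases()  # ~ 309
#' @export
dnaResidueMassPer1000Bases <- function() {
  dnmp <- c(dAMP = 331.22, dCMP = 307.20, dGMP = 347.22, dTMP = 322.21)
  water <- 18.02
  mean(dnmp - water)  # Da per base is numerically kDa per 1,000 bases
}

#' Build a linear calibration curve for one family
#'
#' Ordinary least squares fit of `contrast = slope * response + intercept`.
#' The intercept is always estimated; for the ssDNA-plasmid family the
#' `(0, 0)` zero point enters as an ordinary datum (not a constraint) and
#' is appended automatically unless already present. For the
#' `aav_abs_bases` family, `includeEmpty` records whether the empty-AAV
#' point at 0 bases was part of the fit.
#'
#' @param points data.frame with columns `name`, `contrast` (peak contrast,
#'   canonical sign), `response` (size in the family unit). For
#'   `aav_delta_bases` the "contrast" column holds delta contrasts
#'   (filled minus reference).
#' @param family one of `protein_mass`, `dsDNA_bp`, `RNA_bases`,
#'   `ssDNA_plasmid_bases`, `aav_delta_bases`, `aav_abs_bases`.
#' @param includeEmpty flag stored on the curve (aav_abs_bases only).
#' @param referenceLabel reference population the delta contrasts refer to
#'   (`aav_empty`, `hmw_standard` or `none`).
#' @param addZeroPoint append the `(0, 0)` datum for the plasmid family
#'   (default TRUE).
#' @return A [CalibrationCurve-class].
#' @examples
#' pts <- data.frame(name = c("u272", "u545", "thyro", "aav1"),
#'                   response = c(272, 545, 670, 3700))
#' pts$contrast <- -3e-5 * pts$response
#' cal <- buildLinearCalibration(pts, "protein_mass")
#' slope(cal)      # -3e-5
#' rSquared(cal)   # 1
#' @export
buildLinearCalibration <- function(points, family,
                                   includeEmpty = FALSE,
                                   referenceLabel = c("none", "aav_empty",
                                                      "hmw_standard"),
                                   addZeroPoint = TRUE) {
  referenceLabel <- match.arg(referenceLabel)
  family <- match.arg(family, .CAL_FAMILIES)
  stopifnot(is.data.frame(points),
            all(c("contrast", "response") %in% names(points)))
  if (is.null(points$name)) points$name <- paste0("pt", seq_len(nrow(points)))
  points <- points[, c("name", "contrast", "response")]
  if (family == "ssDNA_plasmid_bases" && addZeroPoint &&
      !any(points$response == 0))
    points <- rbind(points, data.frame(name = "zero_point", contrast = 0,
                                       response = 0))
  minPts <- .FAMILY_MIN_POINTS[[family]]
  if (nrow(points) < minPts)
    stop(sprintf("family '%s' needs at least %d calibration points, got %d",
                 family, minPts, nrow(points)))
  dup <- duplicated(points$response) &
    !duplicated(points[, c("contrast", "response")])
  if (any(dup))
    warning("duplicate responses with conflicting contrasts; keeping all")
  fit <- stats::lm(contrast ~ response, data = points)
  cf <- stats::coef(fit)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn
  if (!is.finite(r2)) r2 <- 1  # saturated two-point fit
  new("CalibrationCurve", family = family,
      slope = unname(cf[["response"]]), intercept = unname(cf[["(Intercept)"]]),
      responseUnit = .FAMILY_UNIT[[family]], points = points,
      rSquared = r2, includeEmpty = includeEmpty,
      referenceLabel = referenceLabel)
}

#' Invert a calibration line: contrast to response
#'
#' `response = (contrast - intercept) / slope`, without clipping. A
#' negative prediction (contrast on the wrong side of the intercept) is
#' returned with a warning.
#'
#' @param curve a [CalibrationCurve-class].
#' @param contrast signed ratiometric contrast (scalar or vector).
#' @return Predicted response in the curve's unit (kDa, bp or bases).
#' @export
predictResponse <- function(curve, contrast) {
  if (!is.finite(curve@slope) || curve@slope == 0)
    stop("degenerate calibration curve: zero slope")
  resp <- (contrast - curve@intercept) / curve@slope
  if (any(resp < 0))
    warning("negative predicted response; contrast outside calibrated range")
  resp
}

#' Convert a mass difference into bases
#'
#' Applies the 309 kDa per 1,000 bases conversion for encapsidated ssDNA:
#' `bases = delta_kDa * 1000 / 309`. Sign preserved.
#'
#' @param deltaMass mass difference in kDa.
#' @return Length in bases.
#' @examples
#' convertMassDiffToBases(309)  # 1000
#' @export
convertMassDiffToBases <- function(deltaMass) deltaMass * 1000 / 309

#' Convert base pairs into bases
#'
#' One base pair of dsDNA counts as two bases: `bases = 2 * bp`.
#'
#' @param deltaBp length (difference) in base pairs.
#' @return Length in bases.
#' @export
convertBpToBases <- function(deltaBp) 2 * deltaBp

#' Convert a contrast difference into a genome length
#'
#' The core of the intact-AAV sizing approaches: a contrast difference
#' between the filled population and a reference population is pushed
#' through the calibration family's conversion chain.
#' * `protein_mass`: delta mass via the slope only (the intercept cancels
#'   on differences), then 309 kDa -> 1,000 bases.
#' * `dsDNA_bp`: delta bp via the slope, then x2.
#' * `RNA_bases`, `ssDNA_plasmid_bases`: delta bases via the slope.
#' * `aav_delta_bases`: the delta-contrast-vs-bases line is applied
#'   directly, slope and intercept.
#' * `aav_abs_bases`: error -- that family sizes absolute contrasts, use
#'   [predictResponse()].
#'
#' @param curve a [CalibrationCurve-class].
#' @param deltaContrast `c_filled - c_reference` (negative under the
#'   canonical sign when the filled capsid is heavier).
#' @return Genome length (difference) in bases.
#' @export
deltaContrastToBases <- function(curve, deltaContrast) {
  if (!is.finite(curve@slope) || curve@slope == 0)
    stop("degenerate calibration curve: zero slope")
  switch(curve@family,
         protein_mass = convertMassDiffToBases(deltaContrast / curve@slope),
         dsDNA_bp = convertBpToBases(deltaContrast / curve@slope),
         RNA_bases = deltaContrast / curve@slope,
         ssDNA_plasmid_bases = deltaContrast / curve@slope,
         aav_delta_bases = (deltaContrast - curve@intercept) / curve@slope,
         aav_abs_bases = stop("aav_abs_bases sizes absolute contrasts, ",
                              "not differences; use predictResponse()"))
}

#' Leverage of each calibration point
#'
#' Hat-matrix diagonal of the simple linear regression,
#' `h_i = 1/n + (x_i - xbar)^2 / sum((x_j - xbar)^2)` with `x` the
#' response values. Quantifies how strongly an extreme point (such as the
#' 0-base empty capsid in an absolute-contrast AAV calibration) pulls the
#' fitted slope. Each `h_i` lies in `[1/n, 1]` and the diagonal sums to 2.
#'
#' @param curve a [CalibrationCurve-class] (two points give the saturated
#'   fit, `h = 1` for both).
#' @return Named numeric vector of leverages, one per point.
#' @export
pointLeverage <- function(curve) {
  x <- curve@points$response
  if (length(x) < 2L) stop("leverage diagnostics need at least 2 points")
  ssx <- sum((x - mean(x))^2)
  if (ssx == 0) stop("degenerate design: all responses equal")
  h <- 1 / length(x) + (x - mean(x))^2 / ssx
  names(h) <- curve@points$name
  h
}

## ---- calibration JSON -----------------------------------------------------

.calibrationToList <- function(curve) {
  list(family = curve@family, slope = curve@slope,
       intercept = curve@intercept, response_unit = curve@responseUnit,
       r_squared = curve@rSquared, include_empty = curve@includeEmpty,
       reference_label = curve@referenceLabel,
       points = lapply(seq_len(nrow(curve@points)), function(i) {
         list(name = curve@points$name[i],
              contrast = curve@points$contrast[i],
              response = curve@points$response[i])
       }))
}

.calibrationFromList <- function(x) {
  pts <- do.call(rbind, lapply(x$points, function(p) {
    data.frame(name = p$name, contrast = as.numeric(p$contrast),
               response = as.numeric(p$response), stringsAsFactors = FALSE)
  }))
  new("CalibrationCurve", family = x$family, slope = as.numeric(x$slope),
      intercept = as.numeric(x$intercept), responseUnit = x$response_unit,
      points = pts, rSquared = as.numeric(x$r_squared),
      includeEmpty = isTRUE(x$include_empty),
      referenceLabel = if (is.null(x$reference_label)) "none"
                       else x$reference_label)
}

#' Write / read a calibration curve as JSON
#'
#' Full-precision serialization; `readCalibration(writeCalibration(x, f))`
#' reproduces slope, intercept and points bit-exactly.
#'
#' @param curve a [CalibrationCurve-class].
#' @param dest,source file path.
#' @return `writeCalibration`: `dest` invisibly; `readCalibration`: a
#'   [CalibrationCurve-class].
#' @export
writeCalibration <- function(curve, dest) {
  json <- jsonlite::toJSON(.calibrationToList(curve), auto_unbox = TRUE,
                           digits = I(17), pretty = TRUE)
  writeLines(json, dest, useBytes = TRUE)
  invisible(dest)
}

#' @rdname writeCalibration
#' @export
readCalibration <- function(source) {
  .calibrationFromList(jsonlite::fromJSON(source, simplifyVector = FALSE))
}
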