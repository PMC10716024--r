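# Shared fixture builders. Everything is generated in code; no data files.

# noiseless simulator configuration with unit class ratios: the sizing
# chain must reproduce the truth exactly under these conditions
noiselessConfig <- function(seed = 1L) {
  cfg <- simConfig(sigmaEvent = 0, driftSd = 0, seed = seed)
  cfg@classRatio[] <- 1
  cfg
}

# calibration points from a simulated calibrant set, taking each
# measurement's event mean as its peak contrast (exact for noiseless data)
pointsFromSet <- function(calSet) {
  do.call(rbind, lapply(calSet, function(m) {
    data.frame(name = m@sampleId, contrast = mean(events(m)),
               response = m@metadata$species@sizeValue,
               stringsAsFactors = FALSE)
  }))
}

# exact line as a CalibrationCurve via two synthetic points
lineCurve <- function(slope, intercept = 0, family = "aav_delta_bases",
                      responses = c(3000, 5000), ...) {
  pts <- data.frame(name = paste0("p", seq_along(responses)),
                    contrast = slope * responses + intercept,
                    response = responses)
  buildLinearCalibration(pts, family, addZeroPoint = FALSE, ...)
}

expectedLengths <- c(aav2 = 3793, aav3 = 4142, aav4 = 4504,
                     aav5 = 4596, aav6 = 4658)
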