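## Seeded end-to-end accuracy studies: simulate a multi-day experiment,
## run the full peak-fit -> calibrate -> size chain, and report the mean
## absolute relative error of the recovered genome length. These drive the
## reproducibility script and double as integration checks of the whole
## pipeline.

.absRelErrPct <- function(est, truth) abs(est - truth) / truth * 100

## fit the single calibrant peak of a measurement and return its contrast
.calibrantPeakMu <- function(m, bandwidthContrast, minEvents = 50L) {
  dist <- smoothEvents(m, bandwidthContrast, "contrast")
  wins <- detectPeaks(dist, minEvents = minEvents)
  if (!length(wins)) stop("no calibrant peak found in ", m@measurementId)
  fit <- fitGaussianPeak(m, wins[[1]], dist, minEvents = minEvents)
  fit@mu
}

## calibration points (peak contrast vs declared size) from a calibrant
## measurement set produced by the simulator
.calibrationPointsFromSet <- function(calSet, bandwidthContrast) {
  do.call(rbind, lapply(calSet, function(m) {
    sp <- m@metadata$species
    data.frame(name = sp@name,
               contrast = .calibrantPeakMu(m, bandwidthContrast),
               response = sp@sizeValue, stringsAsFactors = FALSE)
  }))
}

#' Accuracy study for approach 1 (protein calibration)
#'
#' For each simulated day: measure the protein calibrant set (urease
#' 272/545, thyroglobulin 670, empty AAV 3,700 kDa), build the protein
#' calibration from the fitted peak contrasts, then size `repsPerDay`
#' replicate intact measurements of an AAV sample via the empty/filled
#' contrast difference and the 309 kDa / 1,000 bases conversion. The
#' smoothing slope hint is recomputed from the day's calibration (second
#' pass) before the sample peaks are fitted.
#'
#' @param seed integer seed for the whole study.
#' @param genomeLength true genome length in bases.
#' @param nDays,repsPerDay study design.
#' @param cfg a [SimConfig-class]; by default the study conditions with
#'   the protein-route class ratio at 1 (matched protein/capsid optics).
#' @return A list: `perDayEstimate` (bases), `perDayErrorPct`,
#'   `meanAbsRelErrorPct`.
#' @export
benchmarkApproach1 <- function(seed = 1L, genomeLength = 4658,
                               nDays = 3L, repsPerDay = 3L,
                               cfg = NULL) {
  if (is.null(cfg)) {
    cfg <- simConfig(seed = seed)
    cfg@classRatio[["protein_mass_route"]] <- 1.0
  } else {
    cfg@seed <- as.integer(seed)
  }
  fx <- makeStudyFixture(cfg, nDays = nDays, repsPerDay = repsPerDay,
                         genomeLengths = c(sample = genomeLength),
                         withRelease = FALSE)
  bwProvisional <- 40 * 3e-5
  perDay <- vapply(fx$days, function(day) {
    pts <- .calibrationPointsFromSet(day$calibrants$protein_mass,
                                     bwProvisional)
    cal <- buildLinearCalibration(pts, "protein_mass")
    reps <- vapply(day$intact$sample, function(m)
      sizeApproach1(m, cal, bandwidth = 40, bandwidthUnit = "kDa",
                    slopeHint = slopeHintFromCalibration(cal)),
      numeric(1))
    mean(reps)
  }, numeric(1))
  errs <- .absRelErrPct(perDay, genomeLength)
  list(perDayEstimate = perDay, perDayErrorPct = errs,
       meanAbsRelErrorPct = mean(errs))
}

#' Accuracy study for approach 2 (delta contrast, leave-one-out)
#'
#' Simulates `nDays` x `repsPerDay` intact measurements of five AAV
#' samples of known genome length, each containing an empty-capsid
#' reference population. Per day, every sample's mean delta contrast
#' (filled minus empty, averaged over replicates) is computed; the
#' delta-contrast-vs-bases calibration for the target sample is built
#' from the other four samples and the held-out sample is sized with it.
#'
#' @param seed integer seed.
#' @param genomeLengths named numeric of the calibration-set genome
#'   lengths in bases.
#' @param target name of the held-out sample to report.
#' @param nDays,repsPerDay study design.
#' @param cfg a [SimConfig-class] (defaults to the study conditions).
#' @return A list: `perDayEstimate`, `perDayErrorPct`,
#'   `meanAbsRelErrorPct` for the held-out sample.
#' @export
benchmarkApproach2Delta <- function(seed = 1L,
                                    genomeLengths = c(aav2 = 3793,
                                                      aav3 = 4142,
                                                      aav4 = 4504,
                                                      aav5 = 4596,
                                                      aav6 = 4658),
                                    target = "aav6",
                                    nDays = 3L, repsPerDay = 3L,
                                    cfg = NULL) {
  stopifnot(target %in% names(genomeLengths))
  if (is.null(cfg)) cfg <- simConfig(seed = seed)
  else cfg@seed <- as.integer(seed)
  fx <- makeStudyFixture(cfg, nDays = nDays, repsPerDay = repsPerDay,
                         genomeLengths = genomeLengths,
                         withRelease = FALSE)
  truth <- genomeLengths[[target]]
  others <- setdiff(names(genomeLengths), target)
  perDay <- vapply(fx$days, function(day) {
    deltaOf <- function(m) {
      peaks <- fitMeasurementPeaks(m)
      filled <- .findPeak(peaks, "aav_filled")
      empty <- .findPeak(peaks, "aav_empty")
      if (is.null(filled) || is.null(empty))
        stop("empty/filled pair not resolved in ", m@measurementId)
      filled@mu - empty@mu
    }
    pts <- do.call(rbind, lapply(others, function(s) {
      data.frame(name = s,
                 contrast = mean(vapply(day$intact[[s]], deltaOf,
                                        numeric(1))),
                 response = genomeLengths[[s]], stringsAsFactors = FALSE)
    }))
    cal <- buildLinearCalibration(pts, "aav_delta_bases",
                                  referenceLabel = "aav_empty")
    reps <- vapply(day$intact[[target]], function(m)
      sizeApproach2Delta(m, cal, "aav_empty"), numeric(1))
    mean(reps)
  }, numeric(1))
  errs <- .absRelErrPct(perDay, truth)
  list(perDayEstimate = perDay, perDayErrorPct = errs,
       meanAbsRelErrorPct = mean(errs))
}

#' Accuracy study for approach 3 (SDS release, ssDNA-plasmid calibration)
#'
#' Simulates noise-free, coefficient-matched measurements of the two
#' circular ssDNA plasmid calibrants (ΦX174 5,386 and M13 mp18 7,249
#' bases), builds the ssDNA-plasmid calibration (with the zero point),
#' then sizes `nReps` replicate SDS-workflow release measurements of the
#' target genome.
#'
#' @param seed integer seed.
#' @param genomeLength true genome length in bases.
#' @param nReps number of release replicates.
#' @param cfg a [SimConfig-class] for the release measurements (defaults
#'   to the study conditions with a coefficient-matched plasmid class).
#' @return A list: `perRepEstimate`, `perRepErrorPct`,
#'   `meanAbsRelErrorPct`.
#' @export
benchmarkApproach3 <- function(seed = 1L, genomeLength = 4658, nReps = 3L,
                               cfg = NULL) {
  if (is.null(cfg)) {
    cfg <- simConfig(seed = seed)
    cfg@classRatio[["ssDNA_circular"]] <- 1.0
  } else {
    cfg@seed <- as.integer(seed)
  }
  set.seed(cfg@seed)
  ## noiseless, coefficient-matched calibrant measurements
  calCfg <- cfg
  calCfg@sigmaEvent <- 0
  calCfg@driftSd <- 0
  calSet <- lapply(calibrantSpecies("ssDNA_plasmid_bases"), function(s)
    .simSpeciesEvents(s, calCfg@nPerPeak, calCfg, measurementId = s@name))
  pts <- do.call(rbind, lapply(calSet, function(m) {
    sp <- m@metadata$species
    ## zero spread: the peak contrast is the (degenerate) event value
    data.frame(name = sp@name, contrast = m@events[1],
               response = sp@sizeValue, stringsAsFactors = FALSE)
  }))
  cal <- buildLinearCalibration(pts, "ssDNA_plasmid_bases")
  reps <- vapply(seq_len(nReps), function(r) {
    m <- .simRelease(genomeLength, "sds", cfg,
                     measurementId = sprintf("release_rep%d", r))
    sizeApproach3(m, cal)
  }, numeric(1))
  errs <- .absRelErrPct(reps, genomeLength)
  list(perRepEstimate = reps, perRepErrorPct = errs,
       meanAbsRelErrorPct = mean(errs))
}
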