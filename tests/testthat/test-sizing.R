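test_that("noiseless simulation round-trips exactly through all approaches", {
  cfg <- noiselessConfig()
  truth <- 4658

  # approach 1, protein calibration + mass-to-bases conversion
  calSet <- simulateCalibrantSet("protein_mass", cfg, seed = 31)
  prot <- buildLinearCalibration(pointsFromSet(calSet), "protein_mass")
  m <- simulateIntactAAVSample(truth, 0.5, 600, cfg, seed = 32)
  expect_equal(sizeApproach1(m, prot), truth, tolerance = 1e-6)

  # approach 2 delta: leave-one-out over the five-sample calibration set
  deltas <- vapply(names(expectedLengths), function(s) {
    ms <- simulateIntactAAVSample(expectedLengths[[s]], 0.5, 600, cfg,
                                  seed = 33)
    peaks <- fitMeasurementPeaks(ms)
    peakContrast(peaks[[2]]) - peakContrast(peaks[[1]])
  }, numeric(1))
  for (held in names(expectedLengths)) {
    others <- setdiff(names(expectedLengths), held)
    cal <- buildLinearCalibration(
      data.frame(name = others, contrast = deltas[others],
                 response = expectedLengths[others]),
      "aav_delta_bases", referenceLabel = "aav_empty")
    mh <- simulateIntactAAVSample(expectedLengths[[held]], 0.5, 600, cfg,
                                  seed = 34)
    expect_equal(sizeApproach2Delta(mh, cal, "aav_empty"),
                 expectedLengths[[held]],
                 tolerance = 1e-6)
  }

  # approach 2 abs: filled-peak contrasts of four samples size the fifth
  absMu <- vapply(names(expectedLengths), function(s) {
    ms <- simulateIntactAAVSample(expectedLengths[[s]], 0, 300, cfg,
                                  seed = 35)
    peakContrast(fitMeasurementPeaks(ms)[[1]])
  }, numeric(1))
  calAbs <- buildLinearCalibration(
    data.frame(name = names(expectedLengths)[-5],
               contrast = absMu[-5], response = expectedLengths[-5]),
    "aav_abs_bases")
  m6 <- simulateIntactAAVSample(truth, 0, 300, cfg, seed = 36)
  expect_equal(sizeApproach2Abs(m6, calAbs), truth, tolerance = 1e-6)

  # approach 3: released genome against the ssDNA-plasmid calibration
  plas <- buildLinearCalibration(
    pointsFromSet(simulateCalibrantSet("ssDNA_plasmid_bases", cfg,
                                       seed = 37)),
    "ssDNA_plasmid_bases")
  mr <- simulateGenomeRelease(truth, "sds", cfg, seed = 38)
  expect_equal(sizeApproach3(mr, plas), truth, tolerance = 1e-6)
})

test_that("a coincident empty/filled pair gives zero genome length", {
  prot <- lineCurve(-3e-5, 0, "protein_mass", c(272, 545, 3700))
  expect_equal(deltaContrastToBases(prot, 0), 0)
})

test_that("class ratios propagate into approach-1 calibration biases", {
  cfg <- simConfig(sigmaEvent = 0, driftSd = 0)  # default class ratios
  truth <- 4658
  m <- simulateIntactAAVSample(truth, 0.5, 600, cfg, seed = 41)
  est <- vapply(c("dsDNA_bp", "RNA_bases", "ssDNA_plasmid_bases"),
                function(fam) {
    cal <- buildLinearCalibration(
      pointsFromSet(simulateCalibrantSet(fam, cfg, seed = 42)), fam)
    sizeApproach1(m, cal)
  }, numeric(1))
  expect_equal(est[["dsDNA_bp"]] / truth, 1.47, tolerance = 1e-6)
  expect_equal(est[["RNA_bases"]] / truth, 1.10, tolerance = 1e-6)
  expect_equal(est[["ssDNA_plasmid_bases"]] / truth, 1.19, tolerance = 1e-6)
})

test_that("additive drift cancels in difference methods only", {
  cfg <- simConfig(driftSd = 0)
  truth <- 4658
  set.seed(43)
  m <- simulateIntactAAVSample(truth, 0.5, 600, cfg, seed = 43)
  off <- 0.003  # keeps both populations inside the intact band
  m2 <- ContrastMeasurement(measurementId(m), events(m) + off)

  prot <- lineCurve(-cfg@alphaCapsid, 0, "protein_mass", c(272, 545, 3700))
  expect_equal(sizeApproach1(m, prot), sizeApproach1(m2, prot),
               tolerance = 1e-6)

  dl <- lineCurve(-cfg@alphaCapsid * cfg@perBaseMass, 0, "aav_delta_bases",
                  referenceLabel = "aav_empty")
  expect_equal(sizeApproach2Delta(m, dl, "aav_empty"),
               sizeApproach2Delta(m2, dl, "aav_empty"), tolerance = 1e-6)

  ab <- lineCurve(-cfg@alphaCapsid * cfg@perBaseMass,
                  -cfg@alphaCapsid * cfg@emptyCapsidMass, "aav_abs_bases")
  shift <- sizeApproach2Abs(m2, ab) - sizeApproach2Abs(m, ab)
  expect_equal(shift, off / slope(ab), tolerance = 1e-4)
})

test_that("longer genomes give larger estimates under every approach", {
  cfg <- noiselessConfig()
  prot <- buildLinearCalibration(
    pointsFromSet(simulateCalibrantSet("protein_mass", cfg, seed = 44)),
    "protein_mass")
  plas <- buildLinearCalibration(
    pointsFromSet(simulateCalibrantSet("ssDNA_plasmid_bases", cfg,
                                       seed = 44)),
    "ssDNA_plasmid_bases")
  dl <- lineCurve(-cfg@alphaCapsid * cfg@perBaseMass, 0, "aav_delta_bases",
                  referenceLabel = "aav_empty")
  ab <- lineCurve(-cfg@alphaCapsid * cfg@perBaseMass,
                  -cfg@alphaCapsid * cfg@emptyCapsidMass, "aav_abs_bases")
  for (pair in list(c(4000, 4600), c(3793, 4658))) {
    mA <- simulateIntactAAVSample(pair[1], 0.5, 600, cfg, seed = 45)
    mB <- simulateIntactAAVSample(pair[2], 0.5, 600, cfg, seed = 46)
    expect_lt(sizeApproach1(mA, prot), sizeApproach1(mB, prot))
    expect_lt(sizeApproach2Delta(mA, dl), sizeApproach2Delta(mB, dl))
    expect_lt(sizeApproach2Abs(mA, ab), sizeApproach2Abs(mB, ab))
    rA <- simulateGenomeRelease(pair[1], "sds", cfg, seed = 47)
    rB <- simulateGenomeRelease(pair[2], "sds", cfg, seed = 48)
    expect_lt(sizeApproach3(rA, plas), sizeApproach3(rB, plas))
  }
})

test_that("sizing guards: missing peaks, reference mismatch, intact AAVs", {
  cfg <- noiselessConfig()
  prot <- lineCurve(-cfg@alphaCapsid, 0, "protein_mass", c(272, 545, 3700))
  onlyFilled <- simulateIntactAAVSample(4658, 0, 300, cfg, seed = 51)
  expect_error(sizeApproach1(onlyFilled, prot), "spike")
  onlyEmpty <- simulateIntactAAVSample(4658, 1, 300, cfg, seed = 52)
  expect_error(sizeApproach1(onlyEmpty, prot, singleAAVLabel = "aav_empty"),
               "filled")

  dl <- lineCurve(-8.8e-6, 0, "aav_delta_bases",
                  referenceLabel = "aav_empty")
  m <- simulateIntactAAVSample(4658, 0.5, 600, cfg, seed = 53)
  expect_error(sizeApproach2Delta(m, dl, "hmw_standard"), "mismatch")
  expect_error(sizeApproach2Delta(m, prot), "aav_delta_bases")
  expect_error(sizeApproach2Abs(m, dl), "aav_abs_bases")

  plas <- buildLinearCalibration(
    pointsFromSet(simulateCalibrantSet("ssDNA_plasmid_bases", cfg,
                                       seed = 54)),
    "ssDNA_plasmid_bases")
  # an intact-AAV peak in a release measurement refuses sizing
  set.seed(55)
  undigested <- ContrastMeasurement("u", c(rnorm(300, -0.041, 0.002),
                                           rnorm(300, -0.15, 0.002)))
  expect_error(sizeApproach3(undigested, plas, slopeHint = 8.8e-6),
               "incomplete disassembly")
  # fragments only: no released peak
  set.seed(56)
  fragOnly <- ContrastMeasurement("f", -runif(300, 0.001, 0.029))
  expect_error(sizeApproach3(fragOnly, plas, slopeHint = 8.8e-6),
               "no released-genome peak")
  expect_error(sizeApproach3(m, prot), "RNA_bases")
})

test_that("HMW-standard and empty-AAV references agree on noiseless data", {
  cfg <- noiselessConfig()
  truth <- 4658
  # sample spiked with the HMW standard instead of empty capsids
  mHmw <- simulateIntactAAVSample(truth, 0, 600, cfg, seed = 57,
                                  hmwSpikeFraction = 0.5)
  # delta line vs the HMW reference: contrast difference at genome L is
  # -alpha*(perBase*L + (emptyMass - hmwMass))
  dHmw <- function(L) -cfg@alphaCapsid *
    (cfg@perBaseMass * L + cfg@emptyCapsidMass - cfg@hmwMass)
  calH <- buildLinearCalibration(
    data.frame(name = c("a", "b"), contrast = dHmw(c(3793, 4596)),
               response = c(3793, 4596)),
    "aav_delta_bases", referenceLabel = "hmw_standard")
  expect_equal(sizeApproach2Delta(mHmw, calH, "hmw_standard"), truth,
               tolerance = 1e-6)

  mEmpty <- simulateIntactAAVSample(truth, 0.5, 600, cfg, seed = 58)
  dEmp <- function(L) -cfg@alphaCapsid * cfg@perBaseMass * L
  calE <- buildLinearCalibration(
    data.frame(name = c("a", "b"), contrast = dEmp(c(3793, 4596)),
               response = c(3793, 4596)),
    "aav_delta_bases", referenceLabel = "aav_empty")
  expect_equal(sizeApproach2Delta(mEmpty, calE, "aav_empty"),
               sizeApproach2Delta(mHmw, calH, "hmw_standard"),
               tolerance = 1e-6)
})

test_that("study aggregation reproduces the day-mean statistics", {
  pm <- data.frame(measurementId = paste0("m", 1:3),
                   dayId = paste0("day", 1:3),
                   bases = c(3900, 3991, 4082))
  est <- aggregateStudy(pm, expected = 3793, sampleId = "aav2")
  expect_equal(est@meanBases, 3991)
  expect_equal(est@sdBases, 91)
  expect_equal(est@cvPercent, 100 * 91 / 3991)
  expect_equal(est@accuracyPercent, 100 * 3991 / 3793)
  f <- formatEstimate(est)
  expect_identical(f$accuracy_percent, 105)
  expect_identical(f$cv_percent, 2.3)

  # oracle equality: direct recomputation from the per-measurement list
  pm2 <- data.frame(measurementId = paste0("m", 1:6),
                    dayId = rep(c("d1", "d2"), each = 3),
                    bases = c(4000, 4100, 4050, 3950, 4000, 4020))
  est2 <- aggregateStudy(pm2)
  dm <- tapply(pm2$bases, pm2$dayId, mean)
  expect_equal(unname(est2@perDayMean), as.numeric(dm[c("d1", "d2")]))
  expect_equal(est2@meanBases, mean(dm))
  expect_equal(est2@sdBases, sd(dm))
  expect_true(is.na(est2@accuracyPercent))

  # identical day means: zero SD, accuracy 100%
  pm3 <- data.frame(measurementId = paste0("m", 1:3),
                    dayId = paste0("d", 1:3), bases = rep(4000, 3))
  est3 <- aggregateStudy(pm3, expected = 4000)
  expect_equal(est3@sdBases, 0)
  expect_equal(est3@cvPercent, 0)
  expect_equal(est3@accuracyPercent, 100)

  # a single day reports SD/%CV as not applicable, never zero
  one <- aggregateStudy(data.frame(measurementId = c("m1", "m2"),
                                   dayId = "d1", bases = c(4000, 4100)))
  expect_true(is.na(one@sdBases) && is.na(one@cvPercent))
})

test_that("the resolution limit scales as k * sigma / |slope in bases|", {
  dl <- lineCurve(-8.8e-6, 0, "aav_delta_bases")
  expect_equal(estimateResolutionLimit(0.0015, dl), 401.4,
               tolerance = 1e-3)
  expect_equal(estimateResolutionLimit(0, dl), 0)
  expect_equal(estimateResolutionLimit(0.003, dl),
               2 * estimateResolutionLimit(0.0015, dl))
  # unit chains: protein slope is per kDa, dsDNA per bp
  prot <- lineCurve(-8.8e-6 / 0.309, 0, "protein_mass", c(272, 545, 3700))
  expect_equal(estimateResolutionLimit(0.0015, prot),
               estimateResolutionLimit(0.0015, dl), tolerance = 1e-9)
  ds <- lineCurve(-2 * 8.8e-6, 0, "dsDNA_bp", c(100, 800, 2000))
  expect_equal(estimateResolutionLimit(0.0015, ds),
               estimateResolutionLimit(0.0015, dl), tolerance = 1e-9)
})

test_that("the decision tree picks approaches in the documented priority", {
  expect_identical(recommendApproach(hasAavCalibrationSet = TRUE,
                                     hasEmptyReference = TRUE)$approach,
                   "a2_delta")
  expect_identical(recommendApproach(hasAavCalibrationSet = TRUE,
                                     hasHmwStandard = TRUE)$approach,
                   "a2_delta")
  expect_identical(recommendApproach(hasAavCalibrationSet = TRUE)$approach,
                   "a2_abs")
  expect_identical(recommendApproach(hasEmptyReference = TRUE,
                                     hasProteinCalibrants = TRUE)$approach,
                   "a1")
  expect_identical(recommendApproach(hasSsNucleicCalibrants = TRUE,
                                     canReleaseGenome = TRUE)$approach,
                   "a3")
  expect_error(recommendApproach(), "no sizing route")
})
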