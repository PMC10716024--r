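test_that("declared bandwidths convert to contrast units via the slope hint", {
  m <- ContrastMeasurement("m", rep(-0.05, 500))
  d <- smoothEvents(m, 40, "kDa", slopeHint = 3e-5)
  expect_equal(d@bandwidthContrast, 1.2e-3)
  expect_identical(d@bandwidthDeclared, list(value = 40, unit = "kDa"))
  expect_error(smoothEvents(m, 40, "kDa"), "slopeHint")
  expect_error(smoothEvents(m, -1, "contrast"), "positive")
  expect_error(smoothEvents(ContrastMeasurement("e", numeric(0),
                                                allowEmpty = TRUE),
                            0.001, "contrast"), "empty")
})

test_that("density of identical events peaks exactly at the event value", {
  m <- ContrastMeasurement("m", rep(-0.05, 500))
  d <- smoothEvents(m, 0.001, "contrast")
  step <- mean(diff(d@grid))
  expect_lt(abs(d@grid[which.max(d@density)] - (-0.05)), step)
})

test_that("two well-separated populations give two windows at their means", {
  set.seed(42)
  ev <- c(rnorm(300, -0.041, 0.002), rnorm(300, -0.146, 0.004))
  m <- ContrastMeasurement("m", ev)
  d <- smoothEvents(m, 0.0015, "contrast")
  wins <- detectPeaks(d)
  expect_length(wins, 2L)
  # sorted by |contrast| ascending; each window contains its true mean
  expect_true(wins[[1]]$lo < -0.041 && -0.041 < wins[[1]]$hi)
  expect_true(wins[[2]]$lo < -0.146 && -0.146 < wins[[2]]$hi)
  # modes land near the population means (sample-mode accuracy ~ sigma/sqrt(n))
  expect_lt(abs(wins[[1]]$mode - (-0.041)), 5 * 0.002 / sqrt(300))
  expect_lt(abs(wins[[2]]$mode - (-0.146)), 5 * 0.004 / sqrt(300))
})

test_that("monotone densities and sub-resolution mixtures give no split", {
  d <- new("SmoothedDistribution", grid = seq(0, 1, length.out = 256),
           density = exp(seq(0, 1, length.out = 256)),
           bandwidthContrast = 0.01,
           bandwidthDeclared = list(value = 0.01, unit = "contrast"),
           slopeUsed = NA_real_, nEvents = 1000L)
  expect_length(detectPeaks(d, minEvents = 0), 0L)

  # two Gaussians 0.5 sigma apart are unimodal: one window
  set.seed(7)
  sigma <- 0.002
  ev <- c(rnorm(2000, -0.050, sigma), rnorm(2000, -0.050 - 0.5 * sigma, sigma))
  m <- ContrastMeasurement("m", ev)
  wins <- detectPeaks(smoothEvents(m, 0.001, "contrast"))
  expect_length(wins, 1L)
})

test_that("windowed Gaussian fit recovers seeded population parameters", {
  set.seed(11)
  mu <- -0.041
  sigma <- 0.002
  ev <- rnorm(300, mu, sigma)
  m <- ContrastMeasurement("m", ev)
  d <- smoothEvents(m, 0.0015, "contrast")
  wins <- detectPeaks(d)
  expect_length(wins, 1L)
  fit <- fitGaussianPeak(m, wins[[1]], d)
  expect_lt(abs(peakContrast(fit) - mu), 4 * sigma / sqrt(300))
  expect_gt(peakWidth(fit), sigma / 2)
  expect_lt(peakWidth(fit), sigma * 2)
  expect_false(fit@lowConfidence)
  # mu sits strictly inside the final window
  expect_true(fit@window[1] < peakContrast(fit) &&
                peakContrast(fit) < fit@window[2])
})

test_that("fits are shift-equivariant: mu moves by the offset, sigma fixed", {
  set.seed(12)
  ev <- rnorm(400, -0.105, 0.002)
  off <- 0.01
  m1 <- ContrastMeasurement("a", ev)
  m2 <- ContrastMeasurement("b", ev + off)
  fit1 <- fitMeasurementPeaks(m1, 0.0012, "contrast",
                              singleAAVLabel = "unlabeled")[[1]]
  fit2 <- fitMeasurementPeaks(m2, 0.0012, "contrast",
                              singleAAVLabel = "unlabeled")[[1]]
  expect_equal(peakContrast(fit2) - peakContrast(fit1), off,
               tolerance = 1e-6)
  expect_equal(peakWidth(fit2), peakWidth(fit1), tolerance = 1e-6)
})

test_that("degenerate and sparse windows are flagged, not fatal", {
  m <- ContrastMeasurement("m", rep(-0.041, 300))
  d <- smoothEvents(m, 0.001, "contrast")
  fit <- fitGaussianPeak(m, c(-0.05, -0.03), d)
  expect_true(fit@degenerate)
  expect_equal(peakContrast(fit), -0.041)
  expect_identical(eventCount(fit), 300L)

  set.seed(13)
  sparse <- ContrastMeasurement("s", rnorm(30, -0.05, 0.002))
  ds <- smoothEvents(sparse, 0.002, "contrast")
  fit2 <- fitGaussianPeak(sparse, range(events(sparse)), ds)
  expect_true(fit2@lowConfidence)
})

test_that("event counts over disjoint windows never exceed the total", {
  set.seed(14)
  ev <- c(rnorm(300, -0.041, 0.002), rnorm(300, -0.146, 0.004))
  m <- ContrastMeasurement("m", ev)
  d <- smoothEvents(m, 0.0015, "contrast")
  wins <- detectPeaks(d)
  n <- vapply(wins, function(w) sum(ev >= w$lo & ev <= w$hi), integer(1))
  expect_lte(sum(n), length(ev))
})

test_that("peaks classify into the expected contrast regions", {
  mkpeak <- function(mu) new("PeakFit", mu = mu, sigma = 0.002,
                             nEvents = 300L,
                             window = c(mu - 0.01, mu + 0.01))
  lab <- function(mu, ...) peakLabel(classifyPeaks(list(mkpeak(mu)),
                                                   ...)[[1]])
  expect_identical(lab(-0.15), "aav_filled")  # lone capsid peak, default
  expect_identical(lab(-0.15, singleAAVLabel = "aav_empty"), "aav_empty")
  expect_identical(lab(-0.041), "released_genome")
  expect_identical(lab(-0.02), "fragment")
  expect_identical(lab(-0.6), "aggregate")
  expect_identical(lab(-0.085), "unlabeled")  # gap between bands

  # two capsid-band peaks: smaller magnitude is the empty capsid
  two <- classifyPeaks(list(mkpeak(-0.105), mkpeak(-0.146)))
  expect_identical(vapply(two, peakLabel, character(1)),
                   c("aav_empty", "aav_filled"))

  # three capsid-band peaks are ambiguous
  expect_error(classifyPeaks(list(mkpeak(-0.105), mkpeak(-0.13),
                                  mkpeak(-0.15))), "ambiguous")

  # region bounds are magnitudes
  bad <- regionDefaults()
  bad$fragment_max <- -0.030
  expect_error(classifyPeaks(list(mkpeak(-0.02)), regions = bad),
               "magnitudes")
})

test_that("seeded mixtures with >= 4 sigma separation are fully recovered", {
  set.seed(15)
  pops <- list(c(-0.105, 0.002, 300), c(-0.146, 0.002, 300))
  ev <- unlist(lapply(pops, function(p) rnorm(p[3], p[1], p[2])))
  m <- ContrastMeasurement("m", ev)
  peaks <- fitMeasurementPeaks(m, 0.0012, "contrast")
  expect_length(peaks, 2L)
  mus <- sort(vapply(peaks, peakContrast, numeric(1)))
  for (i in 1:2)
    expect_lt(abs(mus[i] - sort(c(-0.146, -0.105))[i]),
              4 * 0.002 / sqrt(300))
})
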