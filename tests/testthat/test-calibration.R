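test_that("collinear calibrant points are fitted exactly", {
  masses <- c(272, 545, 670, 3700)
  pts <- data.frame(name = paste0("p", 1:4), contrast = -3e-5 * masses,
                    response = masses)
  cal <- buildLinearCalibration(pts, "protein_mass")
  expect_equal(slope(cal), -3e-5, tolerance = 1e-12)
  expect_equal(intercept(cal), 0, tolerance = 1e-12)
  expect_equal(rSquared(cal), 1)
  expect_identical(cal@responseUnit, "kDa")
})

test_that("OLS matches the closed-form normal-equation solution", {
  set.seed(21)
  for (rep in 1:5) {
    x <- sort(runif(3 + rep, 100, 5000))
    y <- -2e-5 * x - 0.001 + rnorm(length(x), 0, 1e-4)
    cal <- buildLinearCalibration(
      data.frame(contrast = y, response = x), "RNA_bases")
    X <- cbind(1, x)
    beta <- solve(t(X) %*% X, t(X) %*% y)  # independent oracle
    expect_lt(abs(intercept(cal) - beta[1]), 1e-12)
    expect_lt(abs(slope(cal) - beta[2]), 1e-12)
  }
})

test_that("family minimum point counts and duplicate responses are policed", {
  two <- data.frame(contrast = c(-0.01, -0.02), response = c(1000, 2000))
  expect_error(buildLinearCalibration(two, "RNA_bases"), "at least 3")
  expect_s4_class(buildLinearCalibration(two, "aav_delta_bases"),
                  "CalibrationCurve")
  dup <- data.frame(contrast = c(-0.01, -0.021, -0.02),
                    response = c(1000, 2000, 2000))
  expect_warning(buildLinearCalibration(dup, "aav_delta_bases"),
                 "duplicate")
})

test_that("the ssDNA plasmid family includes the zero point as a datum", {
  pts <- data.frame(name = c("phiX174", "m13mp18"),
                    contrast = c(-0.0474, -0.0638),
                    response = c(5386, 7249))
  cal <- buildLinearCalibration(pts, "ssDNA_plasmid_bases")
  expect_equal(nrow(calibrationPoints(cal)), 3L)
  expect_true(any(calibrationPoints(cal)$response == 0))
  # the zero point is a datum, not a constraint: intercept is estimated
  fit <- lm(contrast ~ response, data = calibrationPoints(cal))
  expect_equal(intercept(cal), unname(coef(fit)[1]))
})

test_that("prediction inverts the line analytically", {
  cal <- lineCurve(-3e-5, 0, "aav_abs_bases", c(3000, 5000))
  expect_equal(predictResponse(cal, -0.111), 3700, tolerance = 1e-9)
  expect_equal(predictResponse(cal, cal@intercept), 0)
  set.seed(22)
  for (rep in 1:10) {
    sl <- -runif(1, 1e-6, 1e-4)
    ic <- runif(1, -0.01, 0.01)
    cv <- lineCurve(sl, ic, "aav_abs_bases", c(2000, 6000))
    x <- runif(1, 0, 8000)
    expect_lt(abs(predictResponse(cv, sl * x + ic) - x), 1e-9 * max(1, x))
  }
  expect_warning(predictResponse(cal, 0.01), "negative")
})

test_that("unit conversion chains use the exact constants", {
  expect_equal(convertMassDiffToBases(309), 1000)
  expect_equal(convertMassDiffToBases(0), 0)
  expect_equal(convertMassDiffToBases(1172.037), 3793, tolerance = 1e-12)
  expect_equal(convertMassDiffToBases(-309), -1000)  # sign preserved
  expect_equal(convertBpToBases(0), 0)
  expect_equal(convertBpToBases(100), 200)
  expect_equal(convertBpToBases(2329), 4658)
})

test_that("delta-contrast conversion dispatches per family", {
  prot <- lineCurve(-3e-5, -0.002, "protein_mass", c(272, 545, 3700))
  # -0.0309 contrast -> 1030 kDa -> 1030 * 1000/309 bases
  expect_equal(deltaContrastToBases(prot, -0.0309), 1030 * 1000 / 309,
               tolerance = 1e-12)
  expect_equal(deltaContrastToBases(prot, 0), 0)  # intercept cancels
  ds <- lineCurve(-2e-5, -0.004, "dsDNA_bp", c(100, 800, 2000))
  expect_equal(deltaContrastToBases(ds, -0.04), 4000, tolerance = 1e-12)
  rna <- lineCurve(-8.8e-6, 0.001, "RNA_bases", c(200, 2000, 6000))
  expect_equal(deltaContrastToBases(rna, -8.8e-6 * 1234), 1234,
               tolerance = 1e-9)
  # the AAV delta family applies its own intercept
  dl <- lineCurve(-8.8e-6, -0.0005, "aav_delta_bases")
  expect_equal(deltaContrastToBases(dl, -8.8e-6 * 4000 - 0.0005), 4000,
               tolerance = 1e-9)
  abs_cal <- lineCurve(-8.8e-6, -0.105, "aav_abs_bases")
  expect_error(deltaContrastToBases(abs_cal, -0.04), "absolute")
})

test_that("leverage follows the hat-matrix closed form", {
  # the AAV absolute-contrast calibration with the 0-base empty point:
  # that point dominates the design
  resp <- c(0, 3793, 4142, 4504, 4596, 4658)
  cal <- lineCurve(-1e-5, -0.105, "aav_abs_bases", resp)
  h <- pointLeverage(cal)
  expect_equal(sum(h), 2, tolerance = 1e-12)
  expect_true(all(h >= 1 / 6 - 1e-12 & h <= 1 + 1e-12))
  expect_identical(unname(which.max(h)), 1L)
  expect_equal(unname(h[1]), 0.973, tolerance = 1e-3)
  # independent oracle: stats::hatvalues on the same regression
  oracle <- unname(hatvalues(lm(contrast ~ response,
                                data = calibrationPoints(cal))))
  expect_equal(unname(h), oracle, tolerance = 1e-12)

  # saturated two-point fit: both leverages are 1
  h2 <- pointLeverage(lineCurve(-1e-5, 0, "aav_delta_bases", c(1000, 2000)))
  expect_equal(unname(h2), c(1, 1))

  # symmetric three-point design {-a, 0, a}
  h3 <- pointLeverage(lineCurve(-1e-5, -0.05, "aav_delta_bases",
                                c(-500, 0, 500)))
  expect_equal(unname(h3), c(5 / 6, 1 / 3, 5 / 6), tolerance = 1e-12)

  degen <- lineCurve(-1e-5, 0, "aav_delta_bases", c(1000, 2000))
  degen@points$response <- rep(1500, 2)
  expect_error(pointLeverage(degen), "at least 3|degenerate")
})

test_that("excluding a high-leverage empty point flattens the slope", {
  # filled AAVs on a shallow line; the empty capsid's measured contrast
  # lies above the line's extrapolation to 0 bases, so including it
  # steepens the fit (the published-slope-change phenomenology)
  L <- c(3793, 4142, 4504, 4596, 4658)
  filled <- data.frame(name = paste0("aav", 2:6),
                       contrast = -0.1201 - 6.198e-6 * L, response = L)
  empty <- data.frame(name = "aav1", contrast = -0.1034, response = 0)
  with_e <- buildLinearCalibration(rbind(empty, filled), "aav_abs_bases",
                                   includeEmpty = TRUE)
  without <- buildLinearCalibration(filled, "aav_abs_bases")
  expect_gt(abs(slope(with_e)), abs(slope(without)))
  expect_equal(slope(without), -6.198e-6, tolerance = 1e-9)
  # the empty point's residual under the filled-only fit is nonzero,
  # so the slopes must differ
  resid_empty <- empty$contrast -
    (intercept(without) + slope(without) * 0)
  expect_gt(abs(resid_empty), 0)
  expect_false(isTRUE(all.equal(slope(with_e), slope(without))))
})

test_that("calibration JSON round trips bit-exactly", {
  cal <- buildLinearCalibration(
    data.frame(name = c("a", "b", "c"),
               contrast = c(-0.0101, -0.0303, -0.0505) + pi * 1e-9,
               response = c(1010, 3030, 5050)),
    "RNA_bases")
  f <- withr::local_tempfile(fileext = ".json")
  writeCalibration(cal, f)
  back <- readCalibration(f)
  expect_identical(slope(back), slope(cal))
  expect_identical(intercept(back), intercept(cal))
  expect_identical(calibrationPoints(back)$contrast,
                   calibrationPoints(cal)$contrast)
  expect_identical(calibrationFamily(back), calibrationFamily(cal))
})

test_that("the mass-per-base factor follows from nucleotide chemistry", {
  expect_equal(dnaResidueMassPer1000Bases(), 309, tolerance = 0.001)
})
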