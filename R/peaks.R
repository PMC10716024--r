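## Smoothing of event lists, peak detection, windowed Gaussian fitting and
## population classification.
##
## The instrument software exposes a "histogram bandwidth" in calibrated
## units (40 kDa / 120 bases or bp for intact capsids, 50 bases for a
## released genome). Here smoothing is a Gaussian kernel density estimate
## and the declared bandwidth is the kernel SD, converted into contrast
## units through a contrast-per-unit slope hint: on a first pass a
## provisional hint, after a calibration exists the fitted |slope|
## (see slopeHintFromCalibration()).

#' Default contrast region bounds for peak classification
#'
#' Magnitude bounds, in contrast units, for the populations seen in AAV
#' genome-sizing measurements: fragments below 0.030, a released genome in
#' 0.030--0.07, intact capsids (empty or filled) in 0.10--0.20 and large
#' aggregates above 0.5.
#'
#' @return A named list `fragment_max`, `released`, `aav`, `aggregate_min`.
#' @export
regionDefaults <- function() {
  list(fragment_max = 0.030, released = c(0.030, 0.07),
       aav = c(0.10, 0.20), aggregate_min = 0.5)
}

.checkRegions <- function(regions) {
  stopifnot(is.list(regions),
            all(c("fragment_max", "released", "aav", "aggregate_min") %in%
                names(regions)))
  if (any(unlist(regions) < 0))
    stop("region bounds are magnitudes and must be >= 0")
  if (regions$released[1] > regions$released[2] ||
      regions$aav[1] > regions$aav[2])
    stop("region bounds must be ordered")
  if (regions$released[2] > regions$aav[1])
    stop("released and aav regions must not overlap")
  invisible(regions)
}

#' Smooth an event list into a density on a contrast grid
#'
#' Gaussian kernel density estimate of the landing-event contrasts on a
#' regular 2048-point grid spanning `[min(events) - 3 bw, max(events) + 3 bw]`.
#'
#' @param m a nonempty [ContrastMeasurement-class].
#' @param bandwidth kernel bandwidth (SD), in `bandwidthUnit`.
#' @param bandwidthUnit `"contrast"` (use directly) or one of `"kDa"`,
#'   `"bases"`, `"bp"` (converted via `slopeHint`).
#' @param slopeHint |contrast per unit| used to convert a calibrated
#'   bandwidth into contrast units; required unless `bandwidthUnit` is
#'   `"contrast"`.
#' @param gridPoints number of grid points (default 2048).
#' @return A [SmoothedDistribution-class].
#' @examples
#' m <- ContrastMeasurement("m1", rnorm(300, -0.105, 0.002))
#' d <- smoothEvents(m, 40, "kDa", slopeHint = 3e-5)
#' d@bandwidthContrast  # 1.2e-3
#' @export
smoothEvents <- function(m, bandwidth, bandwidthUnit = c("contrast", "kDa",
                                                         "bases", "bp"),
                         slopeHint = NULL, gridPoints = 2048L) {
  bandwidthUnit <- match.arg(bandwidthUnit)
  if (length(m@events) == 0L) stop("cannot smooth an empty measurement")
  if (!is.finite(bandwidth) || bandwidth <= 0)
    stop("bandwidth must be a positive number")
  if (bandwidthUnit == "contrast") {
    bw <- bandwidth
    slopeUsed <- NA_real_
  } else {
    if (is.null(slopeHint) || !is.finite(slopeHint) || slopeHint <= 0)
      stop("a positive slopeHint (|contrast per ", bandwidthUnit,
           "|) is required for a calibrated bandwidth")
    slopeUsed <- abs(slopeHint)
    bw <- bandwidth * slopeUsed
  }
  ev <- m@events
  lo <- min(ev) - 3 * bw
  hi <- max(ev) + 3 * bw
  ## the grid must resolve the kernel: at least 4 points per bandwidth
  ## (wide event ranges, e.g. with aggregate events, would otherwise
  ## undersample a narrow peak)
  n <- min(max(gridPoints, ceiling((hi - lo) / bw * 4)), 32768L)
  d <- stats::density(ev, bw = bw, kernel = "gaussian", n = n,
                      from = lo, to = hi)
  new("SmoothedDistribution", grid = d$x, density = pmax(d$y, 0),
      bandwidthContrast = bw,
      bandwidthDeclared = list(value = bandwidth, unit = bandwidthUnit),
      slopeUsed = slopeUsed, nEvents = length(ev))
}

## Prominence of interior local maxima: on each side take the minimum of y
## between the peak and the nearest higher point (or the boundary if none);
## prominence = height minus the higher of the two side minima. For the
## global maximum of a density both sides run into the tails, so its
## prominence is close to its full height.
.peakProminence <- function(y, peaks) {
  n <- length(y)
  vapply(peaks, function(p) {
    h <- y[p]
    side_min <- function(idx) if (length(idx)) min(y[idx]) else h
    left <- which(y[seq_len(p - 1L)] > h)
    lmin <- if (length(left)) side_min(seq(max(left) + 1L, p - 1L))
            else side_min(seq_len(p - 1L))
    right <- which(y[seq(p + 1L, n)] > h) + p
    rmin <- if (length(right)) side_min(seq(p + 1L, min(right) - 1L))
            else side_min(seq(p + 1L, n))
    h - max(lmin, rmin)
  }, numeric(1))
}

.localMaxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

#' Detect candidate peak windows in a smoothed distribution
#'
#' Interior local maxima of the density with prominence at least
#' `minProminenceFrac` times the maximum density are kept and expanded to
#' windows of +/- 2 kernel bandwidths; windows of adjacent candidates are
#' truncated at the density minimum between them. Candidates whose window
#' holds fewer than `minEvents` expected events (density mass times the
#' event count) are dropped.
#'
#' @param dist a [SmoothedDistribution-class].
#' @param minEvents minimum expected events per window (default 50).
#' @param minProminenceFrac prominence threshold as a fraction of the
#'   maximum density (default 0.10).
#' @return A list of candidate windows, each a list with `lo`, `hi` and
#'   `mode` (grid contrast of the maximum), sorted by |mode| ascending.
#'   May be empty.
#' @export
detectPeaks <- function(dist, minEvents = 50L, minProminenceFrac = 0.10) {
  y <- dist@density
  x <- dist@grid
  peaks <- .localMaxima(y)
  if (!length(peaks)) return(list())
  prom <- .peakProminence(y, peaks)
  keep <- peaks[prom >= minProminenceFrac * max(y)]
  if (!length(keep)) return(list())
  keep <- sort(keep)
  bw <- dist@bandwidthContrast
  wins <- lapply(seq_along(keep), function(i) {
    p <- keep[i]
    lo <- x[p] - 2 * bw
    hi <- x[p] + 2 * bw
    if (i > 1L) {
      between <- seq(keep[i - 1L], p)
      valley <- x[between[which.min(y[between])]]
      lo <- max(lo, valley)
    }
    if (i < length(keep)) {
      between <- seq(p, keep[i + 1L])
      valley <- x[between[which.min(y[between])]]
      hi <- min(hi, valley)
    }
    list(lo = lo, hi = hi, mode = x[p])
  })
  ## drop windows with too little expected event mass
  dx <- mean(diff(x))
  expEvents <- vapply(wins, function(w) {
    idx <- x >= w$lo & x <= w$hi
    sum(y[idx]) * dx * dist@nEvents
  }, numeric(1))
  wins <- wins[expEvents >= minEvents]
  wins[order(vapply(wins, function(w) abs(w$mode), numeric(1)))]
}

.gaussianLSFit <- function(x, y, A0, mu0, s0) {
  df <- data.frame(x = x, y = y)
  fit <- try(minpack.lm::nlsLM(
    y ~ A * exp(-(x - mu)^2 / (2 * s^2)), data = df,
    start = list(A = A0, mu = mu0, s = s0),
    lower = c(A = 0, mu = min(x), s = 1e-8),
    upper = c(A = Inf, mu = max(x), s = diff(range(x)) * 4 + 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  cf <- stats::coef(fit)
  list(A = cf[["A"]], mu = cf[["mu"]], s = cf[["s"]],
       rms = sqrt(mean(stats::resid(fit)^2)))
}

#' Fit a single Gaussian to the events in a contrast window
#'
#' Least-squares fit of `A exp(-(c - mu)^2 / 2 sigma^2)` to the smoothed
#' density restricted to the window, initialized at the windowed density
#' mode and the sample SD of the windowed events, followed by one refit
#' pass on a window recentered to `mu +/- max(2.5 sigma, 2 bandwidths)`.
#' Events with zero spread short-circuit to a degenerate fit (sigma floored
#' at 1e-6). Fewer than `minEvents` events flags the fit low-confidence
#' rather than failing.
#'
#' @param m the [ContrastMeasurement-class] the window refers to.
#' @param window numeric(2) `(lo, hi)` in contrast units, or a window list
#'   from [detectPeaks()].
#' @param dist the [SmoothedDistribution-class] of `m` (as produced by
#'   [smoothEvents()]); refitting reuses its grid and bandwidth.
#' @param minEvents low-confidence threshold on raw events in the window
#'   (default 50).
#' @return A [PeakFit-class].
#' @export
fitGaussianPeak <- function(m, window, dist, minEvents = 50L) {
  if (is.list(window)) window <- c(window$lo, window$hi)
  stopifnot(length(window) == 2L, window[1] < window[2])
  inWin <- function(w) m@events >= w[1] & m@events <= w[2]
  ev <- m@events[inWin(window)]
  lowConf <- length(ev) < minEvents
  if (length(ev) == 0L)
    stop(sprintf("no events in window [%.4g, %.4g]", window[1], window[2]))
  bw <- dist@bandwidthContrast
  if (stats::sd(ev) < 1e-12 || length(ev) == 1L) {
    v <- ev[1]
    return(new("PeakFit", mu = v, sigma = 1e-6, nEvents = length(ev),
               window = c(v - 2 * bw, v + 2 * bw), rmsResidual = 0,
               lowConfidence = lowConf, degenerate = TRUE))
  }
  fitPass <- function(w) {
    idx <- dist@grid >= w[1] & dist@grid <= w[2]
    if (sum(idx) < 5L)
      stop(sprintf("window [%.4g, %.4g] covers too few grid points",
                   w[1], w[2]))
    x <- dist@grid[idx]
    y <- dist@density[idx]
    evw <- m@events[inWin(w)]
    s0 <- max(stats::sd(evw), bw / 2, 1e-8)
    mu0 <- x[which.max(y)]
    .gaussianLSFit(x, y, A0 = max(y), mu0 = mu0, s0 = s0)
  }
  f1 <- fitPass(window)
  if (is.null(f1))
    stop(sprintf("Gaussian fit failed to converge in window [%.4g, %.4g]",
                 window[1], window[2]))
  half <- max(2.5 * f1$s, 2 * bw)
  window2 <- c(f1$mu - half, f1$mu + half)
  f2 <- fitPass(window2)
  if (is.null(f2))
    stop(sprintf("Gaussian refit failed to converge in window [%.4g, %.4g]",
                 window2[1], window2[2]))
  nEv <- sum(inWin(window2))
  new("PeakFit", mu = f2$mu, sigma = f2$s, nEvents = nEv, window = window2,
      rmsResidual = f2$rms, lowConfidence = nEv < minEvents,
      degenerate = FALSE)
}

#' Classify fitted peaks into AAV-analysis populations
#'
#' Labels each peak by the magnitude of its fitted contrast: `fragment`
#' below `fragment_max`, `released_genome` inside the released band,
#' `aav_empty` / `aav_filled` inside the intact-capsid band, `aggregate`
#' above `aggregate_min`, otherwise `unlabeled`. When two peaks fall in
#' the capsid band, the smaller-|contrast| one is the empty capsid; a
#' single capsid-band peak gets `singleAAVLabel` (the sample sheet decides
#' empty vs filled in that case). Three or more capsid-band peaks raise an
#' ambiguity error listing the candidates.
#'
#' @param peaks list of [PeakFit-class] objects.
#' @param regions region bounds, see [regionDefaults()].
#' @param singleAAVLabel label for a lone capsid-band peak (default
#'   `"aav_filled"`).
#' @return The peaks, relabeled, in the input order.
#' @export
classifyPeaks <- function(peaks, regions = regionDefaults(),
                          singleAAVLabel = c("aav_filled", "aav_empty",
                                             "unlabeled")) {
  singleAAVLabel <- match.arg(singleAAVLabel)
  .checkRegions(regions)
  if (methods::is(peaks, "PeakFit")) peaks <- list(peaks)
  mus <- abs(vapply(peaks, function(p) p@mu, numeric(1)))
  lab <- rep("unlabeled", length(peaks))
  lab[mus < regions$fragment_max] <- "fragment"
  lab[mus >= regions$released[1] & mus <= regions$released[2]] <-
    "released_genome"
  inAAV <- which(mus >= regions$aav[1] & mus <= regions$aav[2])
  lab[mus > regions$aggregate_min] <- "aggregate"
  if (length(inAAV) >= 3L)
    stop("ambiguous: ", length(inAAV), " peaks in the intact-AAV band (",
         paste(sprintf("%.4f", -mus[inAAV]), collapse = ", "),
         "); resolve via the sample sheet")
  if (length(inAAV) == 2L) {
    lab[inAAV[which.min(mus[inAAV])]] <- "aav_empty"
    lab[inAAV[which.max(mus[inAAV])]] <- "aav_filled"
  } else if (length(inAAV) == 1L) {
    lab[inAAV] <- singleAAVLabel
  }
  mapply(function(p, l) methods::initialize(p, label = l), peaks, lab,
         SIMPLIFY = FALSE)
}

#' Smooth, detect, fit and classify the peaks of one measurement
#'
#' Convenience composition of [smoothEvents()], [detectPeaks()],
#' [fitGaussianPeak()] and [classifyPeaks()] -- the standard per-
#' measurement analysis used by the sizing approaches.
#'
#' @inheritParams smoothEvents
#' @inheritParams detectPeaks
#' @inheritParams classifyPeaks
#' @return A list of classified [PeakFit-class] objects, sorted by
#'   |contrast| ascending.
#' @export
fitMeasurementPeaks <- function(m, bandwidth = 40, bandwidthUnit = "kDa",
                                slopeHint = 3e-5, regions = regionDefaults(),
                                minEvents = 50L, minProminenceFrac = 0.10,
                                singleAAVLabel = "aav_filled") {
  dist <- smoothEvents(m, bandwidth, bandwidthUnit, slopeHint)
  wins <- detectPeaks(dist, minEvents = minEvents,
                      minProminenceFrac = minProminenceFrac)
  fits <- lapply(wins, function(w)
    fitGaussianPeak(m, w, dist, minEvents = minEvents))
  classifyPeaks(fits, regions, singleAAVLabel = singleAAVLabel)
}

#' Slope hint from a fitted calibration
#'
#' Returns |slope| of a calibration curve, for use as the contrast-per-unit
#' `slopeHint` of [smoothEvents()] on a second analysis pass.
#'
#' @param curve a [CalibrationCurve-class].
#' @return Positive contrast per response unit.
#' @export
slopeHintFromCalibration <- function(curve) abs(curve@slope)
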