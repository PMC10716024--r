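## Seeded generative model of MP landing events for calibrants, intact AAV
## samples and genome-release products.
##
## Generative model: every population's events are drawn as
##   c = -(coefficient x size) + N(0, sigmaEvent) + drift,
## with one additive drift offset ~ N(0, driftSd) per measurement. The
## class-specific coefficients encode, as pure configuration, the observed
## calibration-material biases: free nucleic classes scatter per base by
## alphaFreeSS divided by their class ratio, so sizing an encapsidated
## genome with that family over-estimates by exactly that ratio.

#' Create a simulator configuration
#'
#' Defaults define the study conditions the simulator emulates:
#' populations of ~300 events, per-event contrast SD 0.002, additive
#' per-measurement drift SD 0.001, an empty capsid of 3,700 kDa, a HMW
#' standard of 3,643 kDa, encapsidated ssDNA at 0.309 kDa per base, a free
#' linear ssDNA coefficient anchored so a 4,658-base released genome sits
#' at contrast -0.041, and class ratios (RNA 1.10, circular ssDNA 1.19,
#' dsDNA 1.47, protein route 1.03) reproducing the over-estimation pattern
#' of nucleic-acid calibrations. The capsid coefficient places the empty
#' capsid near -0.105, inside the -0.1..-0.2 intact band.
#'
#' @param alphaCapsid contrast per kDa for capsid-like particles.
#' @param perBaseMass kDa per base of encapsidated ssDNA.
#' @param alphaFreeSS contrast per base of free linear ssDNA.
#' @param classRatio named numeric, see Details.
#' @param sigmaEvent per-event contrast SD.
#' @param driftSd SD of the per-measurement additive offset.
#' @param nPerPeak default events per population.
#' @param emptyCapsidMass,hmwMass reference masses in kDa.
#' @param fragmentFraction,aggregateFraction artifact event fractions per
#'   release workflow (`heat`, `sds`).
#' @param seed integer RNG seed.
#' @return A [SimConfig-class].
#' @examples
#' cfg <- simConfig(seed = 1)
#' cfg@alphaCapsid * cfg@emptyCapsidMass  # ~0.105
#' @export
simConfig <- function(alphaCapsid = (0.041 / 4658) / 0.309,
                      perBaseMass = 0.309,
                      alphaFreeSS = 0.041 / 4658,
                      classRatio = c(ssRNA = 1.10, ssDNA_circular = 1.19,
                                     dsDNA_per_2bases = 1.47,
                                     protein_mass_route = 1.03),
                      sigmaEvent = 0.002, driftSd = 0.001,
                      nPerPeak = 300L, emptyCapsidMass = 3700,
                      hmwMass = 3643,
                      fragmentFraction = c(heat = 0.25, sds = 0.05),
                      aggregateFraction = c(heat = 0.05, sds = 0.005),
                      seed = 1L) {
  new("SimConfig", alphaCapsid = alphaCapsid, perBaseMass = perBaseMass,
      alphaFreeSS = alphaFreeSS, classRatio = classRatio,
      sigmaEvent = sigmaEvent, driftSd = driftSd,
      nPerPeak = as.integer(nPerPeak), emptyCapsidMass = emptyCapsidMass,
      hmwMass = hmwMass, fragmentFraction = fragmentFraction,
      aggregateFraction = aggregateFraction, seed = as.integer(seed))
}

#' Contrast-per-size coefficient of a material class
#'
#' The (positive) coefficient applied with negative sign in the generative
#' model, in contrast per kDa (protein/capsid/HMW classes), per bp (dsDNA)
#' or per base (single-stranded classes).
#'
#' @param materialClass one of the [SpeciesSpec-class] material classes.
#' @param cfg a [SimConfig-class].
#' @return Positive coefficient.
#' @export
classCoefficient <- function(materialClass, cfg) {
  r <- cfg@classRatio
  switch(materialClass,
         aav_capsid = cfg@alphaCapsid,
         hmw_standard = cfg@alphaCapsid,
         protein = cfg@alphaCapsid / r[["protein_mass_route"]],
         ssRNA = cfg@alphaFreeSS / r[["ssRNA"]],
         ssDNA_circular = cfg@alphaFreeSS / r[["ssDNA_circular"]],
         ssDNA_linear = cfg@alphaFreeSS,
         dsDNA = 2 * cfg@alphaFreeSS / r[["dsDNA_per_2bases"]],
         stop("unknown material class '", materialClass, "'"))
}

## internal workers draw from the *current* RNG state so composite
## generators can seed once at the top.
.simDrift <- function(cfg) if (cfg@driftSd > 0) stats::rnorm(1, 0, cfg@driftSd) else 0

.simPopulation <- function(meanContrast, n, cfg) {
  meanContrast + if (cfg@sigmaEvent > 0) stats::rnorm(n, 0, cfg@sigmaEvent)
                 else numeric(n)
}

.simSpeciesEvents <- function(spec, n, cfg, measurementId, dayId = "day1") {
  coef <- classCoefficient(spec@materialClass, cfg)
  mu <- -coef * spec@sizeValue
  ev <- .simPopulation(mu, n, cfg) + .simDrift(cfg)
  ContrastMeasurement(measurementId, ev, dayId = dayId,
                      sampleId = spec@name, allowEmpty = n == 0L,
                      metadata = list(species = spec, trueMean = mu))
}

#' Simulate the landing events of one calibrant species
#'
#' Draws `n` events around `-(coefficient x size)` plus event noise and a
#' per-measurement drift offset. With an explicit `seed` the output is
#' reproducible call-by-call; with `seed = NULL` the current RNG state is
#' used (for composing larger seeded fixtures).
#'
#' @param spec a [SpeciesSpec-class].
#' @param n number of events (`0` gives an empty, flagged measurement).
#' @param cfg a [SimConfig-class].
#' @param seed integer seed, or `NULL` to draw from the current RNG state.
#' @param measurementId,dayId identifiers for the measurement.
#' @return A [ContrastMeasurement-class]; `metadata$trueMean` records the
#'   noise-free population contrast.
#' @export
simulateSpeciesEvents <- function(spec, n = cfg@nPerPeak, cfg = simConfig(),
                                  seed = cfg@seed,
                                  measurementId = spec@name,
                                  dayId = "day1") {
  if (!is.null(seed)) set.seed(seed)
  .simSpeciesEvents(spec, n, cfg, measurementId, dayId)
}

.simIntactAAV <- function(genomeLength, emptyFraction, nTotal, cfg,
                          measurementId, dayId = "day1", sampleId = "aav",
                          hmwSpikeFraction = 0) {
  stopifnot(emptyFraction >= 0, emptyFraction <= 1,
            hmwSpikeFraction >= 0, hmwSpikeFraction < 1)
  pr <- c(empty = emptyFraction * (1 - hmwSpikeFraction),
          filled = (1 - emptyFraction) * (1 - hmwSpikeFraction),
          hmw = hmwSpikeFraction)
  counts <- stats::rmultinom(1, nTotal, pr)[, 1]
  muEmpty <- -cfg@alphaCapsid * cfg@emptyCapsidMass
  muFilled <- -cfg@alphaCapsid *
    (cfg@emptyCapsidMass + cfg@perBaseMass * genomeLength)
  muHmw <- -cfg@alphaCapsid * cfg@hmwMass
  ev <- c(.simPopulation(muEmpty, counts[["empty"]], cfg),
          .simPopulation(muFilled, counts[["filled"]], cfg),
          .simPopulation(muHmw, counts[["hmw"]], cfg))
  ev <- ev[sample.int(length(ev))] + .simDrift(cfg)
  ContrastMeasurement(measurementId, ev, dayId = dayId, sampleId = sampleId,
                      allowEmpty = nTotal == 0L,
                      metadata = list(genomeLength = genomeLength,
                                      counts = counts,
                                      trueMeans = c(empty = muEmpty,
                                                    filled = muFilled,
                                                    hmw = muHmw)))
}

#' Simulate an intact AAV sample (empty + filled capsid mixture)
#'
#' Empty capsids sit at the empty-capsid mass, filled capsids at
#' `emptyCapsidMass + perBaseMass x genomeLength`; event counts are
#' multinomial. An optional HMW-standard spike adds a third population.
#'
#' @param genomeLength encapsidated genome length in bases (0 collapses
#'   filled onto empty).
#' @param emptyFraction expected fraction of empty capsids.
#' @param nTotal total events in the measurement.
#' @param cfg a [SimConfig-class].
#' @param hmwSpikeFraction expected fraction of HMW-standard events.
#' @inheritParams simulateSpeciesEvents
#' @param sampleId sample identifier.
#' @return A [ContrastMeasurement-class] with simulation truth in
#'   `metadata`.
#' @export
simulateIntactAAVSample <- function(genomeLength, emptyFraction = 0.5,
                                    nTotal = 2L * cfg@nPerPeak,
                                    cfg = simConfig(), seed = cfg@seed,
                                    measurementId = "aav_sample",
                                    dayId = "day1", sampleId = "aav",
                                    hmwSpikeFraction = 0) {
  if (!is.null(seed)) set.seed(seed)
  .simIntactAAV(genomeLength, emptyFraction, nTotal, cfg, measurementId,
                dayId, sampleId, hmwSpikeFraction)
}

#' Calibrant species sets of the four standard families
#'
#' @param family `protein_mass`, `dsDNA_bp`, `RNA_bases` or
#'   `ssDNA_plasmid_bases`.
#' @return A named list of [SpeciesSpec-class] objects: urease oligomers
#'   (272/545 kDa), thyroglobulin (670 kDa) and the empty AAV (3,700 kDa)
#'   for proteins; 100--2,000 bp dsDNA ladder; 200--6,000 base RNA ladder;
#'   ΦX174 (5,386 bases) and M13 mp18 (7,249 bases) circular ssDNA
#'   plasmids.
#' @export
calibrantSpecies <- function(family = c("protein_mass", "dsDNA_bp",
                                        "RNA_bases",
                                        "ssDNA_plasmid_bases")) {
  family <- match.arg(family)
  specs <- switch(family,
    protein_mass = list(
      SpeciesSpec("urease_272", "protein", 272, "kDa"),
      SpeciesSpec("urease_545", "protein", 545, "kDa"),
      SpeciesSpec("thyroglobulin_670", "protein", 670, "kDa"),
      SpeciesSpec("aav1_empty", "aav_capsid", 3700, "kDa")),
    dsDNA_bp = lapply(c(100, 200, 400, 800, 1200, 2000), function(bp)
      SpeciesSpec(sprintf("dsDNA_%dbp", bp), "dsDNA", bp, "bp")),
    RNA_bases = lapply(c(200, 500, 1000, 1500, 2000, 3000, 4000, 6000),
                       function(b)
      SpeciesSpec(sprintf("RNA_%db", b), "ssRNA", b, "bases")),
    ssDNA_plasmid_bases = list(
      SpeciesSpec("phiX174", "ssDNA_circular", 5386, "bases"),
      SpeciesSpec("m13mp18", "ssDNA_circular", 7249, "bases")))
  names(specs) <- vapply(specs, function(s) s@name, character(1))
  specs
}

#' Simulate the calibrant measurement set of one family
#'
#' One measurement of `nPerPeak` events per calibrant species, each with
#' its own drift offset.
#'
#' @inheritParams calibrantSpecies
#' @inheritParams simulateSpeciesEvents
#' @return A named list of [ContrastMeasurement-class] objects (the
#'   species spec rides along in each measurement's `metadata$species`).
#' @export
simulateCalibrantSet <- function(family, cfg = simConfig(),
                                 seed = cfg@seed, dayId = "day1") {
  if (!is.null(seed)) set.seed(seed)
  specs <- calibrantSpecies(family)
  out <- lapply(specs, function(s)
    .simSpeciesEvents(s, cfg@nPerPeak, cfg,
                      measurementId = paste(dayId, s@name, sep = "_"),
                      dayId = dayId))
  names(out) <- names(specs)
  out
}

#' Simulate a genome-release measurement
#'
#' Released-genome events at `-alphaFreeSS x genomeLength`, plus workflow-
#' dependent artifact events: fragments uniform in magnitude over
#' (0, 0.030) and large aggregates uniform over (0.5, 1.0). The heat-only
#' workflow produces substantially more of both than the SDS workflow.
#' No intact-AAV population is generated (disassembly is complete).
#'
#' @param genomeLength released genome length in bases.
#' @param workflow `"sds"` (heat in 1% SDS + SDS removal) or `"heat"`.
#' @inheritParams simulateSpeciesEvents
#' @param sampleId sample identifier.
#' @return A [ContrastMeasurement-class]; `metadata$counts` records the
#'   genome/fragment/aggregate split.
#' @export
simulateGenomeRelease <- function(genomeLength, workflow = c("sds", "heat"),
                                  cfg = simConfig(), seed = cfg@seed,
                                  measurementId = "release", dayId = "day1",
                                  sampleId = "release") {
  workflow <- match.arg(workflow)
  if (!is.null(seed)) set.seed(seed)
  .simRelease(genomeLength, workflow, cfg, measurementId, dayId, sampleId)
}

.simRelease <- function(genomeLength, workflow, cfg, measurementId,
                        dayId = "day1", sampleId = "release") {
  f <- cfg@fragmentFraction[[workflow]]
  a <- cfg@aggregateFraction[[workflow]]
  nTotal <- round(cfg@nPerPeak / (1 - f - a))
  counts <- stats::rmultinom(1, nTotal,
                             c(genome = 1 - f - a, fragment = f,
                               aggregate = a))[, 1]
  muGenome <- -cfg@alphaFreeSS * genomeLength
  ev <- c(.simPopulation(muGenome, counts[["genome"]], cfg),
          -stats::runif(counts[["fragment"]], 0, 0.030),
          -stats::runif(counts[["aggregate"]], 0.5, 1.0))
  ev <- ev[sample.int(length(ev))] + .simDrift(cfg)
  ContrastMeasurement(measurementId, ev, dayId = dayId, sampleId = sampleId,
                      metadata = list(genomeLength = genomeLength,
                                      workflow = workflow, counts = counts,
                                      trueMean = muGenome))
}

#' Build a full seeded study fixture
#'
#' Deterministic multi-day bundle mirroring a three-day study design:
#' per day, one calibrant measurement set for each of the four standard
#' families, `repsPerDay` intact measurements of each AAV sample (the
#' default genome lengths are 3,793 / 4,142 / 4,504 / 4,596 / 4,658
#' bases, each sample spiked so both populations are present), and
#' `repsPerDay` genome-release measurements per sample.
#'
#' @param cfg a [SimConfig-class]; `cfg@seed` fixes the whole bundle.
#' @param nDays number of measurement days.
#' @param repsPerDay measurements per sample per day.
#' @param genomeLengths named or unnamed numeric of expected genome
#'   lengths in bases.
#' @param emptyFraction expected empty-capsid fraction in each intact
#'   measurement.
#' @param releaseWorkflow workflow for the release runs.
#' @param withRelease include genome-release measurements.
#' @return A list with elements `config`, `samples` (an
#'   [AAVSampleSpec-class] per genome length) and `days`; each day holds
#'   `calibrants` (per family), `intact` (per sample: list of
#'   measurements) and `release` (per sample).
#' @export
makeStudyFixture <- function(cfg = simConfig(), nDays = 3L, repsPerDay = 3L,
                             genomeLengths = c(aav2 = 3793, aav3 = 4142,
                                               aav4 = 4504, aav5 = 4596,
                                               aav6 = 4658),
                             emptyFraction = 0.5,
                             releaseWorkflow = "sds",
                             withRelease = TRUE) {
  set.seed(cfg@seed)
  if (is.null(names(genomeLengths)))
    names(genomeLengths) <- paste0("sample", seq_along(genomeLengths))
  samples <- lapply(names(genomeLengths), function(s)
    AAVSampleSpec(s, genomeLengths[[s]]))
  names(samples) <- names(genomeLengths)
  days <- lapply(seq_len(nDays), function(d) {
    dayId <- paste0("day", d)
    calibrants <- lapply(c("protein_mass", "dsDNA_bp", "RNA_bases",
                           "ssDNA_plasmid_bases"), function(fam) {
      specs <- calibrantSpecies(fam)
      out <- lapply(specs, function(s)
        .simSpeciesEvents(s, cfg@nPerPeak, cfg,
                          measurementId = paste(dayId, s@name, sep = "_"),
                          dayId = dayId))
      names(out) <- names(specs)
      out
    })
    names(calibrants) <- c("protein_mass", "dsDNA_bp", "RNA_bases",
                           "ssDNA_plasmid_bases")
    intact <- lapply(names(genomeLengths), function(s) {
      lapply(seq_len(repsPerDay), function(r)
        .simIntactAAV(genomeLengths[[s]], emptyFraction,
                      2L * cfg@nPerPeak, cfg,
                      measurementId = sprintf("%s_%s_rep%d", dayId, s, r),
                      dayId = dayId, sampleId = s))
    })
    names(intact) <- names(genomeLengths)
    release <- NULL
    if (withRelease) {
      release <- lapply(names(genomeLengths), function(s) {
        lapply(seq_len(repsPerDay), function(r)
          .simRelease(genomeLengths[[s]], releaseWorkflow, cfg,
                      measurementId = sprintf("%s_%s_release%d", dayId, s, r),
                      dayId = dayId, sampleId = s))
      })
      names(release) <- names(genomeLengths)
    }
    list(dayId = dayId, calibrants = calibrants, intact = intact,
         release = release)
  })
  names(days) <- paste0("day", seq_len(nDays))
  list(config = cfg, samples = samples, days = days)
}
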