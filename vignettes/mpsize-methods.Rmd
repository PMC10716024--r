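---
title: "Sizing AAV genomes from mass-photometry contrast events"
author: "mpsize authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sizing AAV genomes from mass-photometry contrast events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpsize)
```

## The measurement model

Mass photometry detects single particles landing on a glass–water
interface; each landing event yields one ratiometric contrast value,
negative under the mass-binding convention used throughout this package.
Within one material class the contrast is, to good approximation, linear
in particle mass (or chain length), so a set of standards of known size
defines a line

$$c = s \cdot x + b, \qquad s < 0,$$

with $x$ in kDa, bp or bases depending on the calibration family. All
calibrations in `mpsize` are fitted in this orientation (contrast as a
function of size, the orientation in which calibration slopes are
conventionally quoted) by ordinary least squares with a free intercept,
and are inverted analytically for prediction,
$\hat x = (c - b)/s$. For difference-based conversions only the slope is
used, so the intercept cancels; the zero point of the circular-ssDNA
plasmid family is an ordinary datum, never a constraint. Fitting
mass-on-contrast instead would change predictions only through the
regression's noise asymmetry; for the well-conditioned, nearly collinear
calibrations used here the difference is negligible, and the chosen
orientation is stated rather than hidden.

Six calibration families are supported: protein mass (urease oligomers
at 272 and 545 kDa, thyroglobulin at 670 kDa and the 3,700 kDa empty
capsid), a dsDNA ladder (100–2,000 bp), an RNA ladder (200–6,000 bases),
circular ssDNA plasmids (ΦX174 at 5,386 and M13 mp18 at 7,249 bases plus
the zero point), and two AAV-based calibrations built from capsids of
known genome length — delta contrast against a reference population, and
absolute filled-peak contrast. Conversion chains into bases are exact
rationals: a mass difference converts at 309 kDa per 1,000 bases (the
mean dNMP chain-residue mass — monomer minus water — is 308.9 Da, see
`dnaResidueMassPer1000Bases()`), and one base pair counts as two bases.

## Peak analysis

The instrument-style "histogram bandwidth" (40 kDa or 120 bases/bp for
intact capsids, 50 bases for a released genome) is interpreted as the
standard deviation of a Gaussian smoothing kernel. Declared in
calibrated units it must be converted into contrast units through a
contrast-per-unit slope; this is a two-pass design: a provisional hint
(3×10⁻⁵ per kDa, a typical capsid coefficient) serves for the first
pass over the calibrants, after which the fitted calibration slope is
the hint for the sample pass (`slopeHintFromCalibration()`).

`smoothEvents()` evaluates the kernel density on a regular grid spanning
the event range plus three bandwidths. The grid holds at least 2,048
points and at least four points per bandwidth — the latter matters when
rare large-magnitude aggregate events stretch the support to
contrast −1 while the released-genome bandwidth is only ~4×10⁻⁴.

`detectPeaks()` keeps interior local maxima whose topographic prominence
is at least 10% of the maximum density (so shot-noise wiggles and
shoulder artifacts are ignored), expands each to ±2 bandwidths,
truncates overlapping windows at the density minimum between maxima and
drops windows expected to hold fewer than 50 events. `fitGaussianPeak()`
then least-squares fits a single Gaussian to the windowed density
(initialized at the windowed mode and the sample SD of the windowed
events) and refits once on a window recentered to
$\hat\mu \pm \max(2.5\hat\sigma,\ 2\,\mathrm{bw})$; the floor keeps the
second window meaningful when the first pass saw only the top of a peak.
Degenerate inputs (zero spread) short-circuit with the exact value and a
flagged, floored sigma; windows with fewer than 50 raw events are
flagged low-confidence rather than failing.

Classification is by fitted |contrast|: fragments below 0.030, a
released genome in 0.030–0.07, intact capsids in 0.10–0.20, aggregates
above 0.5, all configurable (`regionDefaults()`). The fragment region is
deliberately read as a magnitude bound — "small fragments" are events of
*small* contrast magnitude; a literal signed reading of `c < −0.030`
would swallow the intact-capsid band. With two capsid-band peaks the
smaller-magnitude one is the empty capsid (the high-molecular-weight
standard, at 3,643 kDa, falls in the same band and plays the same
reference role when spiked instead); a lone capsid-band peak defaults to
"filled" — the common case for a sample with a small empty fraction —
and is overridable; three or more raise an ambiguity error for the
caller to resolve from the sample sheet. When two candidate filled peaks
survive, the one with more events wins: the dominant population defines
the sample.

## The three sizing approaches

* **Approach 1** requires both populations; `sizeApproach1()` converts
  $\Delta c = c_\mathrm{filled} - c_\mathrm{empty}$ through a standard
  calibration. Additive per-measurement drift cancels exactly in
  $\Delta c$.
* **Approach 2 (delta)** applies the $\Delta c$-vs-bases line of an AAV
  calibration set, slope and intercept, against an empty-AAV or
  HMW-standard reference; also drift-invariant, and in practice the most
  accurate route.
* **Approach 2 (absolute)** inverts the absolute-contrast line at the
  filled peak; no reference needed, but an event-list offset $d$ moves
  the estimate by $-d/s$ — this sensitivity is asserted numerically in
  the test suite. With the empty capsid included, that 0-base point
  carries ~0.97 of the design's leverage (`pointLeverage()`, the
  hat-matrix diagonal), so a small error in its contrast moves the slope
  substantially; the package exposes both the with-empty and
  filled-only fits.
* **Approach 3** sizes the released genome directly
  (slope and intercept), refusing to size when an intact-capsid peak
  survives the disassembly workflow.

Study aggregation mirrors a multi-day design: measurements are averaged
within day, headline statistics are computed across day means (n =
days), %CV = 100·SD/mean, accuracy = 100·mean/expected. A single day
reports SD and %CV as not applicable rather than zero, an expected
length of 0 (an empty capsid) never yields an accuracy, and an unknown
expected length is an explicit marker, never 0. Display rounding is
fixed (integer bases and accuracy, one-decimal %CV) so table-style
output is reproducible; slots keep full precision.

The within-sample resolution estimate uses the full-width-at-half-maximum
criterion: two equal Gaussian populations of width $\sigma$ merge into
one mode below a separation of about $2.355\,\sigma$, so
`estimateResolutionLimit()` returns $k\sigma/|s_\mathrm{bases}|$ with
$k = 2.355$ by default. The criterion constant is a declared choice —
resolvability thresholds between $2\sigma$ and $3\sigma$ are all
defensible — and is configurable. With typical intact-capsid peak widths
(σ ≈ 0.0015–0.002) and AAV-calibration slopes (≈ 9×10⁻⁶ per base) this
lands at roughly 400–500 bases.

`recommendApproach()` encodes the decision tree in priority order:
delta-contrast AAV calibration when an AAV set and a reference exist;
absolute-contrast AAV calibration when no reference can be spiked;
the empty/filled difference with standard calibrants as the fastest
route; genome release when only single-stranded nucleic calibrants are
available.

## What the simulator emulates — and what it does not

The generator draws each population's events as

$$c = -(\alpha_\mathrm{class} \cdot \mathrm{size}) +
      \mathcal{N}(0, \sigma_\mathrm{event}) + d,$$

with one additive drift offset $d \sim \mathcal{N}(0, \sigma_d)$ per
measurement. Defaults define the emulated study conditions: ~300 events
per population (the practical target count for a 60 s acquisition),
$\sigma_\mathrm{event} = 0.002$ contrast (the published summaries quote
no peak widths; this value puts empty and filled capsids ≈ 20σ apart and
reproduces percent-level %CVs, and is revisable configuration),
$\sigma_d = 0.001$, an empty capsid of 3,700 kDa, a HMW standard of
3,643 kDa, encapsidated ssDNA at 0.309 kDa per base, and a free-ssDNA
coefficient anchored so a 4,658-base released genome sits at
contrast −0.041.

Material-class optics are *not* modeled. The observed biases of the
calibration materials — nucleic-acid calibrations overestimate an
encapsidated genome, dsDNA worst — are encoded purely as configurable
class ratios (RNA 1.10, circular ssDNA 1.19, dsDNA 1.47, protein route
1.03): a free nucleic class scatters per base at
$\alpha_\mathrm{freeSS}/\mathrm{ratio}$, so sizing an encapsidated
genome with that family overestimates by exactly that ratio. The capsid
coefficient is chosen as $\alpha_\mathrm{freeSS}/0.309$ per kDa, which
(a) places the empty capsid near contrast −0.105, inside the intact
band, and (b) makes the encapsidated contrast-per-base equal
$\alpha_\mathrm{freeSS}$, so the ratio chain is exact rather than
approximate. One caveat is documented deliberately: the protein-route
ratio scales only the isolated protein calibrants, while the 3,700 kDa
empty-capsid point keeps the capsid coefficient; because that point
holds ~0.97 leverage in the protein calibration, the effective
protein-route bias is damped to ≈ 1.00. The qualitative ordering
protein < RNA < ssDNA < dsDNA survives and is asserted in the tests.

Genome-release simulations add artifact events — fragments uniform in
|c| over (0, 0.030), aggregates over (0.5, 1.0) — with workflow-specific
fractions (heat: 25%/5%; SDS: 5%/0.5%), reproducing the phenomenology
that SDS-assisted release is much cleaner. Event counts are multinomial;
the same seed yields bit-identical output.

What passing simulation tests show is that the *analysis chain* is
correct under the stated generative model: exact recovery in the
noiseless limit, drift theorems, bias ordering and seeded error bounds.
They do not validate the linearity assumption itself, real instrument
noise (which is not i.i.d. Gaussian per event), partial-filling
heterogeneity within one peak, surface or buffer artifacts, or
class-coefficient values for any particular instrument — those require
instrument data.

## Numerical choices and problem sizes

Ties and degeneracies: windows are truncated at inter-peak density
minima; among competing filled candidates the larger event count wins;
zero-spread windows yield flagged degenerate fits; zero calibration
slope raises a degenerate-curve error; negative predicted responses are
returned with a warning, never clipped. Gaussian fits use
Levenberg–Marquardt least squares with bounded parameters; the seeded
study fixtures used by the tests and the reproduction script run
3 days × 3 replicates per sample (5 samples for the leave-one-out
study), ~300 events per population — a full suite executes in well under
a minute on one CPU.

Known limitations: single-Gaussian windowed fits (no mixture
deconvolution of partially filled capsids), no weighted or orthogonal
regression, no refractive-index modeling, and vendor binary formats and
raw video processing are out of scope; the CSV/JSON/YAML interfaces are
the contract.
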