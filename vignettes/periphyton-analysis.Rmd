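---
title: "Quantifying synthetic periphyton: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying synthetic periphyton: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periphytonr)
```

Periphyton — the benthic biofilm community of diatoms, green algae and
cyanobacteria coating submerged surfaces in freshwater — can be rebuilt in
the laboratory as a *synthetic* community: defined species, defined
inoculation densities, sequential introduction waves that mimic natural
colonization. This package implements the quantitative layer such a system
needs: designing the inoculum and schedule from growth kinetics, and
measuring the resulting biofilm with optical coherence tomography (OCT),
colonization micrographs, chlorophyll fluorescence, and marker-gene count
tables. Every analysis has a seeded synthetic-data generator with known
ground truth, so the whole pipeline is validated by parameter recovery
rather than by eye.

## OCT morphometrics

An OCT B-scan is a gray-level cross-section: columns are adjacent A-scans
(lateral direction, 15 µm per pixel by default), rows run axially
(4.4 µm per pixel), with row 1 at the probe side and the biofilm growing
upward from the bright chamber-surface line. The analysis is three steps.

**Substrate detection.** Each column is smoothed axially with a Gaussian
(`sigma`, default 2 px) and the position of its strongest dark-to-bright
gradient is taken as the entry into the bright substrate line; the
per-column votes are consolidated by the median, because the chamber glass
is flat. The per-column gradient must exceed `min_gradient` (default 5 gray
levels/px) to vote; if no column qualifies, the scan has no detectable
interface and an error is raised rather than a guess returned.

**Binarisation.** Foreground (biomass) is the above-threshold class. The
default automatic threshold is Otsu's between-class-variance criterion,
the conventional choice for bimodal OCT histograms; Huang's fuzzy-entropy
threshold (see below) and a fixed level are also available. A constant
image has no meaningful automatic threshold and is rejected.

**Physical properties.** With per-A-scan thicknesses $L_{F,i}$ (µm) and $N$
A-scans:

$$\bar L_F = \frac{1}{N}\sum_{i=1}^{N} L_{F,i}, \qquad
  R_a^* = \frac{1}{N}\sum_{i=1}^{N}
  \frac{|L_{F,i} - \bar L_F|}{\bar L_F}.$$

The relative roughness $R_a^*$ is dimensionless: near 0 for smooth mats,
with values above roughly 0.5 indicating a heterogeneous canopy. The
per-column top edge is the first run of at least `min_run` (default 3)
consecutive foreground pixels above the substrate; the run-length rule
rejects isolated speckle at a worst-case thickness bias of about two
pixels. Columns with no biofilm count as $L_{F,i} = 0$: they are part of
the scanned surface, and excluding them would overstate the mean. An
exclusion flag is deliberately not provided at the metric level — filter
the profile beforehand if a different convention is needed.

Internal porosity is genuinely ambiguous for OCT, so both readings are
implemented and the caller must name one: `mean_to_max`
($\bar L_F / \max_i L_{F,i}$, a canopy-shape measure) and `void_fraction`
(background pixels inside the biofilm envelope divided by envelope pixels,
which rests on the debatable assumption that absent signal means absent
biomass). Neither is asserted to be "the" published metric.

## Huang thresholding and surface coverage

Colonization micrographs show dark attached cells on a bright background.
Coverage is measured by reimplementing the standard particle-counting
macro: Huang–Wang fuzzy-entropy thresholding with dark polarity, a
counting mask, connected-component particle analysis, and the covered
fraction. For a candidate threshold $t$ the two classes get fuzzy
memberships $u(g) = 1/(1 + |g - \mu_{\text{class}}|/C)$ with $C$ the
gray-level range, and the histogram-weighted Shannon entropy
$\sum_g h(g)\,[-u\log u - (1-u)\log(1-u)]$ is minimised by exhaustive scan
over all candidate levels — at most 65 536 bins, so speed is a non-issue
and the fast path is *identical* to the brute-force oracle, which the test
suite asserts on random histograms. Particles are 8-connected by default
(the common particle-analyzer convention; 4-connectivity is available),
and `min_particle_px` (default 0, as no published size filter value
exists) removes small components from both count and mask — necessarily
monotone in both. Tile acquisition and stitching are out of scope: the
function consumes single assembled fields.

## PSII quantum yield

The effective photosystem II quantum yield under actinic light is

$$\phi' = \frac{F'_m - F'_0}{F'_m}$$

from the steady-state fluorescence $F'_0$ and the post-saturation-pulse
maximum $F'_m$. For imagery the yield is computed per pixel and then
averaged over the region of interest — the whole-field average an imaging
PAM reports — rather than computing the yield of the mean image; the two
differ for heterogeneous fields and the per-pixel form weights every pixel
equally. Instrument noise at dark pixels can produce $F'_m \le 0$ or
$F'_0 > F'_m$; the default `mask_invalid` policy excludes such pixels from
the mean (an `error` policy is available for strict pipelines). For valid
pixels $0 \le \phi' \le 1$ and the value is invariant to common scaling of
both frames.

## Growth kinetics and inoculum design

Suspension growth series (sampled every 48 h, on whatever biomass scale
the instrument provides — optical density at 685 nm or cells/mL) are fit
to the three-parameter logistic

$$y(t) = \frac{K}{1 + \frac{K - N_0}{N_0} e^{-kt}}$$

by Levenberg–Marquardt least squares, with starting values from the data
(observed maximum for $K$, first positive value for $N_0$, logit-slope
regression for $k$). $N_0$ is a nuisance parameter; $k$ (h⁻¹) and the
capacity $K$ are the design quantities. Degenerate series return a
non-converged fit with a diagnostic instead of an exception, and both
readings of "maximum reached biomass" — fitted asymptote `K_hat` and
observed maximum `K_obs` — are reported because the published tables do
not disambiguate them.

A practical identifiability note, quantified by the recovery suite: at
zero noise both $k$ and $K$ are recovered to machine precision, but with
measurement noise at 5% of $K$ and 48-h sampling, $K$ keeps a median
relative error under 2% while $k$ retains an intrinsic ~8–10% relative
standard error — the information about $k$ lives in the handful of points
around the inflection. The fits are verified global least-squares optima,
so this is a property of the sampling design, not of the optimizer.
Recovery simulations use $N_0 = K/30$ (a typical batch inoculum, ~3% of
capacity) and sample every 48 h until about 2.5× the inflection time,
i.e. into stationary phase.

Species are classed into growth groups — G1 (fast growth, high biomass),
G2 (fast, low/intermediate), G3 (slow, low) — by an explicit rule:
G1 if $K \ge K_{\text{high}}$, else G3 if $k < k_{\text{slow}}$ or
$K < K_{\text{verylow}}$, else G2, with cohort-percentile defaults (60th
of $K$, 25th of $k$, 10th of $K$). The published group labels, however,
encode expert judgment that no two-threshold rule on $(k, K)$ can fully
reproduce — the packaged table contains pairs with equal $k$ and similar
$K$ assigned to different groups — so the authoritative labels ship as
data in `species_table()`, drive inoculum allocation, and
`growth_group_concordance()` reports where the rule and the labels
disagree instead of pretending they coincide.

Inoculum allocation inverts competitiveness: the faster and higher a
species grows, the fewer cells it gets. Defaults per (wave, growth group)
are A: 125 000; B: 75 000 / 125 000 / 133 000; C: 65 000 / 125 000 /
300 000 cells/mL for G1/G2/G3, with per-species overrides (one species,
*Pseudanabaena galeata*, uses 190 000). With the packaged table this gives
wave totals of 250 000, 999 000 and 2 175 000 cells/mL. The three waves —
pioneer low-profile diatoms, high-profile diatoms, then motile diatoms
plus green algae and cyanobacteria — run 4, 14 and 12 days, so waves
start on days 0, 4 and 18 and establishment spans 30 days.

## Count-table operations

Rarefaction subsamples each sample without replacement (multivariate
hypergeometric — the standard contract) to a common depth, via
`vegan::rrarefy` behind the package's interface; shallower samples are
dropped with a warning or raise, by policy. Relative abundances are
per-sample proportions, optionally averaged over replicates within
metadata groups. Succession tracking marks a roster species detected at a
time point when its count (or proportion) reaches `detection_threshold`
(default 1 read post-rarefaction — no published limit of detection
exists, so the threshold is exposed) in at least one replicate; species
undetected at the final time point are the lost set, which can only grow
as the threshold rises. Marker datasets (16S, 18S, rbcL) are processed
independently; no cross-marker abundance reconciliation is attempted,
since copy-number and PCR biases differ by marker.

## What the generators emulate — and what they do not

`generate_bscan()` builds a background field, a bright substrate band
(default 8 px deep, gray level 250 on an 8-bit scale, vs 120 for biofilm
and 20 for background — contrasts chosen so the substrate line dominates
the axial gradient as it does in real scans), a biofilm band following the
requested per-column thickness profile, elliptical void blobs
rejection-sampled to the target void fraction, and additive Gaussian noise
clipped to the bit depth. Voids keep a 3-px margin below each column's top
edge and 1 px above the substrate, so they are strictly internal and the
noiseless profile is exactly recoverable. Real OCT speckle is
multiplicative and correlated; Gaussian noise is deliberately simpler —
sufficient for recovery tests, but passing them does not certify
performance on true speckle statistics, wavy substrates, or multiple
scattering artefacts. Bit depth and intensity units are arbitrary, as no
physical intensity calibration is modelled.

`generate_colonization_image()` places dark elliptical blobs on a bright
background, trimming the final blob so the truth mask hits the requested
coverage to within one pixel. `generate_growth_curve()` adds Gaussian
noise to the logistic; negative observations are possible at low signal,
as with a blank-corrected spectrophotometer. `generate_count_table()`
draws multinomial reads from per-sample taxon probabilities. All
generators are bitwise-reproducible under a seed.

## Numerical choices and degenerate inputs

Thresholds operate on rounded gray levels with exhaustive candidate scans;
ties break toward the lower level. The substrate median is rounded to the
nearest row. Empty profiles, all-zero profiles (roughness, porosity),
constant images (automatic thresholds), and all-invalid fluorescence
raise classed errors; batch analysis (`analyze_bscans()`) converts
per-scan errors into flagged rows so one bad scan cannot abort a
replicate set. A blank, zero-contrast micrograph is the one deliberate
exception: `coverage()` reports zero coverage and no particles, since an
empty field is a legitimate observation, while `huang_threshold()` itself
still rejects constant input.

## Problem sizes in the shipped tests

The recovery suites use 230 × 133 px B-scans (2 × 1 mm at the default
scales) over 50 seeds per noise condition, 192 × 192 px colonization
images at the three field coverage levels, 50-seed growth-curve studies
for five kinetics pairs spanning the packaged table, 10⁴-profile oracle
sweeps for the thickness/roughness sums, and 200-seed rarefaction
unbiasedness checks at depth 10⁴ from paired 10⁶-read samples. These sizes
keep every property statistically meaningful while the full suite runs in
a few minutes.

## Known limitations

Single-field 2-D analysis only (no tile stitching, no 3-D volumes or CLSM
rendering); no mechanistic succession or competition model (the design is
kinetics-based allocation, not simulation); benthic growth may differ from
the planktonic kinetics used for classification, and no correction is
attempted; treatment statistics beyond detection counts (ANOVA/Tukey and
friends) are left to the standard tools.
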