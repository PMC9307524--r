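# periphytonr

Quantitative toolkit for **synthetic periphyton** — lab-assembled benthic
phototrophic biofilm communities of diatoms, green algae and cyanobacteria.
It is aimed at microbial ecologists and biofilm researchers who build
defined multi-species biofilms and need the numbers behind them: how many
cells of each species to inoculate and when, and how to measure the
biofilm that grows — its physical structure, surface colonization,
photosynthetic activity, and community composition.

## What it computes

**OCT morphometrics.** From an optical-coherence-tomography B-scan
(axial × lateral gray-level image): substrate interface detection by axial
gradient analysis, automatic binarisation (Otsu or Huang), and the
physical properties of the biofilm from the per-A-scan thicknesses
*L*<sub>F,i</sub> (µm):

- mean thickness  L̄<sub>F</sub> = (1/N) Σ L<sub>F,i</sub>
- relative roughness  R<sub>a</sub>\* = (1/N) Σ |L<sub>F,i</sub> − L̄<sub>F</sub>| / L̄<sub>F</sub>
- internal porosity, either L̄<sub>F</sub>/max(L<sub>F,i</sub>) or the
  void-pixel fraction inside the biofilm envelope

**Surface coverage.** Huang–Wang fuzzy-entropy thresholding ("dark"
polarity: cells are the dark class), counting mask, 8-connected particle
analysis, covered fraction.

**PSII quantum yield.** φ′ = (F′<sub>m</sub> − F′<sub>0</sub>)/F′<sub>m</sub>
from paired steady-state / saturation-pulse chlorophyll-fluorescence
measurements, scalar or image-wise with ROI averaging.

**Growth kinetics and assembly design.** Logistic fits
y = K/(1 + ((K−N₀)/N₀)e<sup>−kt</sup>) of suspension growth series;
growth-group classification (G1/G2/G3); starting-inoculum allocation over
three sequential introduction waves (A/B/C) and the 30-day colonization
schedule. The 26-species parameter table ships with the package
(`species_table()`).

**Community composition.** Rarefaction to equal depth (without
replacement), relative-abundance profiles with replicate averaging, and
succession tracking of detected/lost species across time points.

**Synthetic data with ground truth.** Seeded generators for B-scans,
colonization micrographs, fluorescence pairs, growth curves and count
tables, so every stage is testable by parameter recovery.

## Worked example

```r
library(periphytonr)

# -- design: who goes in, how many, when ------------------------------------
plan <- allocate_inoculum(species_table(),
                          overrides = c("Pseudanabaena galeata" = 190000))
plan
#> <inoculum_plan> 27 species in 3 assembly groups
#>   group A: 250,000 cells/mL
#>   group B: 999,000 cells/mL
#>   group C: 2,175,000 cells/mL
#>   schedule span: 30 days

# -- measure a (here synthetic) biofilm cross-section -----------------------
scan <- generate_bscan(rep(101, 133), height_px = 230, substrate_row = 200,
                       noise_sd = 23, seed = 7)
sr   <- detect_substrate(scan)        # 200 (axial row of the chamber surface)
mask <- binarize(scan, "otsu")        # threshold 90
prof <- thickness_profile(mask, sr, axial_scale = 4.4)
mean_thickness(prof)                  # 97.8 um  (truth: 101 um band)
roughness(prof)                       # 0.052    (smooth, homogeneous canopy)

# -- surface colonization from a micrograph ---------------------------------
field <- generate_colonization_image(0.474, blob_count = 25,
                                     size_px = c(192, 192),
                                     noise_sd = 15, seed = 5)
coverage(field$image)
#>   threshold coverage_fraction particle_count particle_areas
#> 1       137             0.474             10 <int [10]>

# -- growth kinetics from a culture series ----------------------------------
curve <- generate_growth_curve(k = 0.017, K = 0.285, N0 = 0.0095,
                               noise_sd = 0.014, seed = 3)
tidy(fit_logistic(curve))
#>   term  estimate std.error
#> 1 k      0.0196    0.00198
#> 2 K      0.278     0.00557
#> 3 N0     0.00587   0.00221
```

Reading the numbers: the inoculum plan allocates fewest cells to fast,
high-biomass species and most to slow, low-biomass ones, giving the three
wave totals shown; the OCT pipeline recovers the ~101 µm early-stage
biofilm to within a pixel-scale error with a near-zero roughness
coefficient, as expected for a flat synthetic mat; the coverage call
recovers the 47.4% colonization level of the mid-stage field; and the
logistic fit returns the rate constant *k* (h⁻¹, OD₆₈₅ scale) and
capacity *K* with their standard errors.

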