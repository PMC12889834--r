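---
title: "Methods: quantifying temperature-dependent AMP assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying temperature-dependent AMP assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ampfever)
```

This vignette documents the models, parameters, and design choices behind
the four quantification pipelines and the synthetic-data generator that
validates them. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## Scientific setting

Antimicrobial peptides (AMPs, e.g. human LL-37) and histones permeabilize
bacterial membranes, and their activity rises steeply between body
temperature (37 °C) and febrile temperatures (38.5–40 °C), especially for
the synergistic AMP + histone combination. The same molecules sit on lipid
droplets (LDs) inside host cells and can damage mitochondria, whose
membranes resemble bacterial ones; cells appear to compensate at high
temperature by moving LDs away from mitochondria. Four readouts quantify
this picture:

1. **PI entry** — propidium iodide only enters permeabilized bacteria, so
   the fraction of PI-positive cells is a per-cell killing-activity proxy.
2. **JC-1 red/green ratio** — JC-1 aggregates (red) at high mitochondrial
   membrane potential and stays monomeric (green) when depolarized; the
   per-cell red/green ratio tracks mitochondrial health. An Annexin V
   stained-cell fraction (apoptosis) is the same fraction-positive readout
   on a different channel and reuses `classify_positive()` unchanged.
3. **LD–mitochondria contact ratio** — from two-channel 3D stacks:
   contact area between the thresholded channels, normalized by total LD
   volume.
4. **CFU survival** — colonies from ten-fold serial-dilution droplets,
   treated over untreated control at the same temperature.

## Image model and containers

Volumes are ZYX arrays with physical voxel sizes; the default
`(0.329, 0.063, 0.063)` µm combines the stated 0.329 µm z-interval of the
lattice-SIM acquisition with a plausible reconstructed lateral pixel pitch
(the original pitch is unpublished; both are config parameters, as is the
camera bit depth). Channels are separate `volume_image` objects, never
interleaved. On disk, images are 16-bit multi-page TIFFs (pages
channel-major) with a JSON sidecar carrying channel names, axes, voxel
size, and bit depth; integer images round-trip bit-for-bit. Everything
downstream of pixel measurement is a tibble, so results compose with dplyr
and ggplot2.

## Contact pipeline

`preprocess()` applies a separable Gaussian blur (per-axis sigma =
physical sigma / voxel size) and a white top-hat with an ellipsoidal
(physical-radius) structuring element; `segment()` thresholds with 256-bin
Otsu over the full 3D histogram (strictly above; degenerate histograms
yield an empty mask with a warning) and drops components under
`min_component_voxels` (default 5). `contact_area()` counts exposed
LD-surface faces whose far side reaches the mitochondrial mask within
`contact_distance_voxels` (default 1), weighting each face by its physical
area per axis rather than resampling to isotropic voxels — interpolation
would smear the thin tubules. Face adjacency rather than mask overlap
defines contact because PSF-blurred channels overlap spuriously;
overlapping voxels still contribute through their exposed faces.
"Contact area normalized by total LD volume" is taken literally, so the
contact ratio has units µm⁻¹; raw area and volume are reported alongside
for renormalization. Whether the original analysis also computed a
separate distance statistic is unclear from its description; only the
contact ratio is implemented.

Two defaults deserve justification. The processing blur default is
0.04 µm: with 0.063 µm pixels, a 0.08 µm blur (1.3 px) visibly widens the
Otsu half-max contour of 0.15 µm tubules and inflates tangent contact
patches several-fold, while 0.04 µm suppresses shot noise without
measurable mask dilation — the published macro's parameter values are not
available, so these are the package's own estimates, checked against the
generator's ground truth. The top-hat radius default is 0.5 µm, larger
than droplets (radius ≈ 0.3 µm) and tubule cross-sections (0.15 µm) but
smaller than background structure, so objects survive and smooth
background is annihilated.

## Per-cell pipelines

`segment_cells()` thresholds 2D fields with Otsu (phase-contrast rods are
darker than background and are inverted first; round cells are brighter),
labels connected components (EBImage), filters by area, and removes
border-touching cells; labels are raster-ordered by centroid.
`per_cell_intensity()` subtracts the median of non-cell pixels (robust to
bright cells) and floors at zero; the MAD of those pixels is kept as the
background noise scale. `classify_positive()` defaults to Otsu **on the
pooled per-cell intensity distribution across all conditions of one
experiment** — per-condition thresholds would drift with the effect being
measured — with a strict `> k·σ` background rule (default k = 3) as the
fallback for unimodal data. `jc1_ratio()` applies one segmentation to both
channels and divides background-subtracted means, excluding (and
counting) cells whose green mean falls below a floor; the per-cell ratio
is used rather than a per-field mean because the dot plots this mirrors
are per-cell (a per-field variant is a trivial `group_by` away).
Condition statistics are always computed per biological replicate first,
then summarized as mean ± SEM over replicates, matching how three-replicate
imaging figures report error.

## Statistics

`welch_ttest()` implements the unequal-variance t-test with
Welch–Satterthwaite degrees of freedom and a two-sided p from the t
distribution; zero-variance degenerate inputs return t = 0, p = 1 (equal
means) or p = 0 with a flag. `fold_change()` divides condition grand means
with first-order error propagation. `compare_conditions()` runs Welch
tests on replicate-level values and attaches the "ns if p > 0.05" label;
no multiple-testing correction is applied by default, matching the
original analysis convention, and a Holm flag is provided with that caveat
documented. With three replicates per arm a permutation test has no
resolution, so p-values come from the t distribution only.

`cfu_per_ml()` uses rows in the countable range (default 3–30 colonies for
10 µl droplets, standard droplet-plate practice); multiple countable rows
are pooled as total colonies over total effective plated volume — each
row weighted by its observed colonies, the Poisson-information weighting —
with a flag when rows disagree by more than 2×. All-zero series report 0
with a below-detection flag. Survival is treated/control strictly within
temperature; the CLI pairs controls per replicate (a pooled-control
fallback is available) because the original pairing convention is not
stated.

## Synthetic data: what it emulates and what it does not

The generator plants every quantity the pipelines estimate:

* **Bacterial fields** — non-overlapping rods (12 × 4 px capsules, 100
  cells per field as in the source figures); exactly
  `round(n_cells × positive_fraction)` cells carry the positive PI level
  (600 vs 60 counts above background, Gaussian noise σ = 10). The exact
  count makes planted fractions noiseless study conditions.
* **JC-1 fields** — round cells; per-cell green is log-normal around its
  base, red = green × ratio × log-normal scatter (sdlog 0.10, a realistic
  per-cell spread), so the planted ratio has median `red_green_ratio` and
  treated/untreated quotients are unbiased.
* **Contact scenes** — 16 z-planes × 128² voxels (5.3 × 8.1 × 8.1 µm)
  holding 5 two-segment tubules (radius 0.15 µm, length ~3 µm) and 16
  droplets (radius 0.30 ± 0.03 µm, a realistic droplet load for one
  macrophage field). Contacting droplets are placed with surface gap
  exactly 0 (tangent to a tubule, mostly laterally where the grid
  resolves the interface); the rest sit ≥ `gap_um` away. Ground truth is
  the voxelized noiseless geometry and its face-enumeration metrics,
  recorded before the PSF and noise. Radii are drawn first and contacting
  droplets placed first, so scenes differing only in `gap_um` share
  contacting geometry under one seed — which is what makes the
  gap-monotonicity property exactly testable.
* **Rendering** — a single anisotropic Gaussian PSF (σ = 0.03 µm,
  FWHM ≈ 70 nm, lattice-SIM²-class lateral resolution), uniform
  background (20), photon amplitude 200, Poisson shot noise. No
  depth-dependent aberration, reconstruction artifacts, drift, or
  photobleaching are modeled: passing tests show the pipelines are
  correct on resolvable, well-corrected data, not that they are robust to
  every real-world artifact.
* **CFU tables** — expected colonies `survival × titre × plated_ml /
  dilution`, Poisson-observed.

Replicate seeds derive from the master seed by fixed offsets (seed,
seed + 1, seed + 2; condition blocks offset by 10), so whole experiments
are reproducible from one integer.

## Calibrated presets

Published effects are folds; the underlying absolutes are not in the
available text, so the presets fix them once: PI-positive baseline 0.06 at
the lower temperature for the dual-treatment presets (11× → 0.66 at 40 °C,
7× → 0.42 at 38.5 °C — both integer cell counts out of 100); untreated
JC-1 ratio 2.0; mitochondrial damage, defined as
(untreated − treated)/untreated of the replicate-mean JC-1 ratio, 0.30 at
37 °C for the fold presets (so 1.7× → 0.51 and 1.2× → 0.36 at 40 °C,
safely below 1). The LL-37 preset's PI arm uses baseline 0.20 (20 → 34
cells) because 1.7 × 6 cells is not an integer and the planted-count rule
is exact. The activity preset plants a 0.6 treated/untreated quotient at
37 °C and 1.0 at 35 °C. The contact preset plants droplet contact
fractions 0.6 (low glucose, 37 °C) versus 0.15 (high glucose 37 °C; low
glucose 40 °C), and a biological replicate is the mean over 3 imaged
fields — one 8 × 8 µm field holds only ~16 droplets, and real replicate
statistics in this assay pool many cells per dish. These choices were made
once, from realism, and are not tuned.

## Numerical notes and limitations

Otsu uses 256 equal-width bins over the observed range and returns the
upper edge of the optimal bin; masks are strictly above the threshold.
The Gaussian blur uses clamp-to-edge boundaries and a 4σ kernel; the
morphology kernel treats out-of-volume neighbours as ±∞ (border faces can
never contact). Cell placement and droplet placement are rejection
samplers with bounded retry budgets that error with the achieved counts
rather than silently under-filling. Problem sizes throughout (100-cell
fields, 16-plane volumes, three replicates, three fields per contact
replicate) match the emulated experiments while keeping a full validation
run in minutes on one CPU.

Known limitations: contact at voxel scale is inherently quantized — a
tangent sphere/cylinder pair may voxelize to a handful of faces, so
per-droplet contact is noisy and only condition-level means are
meaningful; the phase-contrast channel is a flat darker-than-background
rendering, not an optical model; JC-1 aggregates/monomer puncta
substructure is not modeled, so subcellular ratio heterogeneity is absent;
and the Welch layer deliberately mirrors a no-correction, three-replicate
analysis convention rather than a modern multiple-testing workflow.
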