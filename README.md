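# ampfever

Quantification toolkit for the imaging and plate assays used to study how
fever-range temperatures change the antibacterial activity of antimicrobial
peptides (AMPs) and histones — and how host cells shield their mitochondria
while that happens. It is written for microscopists and microbiologists who
need reproducible, scriptable versions of four standard readouts:

* **Propidium iodide (PI) entry** in single bacteria: phase-contrast
  segmentation of rods, background-subtracted per-cell PI intensity, and the
  fraction of PI-positive cells per biological replicate.
* **JC-1 mitochondrial membrane potential** in macrophages: one
  segmentation applied to both channels, the per-cell red/green ratio
  (higher = healthier mitochondria), and a replicate-level mitochondrial
  damage statistic.
* **Lipid droplet (LD)–mitochondria contact** in two-channel 3D SIM-class
  stacks: Gaussian blur, white top-hat background subtraction, Otsu
  thresholding, and an anisotropy-aware voxel-face contact area normalized
  by total LD volume — the *contact ratio*.
* **CFU survival** from ten-fold serial-dilution droplet plates, with
  Welch (unequal-variance) t statistics, SEM over biological replicates,
  and propagated-error fold changes tying it all together.

Because raw microscopy for this kind of study is rarely deposited, the
package ships a first-class synthetic-data generator: rod-shaped bacteria
with bimodal PI intensity, round JC-1 macrophage fields with a controllable
red/green ratio, and 3D volumes of tubular mitochondria plus spherical
droplets at planted separations, all rendered with PSF blur, background and
shot noise from known ground truth. Calibrated presets plant the fold
effects the assays are meant to detect (11× and 7× PI synergy at febrile
temperatures, matched 1.7× mitochondrial-damage/PI increases for LL-37,
1.2× for OH-CATH, a 0.6 treated/untreated JC-1 quotient at 37 °C, and the
glucose/temperature contact ordering), so every pipeline can be validated
end to end against what was planted.

## The metrics

For a droplet mask $L$ and mitochondria mask $M$ on a voxel grid with
spacings $(\Delta_z, \Delta_y, \Delta_x)$ µm, a **contact face** is an
exposed droplet-surface face — a 6-neighbour pair $(a, b)$ with
$a \in L$, $b \notin L$ — whose far side reaches a mitochondrial voxel
within the configured distance (default 1 voxel: $b \in M$). Faces carry
their physical area ($\Delta_y\Delta_x$ for z-neighbours, etc.), and

$$\text{contact ratio} = \frac{\sum_{\text{faces}} A_{\text{face}}}
{N_L\,\Delta_z \Delta_y \Delta_x} \quad [\mu m^{-1}].$$

Per-cell statistics are always summarized per biological replicate first;
condition error bars are SEM over the (typically three) replicates. Fold
changes between conditions propagate first-order error,
$\sigma_F/F = \sqrt{(\sigma_a/\bar a)^2 + (\sigma_b/\bar b)^2}$, and
two-condition comparisons use Welch's $t$ with Welch–Satterthwaite degrees
of freedom — the only significance test in this workflow.

## Worked example

Generate one bacterial field with a planted 25% PI-positive fraction, run
the per-cell pipeline, and score positivity:

```r
library(ampfever)

fld <- make_bacteria_field(cell_field_config(positive_fraction = 0.25,
                                             seed = 42))
cells <- segment_cells(fld$phase, "rod") |>
  per_cell_intensity(fld$pi) |>
  classify_positive()
fraction_positive(cells)
#> # A tibble: 1 × 3
#>   n_cells n_positive fraction_positive
#>     <int>      <int>             <dbl>
#> 1     100         25              0.25
```

The pipeline found all 100 planted rods and recovered the planted fraction
exactly: the PI intensity distribution is bimodal (~58 vs ~603 counts above
background in this field), so the pooled Otsu cutoff separates the classes
cleanly. Replicate-level fractions then feed the statistical layer:

```r
tt <- welch_ttest(c(0.60, 0.67, 0.62), c(0.055, 0.062, 0.060))
tt
#> Welch two-sample t-test: t = 27.29, df = 2.040, p = 0.001205
#>   mean_x = 0.63 (n = 3), mean_y = 0.059 (n = 3)
tidy(tt)$p.value
#> [1] 0.001204558
```

A mean PI-positive fraction of 0.63 at the febrile condition against 0.059
at body temperature is a ~10.7-fold increase, significant despite only
three replicates per arm. `autoplot()` methods draw the matching per-cell
dot plots and mean ± SEM summaries; `run_cli()` (or the installed
`exec/ampfever` script) exposes `simulate`, `contact`, `cells`, `jc1`,
`cfu`, `stats`, and `reproduce` subcommands over the same functions.

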