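# perivasc

Quantifying how far a chemotherapeutic drug penetrates from tumor
microvessels in multi-channel fluorescence microscopy.

## The problem

Intraarterial therapies for liver cancer (hepatic artery infusion, with or
without embolization; drug–Lipiodol emulsions) aim to push chemotherapy
deeper into tumor tissue. Doxorubicin auto-fluoresces and vessels can be
labelled with the endothelial marker CD31, so a two-channel image of a tumor
section answers the question spatially: **for every drug deposit, how far is
it from the nearest blood vessel?**

`perivasc` is an R package for researchers running that assay. Given
per-field drug and vessel channels (TIFF + a manifest), it computes:

- **Penetration distance.** Vessel mask → exact Euclidean distance map
  (each pixel's distance in µm to the nearest vessel pixel) → drug spots as
  8-connected components, each reduced to its center point → per-spot
  nearest-vessel distance → field mean → animal mean over three fields.
- **Microvessel density (MVD)** by the hotspot convention: scan for the most
  intensely vascularized areas, count discrete vessel profiles (single
  endothelial cells or contiguous clusters) in three non-overlapping
  0.27 mm² windows, average the three counts.
- **Exposure summaries**: the fraction of tissue within each distance band
  that sees drug above the detection threshold, and intensity-versus-distance
  decay profiles.
- **Arm comparisons**: mean ± SD per (group × time point), pooled "Total"
  rows reconstructed exactly from equal-n subgroup summaries, one-way ANOVA
  (raw-data or summary-statistics form — the latter needs only a published
  mean/SD table), and Fisher LSD pairwise *t* tests.

Because such image sets are rarely deposited, the package also ships a
seeded **forward simulator**: edge-enriched vessel fields, spots placed
around perfused vessels at distances following an exponential law with
arm-specific scale λ, intensity decaying with distance, unperfused vessels,
avascular patches, necrosis masks — with full ground truth for every spot,
so the whole measurement chain is testable end to end.

## Worked example

Simulate one calibrated field (512 px at 1.02 µm/px, λ = 40 µm) and measure
it:

```r
library(perivasc)

res <- generate_field(synthetic_field_spec(
  width_px = 512, height_px = 512, pixel_pitch_um = 1.02,
  vessel_density_per_mm2 = 50, edge_enrichment = 1.5,
  spot_rate = 800, decay_scale_lambda_um = 40, seed = 2024
))
field_penetration(res$field, perivasc_config(
  drug_method = "fixed", drug_fixed_threshold = 15
))
#>             field_id mean_penetration_um spot_count vessel_count ...
#> 1 synthetic_seed2024               27.33        665           22
mean(res$truth$spots$true_distance_um)
#> [1] 25.38
```

The measured field mean (27.3 µm) tracks the ground-truth mean of the true
spot distances (25.4 µm); the residual gap at this small field size comes
from overlapping spot blobs merging into single components — the package's
validation quantifies exactly this and shows it stays within 3 standard
errors on validation-scale fields. Note the mean sits below λ because a
spot's *nearest* vessel is often not its source vessel.

Published-table arithmetic works straight from summaries — pooling a group's
two sacrifice-time subgroups (n = 4 each) into its Total row:

```r
combine_subgroups(
  tibble::tibble(n = 4, mean = 40.54, sd = 7.23),  # 10 minutes
  tibble::tibble(n = 4, mean = 32.68, sd = 8.73)   # 4 hours
)
#>       n  mean    sd
#> 1     8  36.6  8.53     # 36.61 ± 8.53
```

and a summary-statistics ANOVA needs only (n, mean, sd) per group — here the
baseline tumor diameters of four arms:

```r
fit <- anova_oneway(tibble::tibble(
  n = rep(8, 4), mean = c(1.53, 1.58, 1.63, 1.49),
  sd = c(0.27, 0.30, 0.25, 0.20)
))
glance(fit)
#>   statistic df_between df_within p.value mse_within method
#> 1     0.445          3        28   0.723     0.0664 summary
```

Whole studies run through three verbs: `run_simulate()` writes a synthetic
study (TIFF channels, manifest, ground truth) to disk, `run_measure()`
executes the measurement over a manifest and emits per-field, per-animal and
group-level CSVs plus comparison tables, `run_summarize()` turns any
per-animal table into the published-table shape. A thin CLI wrapper lives in
`inst/scripts/perivasc`.

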