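---
title: "Quantifying perivascular drug penetration: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying perivascular drug penetration: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perivasc)
```

## The measurement problem

Catheter-directed therapies for liver cancer deliver a chemotherapeutic —
typically doxorubicin — through the hepatic artery, sometimes followed by
embolization of the tumor-feeding vessel. Whether those techniques actually
move drug *deeper into the tissue* is a spatial question: doxorubicin is
auto-fluorescent, vessels can be labelled with the endothelial marker CD31,
and a two-channel fluorescence image of a tumor section lets one ask, for
every detected drug deposit, *how far is it from the nearest blood vessel?*

`perivasc` implements that measurement as a reusable pipeline:

1. **Vessel binarization.** The CD31 channel is converted to a binary mask.
   Pre-masked vessel images (vessels white on a zero background) use the rule
   *any non-zero pixel is vessel*; raw stain images can use Otsu's threshold
   or a fixed calibrated cut.
2. **Distance filter.** An exact Euclidean distance transform assigns every
   pixel its distance, in µm, to the center of the nearest vessel pixel.
   Vessel-interior pixels have distance 0.
3. **Spot detection.** The drug channel is thresholded (Otsu by default; a
   fixed threshold for calibrated studies) and 8-connected components of at
   least `min_spot_size` pixels become spots, each represented by its center
   point (the unweighted centroid).
4. **Per-spot distance.** Each spot reads the distance map at the single
   pixel nearest its centroid (rounding half away from zero). The field's
   penetration distance is the mean over its spots; an animal's value is the
   mean of its three fields.
5. **Microvessel density (MVD).** Following the hotspot convention, the
   vessel mask is scanned with a sliding window for the most intensely
   vascularized areas; discrete vessel profiles (single endothelial cells or
   contiguous stained clusters — one 8-connected component each) are counted
   in the three best non-overlapping 0.27 mm² windows and averaged.
6. **Group statistics.** Per-cell mean ± SD (n − 1 denominator), pooled
   "Total" rows across the two sacrifice times, one-way ANOVA across arms,
   and Fisher LSD pairwise *t* tests on the ANOVA's within-group mean square.

## Calibration

Microscope fields carry no pixel pitch, only printed field areas per
magnification: 6.82 mm² at ×40, 1.09 mm² at ×100, 0.27 mm² at ×200 (these
scale as the inverse square of magnification within rounding). Pitch is
therefore *derived*: `pitch = sqrt(area / (width * height))`, assuming square
pixels — a 1024×1024 ×100 field gives ≈ 1.020 µm/px. Channels whose raster
sizes disagree are aligned by nearest-neighbour resampling onto the drug
channel's grid, mirroring the overlay step used when the vessel image and
drug image of one field are captured separately. No sub-pixel registration is
attempted.

## Tunable parameters

| parameter | default | why |
|---|---|---|
| vessel threshold rule | `nonzero` | vessel images arrive pre-masked |
| drug threshold rule | `otsu` | raw auto-fluorescence has no calibrated cut |
| `min_spot_size` | 4 px | suppresses single-pixel noise components |
| `min_vessel_size` | 4 px | a countable vessel profile needs a few stained pixels |
| counting window | 0.27 mm² | the ×200 field of the hotspot convention |
| drug field window | 1.09 mm² | the ×100 field used for drug imaging |
| scan stride | window/4 | dense enough that hotspot scores approach the exhaustive scan |
| exclusion eligibility | ≤ 50 % excluded | a candidate field mostly inside necrosis is not a field |
| distance bands | 25 µm, 0–250 µm | exposure summaries at the scale of observed gradients |

Fields with no vessel pixel or no detected spot are **flagged, not scored
zero** — a zero would bias penetration downward — and flagged fields are
excluded from their animal's mean with a logged warning.

Connectivity is 8-connected for both spots and vessels: diagonal-touching
stained pixels are one cluster, matching the "connected cell cluster" notion
of the counting convention. Distances are measured between pixel centers, not
to a sub-pixel vessel boundary; each spot contributes the map value at its
center pixel rather than an average over its component.

## The synthetic-data generator

Real tissue images for this assay are not publicly deposited, so the package
ships a forward model that emulates the statistical structure the analysis
assumes, with full ground truth:

* **Vessels** follow an inhomogeneous Poisson process whose density rises
  linearly from `vessel_density_per_mm2` at one image edge to
  `edge_enrichment` times that at the other — vascularization in these tumors
  is most intense at the edge. Vessels render as disks (radius ≈ 5 ± 1.5 µm).
* **Spots** choose a perfused source vessel, a uniform direction, and a
  distance from a decay law — exponential with scale λ by default — measured
  from the vessel surface. A spot is redrawn if it lands outside the grid,
  inside any vessel, inside the avascular patch, or inside necrosis.
* **Intensity** at true distance *d* is `I0 * exp(-d / tau)` plus Gaussian
  background and a Poisson-like shot term. A configurable fraction of vessels
  is unperfused (CD31-positive but with no surrounding drug), and an optional
  avascular patch stays free of vessels and spots — the "no detectable drug
  in avascular regions" phenotype.
* **Ground truth** records every accepted spot's sampled distance and its
  true distance to the nearest vessel surface over *all* vessels, plus placed
  and rendered vessel counts and the necrosis mask.

Default arm parameters (λ and expected spot count per arm × time point) are
taken from the published group summaries of the rabbit VX2 study this assay
emulates, so a default `study_design()` reproduces its 4 arms × 2 sacrifice
times × 4 animals × 3 fields layout. These are **simulator inputs** — the
conditions being emulated — not values the pipeline is expected to output.
Per-field seeds derive deterministically from the master seed and the
(group, time, animal, field) indices, so any single field is regenerable in
isolation; identical spec + seed is bitwise-reproducible.

### What the simulator does not emulate

No point-spread function, channel bleed-through, vignetting, uneven
illumination, or autofluorescent background structure; noise is additive
Gaussian plus a shot term only. Vessels are disks, not elongated profiles.
Passing tests against this model therefore demonstrate that the *measurement
chain* is correct and unbiased under known geometry — they do not certify
segmentation robustness on real histology, where threshold choice and
artifact exclusion dominate.

### Known bias, bounded

Ground-truth distances are continuous (to the vessel surface); measured
distances are pixel-quantized (to the nearest vessel *pixel center*, read at
the spot's rounded centroid). This produces a small positive offset bounded
by about one pixel plus the disk-radius discretization. Validation therefore
runs on large sparse fields (2048 px at 0.7 µm/px, ≈ 50 vessels/mm²) where
blob merging is rare and the offset stays well inside 3 standard errors of
the ground-truth mean for λ ∈ {10, 40, 75} µm with ≥ 1000 spots — the
recovery checks in the test suite and the validation script recompute exactly
this.

## Numerical choices

* **Distance transform:** the two-pass separable lower-envelope algorithm
  (exact squared Euclidean distances; integer parabola arithmetic in
  doubles), checked pixel-for-pixel against brute-force nearest-vessel search
  on random masks to < 1e-9 µm, and cross-checked against an independent
  image library's transform.
* **Otsu threshold:** the classic cumulative-histogram form over 256 bins
  spanning the observed range, maximizing `w1 w2 (mu1 - mu2)^2`, boundary bin
  in the lower class, ties to the lowest cut. (An available library variant
  was rejected after it disagreed with the canonical statistic's argmax on a
  clean bimodal case; our implementation matches a brute-force scan and the
  Python reference implementation.)
* **Constant drug channels** under Otsu are flagged as spotless rather than
  thresholded arbitrarily; constant-channel Otsu is a typed error
  (`DegenerateHistogram`) at the operator level.
* **Hotspot tie-break:** windows scored equal resolve in raster order
  (smallest row, then column); the three chosen windows are pairwise
  non-overlapping so one hotspot is never triple-counted.
* **Pooled "Total" rows** use the exact identity for the sample SD of the
  union of two equal-sized subgroups reconstructed from their summaries —
  with `n` the subgroup size:
  `sd = sqrt(((n-1)(s1² + s2²) + n((m1-m)² + (m2-m)²)) / (2n-1))`.
  This reproduces the published Total cells at 2-decimal rounding, except
  two cells that are internally inconsistent in print (one MVD mean, one
  penetration mean off by one rounding step); those are documented and
  excluded from exact checks.
* **ANOVA:** raw-data route via `stats::aov`; summary-statistics route from
  `SSB = Σ nᵢ(mᵢ - m̄)²`, `SSW = Σ (nᵢ-1)sᵢ²`. The routes agree to 1e-10 and
  the null type-I error calibrates to 0.05 ± 0.015 over 2000 simulated
  studies. Groups with exactly zero within-group variance are a typed
  degenerate error. LSD *t* tests are deliberately unadjusted for
  multiplicity (that is what LSD is) and say so in their output.
* **Report rounding** is half-away-from-zero at 2 decimals, matching how
  such tables are printed; internal files keep full precision.

## Problem sizes used in the shipped checks

The package's own validation (test suite and `scripts/acceptance.R`) chooses
sizes that exercise every code path at full fidelity where it matters and
scaled down where only orderings are at stake: oracle equivalence on 200
random masks up to 64×64; λ-recovery on three full-resolution 2048² fields;
arm-ordering recovery on 20 replicate studies of 3 arms × 4 animals × 3
fields at 256 px / 2 µm with spot rates at one eighth of the published
counts (λ, which drives the ordering, stays at published scale). The
spot-count scale factor affects counting statistics only, not the distance
law being recovered.

## Limitations

* Two-dimensional sections overestimate true 3-D distances — the nearest
  vessel may lie out of plane. No multi-section reconstruction is attempted.
* Necrosis and artifact exclusion masks are *inputs* (hand-drawn or
  simulator-provided); the package does not auto-segment necrosis.
* Field-within-animal nesting is averaged out before statistics (three
  fields → one animal value), matching the source design; no mixed-effects
  modelling is offered.
* The drug-field and MVD-field selections are independent procedures; whether
  they should coincide spatially is left to the study design.
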