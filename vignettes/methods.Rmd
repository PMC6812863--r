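---
title: "Methods: 3D cytoplasm volumetry on synthetic confocal stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D cytoplasm volumetry on synthetic confocal stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytovol3d)
```

## The measurement problem

Immunofluorescence studies of CD30-positive cells in lymphoid tissue (classical
Hodgkin lymphoma and reactive lymphadenopathies) quantify three things from
two-channel confocal z-stacks: how much of the imaged tissue volume is
marker-positive cytoplasm, how that volume is split between multi-cell
*networks* (aggregates of at least three cells), *single cells* and *undefined*
edge fragments, and how large a typical single cell's stained cytoplasm is.
The marker stains the membrane and cytoplasm that surround the nucleus; the
nucleus itself is DAPI-stained and excluded from all volumes. Negative-control
sections calibrate the removal of small artifacts (antibody precipitates,
nonspecific binding).

`cytovol3d` implements this measurement chain as a reusable, deterministic
pipeline, and — because the original tissue stacks of such studies are rarely
deposited — ships a synthetic stack generator with voxel-level ground truth,
so every stage is testable end to end by parameter recovery.

## Data model and volumetry

A stack is a pair of 3D arrays in fixed `(Z, Y, X)` axis order plus an
anisotropic voxel spacing in micrometres. All volumes are physical:
`voxel_count * dx * dy * dz`, with no resampling to isotropic grids. The
default spacing mirrors a 63x confocal acquisition (a 365 x 375 um field at
1024 x 1024 px), but every geometric quantity is configuration, not constant.

The segmentation chain is:

1. **Threshold** the marker channel. The default is Otsu's method on the 3D
   histogram; an *absolute intensity* threshold is the faithful analogue of
   surface reconstruction by absolute intensity in commercial confocal
   software and is the recommended mode when the imaging levels are known.
   Otsu has a documented failure mode: when the foreground occupies well
   under ~1% of voxels over a noisy background, maximizing between-class
   variance prefers splitting the dominant background mode, and the threshold
   collapses into the noise. This is why the nucleus channel of sparse stacks
   (a few nuclei in tens of millions of voxels) should use an absolute
   threshold, and why the applied threshold is always logged.
2. **Exclude nucleus voxels** (`marker AND NOT nucleus`), so cytoplasm volumes
   never count nuclear voxels even when channels bleed.
3. **Label 3D connected components** (26-connectivity by default, since
   surface-based tools merge any voxel contact; 6 and 18 are available because
   the network statistic is sensitive to the choice).
4. **Remove artifact-scale objects**. The cutoff is calibrated from a paired
   negative control: `(1 + margin) x` the largest control component volume
   (margin 0.10). The control is thresholded with the *sample-derived*
   threshold applied as an absolute value — an automatic threshold computed on
   a control that has no foreground mode would split its background noise and
   produce a meaningless cutoff.

Classification counts nuclei per component. Nuclei are detected on the DAPI
channel (threshold, label, drop components below 30 um^3), then each nucleus
is assigned to the nearest marker component within 2 um, measured from the
nucleus *region* rather than its centroid: shells surround nuclei, so an
enclosed nucleus is at distance ~0 from its shell while its centroid is a full
nucleus radius away. The rules then fire in fixed order: border-touching
components are undefined (`UD`) regardless of size; interior components with
at least 3 effective nuclei are networks (`NW`); 1-2 nuclei are single cells
(`SC`, pairs are counted separately for auditability); interior survivors with
0 nuclei are `UD`. Multinucleated cells are handled by `nuclei_per_cell`,
which divides counts (rounding up) before the rules.

Per stack, the pipeline reports the marker-positive volume fraction of the
imaged volume, NW/SC/UD volume shares (summing to 100 when any marker volume
exists), and the mean and n-1 sample SD of single-cell volumes. Entity-level
summaries average fractions and single-cell means across stacks and pool
class shares weighted by each stack's marker-positive volume.

## The synthetic generator

Cells are spherical shells: marker-positive cytoplasm between the nucleus
radius and the outer radius, with a solid DAPI nucleus inside. This is the
simplest geometry consistent with "stained membrane and cytoplasm
surrounding an unstained nucleus", and it has a closed-form volume
`(4/3) pi (r_outer^3 - r_nucleus^3)` that serves as an analytic oracle.
Aggregates are rendered either with overlapping shells (centers at 0.95 x the
radius sum) or joined by cylindrical protrusions (radius 0.6 um) — a
deliberate idealization of filigree cell protrusions, for which no
quantitative geometry is published. After digitization each aggregate is
verified to be one 26-connected component; a pinched-off protrusion is
repaired by widening. Distinct aggregates are kept at least 2 um apart, so
separability of networks is guaranteed by construction, and placement is
rejection sampling with an explicit overcrowding error rather than silent
overlap.

Speckle artifacts are marker-only spheres. Every profile renders its first
artifact at exactly `artifact_radius_max`, so a control generated from the
same profile always bounds the artifact sizes of the paired sample stack —
that is what makes the control-derived cutoff a guarantee instead of a
heuristic. Profile validation rejects any configuration whose largest
artifact volume is not strictly below the smallest cell cytoplasm volume.

Noise is additive Gaussian on a constant background, rounded and clamped to
integer intensities; all randomness derives from the profile seed, making
stacks bit-reproducible.

### Calibrating presets to reported tissue values

The five entity presets (LAD, AD, NScHL, MCcHL, MCcHL_EBV) encode reported
tissue measurements: volume fractions 1.51 / 1.99 / 5.99 / 3.13 / 2.23
percent and single-cell cytoplasm means 464 / 458 / 672 / 978 / 1335 um^3.
Two calibration choices deserve explanation:

* **Within-stack volume CV of 20%.** Published per-entity SDs describe
  dispersion *across cases*, not across the cells of one stack; no
  within-stack distribution is published. We fix the per-cell volume CV at
  20% and solve the outer-radius distribution from
  `E[(4/3) pi (1 - f^3) r^3] = mu^3 + 3 mu sigma^2` (with
  `sigma = cv/3 * mu`), so the *mean* single-cell volume is matched exactly
  while the spread is an explicit, documented model choice.
* **Deterministic composition.** Drawing aggregate sizes i.i.d. would make
  the realized network share of a ~20-cell stack so variable that no
  recovery test could be meaningful. Instead the nominal aggregate-size
  distribution is realized by a largest-remainder quota on cell-weighted
  shares: a 20-cell LAD stack contains exactly 14 solitary cells and two
  3-cell networks (30% network share). The network-dominance values (75% for
  NScHL, 30-35% elsewhere) reflect the reported qualitative contrast; the
  aggregate-size distributions behind them are ad hoc, as no quantitative
  network-size data exist.

When `target_volume_fraction` is set, the cell budget is derived from the
stack volume and the drawn radii are rescaled (bounded to [0.8, 1.25]) so the
analytic cytoplasm total meets the budget.

## Recovery study design

The package's own validation study (see `tests/testthat/test-acceptance.R`
and `scripts/acceptance.R`) uses a desk-scale grid chosen as follows: lateral
spacing as in the 1024-px acquisition (0.356 x 0.366 um), but 48 planes at a
0.48 um z-step instead of hundreds of planes at 0.13 um. The axial step is
within realistic confocal sampling, keeps at least four slices across the
thinnest cytoplasm shell, and keeps a five-entity, five-seed study within
minutes on one CPU. Per entity, the lateral field is sized so that 20 cells
of the preset's mean volume realize the preset's volume fraction. One
negative control (hence one artifact cutoff) is used per entity, as a lab
would scan one control per batch. Both channels are thresholded with the
faithful absolute mode at the midpoint of the generator's background (20) and
foreground (200) levels, i.e. 110 — more than 4.5 noise SDs from both modes
at the study's noise level (SD 20, 10% of foreground).

With this design, recovered volume fractions, network shares and single-cell
means land within a few percent of the preset truths for all five entities,
comfortably inside the 15% tolerance the tests assert, and reproduce the
entity ordering NScHL > MCcHL > AD ~ LAD.

```{r recovery, eval = FALSE}
sp <- voxel_spacing(365 / 1024, 375 / 1024, 0.48)
p <- entity_preset("NScHL", seed = 1)
syn <- generate_stack(p, shape = c(48, 272, 272), spacing = sp)
ctrl <- generate_control_stack(p, shape = c(48, 272, 272), spacing = sp)
cfg <- run_config(threshold_method = "absolute", threshold_value = 110,
                  nucleus_threshold_method = "absolute",
                  nucleus_threshold_value = 110, entity = "NScHL")
run_pipeline(cfg, stack = syn$stack, control = ctrl)
```

## Limitations

* Sphere-shell cells and cylindrical protrusions are geometric idealizations;
  the generator validates the *pipeline*, not biological realism. Recovery on
  synthetic data bounds algorithmic error only.
* Cell count is operationalized as nucleus count. Touching nuclei merge under
  threshold-based detection (an undercount the tests exercise deliberately);
  multinucleated cells inflate counts unless `nuclei_per_cell` is set.
* Otsu thresholding is unreliable for very sparse foregrounds (see above);
  the absolute mode exists for exactly that case.
* The noise model is additive Gaussian; no Poisson shot noise or PSF blur.
* No inferential statistics are computed — the measurement chain reports
  descriptive means and SDs only.
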