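---
title: "Quantifying proliferation of transfected cells from three-channel images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying proliferation of transfected cells from three-channel images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prolifscan)
```

## The assay and its automation

EdU incorporation assays measure DNA synthesis: cells in S-phase take up the
thymidine analogue and show a nuclear EdU signal. When the question is whether
an ectopically expressed protein inhibits proliferation, three channels are
acquired per field: DAPI (all nuclei), a Flag immunofluorescence channel
(transfected cells carrying the tagged construct), and EdU (proliferating
cells). The quantity of interest is the *proliferation rate of transfected
cells*: the fraction of Flag-positive cells that are also EdU-positive. In
control-transfected (empty vector) conditions, where the tag carries no
biology, the rate of all EdU-positive cells over all cells is used instead.

prolifscan automates the full chain: nucleus segmentation on DAPI, per-nucleus
signal measurement on Flag and EdU, threshold-based classification,
condition-level rates, and group statistics. A synthetic field generator with
exported ground truth makes every stage testable without microscope data.

## Nucleus segmentation

Segmentation composes four stages, each exposed as its own function:

1. **Difference of Gaussians** (`dog_filter`). The DAPI image is convolved
   with two normalized Gaussian kernels and the wide blur is subtracted from
   the narrow one: `blur(I, sigma_low) - blur(I, sigma_high)`. The narrow
   kernel suppresses pixel noise, the wide one estimates smooth background
   (uneven illumination, glass autofluorescence), so the difference is a
   band-pass that leaves compact nucleus-sized structures. Defaults are
   `sigma_low = 1` px and `sigma_high = 15` px: a nucleus of radius ~8 px sits
   comfortably inside the pass band. Descriptions of this filter sometimes
   swap the roles of the two sigmas; this implementation follows the standard
   semantics (narrow minus wide) and exposes both sigmas, so either convention
   can be configured. Kernels are truncated at 3 sigma; borders are handled by
   replication, with the image replicate-padded first so that wide kernels
   also work on small images.

2. **Adaptive k-means thresholding** (`kmeans_threshold`). Pixel intensities
   of the preprocessed image are clustered into `k` groups by minimizing the
   within-cluster squared error; the brightest cluster is foreground. For the
   default `k = 2` the 1-D k-means objective is solved *exactly* by exhaustive
   split-point search over the intensity histogram (prefix sums make this
   linear in the number of distinct values). This removes the initialization
   nondeterminism of Lloyd iterations while optimizing the identical
   objective; the returned threshold is the midpoint between the clusters'
   adjacent edges. A constant image has no threshold and raises an error
   rather than guessing. For `k > 2`, Lloyd iterations run from
   quantile-spaced centers and only the brightest cluster is foreground.

3. **Hybrid watershed** (`hybrid_watershed`). "Hybrid" here means the
   combination of the binary threshold mask with watershed flooding: the
   Euclidean distance transform of the mask is computed, its regional maxima
   (subject to an h-maxima depth, `watershed_tolerance`) seed the objects, and
   the inverted distance map is flooded so fused nuclei split along the
   watershed lines. Intensities do not enter the flooding; the source image
   travels alongside only for the acceptance filter that follows. Flooding
   ties are resolved in raster-scan order, which makes label maps
   deterministic. The tolerance default of 0.3 px was calibrated on the
   synthetic generator: larger values leave deliberately fused pairs merged,
   smaller values begin to oversplit single nuclei.

4. **Acceptance filter** (`filter_regions`). Each candidate region's mean
   intensity on the *original* DAPI image must reach `min_mean_intensity`
   (default 0.2 on the [0, 1] scale — nuclei simulate at ~0.55 over a ≤0.07
   background) and its area must reach `min_region_area` (default 40 px;
   an intensity-only criterion admits single-pixel noise specks, so a size
   floor is applied as well). Survivors are relabeled 1..n. Border clearing is
   available but off by default. Coordinates are 0-based `(row, col)`; areas
   are reported in px and µm² via the configured pixel size.

## Per-cell measurement and classification

The Flag channel is preprocessed with the *identical* DoG filter and averaged
over each nucleus's pixels; the nuclear EdU signal is averaged directly over
the nucleus regions. Measuring Flag on the nucleus mask only (optionally
dilated by `dilate_radius`) is a deliberate choice: the nucleus is the one
region known to belong to the cell without a cytoplasm segmentation.

Transfection calling automates the manual threshold-from-histogram step of
the bench workflow. The per-cell Flag intensities are split into two
components by the same exact within-class-variance criterion; all-positive
(raw) intensities are split on the log scale, where fluorescence modes are
roughly symmetric, while signed DoG-scale measurements are split linearly
(the band-passed background mode is approximately symmetric around zero and
a log transform would stretch its lower tail into a spurious third mode).
Bimodality is accepted when Ashman's D of the two components — their mean
difference standardized by `sqrt(2 (s1^2 + s2^2))`, computed on the original
intensity scale — is at least 2, the conventional point at which two Gaussian
modes are visually distinct. Otherwise a warning is emitted and a configured
fallback quantile (default 0.75) is used; a numeric `flag_threshold` always
overrides. Within `run_pipeline` the threshold is selected once from the
pooled cells of all fields, mirroring the one-threshold-per-experiment
convention.

Boundary semantics are explicit and configurable: transfection is strict
(`mean_flag > threshold`, plus an inclusive absolute floor
`flag_min_intensity`), EdU positivity is inclusive
(`mean_edu >= edu_min_intensity`, default 0.25 — midway between the simulated
EdU-negative (~0.04) and EdU-positive (~0.55) levels). EdU uses a fixed
minimum-intensity threshold rather than a distribution split because EdU
positivity is a per-cell on/off state tied to S-phase, and its positive mode
can be nearly empty in strongly inhibited conditions, where a split would be
unstable.

## Rates and statistics

`proliferation_rate` implements the two-branch definition (transfected
double-positives over transfected cells; control: EdU-positives over all
cells) with explicit errors on empty denominators, naming the condition.
`compare_groups` runs the comparison chain: Levene's test (mean-centred, the
SPSS convention) must give P > 0.05 before a one-way ANOVA and Tukey HSD
post hoc comparisons are fitted; stars follow the conventional mapping
(*P < 0.05, **P < 0.01, ***P < 0.001). When Levene fails, the violation is
reported and only descriptive statistics are returned — the chain does not
silently switch to a nonparametric test, so the analyst sees the violation.
Note a structural consequence: under homogeneous variances Levene still fails
5% of the time by construction, so a fraction of perfectly well-behaved
experiments end without an ANOVA verdict. The two-sample `two_group_test` is
pooled-variance by default (consistent with Levene prescreening), Welch by
flag, with p = 1 by convention when both groups are constant and equal.

## The synthetic generator

`simulate_field` emulates the statistical structure the pipeline assumes,
not optics. Nuclei are mildly elliptical discs (eccentricity up to 0.15) with
a flat top and a Gaussian edge taper (sigma 1.2 px, truncated 3 px beyond the
boundary); ground-truth masks are the analytic ellipses, so at zero noise the
mean of any channel over a true mask equals the drawn per-cell level exactly —
several tests rely on this. Default conditions: 512×512 px at 0.65 µm/px,
300 nuclei of radius 8 ± 1.2 px, 10% of cells placed at centre distances
0.65–0.80 of the summed radii so their blobs fuse (the cases the watershed
must split), transfected fraction 0.40, EdU fraction 0.20 in transfected and
0.50 in control cells, DAPI level 0.55 ± 0.08, Flag modes 0.06/0.50 ± 0.06,
EdU modes 0.04/0.55 ± 0.06, a smooth sinusoidal background of amplitude 0.05
per channel and additive Gaussian noise of SD 0.02 (signal-to-noise ≈ 27).
These are realistic for a well-exposed slide-scanner field; sample sizes
(300-cell fields, 500 cells for classification checks, 3 replicates per
condition, 20 seeded runs for the sensitivity study) were chosen as typical
of the assay. Placement is rejection sampling with bounded attempts; an
over-packed configuration raises an explicit error. A single seeded RNG
stream drives the whole field, restored afterwards, so identical
configurations are bit-identical; channels quantize to 16-bit on TIFF export.

What the generator does *not* emulate: point-spread blur, chromatic shifts,
cytoplasmic Flag signal, clumps of more than a few cells, debris, or
intensity-dependent (shot) noise. Passing tests therefore demonstrate the
pipeline's correctness under its stated model — clean roundish nuclei on
smooth background — not robustness to every real-world artifact.

## Numerical choices and degenerate inputs

- Exact 1-D 2-means via histogram prefix sums; deterministic, seed-free.
- Watershed ties: raster-scan order. Label maps always relabel to 1..n.
- Constant images: thresholding errors; empty masks: zero-region label maps
  (not an error); empty label maps: empty record tables.
- ΔΔCt is implemented exactly as conventionally printed for this assay:
  ΔΔCt = ΔCt(control) − ΔCt(condition), fold = 2^(−ΔΔCt), replicates
  aggregated by arithmetic mean. Note the consequence of this sign
  convention: a condition whose target Ct *rises* (less transcript) yields a
  fold change above 1. The more common convention reverses the subtraction;
  this one is kept deliberately and prominently documented.
- Spreading areas exactly at the 120 µm² cutoff count as "below".
- Docking contacts use all atoms by default (`ca_only` available); a model is
  a contact when its minimum atomic distance to the receptor's reference
  residues (default 376–382) is *strictly* below the cutoff (default 10 Å).
- Alanine cassettes must tile the scanned region exactly; a region length
  not divisible by the cassette length is an error, not a truncation.

## Known limitations

Heavily overlapped nucleus pairs with unequal radii can defeat the
distance-transform watershed: across seeds, recovered counts on
deliberately-fused synthetic fields stay within ±5% of truth, but exact
recovery of every fused pair on every field is not achieved at any single
tolerance — lower tolerances oversplit as often as they rescue a merge. The
transfection threshold assumes a two-mode Flag distribution; with very low
or very high transfection efficiency the automatic split falls back to a
quantile and should be overridden manually. The statistics layer treats
replicate rates as exchangeable and offers no mixed models or batch
correction.
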