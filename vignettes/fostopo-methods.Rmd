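---
title: "Methods: topographic c-Fos analysis in dorsal CA1"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: topographic c-Fos analysis in dorsal CA1}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fostopo)
```

This vignette documents the models, conventions and design choices behind
`fostopo`. It is the reference for *why* the defaults are what they are;
the function reference documents *what* each function computes.

## The grid model

Dorsal CA1 is discretized into a fixed grid: 12 coronal sections along the
antero-posterior (AP) axis, labelled with bregma coordinates from −1.22 to
−1.92 mm, each carrying a row of contiguous 200 µm-wide counting ROIs along
the proximo-distal (PD) axis, in two hemispheres. The four most anterior
sections carry 8 ROIs, the four medial ones 10, the four posterior ones 12
(120 nominal positions per hemisphere). ROI index 1 is the most **distal**
position (nearest the subiculum, anchored at the ventricle midline);
indices grow toward proximal CA1. A configurable flip
(`default_subregion_scheme(flip_pd = TRUE)`) reverses this orientation if a
laboratory anchors ROIs from the proximal end.

**Subregions.** Crossing AP bands (anterior = sections 1–4, medial = 5–8,
posterior = 9–12; equal thirds) with PD bands of the ROI index
(distal = 1–4, central = 5–8, proximal = 9+) yields eight subregions — AD,
AC, MD, MC, MP, PD, PC, PP — with no antero-proximal block because anterior
sections stop at ROI 8. Under this uniform banding every subregion contains
16 ROIs per hemisphere except the medio-proximal one, which contains 8
(4 medial sections × ROIs 9–10). Published descriptions of this scheme
state 16 everywhere with 10 in MP; no uniform section-by-ROI banding can
produce a 10-ROI medio-proximal block, so the scheme is kept uniform and is
exposed as a configuration object (`default_subregion_scheme()`) so an
alternative, irregular assignment can be supplied if a laboratory's
convention requires one.

**Distances.** All spatial rules operate in grid-index units:
`d = sqrt((Δsection)^2 + (Δroi)^2)`, within a hemisphere only. A radius of
"5" in this metric spans about 5 ROIs laterally (≈ 1 mm of tissue) or 5
alternate sections axially; physical anisotropy between the axes is
deliberately ignored because the neighbor rule it serves is defined on
indices. Cross-hemisphere distances are undefined and raise an error —
mirrored positions are anatomically, not spatially, related.

**Missing data.** Damaged or unscorable ROIs are encoded by *absence* of a
row in the count table, never by a zero (zero is a legitimate count). Every
downstream mean excludes missing ROIs from its denominator, and a subregion
with no sampled ROI for an animal is reported absent (`NA`), not zero.

## The synthetic cohort generator

The generator is first-class, tested code: it defines the study conditions
under which the pipeline's statistical behavior is validated. Per-ROI
counts follow

$$\text{count} \sim \mathrm{NegBin}(\mu, \theta), \qquad
\mu = \beta \cdot e_g(\text{subregion}) \cdot A \cdot S(\text{section, roi}),$$

with baseline $\beta$, group effect field $e_g$, a per-animal lognormal
mean-one multiplier $A$ (shared by both hemispheres), and a mean-one
log-Gaussian spatial field $S$ generated per hemisphere by smoothing white
noise on the section × ROI lattice with a Gaussian kernel of scale equal
to the correlation length, standardizing the log-field to a fixed marginal
SD, exponentiating, and normalizing to mean one over the grid. Holding the
marginal SD fixed across correlation lengths means the correlation length
changes only the *spatial coherence* of high-count patches, not the
marginal overdispersion — a correlation length of 0 disables spatial
structure entirely. ROI positions drop out independently with a fixed
probability.

Default values, chosen once and frozen:

| parameter | default | rationale |
|---|---|---|
| group sizes | 14 / 6 / 7 | control / massed / distributed cohort sizes of the emulated design |
| baseline | 20.4 cells/ROI | control grand mean of the emulated study |
| massed field | MD 1.4, MC 1.8, MP 3.1588 | medial elevation peaking medio-proximally; solved analytically (given subregion sizes 16/16/8) so the expected massed grand mean is 26.6 |
| distributed field | PD 2.4, PC 2.2, PP 1.6721 | posterior elevation peaking postero-distally/centrally; solved so the expected grand mean is 29.3 |
| dispersion $\theta$ | 8 | per-ROI counts overdispersed relative to Poisson (SD ≈ 8 at $\mu$ = 20), a typical nucleus-count regime |
| animal effect SD | 0.35 (log scale) | makes simulated between-animal SEMs bracket the reported ones (±2.4 to ±5.6 at these group sizes) |
| spatial corr. length | 2 index units | produces contiguous multi-ROI high-count patches of the size the clustering rule targets |
| spatial log-SD | 0.5 | patch amplitude; occasional control-animal patches cross the count-40 bar, so control clustered counts are small but nonzero |
| dropout | 1 − 89/120 ≈ 0.258 | expected ≈ 89 sampled ROIs per animal and hemisphere (reported range 87–90) |

The generator emulates: group differences in regional means, spatially
coherent high-count clusters, between-animal variability, and random
missingness. It does **not** emulate: staining-batch effects, AP gradients
within a subregion, spatially structured (e.g. edge-concentrated)
missingness, left–right asymmetries, or section-to-section registration
error. Passing tests therefore demonstrate correctness of the *computations*
and sensible statistical behavior under a plausible generative model — not
that real histology satisfies that model.

The stained-section renderer draws dark nuclear disks (nickel-DAB polarity)
on a light noisy background inside a band representing the pyramidal layer.
Placement rejects any center closer than twice the maximum radius (plus a
guard gap) to another, keeps disks fully inside the band, and keeps centers
a small margin away from ROI box edges; by construction the per-box ground
truth equals the requested counts, so the detector can be scored exactly.

## Nucleus detection

The detection contract is intensity-relative-to-background with a size
filter: the background is the global median (robust to ≤ 50% contamination;
a percentile estimator is available), spread is the MAD, and pixels darker
than `background − k·MAD` (k = 3 by default) form the mask. Connected
components (8-connectivity by default, 4 available) with area inside
[20, 250] px² are accepted. The procedure is deterministic and equivariant
to intensity shifts since both location and spread are re-estimated per
image. Touching-nucleus splitting (watershed) is intentionally absent: the
detection contract does not define it, and the renderer excludes overlap,
so adding one would be validated against nothing. On real, denser material
the counts would under-split and this stage should be replaced while
keeping the per-ROI tally interface. A detection centroid exactly on a
shared ROI-box edge belongs to the lower-index (more distal) box.

## Statistical conventions

- **Hemisphere pooling.** For heat maps and subregion means, the two
  hemispheres are averaged where both are sampled, else the sampled one is
  used. For the shared-pattern statistic a position is "above threshold"
  when either hemisphere is (configurable to per-hemisphere). The
  classifier keeps hemispheres as separate features.
- **Subregion ANOVA** is a fixed-effects one-way ANOVA on per-animal
  subregion means, with Tukey HSD (automatically Tukey–Kramer under
  unequal group sizes) for the three pairwise contrasts.
- **Frequency bins** are 0–10, 11–20, …, 91–100, *upper-edge inclusive*
  (a count of 20 falls in 11–20), as percentages of each animal's sampled
  ROIs. Counts above 100 go to an explicit overflow bin with a warning.
  Bins are compared across groups with the two-sided Mann–Whitney U on
  per-animal percentages (normal approximation with tie correction);
  all-tied bins are flagged degenerate instead of tested. All bins are
  tested and reported, not a pre-selected subset.
- **Clustering rule.** "Within 5" is closed (≤ 5, flag for strict); the
  neighbor count excludes the ROI itself; neighborhoods never cross
  hemispheres; the output depends only on the above-threshold mask, never
  on count magnitudes beyond it. Group comparisons of per-animal clustered
  counts use two-sided pooled-variance t tests; zero-variance pairs are
  flagged rather than tested.
- **Shared-pattern rule.** The threshold is the pooled mean of all sampled
  control ROI counts rounded half-up (the emulated study prints 23 from a
  control mean reported elsewhere as 20.4 ± 2.4 — the two are consistent
  only under different pooling, so the rule, not the constant, is
  implemented; the constant can be forced via
  `shared_pattern_params(threshold = 23)`). The animal rule defaults to
  "n − 1 of n", auto-resolved per group (5/6, 6/7, 13/14 at the default
  sizes); `shared_sweep()` exposes the robustness sweep over smaller
  quorums. Missing ROIs count as below threshold.
- **Two-sided tests throughout**; no multiplicity correction beyond Tukey
  HSD is applied, matching the descriptive character of the analysis.

## Classification

The feature table has one record per (animal, section, ROI) position —
necessarily so, because the grid coordinates themselves are features. The
ten features are the section and ROI indices, the two hemisphere counts
and their mean, the pooled above-threshold flag, the per-section number of
above-threshold positions, and the per-hemisphere counts of 8-adjacent
above-threshold positions with their mean. Positions sampled in a single
hemisphere are completed by copying the sampled count (default) or dropped;
the published feature list names "ROI" and "ROI number" as distinct
variables without defining them, and this package fixes them as the
above-threshold flag and the PD index respectively — a declared convention.

QDA uses class-specific covariance estimates regularized by
$\Sigma_k + \lambda\,(\mathrm{tr}\,\Sigma_k/d)\,I$ with $\lambda = 10^{-6}$,
enough to invert the exact collinearity of `cell_count_both` with its two
parents after per-feature z-scoring on the training data. Score ties are
resolved in class-level order and logged. Cross-validation defaults to
record-level folds (the straightforward cross-validation call the emulated
Methods describe); because records of one animal are correlated, this
leaks animal identity across folds and flatters accuracy — animal-grouped
folds (`grouping = "animal"`) are provided and recommended for inference
about animals. Folds are assigned from the seed after sorting records by
their stable key, so results are invariant to row order.

**A structural caveat on feature importance.** Importance is the per-feature
Kruskal–Wallis H across class labels, normalized to fractions. Because
every animal samples (up to dropout) the same grid, the *marginal*
distribution of the section index is identical across groups by
construction, so its H hovers at the null level regardless of how strongly
group effects vary along the AP axis: under this record unit and this
importance measure, coordinate indices cannot rank highly even when
location is what separates the groups (the QDA itself *can* exploit
location, through class-specific covariances between coordinates and
counts). An importance measure that credited location would need a
different feature semantic — e.g. per-section count profiles — which is
outside the feature contract adopted here.

## Numerical choices and degenerate inputs

- All randomness flows from explicit integer seeds; the generator restores
  the caller's RNG state. Identical configuration + seed reproduces every
  artifact byte for byte (the run manifest records a configuration hash).
- Rounding of the control threshold is half-up (22.5 → 23).
- Monte-Carlo problem sizes used by the test suite: 200 randomized grids
  per brute-force oracle, 200 simulated cohorts for type-I and power
  checks, 100 for the clustering/shared orderings, 50 for classifier
  orderings, 50 rendered images — sizes at which the binomial error of the
  checked proportions is well below the margins being asserted.
- Degenerate inputs have defined behavior rather than accidents: empty
  masks return empty sets; groups with fewer than two animals are rejected
  by name; zero-variance t tests and all-tied bins are flagged; a singular
  covariance at $\lambda = 0$ raises an error advising regularization;
  unplaceable nucleus densities name the remedy (larger band or smaller
  radii).

## Known limitations

- The uniform subregion banding gives MP 8 ROIs per hemisphere, not the
  published 10 (see above); subregion-resolved comparisons with published
  MP values should account for this.
- The generator's dropout is spatially uniform; real missingness is often
  edge- or artifact-concentrated.
- Record-level cross-validation overstates animal-level predictive
  accuracy (leakage caveat above).
- The detector assumes non-touching nuclei and homogeneous illumination;
  it is validated on the renderer's ground truth, not on real stains.
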