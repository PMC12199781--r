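---
title: "Lesion network mapping with lnmapper: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion network mapping with lnmapper: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The procedure

Lesion network mapping infers the brain network functionally connected
to a cohort of symptom-causing lesions. Its inputs are binary lesion
masks (one per case, possibly multi-focal, all on one voxel grid) and a
normative connectome: resting-state BOLD data from healthy subjects on
the same grid. For each case the lesion is a seed: the BOLD signal is
averaged over the lesion's voxels, correlated with every other in-mask
voxel in every connectome subject, and the per-subject Pearson r values
are summarized voxel-wise by a one-sample t-test into the case's T-map
(df = number of subjects − 1). Two aggregation routes then produce the
group-level lesion network map (LNM):

* **Binary overlap** — each T-map is thresholded at t > 7
  (strictly greater), binarized, and summed across cases; the LNM keeps
  voxels connected to at least a fraction `frac` of cases, with
  `min_count = ceiling(frac * n_cases)`. At the defaults
  (`frac = 0.95`, 23 cases) that is 22 of 23 cases. The t = 7 cutoff
  corresponds to a two-sided uncorrected tail probability of about
  3.1e-10 at df = 99 (`tmap_threshold_pvalue(7, 99)`), far below the
  conventional 0.001.
* **Sign-flip permutation** — a voxel-wise one-sample t across the case
  T-maps, with a null built by independently negating whole case maps,
  and family-wise error control by the permutation distribution of the
  image-wide maximum statistic.

Around the core map sit a two-sample permutation contrast against
control cohorts (specificity), leave-k-out resampling (stability), a
winner-takes-all parcellation of a target structure from cortical ROI
groups with a repeated-measures post-hoc (which functional subdivision
of the thalamus do lesions connect to most strongly?), and a tabulator
for MRICS-style lesion-pattern findings across studies.

## Parameters that matter

| parameter | default | role |
|---|---|---|
| `t_threshold` | 7 | per-case binarization cutoff (t units); strict inequality |
| `frac` | 0.95 | fraction of cases a voxel must be connected to |
| `n_perm` | 5000 | permutations for sign-flip and two-sample tests |
| `alpha` | 0.05 | FWE significance level |
| `tail` | "one" | the analysis targets connected, not anti-connected, voxels |
| `fisher_z` | FALSE | t-test on raw r (faithful to common practice) or on atanh(r) |
| `k_leave_out` | 5, 7, 9 | cases removed per stability subset |
| `n_subsets` | 100 | distinct random subsets per k |
| `radius_mm` (spheres) | 12 | control-sphere radius in world mm |

All defaults are carried in `run_config()` and serialized into every
output's provenance manifest.

## Numerical and procedural choices

* **Voxel bookkeeping.** All voxel-wise quantities live on the ordered
  list `in_mask_indices(grid)` — R's native column-major linear order
  over the brain mask. Written statistic maps contain 0 outside the
  mask (viewer compatibility) and the mask is written alongside.
  Inputs must already share one grid; mismatches are errors, never
  resampled, because registration is out of scope.
* **Undefined voxels.** A voxel whose time series has zero variance in
  any subject has no defined correlation there; it is flagged and
  excluded from thresholding, overlap and permutation pools rather than
  zero-filled, so absent signal cannot masquerade as absent
  connectivity.
* **Saturation sentinel.** A voxel whose r values are constant across
  subjects with non-zero mean has an infinite t; it is stored as
  ±1e9, which binarizes correctly at any finite threshold and is
  excluded from permutation statistic pools. A sample standard
  deviation below 1e-10 is treated as zero (a seed's own voxel
  correlates at exactly 1 up to float rounding).
* **Permutation p-values.** Random permutations use add-one counting,
  p = (1 + #{perm ≥ observed}) / (1 + n_perm), so p is never zero.
  When the group structure is small enough (2^n sign patterns or
  C(n, n_a) relabelings within the permutation budget) the null is
  enumerated exhaustively and p = count / total with the identity
  included — the minimal attainable p is then exactly 1/2^n or
  1/C(n, n_a).
* **Two-sample statistic.** Pooled-variance t by default (the common
  permutation-test family); Welch available via `pooled = FALSE`. The
  specific set keeps voxels where the lesion cohort exceeds the control
  cohort with FWE p < alpha.
* **Stability correlates overlap-fraction maps** (count / subset size),
  not binary network maps: Pearson r on a nearly-empty binary map is
  degenerate. Subsets are drawn without repetition of combinations and
  are reproducible from the seed.
* **Winner-takes-all ties** go to the lowest-index label and are
  flagged in a tie map, so downstream consumers can see where the
  assignment was arbitrary.
* **Repeated-measures ANOVA.** Parcel strengths are within-case
  measurements, so the omnibus test is a one-way repeated-measures
  ANOVA with case as the error stratum, followed by all pairwise
  paired t-tests, Bonferroni-multiplied by the number of pairs (6) and
  capped at 1. Degenerate inputs resolve conservatively: no within-case
  variation gives "no effect" (p = 1); a constant non-zero pairwise
  difference gives p = 0 with the difference reported. "Strength" is
  the mean T-value over a parcel's usable voxels (the peak is available
  via `reduce = "peak"`); the mean is preferred for robustness.
* **Rounding of review percentages** is half-up to integer percent,
  which reproduces every printed numerator/denominator pair in the
  shipped fixture (e.g. 451/893 → 51, 296/597 → 50).

## What the synthetic data emulate — and what they do not

`generate_connectome()` builds per-subject voxel × time matrices in
which voxels of a network region load on a shared latent Gaussian
signal (loading `coupling`) plus i.i.d. Gaussian noise, and regions
sharing a latent id are functionally connected to each other. Latents
are white in time: the downstream analysis consumes only spatial
correlation, so temporal autocorrelation, haemodynamics and head motion
are deliberately not modelled. Consequences: passing tests demonstrate
the *statistical machinery* (estimators, thresholds, permutation
schemes, recovery of planted structure), not robustness to scanner
artefacts, preprocessing choices or physiological confounds.

`simulate_planted_study()` is the package's reference construction,
chosen once to mirror the structure of a literature-based lesion
cohort:

* a **desk-scale grid** of 24 × 28 × 24 voxels at 2 mm isotropic with
  an ellipsoidal brain mask (~5000 in-mask voxels), small enough that
  the full validation battery runs in minutes on one CPU;
* **four spatially separate lesion-site subregions** (radius 2.5
  voxels) — literature lesions are heterogeneously distributed over
  several structures, and concentrating all seeds in one blob would
  make every seed carry the same signal;
* **one deep remote hub** (radius 4 voxels, entirely interior), wired
  to the sites through a shared latent at `coupling = 0.8`; lesions
  are never planted there, so recovering it is a genuine network
  inference;
* **a case-private latent on each lesion's own voxels at full
  loading** — each real traced case has a dominant individual
  connectivity fingerprint, and the common network is the weaker
  pooled signal. Without this term all 23 seed series collapse onto
  one latent, the case T-maps become nearly collinear, and the pooled
  sign-flip t detects the sign of finite-connectome sampling noise at
  every voxel. This is worth knowing about the method itself: pooled
  LNM inference presumes case maps that are not near-duplicates;
* the study conditions of the validation battery: 100 subjects ×
  150 timepoints, 23 lesions of 4 mm radius, noise SD 1.

Lesion centres are drawn uniformly within a randomly chosen site;
sphere-cohort centres are drawn uniformly over grey-matter voxels
without replacement (the sampling law for the real control cohort is
not specified anywhere, so distinct-centres uniform sampling is this
package's choice). Sphere masks keep every voxel whose world-coordinate
centre lies within `radius_mm` of the centre voxel, intersected with
grey matter.

### Scale of the control spheres

`sphere_cohort_spec()` defaults to the conventional 12 mm radius. On a
real template that is roughly a sixth of a hemisphere's extent; on the
desk-scale grid a 12 mm sphere covers about a sixth of the *entire*
grey mask, so a large share of random spheres would overlap planted
network tissue and the "control" cohort would itself be a network
cohort. The desk-scale validation therefore uses the proportionally
scaled 4 mm radius with the cortex-like `grey_shell_mask()`; at
template scale the 12 mm default stands.

### Calibration needs independent seeds

The null-calibration property (coupling 0 everywhere) is checked with
disjoint single-voxel seeds. With heavily overlapping seeds, all case
maps are computed from the same connectome noise and become
near-duplicates; independently sign-flipping dependent maps is not a
valid null and the family-wise error rate inflates several-fold. This
is a genuine operating caveat of pooled LNM inference with overlapping
lesions, not an artefact of the simulation.

## Problem sizes used in validation

The test suite and the acceptance script run, as the package's own
choice of validation scale: the planted study at 100 × 150 × 23 (hub
recovery and replication Dice, stability medians over 100 subsets for
k = 5 and 9, sign-flip at 1000 permutations); null calibration over
200 runs of 200 permutations on a ~550-voxel spherical grid with 6
subjects × 20 timepoints × 8 seeds; parcellation recovery on a
noiseless 10³ grid with four 20-voxel ROI groups and 80 target voxels.

## Known limitations

* The normative-connectome preprocessing that precedes this pipeline
  (registration, motion correction, nuisance regression) is out of
  scope; inputs must arrive on one shared grid.
* Inference is voxel-wise max-statistic FWE only — no cluster-extent
  or TFCE options, no spatial smoothing.
* The sign-flip null assumes case maps are exchangeable under sign
  reversal and not near-duplicates (see above); cohorts of heavily
  overlapping lesions should interpret pooled permutation p-values
  with caution.
* Synthetic BOLD is temporally white Gaussian; conclusions about
  real-data robustness to autocorrelation or artefacts cannot be drawn
  from these simulations.
* The review tabulator operates on already-extracted per-study counts;
  literature retrieval, screening and risk-of-bias assessment are
  manual steps outside the package.
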