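---
title: "Cognitive phenotyping of pediatric MS cohorts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cognitive phenotyping of pediatric MS cohorts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogphen)
```

# The analysis model

`cogphen` implements a phenotyping analysis for pediatric multiple
sclerosis cohorts in five stages. This vignette is the package's account
of the science in each stage: the model, its assumptions, the parameters
that matter, and the design decisions that were genuinely open.

## Phenotype discovery by K-means with consensus k

Patients are described by 10 normative z-scores from a pediatric
neuropsychological battery: the Selective Reminding Test (long-term
storage, consistent long-term retrieval, delayed recall), the 10/36
Spatial Recall Test (immediate and delayed), Trail Making Test A and B,
the Symbol Digit Modalities Test, and semantic and phonemic verbal
fluency. Clustering operates on these **test-level** z-scores, not on the
four domain averages; domain scores (unweighted means of the mapped
tests, `domain_scores()`) are reporting-only. The inputs are already on a
normative z scale, so no further feature standardization is applied
before clustering.

`kmeans_fit()` is Lloyd's algorithm with:

* **random-subject initialization** — k distinct subjects per restart;
* **50 restarts** (default), keeping the partition with minimal WCSS;
  restarting guards against the bias of any single random start;
* convergence when assignments are stable, capped at 300 iterations;
* **empty-cluster repair** by reseeding the empty centroid at the point
  farthest from its current centroid.

The number of clusters is chosen by `consensus_k()`: every candidate
k in 2..8 is fitted, each of nine cluster-validity indices votes for its
optimal k, and the modal k wins (ties broken toward the smaller k, the
more parsimonious model). All indices vote on the *same* kept-best
K-means partitions — the voted k is therefore the k the clustering itself
will use, rather than an index-internal refit. Orientation rules:

| index | rule |
|---|---|
| Calinski–Harabasz, silhouette, Dunn, Krzanowski–Lai | maximize |
| Davies–Bouldin, C-index | minimize |
| Hartigan, Ball–Hall | largest second difference of the level curve (maximum curvature) |
| gap statistic | Tibshirani's one-standard-error rule, 25 uniform reference datasets over the feature ranges |

The panel is nine indices rather than a larger battery: the registry in
`validity_indices()` is the configured voting population, and votes are
reported as fractions of the panel so results remain comparable across
panel sizes. The Calinski–Harabasz, silhouette and Davies–Bouldin
implementations are verified in the test suite against independent
implementations to ~1e-12.

For k = 3, `label_phenotypes()` names the clusters by the overall mean of
their centroids: highest → `PC-like` (preserved cognition), lowest →
`MI-like` (multidomain involvement), middle → `intermediate`. Ties are
broken deterministically by the centroid's first coordinate.

### What consensus voting shows on synthetic cohorts

On cohorts drawn from the published per-phenotype means/SDs with
**independent** test scores (the generator default), the two milder
phenotypes differ materially on only four of the ten tests, so their
point clouds overlap substantially. Variance-ratio and
silhouette-type indices then prefer the two-cluster merge, and the panel
majority lands on k = 2; the gap statistic and Hartigan still vote 3.
This is a property of the generative conditions, not of the
implementation: the kept-best WCSS per k and the index values agree with
independent reference implementations, and on well-separated planted
three-cluster data the panel selects k = 3 in 20/20 seeded runs (both
facts are asserted in the test suite). Real cognitive scores are
positively correlated and were scored by a larger index battery, which is
the regime in which a three-way split won the vote. With k = 3 imposed,
the extreme clusters are recovered reliably — the acceptance script shows
the verbal-learning domain mean of the top/bottom centroid within ±0.3 of
the planted 0.9 / −1.2.

## Scanner-referenced normalization

Two 3T scanners contribute subjects (patients ~75%/25%, controls 21/9).
MRI metrics are comparable across scanners only after referencing each
subject to the healthy controls of the *same* scanner:
`z = (x − μ_HC,sc)/σ_HC,sc` (`zscore_vs_hc()`). Conventions:

* the sample SD (n − 1 denominator) is used throughout;
* healthy controls are passed through the same rule, so group contrasts
  share one scale (their within-scanner mean/SD is then 0/1 by
  construction);
* fewer than two reference values or a zero reference SD is an error,
  never a silent NaN.

T2 lesion volume is handled differently (`lesion_volume_z()`): volumes
are log-transformed and standardized within the **patient cohort**
(controls have no lesions). The log base is immaterial — standardization
removes the `1/log(b)` scale factor — which the suite asserts by
comparing natural-log and log10 pipelines.

## Structural disconnection

The change-in-connectivity score of a region pair is the proportion of
reference streamlines connecting the pair that intersect the lesion:
0 = no disconnection, 1 = complete disconnection. Design decisions:

* **"intersect" is a binary hit** — any streamline voxel inside the
  mask; no partial-volume weighting;
* pairs with **no reference streamlines score 0 and are flagged**
  (`no_streamline_pairs`); they are *included* as zeros in network
  averages so that means stay comparable across subjects sharing a
  parcellation (`drop_unconnected = TRUE` switches to connected-pairs
  averaging);
* network values are means over **within-network unordered pairs** of
  distinct regions; only labeled (cortical) regions enter; the scheme has
  exactly the seven cortical networks of `yeo7_networks()`;
* voxel coordinates are 0-based in exported JSON, 1-based linear indices
  internally; NIfTI export uses an identity affine on the toy grid.

The score is monotone in the lesion (growing a mask never decreases any
pairwise or network value) and sub-additive over mask unions; both
properties are tested against a streamline-by-streamline brute-force
oracle on random toy worlds.

## Functional connectivity degree

ROI time series (TR = 3 s ⇒ Nyquist ≈ 0.167 Hz) are linearly detrended
and band-pass filtered at 0.01–0.1 Hz with a zero-phase 2nd-order
Butterworth (`signal::filtfilt`), then correlated pairwise (Pearson).
Matrices are thresholded at τ = 0: negative correlations are zeroed,
non-negative ones kept as weights. A node's degree is the weighted sum of
its connections **excluding the self-correlation** — including the
diagonal would add a constant 1 and distort the later z-referencing — so
degrees lie in [0, N−1]. Network degree is the unweighted mean of node
degrees over each network's nodes, with degrees computed over the full
matrix (a node keeps its cross-network connections); the
`within_network_edges` switch restricts degrees to within-network edges
for sensitivity analyses, since the phrase "average degree within a
network" admits both readings. Network degrees are finally z-referenced
to scanner-matched controls with the same rule as the MRI volumes.

Zero-variance ROIs are flagged and excluded (NA rows/columns) rather
than propagated.

## Group statistics

`adjusted_linear_comparison()` fits OLS of a metric on group indicators
plus age (years) and sex (binary indicator), and reports:

* **estimated marginal means** — model predictions per group with age
  and sex held at the *pooled sample means* (not averaged over sex as a
  factor; the test suite pins this convention against `emmeans` with
  `cov.keep = character(0)`);
* all pairwise contrasts with t-based two-sided p-values and 95% CIs
  (residual df). Covariate terms cancel in contrasts.

Mann–Whitney U uses the tie-corrected normal approximation (exact mode
available for small untied samples); chi-square is Pearson's without
continuity correction. Benjamini–Hochberg FDR (`bh_fdr()`, verified
against brute-force step-up enumeration) is applied **per table of
contrasts** by default — all metrics × contrasts of one report form one
family — with a `per-metric` alternative, since "correcting for the
overall number of tests" does not pin down the family. Under a simulated
global null the realized FDR-significant contrast rate stays at or below
q = 0.05 (500-replicate calibration in the acceptance suite).

# The synthetic-data generator

The generator defines the study conditions; it is not a tuning knob.

* **Cognitive cohort** (`generate_cognitive_cohort()`): three planted
  phenotypes of sizes 27/28/18 with the published per-test means and SDs;
  test scores are independent normals by default because only marginals
  are published — a cross-test correlation matrix is accepted for
  robustness experiments but never guessed. Covariates emulate the
  published demographics: age ≈ N(15.5, 1.8) years, 61–78% girls by
  phenotype, education ≈ 9 years, EDSS on its 0.5-point ordinal grid with
  phenotype-graded means (0.9/1.1/1.6), lognormal disease duration
  (median ≈ 1.4 y) and T2 lesion volume (mL). Scanner assignment is
  Bernoulli(0.75) for scanner S1.
* **Healthy controls** (`generate_hc_reference()`): 21 + 9 per scanner by
  default, raw MRI metrics with plausible volumetric scales.
* **Patient MRI metrics** (`generate_patient_mri()`): phenotype-graded
  planted z-shifts (in HC SD units) reproducing the published pattern of
  graded atrophy, used by the pipeline stage that exercises the
  comparison machinery.
* **Toy voxel world** (`generate_toy_world()`): 20 regions as 2×2×1
  blocks on one slice of a small 3-D grid, white matter elsewhere,
  streamlines as voxel paths with endpoints inside their declared
  regions, region→network labels cycling through the seven networks, and
  per-subject lesion masks drawn uniformly over white-matter voxels at a
  configurable fraction. It stands in for a reference tractogram plus
  parcellation at desk scale; the scoring contract is identical.
* **BOLD series** (`generate_bold()`): independent multivariate-normal
  timepoints with zero-lag covariance `planted + σ²I` (a white stationary
  Gaussian process at ROI level). `factor_covariance()` plants a rank-1
  common signal on one network's regions, giving the closed-form
  within-network correlation `λ²/(λ² + σ²)` that the suite checks against
  sample estimates.

What the generator does **not** emulate — and what passing tests
therefore cannot show about real data: raw EPI images, head motion and
physiological noise (series are white, with no autocorrelation),
registration error, partial-volume effects, real tractography, cross-test
correlation structure, and covariate–score dependencies (cognition is
independent of age/sex/EDSS in the generator). Tests demonstrate that the
*machinery* is correct under known generative conditions, not that the
clinical findings generalize.

All randomness flows from one master seed through named substreams
(`substream_seed(master, "cohort")`, `"kmeans"`, `"world"`,
`"bold-<id>"`, ...), a multiplicative string hash modulo a prime below
2³¹, so any stage can be regenerated independently and reruns are
byte-identical.

# Numerical choices and degenerate inputs

* K-means ties in nearest-centroid assignment break toward the
  lower-indexed centroid; consensus ties break toward smaller k.
* WCSS comparisons in the oracle tests use tolerance 1e-9; hand-checked
  correlation/degree examples use 1e-12.
* Degenerate references (zero SD, identical lesion volumes, missing
  scanner) raise errors; σ → 0 cluster specs are allowed via tiny
  positive SDs.
* The band-pass validates 0 < low < high < Nyquist; series shorter than
  64 timepoints are rejected.
* Filter edge transients: amplitude checks in the suite measure the
  middle half of the series.

# Problem sizes

The shipped tests and acceptance script run at the cohort's natural scale
(73 patients + 30 controls, 10 features) for clustering and statistics;
toy worlds use 2–20 regions with 2–5 streamlines per pair; BOLD checks
use 6–14 regions and 128–4096 timepoints; the null calibration uses 500
replicated cohorts; convergence checks use one 10⁴-subject draw. These
sizes were chosen so every stochastic assertion has comfortable margin
while the whole suite stays quick to iterate on.

# Known limitations

* The toy disconnection world shares only the *contract* of a reference
  tractogram (proportion-of-streamlines-hit); its geometry is not
  brain-like, so absolute network disconnection values are not
  comparable to published ones.
* The consensus panel is a nine-index subset of the larger batteries used
  by dedicated packages; the majority is taken over the configured panel
  and reported as a fraction.
* No longitudinal or mixed-effects modeling; no scanner harmonization
  beyond z-referencing; no voxelwise or seed-based FC.
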