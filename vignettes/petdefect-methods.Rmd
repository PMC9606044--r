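---
title: "Quantifying metabolic defects in longitudinal FDG-PET: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying metabolic defects in longitudinal FDG-PET: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petdefect)
```

## The analysis model

petdefect implements the quantification chain used in longitudinal
FDG-PET studies of Alzheimer's disease, where the question is whether a
treatment slows the metabolic decline that the disease produces in the
posterior cingulate, precuneus and parieto-temporal cortex. The chain has
five stages.

**Preprocessing.** Every scan is intensity-normalized to the mean uptake
of the cerebellum — a large, stable reference region minimally affected
by the disease — and smoothed with an isotropic Gaussian kernel of 8 mm
FWHM (sigma = FWHM / (2·sqrt(2·ln 2)) per axis, converted to voxels via
the header voxel size). Smoothing raises signal-to-noise and absorbs
small anatomical variation; normalization makes scans from different
sessions comparable on a common unitless scale where the cerebellum mean
is exactly 1. Spatial registration to the common analysis space is
assumed to have happened upstream; the package enforces the assumption
through a `space` tag that every pairwise voxel operation checks.

**Normative template.** From `n` preprocessed healthy-control scans the
package computes the voxel-wise mean and sample standard deviation
(n − 1 denominator). A patient voxel is then scored as
`z = (patient − mean) / sd`. A voxel at least 2 SD below the control mean
(`z <= -2`, boundary inclusive) is a metabolic *defect*. Severity is
graded in whole-SD steps — bins `(-3,-2] -> 1`, `(-4,-3] -> 2`,
`<= -4 -> 3` by default. The exact grading table used in the clinical
deployment of this chain is not public; whole-SD steps are the
conventional choice and the bins are configurable.

**Atrophy correction.** Hypometabolism at a voxel that has lost its gray
matter is atrophy, not metabolic dysfunction. Each patient's gray-matter
probability map is thresholded at 0.5 (`>=` keeps the boundary) and the
resulting mask gates all defect statistics: voxels outside it carry
severity 0 and are excluded from every regional summary.

**Regional metrics.** For each atlas region, three parameters are
computed over the region's in-mask voxels: *metabolism intensity* (mean
normalized counts), *defect extension* (% of in-mask voxels flagged as
defect) and *defect intensity* (mean severity grade). A region fully
removed by the mask yields `NA`, never a silent zero. Longitudinal
change per region is tested with a two-sided paired Student's t at
alpha = 0.05 on per-subject change scores, and cross-sectional arm
differences with one-way equal-variance ANOVA. No multiple-testing
correction is applied across regions — deliberately, because the summary
tables this machinery reproduces report raw p < 0.05 counts; a
Benjamini–Hochberg flag (`fdr = TRUE`) is available but off by default.

**Voxel statistics and the progression mask.** Group-level decline is
mapped with a voxel-wise paired t-test (one-sided for decline by
default), thresholded at p < 0.001 uncorrected, and cluster-filtered at a
minimum extent of k = 50 voxels under 18-neighbour connectivity. Applied
to the placebo arm's first-to-last-visit contrast, the union of surviving
clusters is the disease-progression mask (MaskAD): the footprint of
untreated decline. Mean in-mask uptake per subject then yields the
percent metabolism change, `100 * (later - baseline) / baseline`,
averaged per arm.

**Volumetry.** Structure volumes (15 subcortical entries plus GM/WM/CSF)
are consumed as tables, mirroring how a real run consumes the output of a
segmentation tool; segmentation itself is out of scope. TIV is always
derived as GM + WM + CSF, and per-structure longitudinal change uses the
same paired-t machinery at alpha = 0.05, counted over 15 structures.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `fwhm_mm` | 8 | mm | conventional PET smoothing kernel |
| `z_threshold` | 2 | SD | defect definition (boundary inclusive) |
| `severity_bins` | −2, −3, −4 | SD | whole-SD severity steps |
| `gm_threshold` | 0.5 | probability | atrophy-correction cutoff (`>=`) |
| `delta_threshold` | 0.5 | SD | longitudinal improved/worsened cutoff |
| `p_voxel` | 0.001 | — | voxel-level uncorrected threshold |
| `k_min` | 50 | voxels | minimum surviving cluster extent |
| `connectivity` | 18 | — | faces+edges, common SPM practice |
| `alpha` | 0.05 | — | regional/structure significance level |
| `sd_floor` | 1% of in-brain mean | normalized counts | see below |

## The longitudinal voxel classification

Between two visits a voxel *improved* when it was a defect and no longer
is, or when its Z rose by **more than** 0.5; it *worsened* when it became
a defect, or when its Z fell **by 0.5 or more**. The asymmetry (strict
vs. inclusive boundary) follows the clinical definition this implements
verbatim. When a status-change rule and a delta-Z rule disagree, the
status change wins and the conflict is counted in the result
(`rule_conflicts`); with monotone severity bins such conflicts cannot
actually occur, so a nonzero counter signals inconsistent inputs. The
definition of "outside" follows the intersection of both visits'
correction masks by default; `mask_policy` switches to the later or
earlier mask alone for sensitivity analyses.

## The synthetic phantom cohort

Real scans from the trial this machinery targets are not public, so the
package ships a generator whose defaults define the study conditions for
all validation: a 40 × 48 × 40 grid at 4 mm isotropic (desk-scale while
leaving room for the 8 mm kernel), an ellipsoidal brain partitioned into
30 contiguous Voronoi regions grown from seeded points, 4 of them forming
a compact posterior-inferior cerebellum block and 6 a compact
posterior-superior block standing in for the posterior-cingulate/
precuneus/parieto-temporal regions where decline is seeded. Baseline
uptake is 100 arbitrary counts per region with additive Gaussian scan
noise of SD 5 on in-brain voxels.

The cohort emulates a four-arm design — placebo declining most, then low
albumin, low albumin + IVIG, and high albumin + IVIG declining least
(defaults 6, 4.5, 3.5, 2 % of AD-region uptake over the 14-month span;
the real per-arm decline magnitudes are not published, so these are
tunable defaults chosen to span a plausible range, not claims) — crossed
with two severity strata. Moderate disease multiplies the arm decline by
1.6 and starts with a deeper baseline defect (16 % vs 10 % AD-region
deficit), mirroring the deeper and more extensive baseline patterns seen
in moderate patients. Visit progress is linear in months (M0 = 0 …
M14 = 1); no within-study decline curve is published, so linearity is the
neutral choice. Gray-matter probability falls radially from 0.92 at the
brain centre, floored at 0.5 at baseline, and atrophy subtracts
`atrophy_rate x progress` (default 0.05 over the span), which makes the
correction mask shrink strictly with every visit. Volumetry follows
per-structure fractional span losses (hippocampus and accumbens largest)
with 1 % multiplicative measurement noise. The PET schedule is M0, M2,
M9, M14; M6 exists in the visit list but carries volumetry only.

What the generator does **not** emulate: scanner physics, partial-volume
effects, motion, attenuation, registration error, anatomically realistic
region shapes, or spatially correlated biological noise. Passing tests
therefore demonstrate that the estimators recover known truth under
idealized noise — a necessary condition — and say nothing about
robustness to registration or segmentation failures in real data.

Every subject record carries its exact noise-free ground truth (effective
decline per visit), so recovery checks compare against stored truth
rather than re-deriving it.

## Numerical choices

- **SD floor.** With identical controls the voxel SD is 0 and Z would be
  undefined; the template floors the SD at 1 % of the in-brain mean of
  the mean image. In the zero-noise limit every Z-score is governed by
  the floor — a documented degenerate regime, exercised by tests.
- **Sample vs population SD.** The n − 1 form is used; at n = 48 the
  difference is about 1 %, but the choice must be fixed for exact oracle
  tests.
- **Smoothing boundary.** Mirror reflection at the grid edge. The brain
  is interior to the grid so the choice is immaterial, but it is fixed
  for bit-reproducibility; the kernel is normalized so constants pass
  through unchanged and impulse mass is conserved.
- **Implicit analysis mask.** Group voxel statistics run on scans without
  per-subject atrophy masks (which would break paired voxel
  correspondence). Instead the conventional PET implicit mask is applied:
  a voxel is analysed where every scan exceeds 0.8 x its global mean,
  computed over voxels above one eighth of the volume mean. Without it,
  the low-intensity halo that smoothing smears beyond the brain boundary
  shows spuriously significant "decline" (partial-volume artefact), and
  clusters leak out of the brain.
- **Zero-variance voxels** in the paired t get t = 0, p = 1 rather than
  an infinite statistic.
- **Percentages** in summary tables are exact rational arithmetic on
  counts, rounded to one decimal.
- **Precision.** All computation is double; NIfTI storage is float32
  (uint8 for masks and severity codes).

## Design choices where the procedure was open

- **Percent-loss denominator**: each subject's own baseline in-mask mean;
  the arm value is the mean of subject-level percent changes (not the
  percent change of arm means).
- **Change scores**: regional longitudinal tests use per-subject
  (later − baseline) differences, matching a "changed between baseline
  and final visit" reading.
- **Volumetry tests** use absolute volumes; TIV-normalized volumes are
  available behind `normalize_tiv = TRUE`.
- **One global progression mask** built from the placebo arm is applied
  to every arm and stratum; no severity-stratified masks.
- **Mask order**: the atrophy mask is applied after Z computation; the
  two orders are output-equivalent here but the order is stated.
- **Smoothing spill**: seeding decline in a region and smoothing with
  8 mm FWHM spreads a detectable fraction of the signal about one voxel
  beyond the region boundary at this grid scale, so the progression mask
  includes a thin significant shell around the seeded regions. At
  clinical voxel sizes (2 mm) the same shell is proportionally smaller.

## Problem sizes used in validation

The shipped tests validate on: exact brute-force oracle equivalence at
14³–16³ grids; type-I calibration with 50 null arms of 16 subjects at
32 × 36 × 32; parameter recovery with four arms of 16 subjects each over
10 seeds at the default 40 × 48 × 40 grid; and power/size checks with
paired declining/null arms of 16 subjects over 10 seeds. These sizes were
chosen so the whole suite validates every claim in minutes on a laptop
while keeping per-arm subject counts in the range where the t-based
machinery is well-behaved.

## Known limitations

- Registration, segmentation and scanner harmonization are out of scope;
  all inputs are assumed to live on one grid (enforced via the space
  tag), and volumetry consumes precomputed tables.
- The severity grading table and the normative template construction of
  the original clinical deployment are not public; defaults are
  conventional stand-ins and configurable.
- Raw p < 0.05 region counts (no multiplicity correction) reproduce the
  reporting convention faithfully but overstate per-region evidence; use
  the FDR flag for inference.
- Under the default conditions the metabolism-intensity region tests are
  sensitive to the deterministic mask shrink that progressive atrophy
  induces (region means are computed over a shrinking voxel set common to
  all subjects), so near all regions change "significantly" in that
  parameter — visible in the end-to-end tables and worth keeping in mind
  when interpreting real-data analogues.
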