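# petdefect

Voxel-wise FDG-PET defect quantification and longitudinal metabolic
decline analysis, with a synthetic phantom cohort for end-to-end
validation.

## The problem

In longitudinal trials for Alzheimer's disease, FDG-PET tracks whether a
treatment slows the metabolic decline the disease produces in the
posterior cingulate, precuneus and parieto-temporal cortex, while MRI
volumetry tracks structural loss in subcortical structures such as the
hippocampus. petdefect implements the full quantification chain for such
a study, for imaging analysts who have registered scans in a common
space and want reproducible, tested statistics rather than a GUI
pipeline:

- **Preprocessing** — intensity normalization to the cerebellum mean and
  isotropic Gaussian smoothing (8 mm FWHM);
- **Normative template** — voxel-wise mean/SD over healthy-control
  scans, with an SD floor so Z-scores are always defined;
- **Defect mapping** — `z = (patient − mean)/sd`; a voxel ≥ 2 SD below
  the control mean is a defect, graded in whole-SD severity steps, gated
  by a per-patient gray-matter atrophy-correction mask (GM probability
  ≥ 0.5), plus improved/maintained/worsened voxel classification between
  visits (±0.5 Z);
- **Regional metrics** — per atlas region: metabolism intensity, defect
  extension (%), defect intensity; paired-t change tests and
  cross-sectional ANOVA with `n (pct%)` summary tables;
- **Voxel statistics** — voxel-wise paired t for decline (p < 0.001
  uncorrected, cluster extent k ≥ 50, 18-connectivity); the union of
  surviving placebo-arm clusters is the disease-progression mask
  (MaskAD), from which per-arm percent metabolism loss is extracted;
- **Volumetry** — TIV = GM + WM + CSF, tissue fractions, per-structure
  paired tests over 15 subcortical structures;
- **Synthetic cohort generator** — a seeded digital brain phantom
  (Voronoi parcellation of an ellipsoid, compact cerebellum and
  disease-region blocks) with a four-arm, two-severity longitudinal
  design and known ground-truth decline, so every estimator can be
  validated by parameter recovery.

All volumes are NIfTI-1 (via RNifti); all tables are CSV.

## Worked example

Simulate a one-stratum, four-arm cohort (6 subjects per arm, seeded
AD-region declines of 6, 4.5, 3.5 and 2 % over the study span) on a
20 × 24 × 20 phantom and run the whole chain:

```r
library(petdefect)
cfg <- run_config(
  seed = 42,
  phantom = list(grid_shape = c(20, 24, 20), n_regions = 12,
                 cerebellum_region_ids = 1:2, ad_region_ids = 10:12),
  cohort = list(
    arms = data.frame(name = c("placebo", "low_albumin",
                               "low_albumin_ivig", "high_albumin_ivig"),
                      decline = c(0.06, 0.045, 0.035, 0.02),
                      n = rep(6L, 4)),
    severity_strata = list(mild = list(multiplier = 1, baseline_offset = 0.1)),
    n_controls = 10L))
run <- run_pipeline(cfg)
tabs <- report_tables(run)
print(tabs$maskad_percent_loss, row.names = FALSE)
print(tabs$k_extent, row.names = FALSE)
```

which prints

```
 stratum placebo low_albumin low_albumin_ivig high_albumin_ivig
     all    -5.6        -4.1             -3.3              -1.7
 stratum placebo low_albumin low_albumin_ivig high_albumin_ivig
     all     819         588              309                 0
```

Read: in the progression mask built from the placebo arm's M0→M14
decline (819 voxels in one surviving cluster), mean uptake fell 5.6 % in
the placebo arm and only 1.7 % in the high-albumin+IVIG arm — recovering
the seeded 6 %…2 % dose–response ordering. The k-extent row shows the
same ordering as total surviving-cluster size per arm's own contrast; in
the least-declining arm no cluster survives k ≥ 50 at this sample size.
`tabs$regional_changes` and `tabs$volumetry_changes` give the per-arm
`n (pct%)` significant-region and significant-structure summaries.

A command-line wrapper with `simulate`, `run` and `report` subcommands
lives at `inst/cli/petdefect.R`.

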