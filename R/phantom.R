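#' Specification of a synthetic brain phantom
#'
#' Describes a desk-scale digital brain: an ellipsoidal support partitioned
#' into contiguous regions by seeded-point nearest-neighbour (Voronoi)
#' growth. A subset of regions is designated cerebellum (the normalization
#' reference) and a disjoint subset is designated as disease-affected
#' ("AD regions", the posterior-cingulate/precuneus/parieto-temporal
#' analogue) where metabolic decline is seeded.
#'
#' @param grid_shape integer vector of 3 positive voxel counts.
#' @param voxel_mm positive voxel edge length, mm.
#' @param n_regions number of parcellation regions (>= 10 for realistic
#'   use; smaller grids for unit tests are accepted down to 2).
#' @param cerebellum_region_ids nonempty set of region ids flagged as
#'   cerebellum.
#' @param ad_region_ids region ids seeded with metabolic decline; must be
#'   disjoint from the cerebellum set.
#' @param baseline_uptake per-region positive uptake (arbitrary counts);
#'   scalar recycled to all regions, or a vector of length `n_regions`.
#' @param noise_sd default additive scan noise SD, same units as uptake.
#' @param seed integer RNG seed; the phantom is deterministic given it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(40L, 48L, 40L),
                         voxel_mm = 4,
                         n_regions = 30L,
                         cerebellum_region_ids = 1:4,
                         ad_region_ids = 25:30,
                         baseline_uptake = 100,
                         noise_sd = 5,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0))
  n_regions <- as.integer(n_regions)
  if (n_regions < 2L) stop("n_regions must be at least 2")
  cerebellum_region_ids <- as.integer(cerebellum_region_ids)
  ad_region_ids <- as.integer(ad_region_ids)
  if (length(cerebellum_region_ids) == 0L)
    stop("cerebellum_region_ids must be nonempty")
  if (length(intersect(cerebellum_region_ids, ad_region_ids)) > 0L)
    stop("cerebellum_region_ids and ad_region_ids must be disjoint")
  all_ids <- c(cerebellum_region_ids, ad_region_ids)
  if (any(all_ids < 1L) || any(all_ids > n_regions))
    stop("region ids must lie in 1..n_regions")
  if (length(baseline_uptake) == 1L)
    baseline_uptake <- rep(baseline_uptake, n_regions)
  if (length(baseline_uptake) != n_regions || any(baseline_uptake <= 0))
    stop("baseline_uptake must be positive, length 1 or n_regions")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  structure(list(grid_shape = grid_shape, voxel_mm = voxel_mm,
                 n_regions = n_regions,
                 cerebellum_region_ids = cerebellum_region_ids,
                 ad_region_ids = ad_region_ids,
                 baseline_uptake = baseline_uptake,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# normalized squared ellipsoidal radius (1 on the brain surface) for every
# voxel of the grid; semi-axes span 88% of each half-dimension
ellipsoid_rho2 <- function(grid_shape) {
  ctr <- (grid_shape + 1) / 2
  semi <- 0.88 * (grid_shape - 1) / 2
  ix <- ((seq_len(grid_shape[1]) - ctr[1]) / semi[1])^2
  iy <- ((seq_len(grid_shape[2]) - ctr[2]) / semi[2])^2
  iz <- ((seq_len(grid_shape[3]) - ctr[3]) / semi[3])^2
  outer(outer(ix, iy, "+"), iz, "+")
}

#' Build a synthetic brain phantom
#'
#' Generates (1) an atlas parcellation of an ellipsoidal brain support into
#' `n_regions` contiguous regions by nearest-neighbour growth around seeded
#' points, (2) the noise-free baseline uptake volume, and (3) a baseline
#' gray-matter probability volume. Region ids are assigned spatially:
#' cerebellum ids go to the most inferior regions and AD ids to the most
#' superior of the rest, so the reference and disease regions are coherent
#' blocks. GM probability decreases from 0.92 at the brain centre towards
#' the surface and is floored at 0.5, so at baseline every in-brain voxel
#' survives the default 0.5 atrophy-correction threshold.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `phantom` with elements `atlas`
#'   (`atlas_parcellation`), `uptake` (`pet_volume`, noise-free baseline),
#'   `gm` (`pet_volume`, baseline GM probability), `rho2` (internal radial
#'   coordinate reused by the atrophy model) and `spec`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape
  rho2 <- ellipsoid_rho2(gs)
  brain <- rho2 <= 1
  nb <- sum(brain)
  if (spec$n_regions > nb)
    stop("n_regions (", spec$n_regions, ") exceeds in-brain voxels (", nb, ")")

  idx <- which(brain)
  coords <- arrayInd(idx, gs)

  set.seed(spec$seed)
  seed_rows <- sample.int(nb, spec$n_regions)
  seeds <- coords[seed_rows, , drop = FALSE]

  # nearest seeded point, Euclidean in voxel coordinates
  d2 <- matrix(0, nb, spec$n_regions)
  for (k in 1:3)
    d2 <- d2 + outer(coords[, k], seeds[, k], "-")^2
  assign0 <- max.col(-d2, ties.method = "first")

  # spatial id assignment by anatomical anchors: cerebellum ids go to the
  # cells nearest a posterior-inferior anchor, AD ids to the remaining
  # cells nearest a posterior-superior interior anchor (the medial
  # parietal/posterior-cingulate analogue), so both form compact coherent
  # blocks; leftover ids fill in by centroid height for determinism
  cent <- cbind(tapply(coords[, 1], assign0, mean),
                tapply(coords[, 2], assign0, mean),
                tapply(coords[, 3], assign0, mean))
  ctr <- (gs + 1) / 2
  semi <- 0.88 * (gs - 1) / 2
  anchor_cb <- ctr + semi * c(0, -0.35, -0.55)
  anchor_ad <- ctr + semi * c(0, -0.40, 0.30)
  dist_to <- function(anchor)
    sqrt(colSums((t(cent) - anchor)^2))
  n_cb <- length(spec$cerebellum_region_ids)
  n_ad <- length(spec$ad_region_ids)
  prov_cb <- order(dist_to(anchor_cb))[seq_len(n_cb)]
  rest <- setdiff(seq_len(spec$n_regions), prov_cb)
  prov_ad <- rest[order(dist_to(anchor_ad)[rest])][seq_len(n_ad)]
  prov_other <- setdiff(seq_len(spec$n_regions), c(prov_cb, prov_ad))
  other_ids <- setdiff(seq_len(spec$n_regions),
                       c(spec$cerebellum_region_ids, spec$ad_region_ids))
  final_of_prov <- integer(spec$n_regions)
  final_of_prov[prov_cb[order(cent[prov_cb, 3])]] <-
    sort(spec$cerebellum_region_ids)
  if (n_ad > 0)
    final_of_prov[prov_ad[order(cent[prov_ad, 3])]] <-
      sort(spec$ad_region_ids)
  final_of_prov[prov_other[order(cent[prov_other, 3])]] <- sort(other_ids)

  labels <- array(0L, gs)
  labels[idx] <- final_of_prov[assign0]

  regions <- data.frame(
    region_id = seq_len(spec$n_regions),
    name = sprintf("region_%02d", seq_len(spec$n_regions)),
    lobe = "synthetic",
    cerebellum_flag = seq_len(spec$n_regions) %in% spec$cerebellum_region_ids,
    ad_flag = seq_len(spec$n_regions) %in% spec$ad_region_ids,
    stringsAsFactors = FALSE)
  regions$lobe[regions$cerebellum_flag] <- "cerebellum"
  regions$lobe[regions$ad_flag] <- "ad_cortex"

  uptake <- array(0, gs)
  uptake[idx] <- spec$baseline_uptake[labels[idx]]

  gm <- array(0, gs)
  gm[brain] <- pmax(0.5, 0.92 - 0.45 * rho2[brain])

  atlas <- new_atlas(labels, regions, voxel_mm = spec$voxel_mm)
  structure(list(atlas = atlas,
                 uptake = new_volume(uptake, spec$voxel_mm),
                 gm = new_volume(gm, spec$voxel_mm),
                 rho2 = rho2, spec = spec),
            class = "phantom")
}

brain_mask <- function(phantom) phantom$atlas$labels > 0L

#' Sample healthy-control scans from a phantom
#'
#' Each control scan is the noise-free baseline uptake plus i.i.d. Gaussian
#' noise on in-brain voxels (zero outside the brain). Controls emulate the
#' healthy-elderly reference population from which the normative template
#' is built.
#'
#' @param phantom a [build_phantom()] result.
#' @param n_controls number of controls (>= 2).
#' @param noise_sd additive noise SD; defaults to the phantom spec's.
#' @param seed integer seed.
#' @return List of `pet_volume` scans.
#' @export
sample_control_scans <- function(phantom, n_controls = 48L,
                                 noise_sd = phantom$spec$noise_sd,
                                 seed = phantom$spec$seed + 1L) {
  stopifnot(inherits(phantom, "phantom"))
  if (n_controls < 2L) stop("n_controls must be at least 2")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  mask <- brain_mask(phantom)
  nb <- sum(mask)
  set.seed(seed)
  lapply(seq_len(n_controls), function(i) {
    arr <- phantom$uptake$data
    if (noise_sd > 0) arr[mask] <- arr[mask] + rnorm(nb, 0, noise_sd)
    new_volume(arr, phantom$spec$voxel_mm)
  })
}

#' Specification of a synthetic longitudinal cohort
#'
#' Defines the four-arm, two-severity-stratum longitudinal design the
#' generator emulates: per-arm metabolic decline seeded into the phantom's
#' AD regions, per-stratum decline multipliers and baseline defect offsets,
#' the visit schedule, progressive gray-matter atrophy, and per-structure
#' volumetry decline.
#'
#' @param arms data.frame with columns `name`, `decline` (fractional
#'   AD-region uptake loss over the full study span, in `[0,1)`) and `n`
#'   (subjects per arm, >= 2). The default mirrors a placebo arm declining
#'   most and a high-albumin+IVIG arm declining least.
#' @param severity_strata named list; each element has `multiplier`
#'   (scales the arm decline) and `baseline_offset` (fractional AD-region
#'   uptake deficit already present at baseline). Default: moderate
#'   disease declines 1.6x faster and starts with a deeper defect than
#'   mild.
#' @param visits ordered visit labels, must start at `"M0"`; the numeric
#'   part is the month and visit progress is linear in months.
#' @param pet_visits visits at which PET (and GM maps) are acquired;
#'   volumetry is acquired at every visit.
#' @param atrophy_rate GM probability decrement over the full span
#'   (applied linearly in visit progress).
#' @param volumetry_decline named list: `baseline` (named structure volumes
#'   in mm3, including `gm`, `wm`, `csf`), `span_loss` (named fractional
#'   loss over the study span) and `noise_sd_frac` (multiplicative
#'   measurement noise, fraction of baseline).
#' @param n_controls healthy controls for the normative template.
#' @param seed integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(arms = default_arms(),
                        severity_strata = default_strata(),
                        visits = c("M0", "M2", "M6", "M9", "M14"),
                        pet_visits = c("M0", "M2", "M9", "M14"),
                        atrophy_rate = 0.05,
                        volumetry_decline = default_volumetry(),
                        n_controls = 48L,
                        seed = 1L) {
  stopifnot(is.data.frame(arms),
            all(c("name", "decline", "n") %in% names(arms)))
  if (any(arms$decline < 0 | arms$decline >= 1))
    stop("arm decline fractions must lie in [0, 1)")
  if (any(arms$n < 2)) stop("each arm needs at least 2 subjects")
  if (visits[1] != "M0") stop("visit schedule must start at M0")
  if (!all(grepl("^M[0-9]+$", visits)))
    stop("unknown visit label: ",
         paste(visits[!grepl("^M[0-9]+$", visits)], collapse = ", "))
  if (!all(pet_visits %in% visits))
    stop("pet_visits must be a subset of visits")
  structure(list(arms = arms, severity_strata = severity_strata,
                 visits = visits, pet_visits = pet_visits,
                 atrophy_rate = atrophy_rate,
                 volumetry_decline = volumetry_decline,
                 n_controls = as.integer(n_controls),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_arms <- function() {
  data.frame(
    name = c("placebo", "low_albumin", "low_albumin_ivig",
             "high_albumin_ivig"),
    decline = c(0.06, 0.045, 0.035, 0.02),
    n = c(16L, 16L, 16L, 16L),
    stringsAsFactors = FALSE)
}

#' @rdname cohort_spec
#' @export
default_strata <- function() {
  list(mild = list(multiplier = 1.0, baseline_offset = 0.10),
       moderate = list(multiplier = 1.6, baseline_offset = 0.16))
}

#' @rdname cohort_spec
#' @export
default_volumetry <- function() {
  structures <- c(thalamus_L = 7800, thalamus_R = 7700,
                  putamen_L = 5100, putamen_R = 5000,
                  caudate_L = 3700, caudate_R = 3650,
                  pallidum_L = 1800, pallidum_R = 1780,
                  hippocampus_L = 3900, hippocampus_R = 3850,
                  amygdala_L = 1700, amygdala_R = 1680,
                  accumbens_L = 560, accumbens_R = 540,
                  brainstem_4th_ventricle = 21500)
  span_loss <- c(thalamus_L = 0.004, thalamus_R = 0.004,
                 putamen_L = 0.005, putamen_R = 0.005,
                 caudate_L = 0.010, caudate_R = 0.010,
                 pallidum_L = 0.003, pallidum_R = 0.003,
                 hippocampus_L = 0.030, hippocampus_R = 0.030,
                 amygdala_L = 0.010, amygdala_R = 0.010,
                 accumbens_L = 0.025, accumbens_R = 0.025,
                 brainstem_4th_ventricle = 0.002,
                 gm = 0.020, wm = 0.002, csf = -0.020)
  list(baseline = c(structures, gm = 620000, wm = 480000, csf = 330000),
       span_loss = span_loss,
       noise_sd_frac = 0.01)
}

#' Names of the subcortical structures tracked by volumetry
#' @return Character vector of 15 structure names.
#' @export
volumetry_structures <- function() {
  c("thalamus_L", "thalamus_R", "putamen_L", "putamen_R",
    "caudate_L", "caudate_R", "pallidum_L", "pallidum_R",
    "hippocampus_L", "hippocampus_R", "amygdala_L", "amygdala_R",
    "accumbens_L", "accumbens_R", "brainstem_4th_ventricle")
}

visit_month <- function(v) as.numeric(sub("^M", "", v))

visit_progress <- function(visits) {
  m <- visit_month(visits)
  if (max(m) == 0) return(rep(0, length(m)))
  m / max(m)
}

#' Sample a longitudinal patient series from a phantom
#'
#' Generates one record per subject. Per subject and visit the PET scan is
#' the phantom baseline with uptake in AD regions multiplied by
#' `(1 - baseline_offset) * (1 - decline * multiplier * progress)` before
#' additive Gaussian noise; the GM probability map is thinned by
#' `atrophy_rate * progress`; the volumetry table follows the per-structure
#' span loss with multiplicative noise. The exact noise-free ground truth
#' (effective decline at each visit) is stored with every record so
#' downstream recovery checks never re-derive it.
#'
#' @param phantom a [build_phantom()] result.
#' @param cohort a [cohort_spec()].
#' @return List of `subject_record` objects; each has `subject_id`, `arm`,
#'   `stratum`, `visits` (named list with `scan`, `gm`, `volumetry` — PET
#'   entries are `NULL` at volumetry-only visits) and `truth` (data.frame
#'   of effective decline per visit).
#' @export
sample_patient_series <- function(phantom, cohort) {
  stopifnot(inherits(phantom, "phantom"), inherits(cohort, "cohort_spec"))
  spec <- phantom$spec
  gs <- spec$grid_shape
  mask <- brain_mask(phantom)
  nb <- sum(mask)
  ad_mask <- atlas_region_mask(phantom$atlas, spec$ad_region_ids)
  prog <- visit_progress(cohort$visits)
  names(prog) <- cohort$visits
  strata_names <- names(cohort$severity_strata)
  vd <- cohort$volumetry_decline
  all_meas <- names(vd$baseline)

  # GM atrophy uses the continuous radial profile so the correction mask
  # strictly shrinks with progress
  gm0 <- phantom$gm$data

  set.seed(cohort$seed)
  subjects <- list()
  sid <- 0L
  for (a in seq_len(nrow(cohort$arms))) {
    arm <- cohort$arms$name[a]
    for (s in seq_len(cohort$arms$n[a])) {
      sid <- sid + 1L
      stratum <- strata_names[(s - 1L) %% length(strata_names) + 1L]
      st <- cohort$severity_strata[[stratum]]
      eff_decline <- cohort$arms$decline[a] * st$multiplier
      base_arr <- phantom$uptake$data
      base_arr[ad_mask] <- base_arr[ad_mask] * (1 - st$baseline_offset)

      visits <- list()
      truth <- data.frame(visit = cohort$visits,
                          progress = unname(prog),
                          decline_at_visit = unname(eff_decline * prog),
                          stringsAsFactors = FALSE)
      for (v in cohort$visits) {
        g <- prog[[v]]
        entry <- list(scan = NULL, gm = NULL, volumetry = NULL)
        if (v %in% cohort$pet_visits) {
          arr <- base_arr
          arr[ad_mask] <- arr[ad_mask] * (1 - eff_decline * g)
          if (spec$noise_sd > 0)
            arr[mask] <- arr[mask] + rnorm(nb, 0, spec$noise_sd)
          entry$scan <- new_volume(arr, spec$voxel_mm)
          gm <- pmax(gm0 - cohort$atrophy_rate * g, 0)
          gm[!mask] <- 0
          entry$gm <- new_volume(gm, spec$voxel_mm)
        }
        vols <- vd$baseline * (1 - vd$span_loss[all_meas] * g * st$multiplier)
        vols <- vols * (1 + rnorm(length(vols), 0, vd$noise_sd_frac))
        vols <- pmax(vols, 1)
        entry$volumetry <- vols
        visits[[v]] <- entry
      }
      subjects[[sid]] <- structure(
        list(subject_id = sprintf("S%03d", sid), arm = arm,
             stratum = stratum, visits = visits, truth = truth,
             effective_decline = eff_decline,
             baseline_offset = st$baseline_offset),
        class = "subject_record")
    }
  }
  subjects
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper: builds the phantom, samples controls and the
#' longitudinal patient series under a single seed.
#'
#' @param pspec a [phantom_spec()].
#' @param cspec a [cohort_spec()].
#' @return List of class `cohort` with `phantom`, `controls`, `subjects`,
#'   and the two specs.
#' @export
simulate_cohort <- function(pspec = phantom_spec(), cspec = cohort_spec()) {
  phantom <- build_phantom(pspec)
  controls <- sample_control_scans(phantom, cspec$n_controls,
                                   noise_sd = pspec$noise_sd,
                                   seed = cspec$seed + 1000L)
  subjects <- sample_patient_series(phantom, cspec)
  structure(list(phantom = phantom, controls = controls,
                 subjects = subjects, phantom_spec = pspec,
                 cohort_spec = cspec),
            class = "cohort")
}

#' Write a simulated cohort to disk
#'
#' Scans and GM maps are written as NIfTI-1; the parcellation as an integer
#' NIfTI plus a region CSV (`region_id,name,lobe,cerebellum_flag,ad_flag`);
#' volumetry and ground truth as CSV; and a manifest CSV with one row per
#' (subject, visit) binding file paths to arm and stratum.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ph <- cohort$phantom
  write_volume(new_volume(array(as.numeric(ph$atlas$labels),
                                dim(ph$atlas$labels)),
                          ph$spec$voxel_mm), file.path(dir, "atlas.nii.gz"))
  utils::write.csv(ph$atlas$regions, file.path(dir, "regions.csv"),
                   row.names = FALSE)
  cdir <- file.path(dir, "controls")
  dir.create(cdir, showWarnings = FALSE)
  for (i in seq_along(cohort$controls))
    write_volume(cohort$controls[[i]],
                 file.path(cdir, sprintf("control_%02d.nii.gz", i)))

  manifest <- list(); volrows <- list(); truths <- list()
  sdir <- file.path(dir, "subjects")
  dir.create(sdir, showWarnings = FALSE)
  for (sub in cohort$subjects) {
    tr <- sub$truth
    tr$subject <- sub$subject_id; tr$arm <- sub$arm; tr$stratum <- sub$stratum
    truths[[length(truths) + 1L]] <- tr
    for (v in names(sub$visits)) {
      e <- sub$visits[[v]]
      scan_path <- gm_path <- NA_character_
      if (!is.null(e$scan)) {
        scan_path <- file.path("subjects",
                               sprintf("%s_%s_pet.nii.gz", sub$subject_id, v))
        gm_path <- file.path("subjects",
                             sprintf("%s_%s_gm.nii.gz", sub$subject_id, v))
        write_volume(e$scan, file.path(dir, scan_path))
        write_volume(e$gm, file.path(dir, gm_path))
      }
      manifest[[length(manifest) + 1L]] <- data.frame(
        subject = sub$subject_id, arm = sub$arm, stratum = sub$stratum,
        visit = v, scan = scan_path, gm = gm_path,
        stringsAsFactors = FALSE)
      volrows[[length(volrows) + 1L]] <- cbind(
        data.frame(subject = sub$subject_id, arm = sub$arm,
                   stratum = sub$stratum, visit = v,
                   stringsAsFactors = FALSE),
        as.data.frame(as.list(e$volumetry)))
    }
  }
  utils::write.csv(do.call(rbind, manifest), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, volrows), file.path(dir, "volumetry.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, truths), file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
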