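#' Pipeline run configuration
#'
#' Collects every tunable constant of the analysis chain: preprocessing
#' (`fwhm_mm`), defect mapping (`z_threshold`, `severity_bins`,
#' `gm_threshold`, `delta_threshold`), voxel statistics (`p_voxel`,
#' `k_min`, `connectivity`), regional/volumetry testing (`alpha`), the
#' template SD floor, and the phantom/cohort generator arguments. A config
#' round-trips losslessly through YAML.
#'
#' @param seed integer master seed for the run.
#' @param fwhm_mm smoothing kernel FWHM, mm (default 8).
#' @param z_threshold defect threshold in SD units (default 2).
#' @param delta_threshold longitudinal Z-change threshold (default 0.5).
#' @param gm_threshold GM probability cutoff (default 0.5).
#' @param p_voxel voxel-level uncorrected p threshold (default 0.001).
#' @param k_min minimum cluster extent in voxels (default 50).
#' @param alpha regional/structure significance level (default 0.05).
#' @param connectivity cluster connectivity, 6/18/26 (default 18).
#' @param severity_bins strictly decreasing Z cut-points.
#' @param sd_floor template SD floor; `NULL` = 1% of in-brain mean.
#' @param phantom,cohort named lists of arguments forwarded to
#'   [phantom_spec()] / [cohort_spec()] (seeds are overridden by `seed`).
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1L, fwhm_mm = 8, z_threshold = 2,
                       delta_threshold = 0.5, gm_threshold = 0.5,
                       p_voxel = 0.001, k_min = 50, alpha = 0.05,
                       connectivity = 18,
                       severity_bins = c(-2, -3, -4), sd_floor = NULL,
                       phantom = list(), cohort = list()) {
  cfg <- structure(list(seed = as.integer(seed), fwhm_mm = fwhm_mm,
                        z_threshold = z_threshold,
                        delta_threshold = delta_threshold,
                        gm_threshold = gm_threshold, p_voxel = p_voxel,
                        k_min = k_min, alpha = alpha,
                        connectivity = connectivity,
                        severity_bins = severity_bins,
                        sd_floor = sd_floor,
                        phantom = phantom, cohort = cohort),
                   class = "run_config")
  validate_config(cfg)
  cfg
}

#' @rdname run_config
#' @param config object to validate.
#' @export
validate_config <- function(config) {
  with(config, {
    if (fwhm_mm <= 0) stop("invalid config: fwhm_mm must be positive")
    if (z_threshold <= 0) stop("invalid config: z_threshold must be positive")
    if (delta_threshold <= 0)
      stop("invalid config: delta_threshold must be positive")
    if (gm_threshold < 0 || gm_threshold > 1)
      stop("invalid config: gm_threshold must lie in [0, 1]")
    if (p_voxel <= 0 || p_voxel >= 1)
      stop("invalid config: p_voxel must lie in (0, 1)")
    if (k_min < 1) stop("invalid config: k_min must be at least 1")
    if (alpha <= 0 || alpha >= 1)
      stop("invalid config: alpha must lie in (0, 1)")
    if (!connectivity %in% c(6, 18, 26))
      stop("invalid config: connectivity must be 6, 18 or 26")
    if (any(diff(severity_bins) >= 0))
      stop("invalid config: severity_bins must be strictly decreasing")
  })
  invisible(TRUE)
}

#' Read / write a run configuration as YAML
#' @param config a `run_config`.
#' @param path YAML file path.
#' @return `path` (write) or a `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$severity_bins <- as.list(x$severity_bins)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$severity_bins <- as.numeric(unlist(x$severity_bins))
  do.call(run_config, x)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  write_run_config(config, f)
  unname(tools::md5sum(f))
}

arm_order <- function() c("placebo", "low_albumin", "low_albumin_ivig",
                          "high_albumin_ivig")

build_specs <- function(config) {
  pargs <- config$phantom; pargs$seed <- config$seed
  cargs <- config$cohort; cargs$seed <- config$seed
  if (!is.null(cargs$arms) && !is.data.frame(cargs$arms))
    cargs$arms <- as.data.frame(cargs$arms, stringsAsFactors = FALSE)
  list(phantom = do.call(phantom_spec, pargs),
       cohort = do.call(cohort_spec, cargs))
}

preprocessed_pairs <- function(pp_scans, subjects, arm, stratum, v0, v1) {
  sel <- vapply(subjects, function(s)
    s$arm == arm && (is.null(stratum) || s$stratum == stratum), logical(1))
  ids <- vapply(subjects[sel], `[[`, character(1), "subject_id")
  t0 <- lapply(ids, function(id) pp_scans[[id]][[v0]])
  t1 <- lapply(ids, function(id) pp_scans[[id]][[v1]])
  ok <- !vapply(t0, is.null, logical(1)) & !vapply(t1, is.null, logical(1))
  list(t0 = t0[ok], t1 = t1[ok], ids = ids[ok])
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates simulate -> preprocess -> normative template -> defect
#' maps -> regional metrics -> voxel statistics (progression mask, percent
#' loss, k-extents) -> volumetry, and writes per-arm summary tables plus a
#' manifest (config hash, seed, output checksums) under `out_dir`.
#' Identical config and seed give identical outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory; `NULL` keeps everything in memory.
#' @param cohort optionally, a pre-simulated [simulate_cohort()] result
#'   (its specs must match the config's seeds for reproducibility claims).
#' @return List of class `pipeline_run` with all stage outputs; see
#'   details in the package vignette.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         cohort = NULL) {
  validate_config(config)
  specs <- build_specs(config)
  if (is.null(cohort))
    cohort <- simulate_cohort(specs$phantom, specs$cohort)
  atlas <- cohort$phantom$atlas
  visits <- cohort$cohort_spec$visits
  pet_visits <- cohort$cohort_spec$pet_visits
  v_first <- pet_visits[1]
  v_last <- pet_visits[length(pet_visits)]

  # --- preprocessing -------------------------------------------------
  controls_pp <- lapply(cohort$controls, preprocess_scan, atlas = atlas,
                        fwhm_mm = config$fwhm_mm)
  template <- build_template(controls_pp, fwhm_mm = config$fwhm_mm,
                             sd_floor = config$sd_floor)

  pp_scans <- list()       # subject -> visit -> preprocessed volume
  defect_maps <- list()    # subject -> visit -> defect_map
  metrics_rows <- list()
  for (sub in cohort$subjects) {
    id <- sub$subject_id
    pp_scans[[id]] <- list()
    defect_maps[[id]] <- list()
    for (v in pet_visits) {
      e <- sub$visits[[v]]
      if (is.null(e$scan)) next
      pp <- preprocess_scan(e$scan, atlas, config$fwhm_mm)
      pp_scans[[id]][[v]] <- pp
      z <- compute_zmap(pp, template)
      cm <- build_correction_mask(e$gm, config$gm_threshold)
      dm <- classify_defects(z, cm, config$z_threshold,
                             config$severity_bins, visit = v)
      defect_maps[[id]][[v]] <- dm
      mr <- extract_regional_metrics(dm, pp, atlas, subject = id)
      mr$arm <- sub$arm; mr$stratum <- sub$stratum
      metrics_rows[[length(metrics_rows) + 1L]] <- mr
    }
  }
  regional <- do.call(rbind, metrics_rows)

  arms <- intersect(arm_order(), unique(regional$arm))
  params <- c("metabolism_intensity", "defect_extension", "defect_intensity")

  # --- regional longitudinal tests (summary-table machinery) ---------
  regional_tests <- list()
  for (arm in arms) {
    m0 <- regional[regional$arm == arm & regional$visit == v_first, ]
    m1 <- regional[regional$arm == arm & regional$visit == v_last, ]
    regional_tests[[arm]] <- lapply(stats::setNames(params, params),
      function(p) longitudinal_region_tests(m0, m1, p, config$alpha))
  }

  # --- voxel statistics ----------------------------------------------
  pl <- preprocessed_pairs(pp_scans, cohort$subjects, "placebo", NULL,
                           v_first, v_last)
  mask_ad <- build_mask_ad(pl$t0, pl$t1, config$p_voxel, config$k_min,
                           config$connectivity, v_first, v_last)

  strata <- c(list(all = NULL),
              stats::setNames(as.list(names(cohort$cohort_spec$severity_strata)),
                              names(cohort$cohort_spec$severity_strata)))
  pct_loss <- list(); k_extent <- list()
  for (sname in names(strata)) {
    pct_loss[[sname]] <- stats::setNames(rep(NA_real_, length(arms)), arms)
    k_extent[[sname]] <- stats::setNames(rep(NA_integer_, length(arms)), arms)
    for (arm in arms) {
      pr <- preprocessed_pairs(pp_scans, cohort$subjects, arm,
                               strata[[sname]], v_first, v_last)
      if (length(pr$t0) < 3L) next
      if (sum(mask_ad$mask) > 0L)
        pct_loss[[sname]][arm] <-
          mask_ad_percent_loss(pr$t0, pr$t1, mask_ad)$mean_percent_change
      tm <- paired_t_map(pr$t0, pr$t1, "decline", v_first, v_last)
      cl <- cluster_threshold(tm, config$p_voxel, config$k_min,
                              config$connectivity)
      k_extent[[sname]][arm] <- cl$total_k_extent
    }
  }

  # k-extent evolution over the follow-up contrasts, pooled strata
  evolution <- list()
  for (arm in arms) {
    ks <- c()
    for (v in setdiff(pet_visits, v_first)) {
      pr <- preprocessed_pairs(pp_scans, cohort$subjects, arm, NULL,
                               v_first, v)
      tm <- paired_t_map(pr$t0, pr$t1, "decline", v_first, v)
      cl <- cluster_threshold(tm, config$p_voxel, config$k_min,
                              config$connectivity)
      ks[v] <- cl$total_k_extent
    }
    evolution[[arm]] <- ks
  }

  # --- volumetry ------------------------------------------------------
  volumetry <- derive_tiv_fractions(cohort_volumetry(cohort$subjects))
  volumetry_tests <- lapply(stats::setNames(arms, arms), function(arm)
    structure_change_tests(volumetry[volumetry$arm == arm, ],
                           from_visit = visits[1],
                           to_visit = visits[length(visits)],
                           alpha = config$alpha))

  run <- structure(list(
    config = config, config_hash = config_hash(config),
    cohort = cohort, template = template,
    pp_scans = pp_scans, defect_maps = defect_maps,
    regional = regional, regional_tests = regional_tests,
    mask_ad = mask_ad, pct_loss = pct_loss, k_extent = k_extent,
    evolution = evolution,
    volumetry = volumetry, volumetry_tests = volumetry_tests,
    arms = arms), class = "pipeline_run")

  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

fmt_count_pct <- function(cp) sprintf("%d (%.1f%%)", cp$n_significant, cp$pct)

#' Summary tables of a pipeline run
#'
#' Builds the four per-arm summary tables (columns ordered placebo, low
#' albumin, low albumin + IVIG, high albumin + IVIG; percentages to one
#' decimal):
#' \describe{
#'   \item{volumetry_changes}{significant subcortical structures between
#'     first and last visit, with `n/15 (pct)` totals;}
#'   \item{regional_changes}{count and percentage of atlas regions with
#'     significant change per regional parameter;}
#'   \item{maskad_percent_loss}{mean percent metabolism change in the
#'     progression mask, pooled and per severity stratum;}
#'   \item{k_extent}{total surviving cluster extent (voxels), pooled and
#'     per severity stratum.}
#' }
#'
#' @param run a `pipeline_run` (or a run directory written by
#'   [run_pipeline()]).
#' @return Named list of four data.frames.
#' @export
report_tables <- function(run) {
  if (is.character(run)) return(read_run_tables(run))
  stopifnot(inherits(run, "pipeline_run"))
  arms <- run$arms
  blank <- stats::setNames(rep(NA_character_, length(arm_order())),
                           arm_order())

  t1 <- data.frame(row = c("significant_structures", "total"))
  for (a in arm_order()) {
    col <- rep(NA_character_, 2)
    if (a %in% arms) {
      vt <- run$volumetry_tests[[a]]
      col <- c(paste(vt$significant, collapse = "; "),
               sprintf("%d/%d (%.1f%%)", vt$summary$n_significant,
                       vt$summary$total, vt$summary$pct))
    }
    t1[[a]] <- col
  }

  params <- c("metabolism_intensity", "defect_extension", "defect_intensity")
  t2 <- data.frame(parameter = params)
  for (a in arm_order()) {
    col <- rep(NA_character_, length(params))
    if (a %in% arms)
      col <- vapply(params, function(p)
        fmt_count_pct(run$regional_tests[[a]][[p]]$summary), character(1))
    t2[[a]] <- col
  }

  strata <- names(run$pct_loss)
  t3 <- data.frame(stratum = strata)
  t4 <- data.frame(stratum = strata)
  for (a in arm_order()) {
    t3[[a]] <- if (a %in% arms)
      round(vapply(strata, function(s) run$pct_loss[[s]][[a]], numeric(1)), 1)
      else NA_real_
    t4[[a]] <- if (a %in% arms)
      vapply(strata, function(s) run$k_extent[[s]][[a]], numeric(1))
      else NA_real_
  }

  list(volumetry_changes = t1, regional_changes = t2,
       maskad_percent_loss = t3, k_extent = t4)
}

#' Write all stage outputs of a run to disk
#'
#' Tables as CSV (each with a header comment line carrying the config hash
#' and seed), the progression mask and template as NIfTI, regional metrics
#' and volumetry as tidy CSV, and a manifest with output checksums.
#'
#' @param run a `pipeline_run`.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- sprintf("# config_hash=%s seed=%d", run$config_hash,
                   run$config$seed)
  wcsv <- function(df, name) {
    p <- file.path(out_dir, name)
    con <- file(p, "w")
    writeLines(stamp, con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
  }
  tabs <- report_tables(run)
  wcsv(tabs$volumetry_changes, "table_volumetry_changes.csv")
  wcsv(tabs$regional_changes, "table_regional_changes.csv")
  wcsv(tabs$maskad_percent_loss, "table_maskad_percent_loss.csv")
  wcsv(tabs$k_extent, "table_k_extent.csv")
  wcsv(run$regional, "regional_metrics.csv")
  wcsv(run$volumetry, "volumetry.csv")
  wcsv(run$mask_ad$cluster_result$clusters, "maskad_clusters.csv")
  ev <- do.call(rbind, lapply(names(run$evolution), function(a)
    data.frame(arm = a, visit = names(run$evolution[[a]]),
               total_k_extent = unname(run$evolution[[a]]))))
  wcsv(ev, "k_extent_evolution.csv")
  write_template(run$template, file.path(out_dir, "template"))
  write_volume(new_volume(array(as.numeric(run$mask_ad$mask),
                                dim(run$mask_ad$mask)),
                          run$template$mean$voxel_mm),
               file.path(out_dir, "mask_ad.nii.gz"), datatype = "uint8")
  write_run_config(run$config, file.path(out_dir, "config.yaml"))
  csvs <- list.files(out_dir, "\\.csv$", full.names = TRUE)
  manifest <- data.frame(file = basename(csvs),
                         md5 = unname(tools::md5sum(csvs)))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}

read_run_tables <- function(out_dir) {
  rd <- function(name) {
    p <- file.path(out_dir, name)
    if (!file.exists(p)) stop("missing stage output: ", name)
    utils::read.csv(p, comment.char = "#", stringsAsFactors = FALSE)
  }
  list(volumetry_changes = rd("table_volumetry_changes.csv"),
       regional_changes = rd("table_regional_changes.csv"),
       maskad_percent_loss = rd("table_maskad_percent_loss.csv"),
       k_extent = rd("table_k_extent.csv"))
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run: %d subjects, %d controls, seed %d, hash %s>\n",
              length(x$cohort$subjects), length(x$cohort$controls),
              x$config$seed, substr(x$config_hash, 1, 8)))
  invisible(x)
}

#' Export three orthogonal slices of a volume as PNG-ready matrices
#'
#' Plain orthogonal mid-slices for quick visual inspection (no rendering
#' beyond this is provided).
#'
#' @param volume a `pet_volume`.
#' @return List of three matrices (`axial`, `coronal`, `sagittal`).
#' @export
orthogonal_slices <- function(volume) {
  stopifnot(is_volume(volume))
  d <- dim(volume$data)
  list(axial = volume$data[, , ceiling(d[3] / 2)],
       coronal = volume$data[, ceiling(d[2] / 2), ],
       sagittal = volume$data[ceiling(d[1] / 2), , ])
}
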