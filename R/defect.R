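#' Voxel-wise Z-score map against a normative template
#'
#' `z = (patient - mean) / sd` at every in-brain voxel of the template;
#' zero outside the brain mask. The patient scan must already be
#' cerebellum-normalized and smoothed on the template grid.
#'
#' @param patient_scan preprocessed `pet_volume`.
#' @param template a [build_template()] result.
#' @return `pet_volume` of Z-scores.
#' @export
compute_zmap <- function(patient_scan, template) {
  stopifnot(inherits(template, "normal_template"))
  check_same_grid(patient_scan, template$mean)
  z <- array(0, dim(patient_scan$data))
  m <- template$mask
  z[m] <- (patient_scan$data[m] - template$mean$data[m]) / template$sd$data[m]
  new_volume(z, patient_scan$voxel_mm, patient_scan$space)
}

#' Atrophy-correction mask from a gray-matter probability map
#'
#' Voxels whose GM probability falls below the threshold are attributed to
#' tissue loss or ventricular dilation rather than hypometabolism and are
#' excluded from defect statistics. The boundary uses the `>=` convention:
#' probability exactly at the threshold is kept.
#'
#' @param gm_probability `pet_volume` with values in `[0, 1]`.
#' @param threshold GM probability cutoff, default 0.5.
#' @return 3D logical array.
#' @export
build_correction_mask <- function(gm_probability, threshold = 0.5) {
  stopifnot(is_volume(gm_probability))
  p <- gm_probability$data
  if (min(p) < 0 || max(p) > 1)
    stop("gray-matter probabilities must lie in [0, 1]")
  p >= threshold
}

#' Classify defect voxels and grade severity
#'
#' A voxel is a metabolic defect when its Z-score lies at least
#' `z_threshold` SDs below the normative mean (`z <= -z_threshold`,
#' boundary inclusive) and it survives the atrophy-correction mask.
#' Severity grades defects in whole-SD steps: with the default bins
#' `c(-2, -3, -4)` a voxel scores the number of cut-points at or above its
#' Z (z in (-3, -2] -> 1, (-4, -3] -> 2, <= -4 -> 3). Voxels outside the
#' correction mask carry severity 0 and are excluded from all regional
#' statistics downstream.
#'
#' @param z `pet_volume` of Z-scores.
#' @param correction_mask logical array from [build_correction_mask()].
#' @param z_threshold positive defect threshold in SD units (default 2).
#' @param severity_bins strictly decreasing Z cut-points starting at
#'   `-z_threshold`.
#' @param visit visit label carried along for provenance.
#' @return Object of class `defect_map` with `z`, `defect` (logical),
#'   `severity` (integer array), `correction_mask`, `visit`,
#'   `z_threshold`, `severity_bins`.
#' @export
classify_defects <- function(z, correction_mask, z_threshold = 2,
                             severity_bins = c(-2, -3, -4),
                             visit = "M0") {
  stopifnot(is_volume(z), is.logical(correction_mask))
  if (!identical(dim(z$data), dim(correction_mask)))
    stop("grid mismatch: z map and correction mask shapes differ")
  if (any(diff(severity_bins) >= 0))
    stop("severity_bins must be strictly decreasing")
  if (abs(severity_bins[1] + z_threshold) > 1e-12)
    stop("severity_bins must start at -z_threshold")
  defect <- (z$data <= -z_threshold) & correction_mask
  sev <- array(0L, dim(z$data))
  for (cut in severity_bins)
    sev <- sev + as.integer(z$data <= cut)
  sev[!correction_mask] <- 0L
  sev[!defect] <- 0L
  structure(list(z = z, defect = defect, severity = sev,
                 correction_mask = correction_mask, visit = visit,
                 z_threshold = z_threshold, severity_bins = severity_bins),
            class = "defect_map")
}

#' @export
print.defect_map <- function(x, ...) {
  cat(sprintf("<defect_map %s: %d defect voxels (max severity %d) of %d in-mask>\n",
              x$visit, sum(x$defect), max(x$severity), sum(x$correction_mask)))
  invisible(x)
}

#' Group baseline defect pattern
#'
#' Voxel-wise mean of the individual severity maps across subjects; voxels
#' outside a subject's correction mask contribute 0 (their severity).
#'
#' @param defect_maps nonempty list of `defect_map`s on a common grid.
#' @return `pet_volume` of mean severity.
#' @export
baseline_group_pattern <- function(defect_maps) {
  if (length(defect_maps) == 0L)
    stop("need at least one defect map")
  d <- dim(defect_maps[[1]]$severity)
  acc <- array(0, d)
  for (dm in defect_maps) {
    stopifnot(inherits(dm, "defect_map"))
    if (!identical(dim(dm$severity), d))
      stop("grid mismatch across defect maps")
    acc <- acc + dm$severity
  }
  new_volume(acc / length(defect_maps),
             defect_maps[[1]]$z$voxel_mm, defect_maps[[1]]$z$space)
}

visit_rank <- function(v) visit_month(v)

#' Longitudinal improved / maintained / worsened voxel classification
#'
#' Compares a subject's defect maps at two visits. A voxel improved when it
#' was a defect at the first visit and no longer is at the second, or when
#' its Z-score rose by more than `delta_threshold`; it worsened when it
#' became a defect, or when its Z-score fell by `delta_threshold` or more
#' (the improvement boundary is strict, the worsening boundary inclusive —
#' "more than 0.5" vs "worsened by 0.5"); otherwise it is maintained.
#' Status-change rules take precedence over the delta-Z rules when the two
#' disagree; the number of such conflicts is recorded. Voxels excluded by
#' the atrophy-correction mask (by default at either visit) are classed
#' `outside`.
#'
#' @param map_t0,map_t1 `defect_map`s at the earlier and later visit.
#' @param delta_threshold Z-score change threshold, default 0.5.
#' @param mask_policy which correction masks define the `outside` class:
#'   `"both"` (intersection, default), `"later"`, or `"earlier"`.
#' @return Object of class `longitudinal_classes`: `classes` (integer
#'   array coded 0 = outside, 1 = improved, 2 = maintained, 3 = worsened),
#'   `code_table`, `from_visit`, `to_visit`, `delta_threshold`,
#'   `rule_conflicts`.
#' @export
classify_longitudinal <- function(map_t0, map_t1, delta_threshold = 0.5,
                                  mask_policy = c("both", "later", "earlier")) {
  stopifnot(inherits(map_t0, "defect_map"), inherits(map_t1, "defect_map"))
  mask_policy <- match.arg(mask_policy)
  if (delta_threshold <= 0) stop("delta_threshold must be positive")
  if (!identical(dim(map_t0$z$data), dim(map_t1$z$data)))
    stop("grid mismatch between visits")
  if (visit_rank(map_t0$visit) >= visit_rank(map_t1$visit))
    stop("visits out of order: '", map_t0$visit, "' is not earlier than '",
         map_t1$visit, "'")
  inside <- switch(mask_policy,
                   both = map_t0$correction_mask & map_t1$correction_mask,
                   later = map_t1$correction_mask,
                   earlier = map_t0$correction_mask)
  dz <- map_t1$z$data - map_t0$z$data
  imp_status <- map_t0$defect & !map_t1$defect
  wor_status <- !map_t0$defect & map_t1$defect
  imp_dz <- dz > delta_threshold
  wor_dz <- dz <= -delta_threshold

  cls <- array(2L, dim(dz))                      # maintained
  cls[imp_dz] <- 1L
  cls[wor_dz] <- 3L
  cls[imp_status] <- 1L                          # status change wins
  cls[wor_status] <- 3L
  cls[!inside] <- 0L

  conflicts <- sum(((imp_status & wor_dz) | (wor_status & imp_dz)) & inside)
  structure(list(classes = cls,
                 code_table = c(outside = 0L, improved = 1L,
                                maintained = 2L, worsened = 3L),
                 from_visit = map_t0$visit, to_visit = map_t1$visit,
                 delta_threshold = delta_threshold,
                 mask_policy = mask_policy,
                 rule_conflicts = conflicts),
            class = "longitudinal_classes")
}

#' @export
print.longitudinal_classes <- function(x, ...) {
  tab <- table(factor(x$classes, levels = 0:3,
                      labels = names(x$code_table)))
  cat(sprintf("<longitudinal_classes %s->%s: %s; %d rule conflicts>\n",
              x$from_visit, x$to_visit,
              paste(names(tab), tab, sep = "=", collapse = " "),
              x$rule_conflicts))
  invisible(x)
}

#' Write a defect map's volumes as NIfTI
#'
#' Z as float32; severity, defect and correction masks as uint8.
#'
#' @param dm a `defect_map`.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return `dir`, invisibly.
#' @export
write_defect_map <- function(dm, dir, prefix = "subject") {
  stopifnot(inherits(dm, "defect_map"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vx <- dm$z$voxel_mm
  write_volume(dm$z, file.path(dir, paste0(prefix, "_z.nii.gz")))
  write_volume(new_volume(array(as.numeric(dm$severity), dim(dm$severity)), vx),
               file.path(dir, paste0(prefix, "_severity.nii.gz")),
               datatype = "uint8")
  write_volume(new_volume(array(as.numeric(dm$defect), dim(dm$defect)), vx),
               file.path(dir, paste0(prefix, "_defect.nii.gz")),
               datatype = "uint8")
  write_volume(new_volume(array(as.numeric(dm$correction_mask),
                                dim(dm$correction_mask)), vx),
               file.path(dir, paste0(prefix, "_mask.nii.gz")),
               datatype = "uint8")
  invisible(dir)
}
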