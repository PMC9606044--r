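#' Extract the three regional FDG-PET parameters
#'
#' For every atlas region, computed over the region's voxels inside the
#' subject's atrophy-correction mask only:
#' \describe{
#'   \item{metabolism_intensity}{mean normalized counts from the
#'     preprocessed scan;}
#'   \item{defect_extension}{percentage of in-mask voxels classified as
#'     defect (0-100);}
#'   \item{defect_intensity}{mean severity grade over in-mask voxels.}
#' }
#' A region fully removed by the correction mask gets `NA` for all three —
#' never a silent 0.
#'
#' @param defect_map a [classify_defects()] result for one subject/visit.
#' @param scan the normalized+smoothed `pet_volume` the map was computed
#'   from.
#' @param atlas an `atlas_parcellation` on the same grid.
#' @param subject subject id carried into the output.
#' @return data.frame: `subject`, `visit`, `region_id`, `n_voxels` (in
#'   mask), `metabolism_intensity`, `defect_extension`, `defect_intensity`.
#' @export
extract_regional_metrics <- function(defect_map, scan, atlas,
                                     subject = "S000") {
  stopifnot(inherits(defect_map, "defect_map"), is_volume(scan),
            is_atlas(atlas))
  if (!identical(dim(scan$data), dim(atlas$labels)))
    stop("grid mismatch: scan and atlas shapes differ")
  if (!identical(dim(defect_map$z$data), dim(atlas$labels)))
    stop("grid mismatch: defect map and atlas shapes differ")
  ids <- atlas$regions$region_id
  lab <- as.integer(atlas$labels)
  inmask <- as.logical(defect_map$correction_mask)
  keep <- inmask & lab > 0L
  labk <- lab[keep]
  f <- factor(labk, levels = ids)
  nvox <- as.integer(table(f))
  s_scan <- tapply(scan$data[keep], f, mean)
  s_def <- tapply(as.numeric(defect_map$defect[keep]), f, mean)
  s_sev <- tapply(as.numeric(defect_map$severity[keep]), f, mean)
  out <- data.frame(subject = subject, visit = defect_map$visit,
                    region_id = ids, n_voxels = nvox,
                    metabolism_intensity = as.numeric(s_scan),
                    defect_extension = 100 * as.numeric(s_def),
                    defect_intensity = as.numeric(s_sev),
                    stringsAsFactors = FALSE)
  out$metabolism_intensity[out$n_voxels == 0L] <- NA_real_
  out$defect_extension[out$n_voxels == 0L] <- NA_real_
  out$defect_intensity[out$n_voxels == 0L] <- NA_real_
  out
}

#' Count-to-percentage summary arithmetic
#'
#' The per-arm table convention: a count of significant regions out of a
#' total, with the percentage rounded to one decimal.
#'
#' @param n_significant integer count(s).
#' @param total total number of regions/structures.
#' @return data.frame with `n_significant`, `total`, `pct`.
#' @export
count_percent <- function(n_significant, total) {
  data.frame(n_significant = as.integer(n_significant),
             total = as.integer(total),
             pct = round(100 * n_significant / total, 1))
}

# paired two-sided t p-value on a vector of differences; constant (zero
# variance) differences are never declared significant
paired_p <- function(d) {
  d <- d[is.finite(d)]
  if (length(d) < 3L) return(NA_real_)
  if (stats::sd(d) == 0) return(1)
  stats::t.test(d)$p.value
}

#' Per-region paired longitudinal tests
#'
#' For one treatment arm and one regional parameter, tests the per-subject
#' change between two visits with a two-sided paired Student's t-test per
#' region, and counts the regions significant at `alpha` (raw p-values, no
#' multiple-testing correction — matching the convention the summary table
#' reproduces; set `fdr = TRUE` for a Benjamini-Hochberg variant).
#'
#' @param metrics_t0,metrics_t1 data.frames from
#'   [extract_regional_metrics()] stacked over the arm's subjects, at the
#'   earlier and later visit.
#' @param parameter one of `"metabolism_intensity"`,
#'   `"defect_extension"`, `"defect_intensity"`.
#' @param alpha significance level, default 0.05.
#' @param fdr apply Benjamini-Hochberg across regions before counting.
#' @return List: `per_region` (data.frame `region_id`, `n_pairs`,
#'   `mean_change`, `p`), `significant_ids`, `summary` (a
#'   [count_percent()] row).
#' @export
longitudinal_region_tests <- function(metrics_t0, metrics_t1,
                                      parameter = "metabolism_intensity",
                                      alpha = 0.05, fdr = FALSE) {
  stopifnot(parameter %in% c("metabolism_intensity", "defect_extension",
                             "defect_intensity"))
  subs <- intersect(unique(metrics_t0$subject), unique(metrics_t1$subject))
  if (length(subs) < 3L)
    stop("need at least 3 paired subjects for a per-region t-test")
  m0 <- metrics_t0[metrics_t0$subject %in% subs, ]
  m1 <- metrics_t1[metrics_t1$subject %in% subs, ]
  ids <- sort(unique(m0$region_id))
  per <- lapply(ids, function(r) {
    a <- m0[m0$region_id == r, ]
    b <- m1[m1$region_id == r, ]
    a <- a[match(subs, a$subject), parameter]
    b <- b[match(subs, b$subject), parameter]
    d <- b - a
    data.frame(region_id = r, n_pairs = sum(is.finite(d)),
               mean_change = mean(d, na.rm = TRUE), p = paired_p(d))
  })
  per <- do.call(rbind, per)
  p_use <- if (fdr) stats::p.adjust(per$p, "BH") else per$p
  sig <- per$region_id[!is.na(p_use) & p_use < alpha]
  list(per_region = per, significant_ids = sig,
       summary = count_percent(length(sig), length(ids)))
}

#' Per-region cross-sectional ANOVA between arms
#'
#' One-way fixed-effects ANOVA of a regional parameter across treatment
#' arms at a single visit (classical equal-variance F-test).
#'
#' @param metrics data.frame from [extract_regional_metrics()] stacked
#'   over all subjects at one visit, with an `arm` column attached.
#' @param parameter regional parameter name, as in
#'   [longitudinal_region_tests()].
#' @param alpha significance level.
#' @return List: `per_region` (`region_id`, `p`), `significant_ids`,
#'   `summary`.
#' @export
cross_sectional_group_tests <- function(metrics,
                                        parameter = "metabolism_intensity",
                                        alpha = 0.05) {
  if (!"arm" %in% names(metrics))
    stop("metrics must carry an 'arm' column")
  arms <- unique(metrics$arm)
  if (length(arms) < 2L) stop("need at least 2 arms for ANOVA")
  ids <- sort(unique(metrics$region_id))
  per <- lapply(ids, function(r) {
    d <- metrics[metrics$region_id == r, ]
    ok <- is.finite(d[[parameter]])
    d <- d[ok, ]
    p <- if (length(unique(d$arm)) < 2L || nrow(d) < 3L ||
             stats::sd(d[[parameter]]) == 0) NA_real_
         else stats::oneway.test(d[[parameter]] ~ factor(d$arm),
                                 var.equal = TRUE)$p.value
    data.frame(region_id = r, p = p)
  })
  per <- do.call(rbind, per)
  sig <- per$region_id[!is.na(per$p) & per$p < alpha]
  list(per_region = per, significant_ids = sig,
       summary = count_percent(length(sig), length(ids)))
}
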