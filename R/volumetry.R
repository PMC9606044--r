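#' Derive total intracranial volume and tissue fractions
#'
#' TIV is always derived, never stored: `TIV = GM + WM + CSF`. Tissue
#' fractions are each compartment over TIV and sum to 1 by construction.
#'
#' @param volumetry data.frame with one row per (subject, visit) and
#'   columns `gm`, `wm`, `csf` (mm3) plus the 15 subcortical structures
#'   (see [volumetry_structures()]).
#' @return The input with `tiv`, `gm_fraction`, `wm_fraction`,
#'   `csf_fraction` columns appended.
#' @export
derive_tiv_fractions <- function(volumetry) {
  need <- c("gm", "wm", "csf")
  if (!all(need %in% names(volumetry)))
    stop("volumetry table must carry gm, wm and csf columns")
  vols <- c(volumetry_structures(), need)
  vols <- vols[vols %in% names(volumetry)]
  bad <- vapply(vols, function(cn) any(volumetry[[cn]] <= 0), logical(1))
  if (any(bad))
    stop("nonpositive volume in column(s): ",
         paste(vols[bad], collapse = ", "))
  volumetry$tiv <- volumetry$gm + volumetry$wm + volumetry$csf
  volumetry$gm_fraction <- volumetry$gm / volumetry$tiv
  volumetry$wm_fraction <- volumetry$wm / volumetry$tiv
  volumetry$csf_fraction <- volumetry$csf / volumetry$tiv
  volumetry
}

#' Per-structure longitudinal volumetry tests for one arm
#'
#' Two-sided paired Student's t on per-subject volume change between two
#' visits, for each of the 15 subcortical structures; counts the
#' structures significant at `alpha` (raw p-values, no multiple-testing
#' correction). Volumes can optionally be TIV-normalized first.
#'
#' @param volumetry data.frame restricted to one arm, rows per
#'   (subject, visit), structure columns in mm3 plus `gm`,`wm`,`csf`.
#' @param from_visit,to_visit visits compared, defaults `"M0"`/`"M14"`.
#' @param alpha significance level, default 0.05.
#' @param normalize_tiv divide structure volumes by the visit's TIV first.
#' @param structures structure columns to test.
#' @return List: `per_structure` (data.frame `structure`, `n_pairs`,
#'   `mean_change`, `p`), `significant` (character vector), `summary`
#'   (a [count_percent()] row over the structure count).
#' @export
structure_change_tests <- function(volumetry, from_visit = "M0",
                                   to_visit = "M14", alpha = 0.05,
                                   normalize_tiv = FALSE,
                                   structures = volumetry_structures()) {
  if (!all(structures %in% names(volumetry)))
    stop("volumetry table is missing structure column(s): ",
         paste(setdiff(structures, names(volumetry)), collapse = ", "))
  a <- volumetry[volumetry$visit == from_visit, ]
  b <- volumetry[volumetry$visit == to_visit, ]
  subs <- intersect(a$subject, b$subject)
  if (length(subs) < 3L)
    stop("need at least 3 paired subjects (have ", length(subs), ")")
  a <- a[match(subs, a$subject), ]
  b <- b[match(subs, b$subject), ]
  if (normalize_tiv) {
    a <- derive_tiv_fractions(a); b <- derive_tiv_fractions(b)
    for (s in structures) { a[[s]] <- a[[s]] / a$tiv; b[[s]] <- b[[s]] / b$tiv }
  }
  per <- lapply(structures, function(s) {
    d <- b[[s]] - a[[s]]
    data.frame(structure = s, n_pairs = length(d),
               mean_change = mean(d), p = paired_p(d),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  sig <- per$structure[!is.na(per$p) & per$p < alpha]
  list(per_structure = per, significant = sig,
       summary = count_percent(length(sig), length(structures)))
}

#' Cross-sectional volumetry ANOVA between arms at one visit
#'
#' One-way equal-variance ANOVA of each structure volume across arms.
#'
#' @param volumetry data.frame with `arm` column, all arms, one visit.
#' @param visit the visit to test.
#' @param alpha significance level.
#' @param structures structure columns to test.
#' @return List: `per_structure` (`structure`, `p`), `significant`,
#'   `summary`.
#' @export
volumetry_group_tests <- function(volumetry, visit = "M0", alpha = 0.05,
                                  structures = volumetry_structures()) {
  if (!"arm" %in% names(volumetry)) stop("volumetry must carry an 'arm' column")
  d <- volumetry[volumetry$visit == visit, ]
  if (length(unique(d$arm)) < 2L) stop("need at least 2 arms")
  per <- lapply(structures, function(s) {
    p <- if (stats::sd(d[[s]]) == 0) NA_real_
         else stats::oneway.test(d[[s]] ~ factor(d$arm),
                                 var.equal = TRUE)$p.value
    data.frame(structure = s, p = p, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  sig <- per$structure[!is.na(per$p) & per$p < alpha]
  list(per_structure = per, significant = sig,
       summary = count_percent(length(sig), length(structures)))
}

#' Collect the volumetry tables of a simulated cohort
#'
#' @param subjects list of `subject_record`s from
#'   [sample_patient_series()].
#' @return data.frame, one row per (subject, visit), with `arm` and
#'   `stratum` columns plus all volumetry measures.
#' @export
cohort_volumetry <- function(subjects) {
  rows <- list()
  for (sub in subjects)
    for (v in names(sub$visits))
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(subject = sub$subject_id, arm = sub$arm,
                   stratum = sub$stratum, visit = v,
                   stringsAsFactors = FALSE),
        as.data.frame(as.list(sub$visits[[v]]$volumetry)))
  do.call(rbind, rows)
}
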