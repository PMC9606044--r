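#' Build a normative FDG-PET reference template
#'
#' Computes the voxel-wise mean and sample standard deviation (n-1
#' denominator) across preprocessed control scans. The brain mask is the
#' set of voxels where the mean is positive. Inside the mask the SD is
#' floored at `sd_floor` so Z-scores are always defined; the default floor
#' is 1% of the in-brain mean uptake, which only binds at (near-)zero
#' variance voxels. Controls are expected to be cerebellum-normalized and
#' smoothed already — the pipeline enforces the ordering, this function
#' does not re-check it numerically.
#'
#' @param controls list of >= 2 `pet_volume` scans on a common grid.
#' @param fwhm_mm smoothing FWHM the controls were preprocessed with
#'   (recorded for provenance).
#' @param sd_floor positive floor for the SD volume; `NULL` (default)
#'   means 1% of the in-brain mean of the mean image.
#' @return Object of class `normal_template` with `mean` and `sd`
#'   (`pet_volume`s), `mask` (logical array), `n_controls`, `fwhm_mm`,
#'   `sd_floor`.
#' @export
build_template <- function(controls, fwhm_mm = 8, sd_floor = NULL) {
  if (!is.list(controls) || length(controls) < 2L)
    stop("need at least 2 control scans to build a template")
  ref <- controls[[1]]
  for (v in controls[-1]) check_same_grid(ref, v)
  n <- length(controls)
  X <- vapply(controls, function(v) as.numeric(v$data),
              numeric(length(ref$data)))
  mu <- rowMeans(X)
  sdv <- sqrt(rowSums((X - mu)^2) / (n - 1))
  mask <- mu > 0
  if (is.null(sd_floor)) {
    sd_floor <- 0.01 * mean(mu[mask])
  }
  if (!is.finite(sd_floor) || sd_floor <= 0)
    stop("sd_floor must be positive")
  sdv[mask] <- pmax(sdv[mask], sd_floor)
  d <- dim(ref$data)
  structure(list(
    mean = new_volume(array(mu, d), ref$voxel_mm, ref$space),
    sd = new_volume(array(sdv, d), ref$voxel_mm, ref$space),
    mask = array(mask, d),
    n_controls = n, fwhm_mm = fwhm_mm, sd_floor = sd_floor),
    class = "normal_template")
}

#' @export
print.normal_template <- function(x, ...) {
  cat(sprintf("<normal_template from %d controls, %d in-brain voxels, sd_floor %.4g>\n",
              x$n_controls, sum(x$mask), x$sd_floor))
  invisible(x)
}

#' Persist / load a normative template
#'
#' Two NIfTI volumes (`mean.nii.gz`, `sd.nii.gz`) plus a JSON sidecar
#' recording `n_controls`, `fwhm_mm` and `sd_floor`.
#'
#' @param template a `normal_template`.
#' @param dir directory to write into (created if needed).
#' @return `dir` (write) or a `normal_template` (read), invisibly.
#' @export
write_template <- function(template, dir) {
  stopifnot(inherits(template, "normal_template"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(template$mean, file.path(dir, "mean.nii.gz"))
  write_volume(template$sd, file.path(dir, "sd.nii.gz"))
  jsonlite::write_json(
    list(n_controls = template$n_controls, fwhm_mm = template$fwhm_mm,
         sd_floor = template$sd_floor),
    file.path(dir, "template.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_template
#' @param space space tag to attach on read.
#' @export
read_template <- function(dir, space = "phantom") {
  meta <- jsonlite::read_json(file.path(dir, "template.json"),
                              simplifyVector = TRUE)
  mu <- read_volume(file.path(dir, "mean.nii.gz"), space)
  sdv <- read_volume(file.path(dir, "sd.nii.gz"), space)
  structure(list(mean = mu, sd = sdv, mask = mu$data > 0,
                 n_controls = meta$n_controls, fwhm_mm = meta$fwhm_mm,
                 sd_floor = meta$sd_floor),
            class = "normal_template")
}
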