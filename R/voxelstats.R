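#' Voxel-wise paired t contrast map
#'
#' Per voxel, a paired Student's t on the per-subject difference
#' (later - earlier). The default direction tests metabolic decline
#' (uptake at the later visit lower), giving a one-sided p-value
#' `P(T <= t)`; `direction = "increase"` reverses it. Voxels with zero
#' variance across pairs get t = 0, p = 1, as do voxels outside the
#' intersected analysis mask. Group-level voxel statistics run on the
#' normalized+smoothed scans without the per-subject atrophy masks, which
#' would break paired voxel correspondence; only the intersected analysis
#' mask is applied. By default that mask is the conventional implicit
#' relative-intensity mask for brain PET: a voxel is analysed only where
#' every scan exceeds 0.8 times its own global mean, the global mean being
#' taken over voxels above one eighth of the volume mean. This excludes
#' the low-intensity halo that smoothing smears beyond the brain boundary,
#' where relative changes are artefacts of partial-volume mixing with
#' background rather than metabolism.
#'
#' @param scans_t0,scans_t1 lists of preprocessed `pet_volume`s, paired by
#'   position (same subject at the two visits); at least 3 pairs.
#' @param direction `"decline"` (default) or `"increase"`.
#' @param from_visit,to_visit visit labels for provenance.
#' @param analysis_mask explicit logical array of voxels to analyse, or
#'   `NULL` (default) for implicit relative-intensity masking.
#' @return Object of class `t_contrast_map`: `t`, `p` (`pet_volume`s),
#'   `df`, `n_pairs`, `direction`, `contrast`.
#' @export
paired_t_map <- function(scans_t0, scans_t1,
                         direction = c("decline", "increase"),
                         from_visit = "M0", to_visit = "M14",
                         analysis_mask = NULL) {
  direction <- match.arg(direction)
  if (length(scans_t0) != length(scans_t1))
    stop("unpaired inputs: visit lists differ in length")
  n <- length(scans_t0)
  if (n < 3L) stop("need at least 3 pairs for a paired t-map")
  ref <- scans_t0[[1]]
  for (v in c(scans_t0[-1], scans_t1)) check_same_grid(ref, v)
  nv <- length(ref$data)
  implicit <- function(x) {
    rough <- x[x > mean(x) / 8]
    if (length(rough) == 0L) return(rep(FALSE, length(x)))
    x > 0.8 * mean(rough)
  }
  D <- matrix(0, nv, n)
  inb <- if (is.null(analysis_mask)) rep(TRUE, nv)
         else as.logical(analysis_mask)
  for (i in seq_len(n)) {
    a <- as.numeric(scans_t0[[i]]$data)
    b <- as.numeric(scans_t1[[i]]$data)
    D[, i] <- b - a
    inb <- inb & if (is.null(analysis_mask)) implicit(a) & implicit(b)
                 else a > 0 & b > 0
  }
  md <- rowMeans(D)
  sdd <- sqrt(rowSums((D - md)^2) / (n - 1))
  df <- n - 1L
  tval <- rep(0, nv)
  ok <- inb & sdd > 0
  tval[ok] <- md[ok] / (sdd[ok] / sqrt(n))
  p <- rep(1, nv)
  p[ok] <- if (direction == "decline") stats::pt(tval[ok], df)
           else stats::pt(tval[ok], df, lower.tail = FALSE)
  d <- dim(ref$data)
  structure(list(t = new_volume(array(tval, d), ref$voxel_mm, ref$space),
                 p = new_volume(array(p, d), ref$voxel_mm, ref$space),
                 df = df, n_pairs = n, direction = direction,
                 contrast = c(from = from_visit, to = to_visit)),
            class = "t_contrast_map")
}

#' @export
print.t_contrast_map <- function(x, ...) {
  cat(sprintf("<t_contrast_map %s->%s (%s), df=%d, min p=%.3g>\n",
              x$contrast["from"], x$contrast["to"], x$direction, x$df,
              min(x$p$data)))
  invisible(x)
}

neighbour_offsets <- function(connectivity) {
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  manh <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  keep <- switch(as.character(connectivity),
                 "6" = manh == 1, "18" = manh <= 2, "26" = manh <= 3,
                 stop("connectivity must be 6, 18 or 26"))
  as.matrix(offs[keep, ])
}

#' Label connected components of a voxel set
#'
#' Partitions the `TRUE` voxels of a 3D logical array into connected
#' clusters under 6-, 18- or 26-neighbour connectivity, via the components
#' of the voxel adjacency graph.
#'
#' @param mask 3D logical array.
#' @param connectivity 6 (faces), 18 (faces+edges, default) or 26.
#' @return 3D integer array of cluster labels (0 = background), labelled
#'   in decreasing cluster size.
#' @export
label_components <- function(mask, connectivity = 18) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  d <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, d)
  if (length(idx) == 0L) return(lab)
  pos_of <- array(0L, d)          # rank of each supra voxel
  pos_of[idx] <- seq_along(idx)
  co <- arrayInd(idx, d)
  offs <- neighbour_offsets(connectivity)
  # undirected graph: only offsets lexicographically positive
  half <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
               (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0), ,
               drop = FALSE]
  edges <- list()
  for (r in seq_len(nrow(half))) {
    nx <- co[, 1] + half[r, 1]; ny <- co[, 2] + half[r, 2]
    nz <- co[, 3] + half[r, 3]
    ok <- nx >= 1 & nx <= d[1] & ny >= 1 & ny <= d[2] & nz >= 1 & nz <= d[3]
    if (!any(ok)) next
    nidx <- (nz[ok] - 1L) * d[1] * d[2] + (ny[ok] - 1L) * d[1] + nx[ok]
    tgt <- pos_of[nidx]
    hit <- tgt > 0L
    if (any(hit))
      edges[[length(edges) + 1L]] <-
        cbind(which(ok)[hit], tgt[hit])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges) > 0L)
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  comp <- igraph::components(g)
  # relabel in decreasing size, ties by first-voxel order
  sizes <- comp$csize
  ord <- order(-sizes, seq_along(sizes))
  newlab <- integer(length(sizes)); newlab[ord] <- seq_along(sizes)
  lab[idx] <- newlab[comp$membership]
  lab
}

#' Cluster-extent threshold a t contrast map
#'
#' Thresholds the uncorrected p map at `p_threshold` (strict `<`), labels
#' the connected components of the suprathreshold set, and discards
#' clusters smaller than `k_min` voxels. The surviving clusters and their
#' k-extents form the basis of the disease-progression mask.
#'
#' @param tmap a [paired_t_map()] result.
#' @param p_threshold voxel-level p threshold in (0,1), default 0.001.
#' @param k_min minimum cluster extent in voxels (clusters of exactly
#'   `k_min` survive), default 50.
#' @param connectivity neighbourhood definition, see [label_components()].
#' @return Object of class `cluster_result`: `mask` (logical array, union
#'   of surviving clusters), `labels` (integer array over surviving
#'   clusters), `clusters` (data.frame `cluster_id`, `k_extent`, `peak_t`,
#'   `peak_x/y/z`), `total_k_extent`, plus the thresholds used.
#' @export
cluster_threshold <- function(tmap, p_threshold = 0.001, k_min = 50,
                              connectivity = 18) {
  stopifnot(inherits(tmap, "t_contrast_map"))
  if (p_threshold <= 0 || p_threshold >= 1)
    stop("p_threshold must lie in (0, 1)")
  if (k_min < 1) stop("k_min must be at least 1")
  supra <- tmap$p$data < p_threshold
  lab <- label_components(supra, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= k_min)
  out_lab <- array(0L, dim(lab))
  rows <- list()
  new_id <- 0L
  for (k in keep) {
    new_id <- new_id + 1L
    vox <- lab == k
    out_lab[vox] <- new_id
    tv <- tmap$t$data[vox]
    peak_lin <- which(vox)[which.min(tv)]   # decline: most negative t
    pk <- arrayInd(peak_lin, dim(lab))
    rows[[new_id]] <- data.frame(cluster_id = new_id,
                                 k_extent = sizes[k],
                                 peak_t = min(tv),
                                 peak_x = pk[1], peak_y = pk[2],
                                 peak_z = pk[3])
  }
  clusters <- if (length(rows)) do.call(rbind, rows)
              else data.frame(cluster_id = integer(), k_extent = integer(),
                              peak_t = numeric(), peak_x = integer(),
                              peak_y = integer(), peak_z = integer())
  structure(list(mask = out_lab > 0L, labels = out_lab,
                 clusters = clusters,
                 total_k_extent = sum(clusters$k_extent),
                 p_threshold = p_threshold, k_min = k_min,
                 connectivity = connectivity),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result: %d clusters, total k-extent %d (p<%g, k>=%d, conn %d)>\n",
              nrow(x$clusters), x$total_k_extent, x$p_threshold, x$k_min,
              x$connectivity))
  invisible(x)
}

subject_scan <- function(record, visit) record$visits[[visit]]$scan

#' Build the disease-progression mask (MaskAD) from the placebo arm
#'
#' The voxel-wise paired t contrast of metabolic decline from the first to
#' the last visit in the placebo arm, thresholded at `p_threshold`
#' uncorrected with cluster extent `k_min`, identifies the brain regions
#' involved in the natural progression of the disease. The union of
#' surviving clusters is the mask; an empty mask is returned with a
#' warning when no cluster survives (downstream extraction refuses empty
#' masks).
#'
#' @param placebo_scans_t0,placebo_scans_t1 preprocessed placebo scans,
#'   paired by subject, at the two visits (>= 3 completers).
#' @param p_threshold,k_min,connectivity as in [cluster_threshold()].
#' @param from_visit,to_visit provenance labels.
#' @param analysis_mask forwarded to [paired_t_map()].
#' @return Object of class `mask_ad`: `mask` (logical array),
#'   `cluster_result`, `provenance`.
#' @export
build_mask_ad <- function(placebo_scans_t0, placebo_scans_t1,
                          p_threshold = 0.001, k_min = 50,
                          connectivity = 18,
                          from_visit = "M0", to_visit = "M14",
                          analysis_mask = NULL) {
  tmap <- paired_t_map(placebo_scans_t0, placebo_scans_t1,
                       direction = "decline",
                       from_visit = from_visit, to_visit = to_visit,
                       analysis_mask = analysis_mask)
  cl <- cluster_threshold(tmap, p_threshold, k_min, connectivity)
  if (cl$total_k_extent == 0L)
    warning("no cluster survived thresholding; MaskAD is empty")
  structure(list(mask = cl$mask, cluster_result = cl,
                 provenance = list(arm = "placebo",
                                   contrast = c(from_visit, to_visit),
                                   p_threshold = p_threshold,
                                   k_min = k_min,
                                   connectivity = connectivity)),
            class = "mask_ad")
}

#' @export
print.mask_ad <- function(x, ...) {
  cat(sprintf("<mask_ad: %d voxels from %d clusters (%s %s->%s)>\n",
              sum(x$mask), nrow(x$cluster_result$clusters),
              x$provenance$arm, x$provenance$contrast[1],
              x$provenance$contrast[2]))
  invisible(x)
}

#' Percent metabolism change within the disease-progression mask
#'
#' Per subject, `100 * (mean in-mask uptake at the later visit - at the
#' earlier) / (at the earlier)`; the arm value is the mean over its
#' subjects. Negative values are metabolic loss. The denominator is each
#' subject's own baseline in-mask mean.
#'
#' @param scans_t0,scans_t1 preprocessed scans paired by subject.
#' @param mask a `mask_ad` or logical array; must be nonempty.
#' @return List: `per_subject` (numeric vector of percent changes),
#'   `mean_percent_change`.
#' @export
mask_ad_percent_loss <- function(scans_t0, scans_t1, mask) {
  m <- if (inherits(mask, "mask_ad")) mask$mask else mask
  stopifnot(is.logical(m))
  if (sum(m) == 0L)
    stop("MaskAD is empty (no surviving cluster); cannot extract uptake")
  if (length(scans_t0) != length(scans_t1))
    stop("unpaired inputs")
  per <- vapply(seq_along(scans_t0), function(i) {
    a <- mean(scans_t0[[i]]$data[m])
    b <- mean(scans_t1[[i]]$data[m])
    100 * (b - a) / a
  }, numeric(1))
  list(per_subject = per, mean_percent_change = mean(per))
}
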