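# Shared fixtures: small phantoms and cohorts built in code at test time.

tiny_phantom_spec <- function(seed = 7, n_regions = 12L, noise_sd = 5,
                              grid = c(20L, 24L, 20L)) {
  phantom_spec(grid_shape = grid, voxel_mm = 4, n_regions = n_regions,
               cerebellum_region_ids = 1:2,
               ad_region_ids = seq(n_regions - 2L, n_regions),
               baseline_uptake = 100, noise_sd = noise_sd, seed = seed)
}

two_arm_cohort_spec <- function(seed = 1, n = 6L,
                                decline = c(0.06, 0.02),
                                atrophy_rate = 0.05) {
  cohort_spec(
    arms = data.frame(name = c("placebo", "high_albumin_ivig"),
                      decline = decline, n = c(n, n),
                      stringsAsFactors = FALSE),
    severity_strata = list(mild = list(multiplier = 1,
                                       baseline_offset = 0.1)),
    atrophy_rate = atrophy_rate, n_controls = 8L, seed = seed)
}

# independent brute-force flood fill (recursive frontier growth), used as
# the oracle for connected-component labelling
floodfill_labels <- function(mask, connectivity = 18) {
  d <- dim(mask)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  manh <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  offs <- as.matrix(offs[switch(as.character(connectivity),
                                "6" = manh == 1, "18" = manh <= 2,
                                "26" = manh <= 3), ])
  lab <- array(0L, d)
  nxt <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (lab[start] > 0L) next
    nxt <- nxt + 1L
    frontier <- start
    lab[start] <- nxt
    while (length(frontier) > 0L) {
      newf <- integer(0)
      for (v in frontier) {
        co <- arrayInd(v, d)
        for (r in seq_len(nrow(offs))) {
          x <- co[1] + offs[r, 1]; y <- co[2] + offs[r, 2]
          z <- co[3] + offs[r, 3]
          if (x < 1 || x > d[1] || y < 1 || y > d[2] || z < 1 || z > d[3])
            next
          if (mask[x, y, z] && lab[x, y, z] == 0L) {
            lab[x, y, z] <- nxt
            newf <- c(newf, (z - 1L) * d[1] * d[2] + (y - 1L) * d[1] + x)
          }
        }
      }
      frontier <- newf
    }
  }
  lab
}

# partition equality ignoring label numbering
same_partition <- function(a, b) {
  if (!identical(a > 0L, b > 0L)) return(FALSE)
  idx <- which(a > 0L)
  if (length(idx) == 0L) return(TRUE)
  key <- paste(a[idx], b[idx])
  length(unique(key)) == length(unique(a[idx])) &&
    length(unique(key)) == length(unique(b[idx]))
}

const_volume <- function(value, grid = c(8L, 8L, 8L), voxel = 4) {
  new_volume(array(value, grid), voxel)
}
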