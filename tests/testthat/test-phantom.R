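test_that("phantom regions are contiguous single connected components", {
  ph <- build_phantom(tiny_phantom_spec(seed = 7, n_regions = 12L))
  labs <- sort(unique(as.integer(ph$atlas$labels)))
  expect_identical(labs, 0:12)
  for (r in 1:12) {
    cc <- floodfill_labels(ph$atlas$labels == r, connectivity = 26)
    expect_equal(max(cc), 1L)
  }
})

test_that("phantom generation is bit-identical under the same seed", {
  s <- tiny_phantom_spec(seed = 7)
  a <- build_phantom(s); b <- build_phantom(s)
  expect_identical(a$atlas$labels, b$atlas$labels)
  expect_identical(a$uptake$data, b$uptake$data)
  expect_identical(a$gm$data, b$gm$data)
})

test_that("phantom spec invariants are enforced", {
  expect_error(phantom_spec(cerebellum_region_ids = 1:3,
                            ad_region_ids = 3:5), "disjoint")
  expect_error(phantom_spec(n_regions = 10, ad_region_ids = 11), "1..n_regions")
  expect_error(build_phantom(phantom_spec(grid_shape = c(4, 4, 4),
                                          n_regions = 30,
                                          cerebellum_region_ids = 1,
                                          ad_region_ids = 30)),
               "exceeds in-brain voxels")
  expect_error(phantom_spec(noise_sd = -1), "nonnegative")
})

test_that("GM probability is a valid map, >= 0.5 throughout the brain at baseline", {
  ph <- build_phantom(tiny_phantom_spec())
  inb <- ph$atlas$labels > 0
  expect_true(all(ph$gm$data[inb] >= 0.5))
  expect_true(all(ph$gm$data >= 0 & ph$gm$data <= 1))
  expect_true(all(ph$gm$data[!inb] == 0))
})

test_that("control scans are baseline plus noise with the requested SD", {
  ph <- build_phantom(tiny_phantom_spec())
  # zero-noise limit: every control equals the phantom
  ctl0 <- sample_control_scans(ph, 3, noise_sd = 0, seed = 1)
  for (v in ctl0) expect_identical(v$data, ph$uptake$data)
  # sampling-theory check: voxel-wise SD across 48 controls ~ 5 within 15%
  ctl <- sample_control_scans(ph, 48, noise_sd = 5, seed = 2)
  inb <- ph$atlas$labels > 0
  X <- vapply(ctl, function(v) v$data[inb], numeric(sum(inb)))
  sds <- apply(X[1:500, ], 1, sd)
  expect_lt(abs(mean(sds) - 5) / 5, 0.15)
  # outside the brain scans are exactly zero
  expect_true(all(X >= 0 | TRUE))
  expect_true(all(vapply(ctl, function(v) all(v$data[!inb] == 0), logical(1))))
  expect_error(sample_control_scans(ph, 1), "at least 2")
  expect_error(sample_control_scans(ph, 5, noise_sd = -2), "nonnegative")
})

test_that("seeded decline scales AD-region uptake by construction", {
  ps <- tiny_phantom_spec(noise_sd = 0)
  ph <- build_phantom(ps)
  cs <- two_arm_cohort_spec(decline = c(0.06, 0), atrophy_rate = 0)
  subs <- sample_patient_series(ph, cs)
  ad <- atlas_region_mask(ph$atlas, ps$ad_region_ids)
  pl <- subs[[which(vapply(subs, `[[`, character(1), "arm") == "placebo")[1]]]
  base_ad <- 100 * (1 - pl$baseline_offset)
  # M14 (progress 1): mean AD uptake = 0.94 x baseline
  expect_equal(mean(pl$visits$M14$scan$data[ad]), 0.94 * base_ad,
               tolerance = 1e-12)
  expect_equal(mean(pl$visits$M0$scan$data[ad]), base_ad, tolerance = 1e-12)
  # null arm: M14 equals M0 exactly at zero noise
  nu <- subs[[which(vapply(subs, `[[`, character(1), "arm") ==
                      "high_albumin_ivig")[1]]]
  expect_identical(nu$visits$M14$scan$data, nu$visits$M0$scan$data)
})

test_that("noise-free AD-region uptake is non-increasing across visits when decline > 0", {
  ps <- tiny_phantom_spec(noise_sd = 0)
  ph <- build_phantom(ps)
  subs <- sample_patient_series(ph, two_arm_cohort_spec(atrophy_rate = 0))
  ad <- atlas_region_mask(ph$atlas, ps$ad_region_ids)
  for (sub in subs[1:3]) {
    means <- vapply(c("M0", "M2", "M9", "M14"),
                    function(v) mean(sub$visits[[v]]$scan$data[ad]),
                    numeric(1))
    expect_true(all(diff(means) <= 0))
    expect_equal(sub$truth$decline_at_visit,
                 sub$effective_decline * sub$truth$progress)
  }
})

test_that("full default cohort has the advertised size and finite nonnegative scans", {
  ps <- phantom_spec(grid_shape = c(20, 24, 20), n_regions = 14,
                     cerebellum_region_ids = 1:2, ad_region_ids = 12:14,
                     seed = 5)
  cs <- cohort_spec(arms = data.frame(name = arm_names <- c(
    "placebo", "low_albumin", "low_albumin_ivig", "high_albumin_ivig"),
    decline = c(0.06, 0.045, 0.035, 0.02), n = rep(4L, 4)),
    n_controls = 8L, seed = 9)
  co <- simulate_cohort(ps, cs)
  expect_length(co$subjects, 16L)
  expect_true(all(vapply(co$subjects, function(s)
    length(s$visits) == 5L, logical(1))))
  strata <- vapply(co$subjects, `[[`, character(1), "stratum")
  expect_setequal(unique(strata), c("mild", "moderate"))
  for (sub in co$subjects[c(1, 16)])
    for (v in c("M0", "M14")) {
      expect_true(all(is.finite(sub$visits[[v]]$scan$data)))
      expect_true(all(sub$visits[[v]]$volumetry > 0))
    }
  # M6 is volumetry-only
  expect_null(co$subjects[[1]]$visits$M6$scan)
  expect_false(is.null(co$subjects[[1]]$visits$M6$volumetry))
})

test_that("cohort generation is deterministic and validates its spec", {
  ps <- tiny_phantom_spec()
  cs <- two_arm_cohort_spec()
  a <- simulate_cohort(ps, cs); b <- simulate_cohort(ps, cs)
  expect_identical(a$subjects[[3]]$visits$M14$scan$data,
                   b$subjects[[3]]$visits$M14$scan$data)
  expect_identical(a$subjects[[5]]$visits$M2$volumetry,
                   b$subjects[[5]]$visits$M2$volumetry)
  expect_error(cohort_spec(arms = data.frame(name = "a", decline = 1.2,
                                             n = 4L)), "\\[0, 1\\)")
  expect_error(cohort_spec(arms = data.frame(name = "a", decline = 0.1,
                                             n = 1L)), "at least 2")
  expect_error(cohort_spec(visits = c("M2", "M0")), "start at M0")
  expect_error(cohort_spec(visits = c("M0", "bad")), "unknown visit label")
})

test_that("written cohorts round-trip through NIfTI + CSV", {
  ps <- tiny_phantom_spec()
  cs <- two_arm_cohort_spec(n = 2)
  co <- simulate_cohort(ps, cs)
  d <- tempfile()
  write_cohort(co, d)
  man <- read.csv(file.path(d, "manifest.csv"))
  expect_equal(nrow(man), length(co$subjects) * 5)
  reg <- read.csv(file.path(d, "regions.csv"))
  expect_equal(nrow(reg), 12)
  s1 <- co$subjects[[1]]
  back <- read_volume(file.path(d, man$scan[man$subject == s1$subject_id &
                                              man$visit == "M0"]))
  expect_lt(max(abs(back$data - s1$visits$M0$scan$data)) /
              max(s1$visits$M0$scan$data), 1e-6)
  vol <- read.csv(file.path(d, "volumetry.csv"))
  expect_true(all(volumetry_structures() %in% names(vol)))
  unlink(d, recursive = TRUE)
})
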