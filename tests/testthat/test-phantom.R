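test_that("phantom generation is deterministic under seed and well-formed", {
  sp <- phantom_spec(grid_shape = c(28, 28, 28), tumor_radius_mm = 8,
                     seed = 11)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$volume$values, b$volume$values)
  expect_identical(a$mask$values, b$mask$values)
  expect_false(anyNA(a$volume$values))
  expect_true(any(a$mask$values))
  c <- generate_phantom(phantom_spec(grid_shape = c(28, 28, 28),
                                     tumor_radius_mm = 8, seed = 12))
  expect_false(identical(a$volume$values, c$volume$values))
})

test_that("an oversized tumor is rejected with a sizing error", {
  expect_error(phantom_spec(grid_shape = c(32, 32, 32),
                            tumor_radius_mm = 20),
               "does not fit")
})

test_that("noise-free, texture-free phantom is an exact plateau inside", {
  sp <- phantom_spec(grid_shape = c(36, 36, 36), tumor_radius_mm = 12,
                     margin_width_mm = 1, texture_sd = 0, noise_sd = 0,
                     tumor_level = 40, background_level = -800, seed = 2)
  ph <- generate_phantom(sp)
  # interior = voxels farther than the truncated kernel's box diagonal
  # (radius 4 voxels per axis) from the mask boundary
  dims <- dim(ph$mask$values)
  ctr <- ceiling(dims / 2)
  idx <- which(ph$mask$values, arr.ind = TRUE)
  d <- sqrt(rowSums(sweep(idx, 2, ctr)^2))
  interior <- idx[d <= 12 - 4 * sqrt(3) - 1e-9, , drop = FALSE]
  expect_gt(nrow(interior), 0)
  expect_equal(ph$volume$values[interior], rep(40, nrow(interior)),
               tolerance = 1e-12)
  # outside far from the tumor it is exactly background
  far <- ph$volume$values[1, 1, 1]
  expect_equal(far, -800, tolerance = 1e-12)
})

test_that("longer texture correlation raises GLCM inverse difference", {
  id_at <- function(corr_len, seed) {
    ph <- generate_phantom(phantom_spec(
      grid_shape = c(28, 28, 28), tumor_radius_mm = 9,
      texture_correlation_length_mm = corr_len, texture_sd = 60,
      noise_sd = 0, seed = seed))
    binned <- discretize_roi(ph$volume, ph$mask, 16)
    radguide:::glcm_features_avg(binned, 1, 16)[["InverseDifference"]]
  }
  short <- vapply(1:20, function(s) id_at(1, s), 1)
  long <- vapply(1:20, function(s) id_at(2.5, s), 1)
  expect_gt(mean(long), mean(short))
})

test_that("null cohort ground truth is uninformative and censoring rules hold", {
  co <- generate_cohort(survival_spec(500, betas = c(texture_sd = 0),
                                      seed = 5),
                        keep_images = FALSE)
  expect_equal(nrow(co$cohort), 500)
  expect_true(all(co$truth$lp == 0))
  expect_equal(concordance_index(co$truth$lp, co$cohort$time_months,
                                 co$cohort$event), 0.5, tolerance = 0.05)

  # no dropout, no administrative horizon: every follow-up ends in death
  all_ev <- generate_cohort(survival_spec(80, betas = c(texture_sd = 0),
                                          admin_time_months = Inf,
                                          dropout_rate = 0, seed = 3),
                            keep_images = FALSE)
  expect_true(all(all_ev$cohort$event == 1))
})

test_that("a planted unit effect is recoverable from the true predictor", {
  hits <- vapply(1:20, function(s) {
    co <- generate_cohort(survival_spec(300, betas = c(tumor_radius_mm = 1),
                                        seed = s),
                          keep_images = FALSE)
    concordance_index(co$truth$lp, co$cohort$time_months,
                      co$cohort$event) > 0.65
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("event rate is monotone in the baseline hazard", {
  rate_at <- function(h0) {
    co <- generate_cohort(survival_spec(400, betas = c(texture_sd = 0),
                                        baseline_hazard = h0, seed = 9),
                          keep_images = FALSE)
    mean(co$cohort$event)
  }
  r <- vapply(c(1e-4, 1e-3, 1e-2), rate_at, 1)
  expect_true(all(diff(r) > 0))
})

test_that("cohort images reflect the drawn per-patient parameters", {
  co <- suppressWarnings(
    generate_cohort(survival_spec(4, betas = c(texture_sd = 2),
                                  seed = 21)))
  expect_length(co$volumes, 4)
  vols <- vapply(co$masks, function(m) sum(m$values), 1)
  expect_equal(order(co$truth$tumor_radius_mm), order(vols))
  # round trip through NIfTI
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  v <- read_volume(file.path(dir, "P0001_vol.nii.gz"))
  expect_equal(v$values, co$volumes[[1]]$values, tolerance = 1e-6)
  m <- read_mask(file.path(dir, "P0001_mask.nii.gz"))
  expect_identical(m$values, co$masks[[1]]$values)
  expect_true(file.exists(file.path(dir, "cohort.csv")))
})
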