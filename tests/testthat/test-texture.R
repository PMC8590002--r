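make_vol <- function(a) voxel_volume(array(a, dim = dim(a)))
full_mask <- function(dims) roi_mask(array(TRUE, dims))

test_that("discretization uses equal-width range-relative bins", {
  v <- make_vol(array(0:31, c(32, 1, 1)))
  b <- discretize_roi(v, full_mask(c(32, 1, 1)), 32)
  expect_identical(as.integer(b), 1:32)

  v2 <- make_vol(array(c(0, 10, 20, 30), c(4, 1, 1)))
  b2 <- discretize_roi(v2, full_mask(c(4, 1, 1)), 2)
  expect_identical(as.integer(b2), c(1L, 1L, 2L, 2L))

  const <- make_vol(array(7, c(3, 3, 1)))
  expect_true(all(discretize_roi(const, full_mask(c(3, 3, 1)), 32) == 1L))
})

test_that("GLCM matrices are symmetric, normalized and match pair counting", {
  # constant 2x2x1 ROI: only P(1,1) mass
  const <- discretize_roi(make_vol(array(5, c(2, 2, 1))),
                          full_mask(c(2, 2, 1)), 8)
  m <- glcm_matrix(const, c(1, 0, 0), 8)
  expect_equal(m[1, 1], 1)
  expect_equal(sum(m), 1)

  # 3x3 checkerboard, in-plane offsets, against the brute-force oracle
  cb <- array(NA_integer_, c(3, 3, 1))
  cb[, , 1] <- (outer(1:3, 1:3, `+`) %% 2) + 1L
  for (off in list(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(-1, 1, 0))) {
    expect_equal(glcm_matrix(cb, off, 2), oracle_glcm_matrix(cb, off, 2))
  }

  # random ROIs: symmetry + unit mass + oracle equality for all directions
  for (seed in 1:5) {
    roi <- random_roi(c(5, 4, 3), 6, seed)
    dirs <- glcm_directions()
    for (k in seq_len(nrow(dirs))) {
      m <- glcm_matrix(roi$binned, dirs[k, ], 6)
      expect_equal(m, t(m))
      expect_equal(sum(m), 1)
      expect_equal(m, oracle_glcm_matrix(roi$binned, dirs[k, ], 6))
    }
  }

  single <- discretize_roi(make_vol(array(1, c(1, 1, 1))),
                           full_mask(c(1, 1, 1)), 4)
  expect_error(glcm_matrices(single), "degenerate ROI")
})

test_that("GLCM features match hand values and the formula oracle", {
  # single-entry GLCM
  p1 <- matrix(0, 4, 4); p1[1, 1] <- 1
  f1 <- glcm_features(p1)
  expect_equal(f1[["Contrast"]], 0)
  expect_equal(f1[["InverseDifference"]], 1)
  expect_equal(f1[["DifferenceEntropy"]], 0)

  # uniform 2x2 GLCM: p_{x+y} = {.25, .5, .25} so sum entropy = 1.5 bits
  f2 <- glcm_features(matrix(0.25, 2, 2))
  expect_equal(f2[["SumEntropy"]], 1.5)

  # random matrices against the independently coded formulas
  for (seed in 1:8) {
    set.seed(seed)
    raw <- matrix(runif(16), 4, 4)
    P <- (raw + t(raw)) / (2 * sum(raw))
    expect_equal(glcm_features(P), oracle_glcm_features(P),
                 tolerance = 1e-12)
  }
})

test_that("GLSZM obeys mass conservation and matches the flood-fill oracle", {
  # single zone of size N: ZP = 1/N, LAE = N^2
  b <- array(NA_integer_, c(2, 3, 1)); b[1:2, 1:2, 1] <- 3L
  m <- glszm(b, 4)
  f <- glszm_features(m, 4)
  expect_equal(f[["ZonePercentage"]], 1 / 4)
  expect_equal(f[["LargeAreaEmphasis"]], 16)

  # two zones sizes {2, 3}: LAE = (4 + 9) / 2
  b2 <- array(NA_integer_, c(7, 1, 1))
  b2[1:2] <- 1L; b2[4:6] <- 2L
  f2 <- glszm_features(glszm(b2, 2), 5)
  expect_equal(f2[["LargeAreaEmphasis"]], 6.5)
  expect_equal(f2[["ZonePercentage"]], 2 / 5)

  # all-distinct gray levels: every voxel is its own zone
  iso <- array(1:16, c(4, 4, 1))
  expect_equal(glszm_features(glszm(iso, 16), 16)[["ZonePercentage"]], 1)

  for (seed in 1:5) {
    roi <- random_roi(c(5, 5, 4), 4, seed, p_mask = 0.7)
    m <- glszm(roi$binned, 4)
    sizes <- matrix(seq_len(ncol(m)), nrow(m), ncol(m), byrow = TRUE)
    expect_equal(sum(m * sizes), sum(!is.na(roi$binned)))
    zo <- oracle_glszm_zones(roi$binned)
    expect_equal(unname(glszm_features(m, sum(!is.na(roi$binned)))),
                 unname(oracle_glszm_features(zo, sum(!is.na(roi$binned)))),
                 tolerance = 1e-12)
  }
})

test_that("first-order features match forced values and the oracle", {
  const <- make_vol(array(3, c(2, 5, 1)))
  f <- first_order_features(const, full_mask(c(2, 5, 1)))
  expect_equal(f[["Entropy"]], 0)
  expect_equal(f[["Uniformity"]], 1)
  expect_equal(f[["Variance"]], 0)
  expect_equal(f[["Skewness"]], 0)

  two <- make_vol(array(rep(c(0, 10), 8), c(4, 4, 1)))
  f2 <- first_order_features(two, full_mask(c(4, 4, 1)))
  expect_equal(f2[["Entropy"]], 1)
  expect_equal(f2[["Uniformity"]], 0.5)

  # a listed 10-voxel ROI against the direct formula oracle
  vals <- c(-12, 4, 4, 7, 19, 19, 19, 30, 42, 55)
  v <- make_vol(array(vals, c(10, 1, 1)))
  msk <- full_mask(c(10, 1, 1))
  got <- first_order_features(v, msk, n_bins = 8)
  want <- oracle_firstorder(vals,
                            as.integer(discretize_roi(v, msk, 8)),
                            voxel_volume_mm3 = 1)
  expect_equal(got, want[names(got)], tolerance = 1e-12)
})

test_that("texture features are invariant to an intensity shift", {
  roi <- random_roi(c(6, 6, 5), 8, 42)
  shifted <- voxel_volume(roi$volume$values + 123.4)
  b1 <- discretize_roi(roi$volume, roi$mask, 8)
  b2 <- discretize_roi(shifted, roi$mask, 8)
  expect_identical(b1, b2)
  f1 <- radguide:::glcm_features_avg(b1, 1, 8)
  f2 <- radguide:::glcm_features_avg(b2, 1, 8)
  expect_equal(f1, f2)
})
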