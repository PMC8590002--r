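ztab <- function(m, ids = sprintf("P%03d", seq_len(nrow(m)))) {
  out <- tibble::as_tibble(as.data.frame(m))
  tibble::add_column(out, patient_id = ids, .before = 1)
}

test_that("pearson_with_p matches direct arithmetic and cor.test", {
  x <- c(1, 2, 3, 4)
  expect_equal(unname(pearson_with_p(x, x)["r"]), 1)
  expect_equal(unname(pearson_with_p(x, -x)["r"]), -1)

  y <- c(1, 2, 4, 3)
  got <- pearson_with_p(x, y)
  expect_equal(unname(got["r"]), 0.8) # direct covariance arithmetic
  ct <- cor.test(x, y)
  expect_equal(unname(got["p"]), ct$p.value)

  expect_true(all(is.na(pearson_with_p(c(1, 1, 1, 1), y))))
  expect_error(pearson_with_p(1:2, 1:2), "n >= 3")
})

test_that("a copied column is retained with r = 1 and tiny corrected p", {
  set.seed(10)
  rad <- ztab(matrix(rnorm(30 * 4), 30,
                     dimnames = list(NULL, paste0("R", 1:4))))
  dl <- ztab(matrix(rnorm(30 * 3), 30,
                    dimnames = list(NULL, paste0("D", 1:3))))
  dl$D2 <- rad$R3
  sc <- correlation_screen(dl, rad)
  row <- sc$per_dl[sc$per_dl$dl_feature == "D2", ]
  expect_true(row$retained)
  expect_equal(row$r, 1)
  expect_equal(row$best_radiomics, "R3")
  expect_lt(row$p_bonf, 1e-20)
})

test_that("screen equals the exhaustive double-loop oracle on toy tables", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- 40
    rad <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("R", 1:4)))
    dl <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("D", 1:5)))
    # plant a few moderate associations
    dl[, 1] <- 0.6 * rad[, 2] + 0.8 * rnorm(n)
    dl[, 4] <- 0.9 * rad[, 1] + 0.45 * rnorm(n)
    got <- retained_features(correlation_screen(ztab(dl), ztab(rad),
                                                r_threshold = 0.4,
                                                alpha = 0.05))
    want <- oracle_screen(as.data.frame(dl), as.data.frame(rad), 0.4, 0.05)
    expect_identical(got, want)
  }
})

test_that("pure-noise tables keep nothing under Bonferroni control", {
  survived <- vapply(1:20, function(seed) {
    set.seed(seed + 1000)
    dl <- matrix(rnorm(50 * 100), 50,
                 dimnames = list(NULL, paste0("D", 1:100)))
    rad <- matrix(rnorm(50 * 20), 50,
                  dimnames = list(NULL, paste0("R", 1:20)))
    length(retained_features(correlation_screen(ztab(dl), ztab(rad)))) == 0
  }, logical(1))
  expect_gte(sum(survived), 19)
})

test_that("screen is invariant to column order and monotone in threshold", {
  set.seed(77)
  n <- 35
  rad <- matrix(rnorm(n * 6), n, dimnames = list(NULL, paste0("R", 1:6)))
  dl <- matrix(rnorm(n * 8), n, dimnames = list(NULL, paste0("D", 1:8)))
  dl[, 3] <- rad[, 5] + 0.3 * rnorm(n)
  a <- correlation_screen(ztab(dl), ztab(rad))
  b <- correlation_screen(ztab(dl[, sample(8)]), ztab(rad[, sample(6)]))
  expect_setequal(retained_features(a), retained_features(b))

  sweep_res <- threshold_sweep(ztab(dl), ztab(rad),
                               thresholds = c(0.3, 0.4, 0.5, 1))
  expect_true(all(diff(sweep_res$n_retained) <= 0))
  expect_equal(sweep_res$n_retained[4], 0L) # no exact duplicates

  # tighter alpha can only shrink the retained set
  strict <- correlation_screen(ztab(dl), ztab(rad), alpha = 1e-6)
  expect_true(all(retained_features(strict) %in% retained_features(a)))
})

test_that("planted borderline correlations respect the strict 0.4 cut", {
  # construct columns with sample correlation exactly 0.45 to a target
  set.seed(5)
  n <- 200
  base <- scale(rnorm(n))[, 1]
  make_at <- function(r) {
    e <- scale(stats::resid(stats::lm(rnorm(n) ~ base)))[, 1]
    r * base + sqrt(1 - r^2) * e
  }
  rad <- ztab(matrix(base, ncol = 1, dimnames = list(NULL, "R1")))
  dl <- ztab(matrix(c(make_at(0.45), make_at(0.45), make_at(0.45)),
                    ncol = 3, dimnames = list(NULL, paste0("D", 1:3))))
  expect_length(retained_features(
    correlation_screen(dl, rad, r_threshold = 0.4)), 3)
  expect_length(retained_features(
    correlation_screen(dl, rad, r_threshold = 0.5)), 0)
})

test_that("zero-variance deep features are excluded, mismatches rejected", {
  set.seed(2)
  rad <- ztab(matrix(rnorm(20 * 2), 20, dimnames = list(NULL, c("R1", "R2"))))
  dl <- ztab(cbind(D1 = rnorm(20), D2 = rep(1, 20)))
  expect_message(sc <- correlation_screen(dl, rad), "zero-variance")
  expect_identical(sc$excluded, "D2")
  expect_false("D2" %in% sc$per_dl$dl_feature)

  rad_wrong <- rad
  rad_wrong$patient_id <- rev(rad_wrong$patient_id)
  expect_error(correlation_screen(dl, rad_wrong), "different patients")
})
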