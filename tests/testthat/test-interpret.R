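# build a screen with controlled correlations between 3 deep features and
# 5 radiomics features drawn from the real roster names
make_fixture_screen <- function() {
  set.seed(42)
  n <- 60
  roster <- radiomics_feature_info()
  rad_names <- c("Histogram_Entropy", "GLCM_InverseDifference",
                 "GLCM_Contrast", "GLSZM_ZonePercentage",
                 "Margin_CDF_slope_skewness")
  stopifnot(all(rad_names %in% roster$name))
  base <- matrix(rnorm(n * 5), n, dimnames = list(NULL, rad_names))
  dl <- cbind(
    DL_a = base[, "GLCM_InverseDifference"],            # exact copy, r = 1
    DL_b = 0.8 * base[, "Histogram_Entropy"] + 0.4 * rnorm(n),
    DL_c = rnorm(n))
  ids <- sprintf("P%03d", 1:n)
  dl_tab <- tibble::add_column(tibble::as_tibble(as.data.frame(dl)),
                               patient_id = ids, .before = 1)
  rad_tab <- tibble::add_column(tibble::as_tibble(as.data.frame(base)),
                                patient_id = ids, .before = 1)
  correlation_screen(dl_tab, rad_tab,
                     keep_all_pairs_for = c("DL_a", "DL_b", "DL_c"))
}

test_that("associations are read from the stored screen, sorted by |r|", {
  sc <- make_fixture_screen()
  rep_ <- associate(c("DL_a", "DL_b"), sc, threshold = 0.4)
  a <- rep_$associations[rep_$associations$dl_feature == "DL_a", ]
  expect_equal(a$radiomics_feature[1], "GLCM_InverseDifference")
  expect_equal(a$r[1], 1)
  expect_true(all(abs(a$r) > 0.4))
  expect_true(all(diff(abs(a$r)) <= 1e-12)) # descending
  expect_equal(a$category[1], "GLCM")

  # summary counts significance at uncorrected p < 0.05
  s <- rep_$summary[rep_$summary$dl_feature == "DL_a", ]
  expect_gte(s$n_significant, 1)
  expect_equal(s$top_radiomics, "GLCM_InverseDifference")

  # an impossible threshold empties the list
  empty <- associate("DL_a", sc, threshold = 1.01)
  expect_equal(nrow(empty$associations), 0)

  expect_error(associate("DL_nope", sc), "no stored screen profile")

  # pure function of the stored screen
  expect_identical(associate(c("DL_a", "DL_b"), sc),
                   associate(c("DL_a", "DL_b"), sc))
})

test_that("category proportions are normalized counts over the roster", {
  sc <- make_fixture_screen()
  rep_ <- associate(c("DL_a", "DL_b", "DL_c"), sc, threshold = 0.4)
  props <- category_proportions(rep_)
  cats <- c("shape", "first-order", "GLCM", "GLSZM", "margin")
  for (i in seq_len(nrow(props))) {
    total <- sum(props[i, cats])
    if (props$n_associations[i] > 0) {
      expect_equal(total, 1)
    } else {
      expect_equal(total, 0) # no-association flag row
    }
  }
  # the exact-copy deep feature is purely GLCM-associated
  row_a <- props[props$dl_feature == "DL_a", ]
  expect_equal(row_a$GLCM, 1)

  # a 14-association composition: 2 first-order, 10 GLCM, 2 margin
  fake <- structure(list(
    associations = tibble::tibble(
      dl_feature = "D",
      radiomics_feature = c("Histogram_Entropy", "Histogram_Uniformity",
                            paste0("GLCM_", radguide:::glcm_feature_names[1:10]),
                            "Margin_CDF_slope_skewness",
                            "Margin_CDF_slope_kurtosis"),
      category = c(rep("first-order", 2), rep("GLCM", 10),
                   rep("margin", 2)),
      r = seq(0.45, 0.58, length.out = 14)),
    summary = tibble::tibble(dl_feature = "D", n_significant = 14,
                             top_radiomics = "GLCM_IDN", top_r = -0.5),
    threshold = 0.4), class = "association_report")
  p <- category_proportions(fake)
  expect_equal(unname(unlist(p[1, cats])),
               c(0, 2 / 14, 10 / 14, 0, 2 / 14))

  bad <- fake
  bad$associations$radiomics_feature[1] <- "NotAFeature"
  expect_error(category_proportions(bad), "missing from the roster")
})
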