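#' Radiomics configuration
#'
#' Tunable parameters of the 78-feature extraction: the number of gray
#' levels for texture discretization, the GLCM voxel distance, and the
#' margin-profile geometry.
#'
#' @param n_bins Gray levels for GLCM/GLSZM/histogram discretization.
#' @param glcm_distance GLCM offset distance in voxels.
#' @param margin_profile_length_mm,margin_n_profiles,margin_step_mm See
#'   [margin_cdf_features()].
#' @return A named list.
#' @export
radiomics_config <- function(n_bins = 32, glcm_distance = 1,
                             margin_profile_length_mm = 5,
                             margin_n_profiles = 64,
                             margin_step_mm = NULL) {
  list(n_bins = n_bins, glcm_distance = glcm_distance,
       margin_profile_length_mm = margin_profile_length_mm,
       margin_n_profiles = margin_n_profiles,
       margin_step_mm = margin_step_mm)
}

#' The 78-feature radiomics roster
#'
#' Fixed, documented feature order: 14 shape, 18 first-order, 24 GLCM,
#' 16 GLSZM and 6 margin CDF-slope features. Feature names are prefixed
#' with their category.
#'
#' @return A tibble with columns `name` and `category` (one of `shape`,
#'   `first-order`, `GLCM`, `GLSZM`, `margin`), 78 rows.
#' @export
radiomics_feature_info <- function() {
  tibble::tibble(
    name = c(paste0("Shape_", shape_feature_names),
             paste0("Histogram_", firstorder_feature_names),
             paste0("GLCM_", glcm_feature_names),
             paste0("GLSZM_", glszm_feature_names),
             paste0("Margin_", margin_feature_names)),
    category = rep(c("shape", "first-order", "GLCM", "GLSZM", "margin"),
                   times = c(14, 18, 24, 16, 6)))
}

#' Extract the full 78-feature radiomics vector
#'
#' Concatenates, in the fixed order of [radiomics_feature_info()], the
#' shape, first-order, GLCM (feature values computed per direction and
#' averaged over the 13 directions), GLSZM (26-connectivity zones) and
#' margin CDF-slope features of one volume/mask pair.
#'
#' @param volume A [voxel_volume()].
#' @param mask A congruent [roi_mask()].
#' @param config A [radiomics_config()].
#' @return Named numeric vector of length 78, no `NA`s.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(grid_shape = c(24, 24, 24),
#'                                     tumor_radius_mm = 6, seed = 1))
#' f <- extract_all(ph$volume, ph$mask)
#' length(f)
extract_all <- function(volume, mask, config = radiomics_config()) {
  check_congruent(volume, mask)
  step <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      stop_radguide(label, " features failed: ", conditionMessage(e))
    })
  }
  binned <- discretize_roi(volume, mask, config$n_bins)
  f <- c(
    step("shape", setNames(shape_features(mask),
                           paste0("Shape_", shape_feature_names))),
    step("first-order",
         setNames(first_order_features(volume, mask, config$n_bins),
                  paste0("Histogram_", firstorder_feature_names))),
    step("GLCM", setNames(
      glcm_features_avg(binned, config$glcm_distance, config$n_bins),
      paste0("GLCM_", glcm_feature_names))),
    step("GLSZM", setNames(
      glszm_features(glszm(binned, config$n_bins), sum(mask$values)),
      paste0("GLSZM_", glszm_feature_names))),
    step("margin", setNames(
      margin_cdf_features(volume, mask, config$margin_profile_length_mm,
                          config$margin_n_profiles, config$margin_step_mm),
      paste0("Margin_", margin_feature_names))))
  stopifnot(length(f) == 78, !anyNA(f))
  f
}

#' Extract a radiomics feature table for a cohort
#'
#' @param volumes,masks Lists of congruent [voxel_volume()]/[roi_mask()]
#'   pairs.
#' @param patient_id Character vector of patient ids.
#' @param config A [radiomics_config()].
#' @return A tibble: `patient_id` plus 78 named feature columns.
#' @export
extract_features_table <- function(volumes, masks,
                                   patient_id = sprintf(
                                     "P%04d", seq_along(volumes)),
                                   config = radiomics_config()) {
  stopifnot(length(volumes) == length(masks),
            length(volumes) == length(patient_id))
  rows <- vapply(seq_along(volumes),
                 function(i) extract_all(volumes[[i]], masks[[i]], config),
                 numeric(78))
  out <- tibble::as_tibble(t(rows))
  tibble::add_column(out, patient_id = patient_id, .before = 1)
}

feature_matrix <- function(table) {
  cols <- setdiff(names(table), "patient_id")
  m <- as.matrix(table[cols])
  rownames(m) <- table$patient_id
  m
}

#' Training-cohort z-score normalization
#'
#' `fit_zscore()` estimates per-feature mean and SD (sample SD, `n - 1`) on
#' the training table; zero-variance features are recorded and dropped when
#' the params are applied. `apply_zscore()` transforms any table with
#' training-derived parameters only, so test and validation cohorts never
#' contribute to normalization.
#'
#' @param table Feature tibble with a `patient_id` column.
#' @param params Result of `fit_zscore()`.
#' @return `fit_zscore()`: list with `mean`, `sd`, `dropped`;
#'   `apply_zscore()`: transformed tibble without the dropped columns.
#' @export
fit_zscore <- function(table) {
  m <- feature_matrix(table)
  if (nrow(m) < 2) stop_radguide("need >= 2 training patients")
  mu <- colMeans(m)
  sdev <- apply(m, 2, sd)
  dropped <- names(sdev)[sdev == 0]
  if (length(dropped)) {
    message("dropping ", length(dropped), " zero-variance feature(s)")
  }
  list(mean = mu[sdev > 0], sd = sdev[sdev > 0], dropped = dropped)
}

#' @rdname fit_zscore
#' @export
apply_zscore <- function(table, params) {
  keep <- names(params$mean)
  missing <- setdiff(keep, names(table))
  if (length(missing)) {
    stop_radguide("table lacks normalized feature(s): ",
                  paste(head(missing, 3), collapse = ", "))
  }
  m <- as.matrix(table[keep])
  z <- sweep(sweep(m, 2, params$mean, `-`), 2, params$sd, `/`)
  out <- tibble::as_tibble(z)
  tibble::add_column(out, patient_id = table$patient_id, .before = 1)
}

#' Write a feature table / normalization params
#'
#' @param table Feature tibble.
#' @param params Result of [fit_zscore()].
#' @param path Output file path (CSV for tables, JSON for params).
#' @export
write_feature_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
write_zscore_params <- function(params, path) {
  jsonlite::write_json(params, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}
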