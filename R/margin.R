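margin_feature_names <- c(
  "CDF_slope_mean", "CDF_slope_SD", "CDF_slope_skewness",
  "CDF_slope_kurtosis", "CDF_slope_median", "CDF_slope_IQR")

# trilinear interpolation at mm positions; NA outside the grid
trilinear_interp <- function(values, spacing_mm, points_mm) {
  dm <- dim(values)
  gx <- points_mm[, 1] / spacing_mm[1]
  gy <- points_mm[, 2] / spacing_mm[2]
  gz <- points_mm[, 3] / spacing_mm[3]
  ok <- gx >= 0 & gx <= dm[1] - 1 & gy >= 0 & gy <= dm[2] - 1 &
    gz >= 0 & gz <= dm[3] - 1
  out <- rep(NA_real_, nrow(points_mm))
  if (!any(ok)) return(out)
  gx <- gx[ok]; gy <- gy[ok]; gz <- gz[ok]
  x0 <- pmin(floor(gx), dm[1] - 2); fx <- gx - x0
  y0 <- pmin(floor(gy), dm[2] - 2); fy <- gy - y0
  z0 <- pmin(floor(gz), dm[3] - 2); fz <- gz - z0
  at <- function(dx, dy, dz) {
    values[cbind(x0 + dx + 1, y0 + dy + 1, z0 + dz + 1)]
  }
  out[ok] <-
    at(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(1, 0, 0) * fx * (1 - fy) * (1 - fz) +
    at(0, 1, 0) * (1 - fx) * fy * (1 - fz) +
    at(1, 1, 0) * fx * fy * (1 - fz) +
    at(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
    at(1, 0, 1) * fx * (1 - fy) * fz +
    at(0, 1, 1) * (1 - fx) * fy * fz +
    at(1, 1, 1) * fx * fy * fz
  out
}

#' Maximal CDF slope of one intensity profile
#'
#' The empirical CDF of the sampled intensities is evaluated at the
#' distinct sample values; the returned slope is the largest finite
#' difference `diff(F) / diff(value)` between consecutive distinct values.
#' Profiles with fewer than two distinct values have no defined slope and
#' return `NA`.
#'
#' @param values Numeric vector of intensities sampled along one profile.
#' @return Maximal CDF slope (1/HU), or `NA_real_`.
#' @export
cdf_max_slope <- function(values) {
  values <- values[is.finite(values)]
  v <- sort(unique(values))
  if (length(v) < 2) return(NA_real_)
  f <- stats::ecdf(values)(v)
  max(diff(f) / diff(v))
}

#' Summary statistics of a set of margin CDF slopes
#'
#' @param slopes Numeric vector of per-profile maximal CDF slopes.
#' @return Named numeric vector: mean, SD (sample), skewness, kurtosis
#'   (population moments; both 0 for a degenerate distribution), median
#'   and IQR.
#' @export
cdf_slope_stats <- function(slopes) {
  slopes <- slopes[is.finite(slopes)]
  if (!length(slopes)) stop_radguide("no finite slopes")
  setNames(c(mean(slopes),
             if (length(slopes) > 1) sd(slopes) else 0,
             moment_skewness(slopes),
             moment_kurtosis(slopes),
             median(slopes),
             unname(diff(quantile(slopes, c(.25, .75), names = FALSE)))),
           margin_feature_names)
}

#' Margin sharpness features from boundary intensity profiles
#'
#' At boundary voxels of the mask (foreground voxels with a background
#' face-neighbor), intensity profiles are sampled by trilinear
#' interpolation along the outward direction from the mask centroid, over
#' `+/- profile_length_mm`. Each profile is reduced to the maximal slope of
#' its empirical intensity CDF (see [cdf_max_slope()]); sharp margins give
#' tight, high-slope distributions and blurred margins broad, low-slope
#' ones. The six returned features are the summary statistics of the
#' per-profile slope distribution ([cdf_slope_stats()]).
#'
#' @param volume A [voxel_volume()].
#' @param mask A congruent [roi_mask()].
#' @param profile_length_mm Half-length of each profile in mm.
#' @param n_profiles Number of boundary voxels sampled (evenly spaced along
#'   the ordered boundary list).
#' @param step_mm Sampling step along the profile; defaults to the smallest
#'   voxel spacing.
#' @return Named numeric vector of length 6.
#' @export
margin_cdf_features <- function(volume, mask, profile_length_mm = 5,
                                n_profiles = 64, step_mm = NULL) {
  check_congruent(volume, mask)
  sp <- volume$spacing_mm
  step_mm <- step_mm %||% min(sp)
  m <- mask$values
  boundary <- which(m & !erode6(m), arr.ind = TRUE)
  if (nrow(boundary) == 0) stop_radguide("mask has no boundary voxels")
  all_idx <- which(m, arr.ind = TRUE)
  centroid <- colMeans(sweep(all_idx - 1, 2, sp, `*`))

  take <- unique(round(seq(1, nrow(boundary),
                           length.out = min(n_profiles, nrow(boundary)))))
  bpts <- sweep(boundary[take, , drop = FALSE] - 1, 2, sp, `*`)
  dirs <- sweep(bpts, 2, centroid, `-`)
  len <- sqrt(rowSums(dirs^2))
  keep <- len > 0
  bpts <- bpts[keep, , drop = FALSE]
  dirs <- dirs[keep, , drop = FALSE] / len[keep]

  if (nrow(bpts) < 8) {
    stop_radguide("margin undersampled: only ", nrow(bpts),
                  " usable profiles (need >= 8)")
  }
  tt <- seq(-profile_length_mm, profile_length_mm, by = step_mm)
  npf <- nrow(bpts)
  pts <- matrix(0, npf * length(tt), 3)
  for (a in 1:3) {
    pts[, a] <- rep(bpts[, a], each = length(tt)) +
      rep(dirs[, a], each = length(tt)) * tt
  }
  vals <- matrix(trilinear_interp(volume$values, sp, pts),
                 nrow = length(tt))
  clipped <- sum(is.na(vals))
  if (clipped > 0) {
    warning(clipped, " profile samples fell outside the grid and were ",
            "clipped", call. = FALSE)
  }
  slopes <- apply(vals, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 3) return(NA_real_)
    cdf_max_slope(v)
  })
  slopes <- slopes[is.finite(slopes)]
  if (length(slopes) < 8) {
    stop_radguide("margin undersampled: only ", length(slopes),
                  " usable profiles (need >= 8)")
  }
  cdf_slope_stats(slopes)
}
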