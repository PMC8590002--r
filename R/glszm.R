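#' Gray-level size-zone matrix
#'
#' Zones are connected components (26-connectivity in 3D) of voxels
#' sharing the same discretized gray level inside the ROI. The matrix
#' counts zones by gray level and zone size, so
#' `sum(size * count)` equals the number of ROI voxels.
#'
#' @param binned Integer array from [discretize_roi()] (`NA` outside ROI).
#' @param n_bins Number of gray levels.
#' @return Integer count matrix with rows = gray levels `1..n_bins` and
#'   columns = zone sizes `1..max_size`.
#' @export
glszm <- function(binned, n_bins = max(binned, na.rm = TRUE)) {
  if (!any(!is.na(binned))) stop_radguide("empty mask")
  g <- binned
  g[is.na(g)] <- 0L
  zones <- cpp_gray_zones(as.integer(g), dim(g)[1], dim(g)[2], dim(g)[3])
  max_size <- max(zones[, "size"])
  m <- matrix(0L, nrow = n_bins, ncol = max_size)
  for (i in seq_len(nrow(zones))) {
    m[zones[i, "gray"], zones[i, "size"]] <-
      m[zones[i, "gray"], zones[i, "size"]] + 1L
  }
  dimnames(m) <- list(gray = seq_len(n_bins), size = seq_len(max_size))
  m
}

glszm_feature_names <- c(
  "SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "ZonePercentage", "GrayLevelVariance",
  "ZoneVariance", "ZoneEntropy", "LowGrayLevelZoneEmphasis",
  "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
  "SmallAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
  "LargeAreaHighGrayLevelEmphasis")

#' GLSZM texture features
#'
#' The 16 standard size-zone features: small/large-area emphasis, gray-level
#' and size-zone non-uniformity (raw and normalized), zone percentage,
#' gray-level/zone variance, zone entropy, and the four joint
#' low/high-gray-level small/large-area emphases.
#'
#' @param m Count matrix from [glszm()].
#' @param n_voxels Number of ROI voxels (defaults to the mass of `m`).
#' @return Named numeric vector of length 16.
#' @export
glszm_features <- function(m, n_voxels = NULL) {
  nz <- sum(m)
  if (nz <= 0) stop_radguide("empty size-zone matrix")
  g <- matrix(seq_len(nrow(m)), nrow(m), ncol(m))
  s <- matrix(seq_len(ncol(m)), nrow(m), ncol(m), byrow = TRUE)
  np <- n_voxels %||% sum(m * s)
  p <- m / nz
  mug <- sum(g * p)
  mus <- sum(s * p)
  setNames(c(
    sum(m / s^2) / nz,                       # SmallAreaEmphasis
    sum(m * s^2) / nz,                       # LargeAreaEmphasis
    sum(rowSums(m)^2) / nz,                  # GrayLevelNonUniformity
    sum(rowSums(m)^2) / nz^2,                # GLN normalized
    sum(colSums(m)^2) / nz,                  # SizeZoneNonUniformity
    sum(colSums(m)^2) / nz^2,                # SZN normalized
    nz / np,                                 # ZonePercentage
    sum((g - mug)^2 * p),                    # GrayLevelVariance
    sum((s - mus)^2 * p),                    # ZoneVariance
    entropy_bits(p),                         # ZoneEntropy
    sum(m / g^2) / nz,                       # LowGrayLevelZoneEmphasis
    sum(m * g^2) / nz,                       # HighGrayLevelZoneEmphasis
    sum(m / (g^2 * s^2)) / nz,               # SmallAreaLowGrayLevel
    sum(m * g^2 / s^2) / nz,                 # SmallAreaHighGrayLevel
    sum(m * s^2 / g^2) / nz,                 # LargeAreaLowGrayLevel
    sum(m * s^2 * g^2) / nz),                # LargeAreaHighGrayLevel
    glszm_feature_names)
}
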