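#' Discretize ROI intensities into equal-width bins
#'
#' Bins span `[min, max]` of the intensities inside the mask, making every
#' downstream texture feature invariant to adding a constant to the volume.
#' A constant ROI maps entirely to bin 1.
#'
#' @param volume A [voxel_volume()].
#' @param mask A congruent [roi_mask()].
#' @param n_bins Number of gray levels (>= 2).
#' @return Integer array of the volume's shape with bin labels `1..n_bins`
#'   inside the mask and `NA` outside.
#' @export
discretize_roi <- function(volume, mask, n_bins = 32) {
  check_congruent(volume, mask)
  if (n_bins < 2) stop_radguide("n_bins must be >= 2")
  m <- mask$values
  x <- volume$values[m]
  lo <- min(x)
  hi <- max(x)
  binned <- array(NA_integer_, dim = dim(m))
  if (hi == lo) {
    binned[m] <- 1L
    return(binned)
  }
  b <- floor((x - lo) / (hi - lo) * n_bins) + 1L
  b[b > n_bins] <- as.integer(n_bins) # x == hi lands in the top bin
  binned[m] <- as.integer(b)
  binned
}
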