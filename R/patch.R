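#' Select the axial slice with the largest tumor extent
#'
#' @param mask A [roi_mask()].
#' @return Index of the axial (third-axis) slice maximizing in-slice
#'   foreground area; ties resolve to the smallest index.
#' @export
select_center_slice <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  areas <- apply(mask$values, 3, sum)
  which.max(areas) # ties: first (smallest) index
}

#' Extract a 2.5D tumor patch
#'
#' Takes the three consecutive axial slices centered on the slice of
#' largest tumor extent (edge slices are replicated at the volume
#' boundary) and crops an in-plane `size x size` window centered at the
#' rounded in-slice mask centroid (`floor(x + 0.5)` per axis). Regions
#' outside the grid are padded with `pad_value`, by default the lower clip
#' bound of the lung intensity window used by [preprocess_patch()].
#'
#' @param volume A [voxel_volume()].
#' @param mask A congruent [roi_mask()].
#' @param size In-plane patch size in voxels.
#' @param pad_value Intensity used outside the grid.
#' @return `size x size x 3` array with attributes `center_slice`,
#'   `center_inplane` and `pad` (voxels padded left/right/top/bottom).
#' @export
extract_patch <- function(volume, mask, size = 128, pad_value = -1700) {
  check_congruent(volume, mask)
  dm <- dim(volume$values)
  if (dm[3] < 3) stop_radguide("volume has fewer than 3 axial slices")
  k <- select_center_slice(mask)
  slices <- pmin(pmax(c(k - 1L, k, k + 1L), 1L), dm[3])

  sl <- mask$values[, , k]
  idx <- which(sl, arr.ind = TRUE)
  ctr <- floor(colMeans(idx) + 0.5)

  lo <- ctr - size %/% 2 + 1L
  hi <- lo + size - 1L
  src1 <- max(1L, lo[1]):min(dm[1], hi[1])
  src2 <- max(1L, lo[2]):min(dm[2], hi[2])
  dst1 <- src1 - lo[1] + 1L
  dst2 <- src2 - lo[2] + 1L

  patch <- array(pad_value, dim = c(size, size, 3L))
  patch[dst1, dst2, ] <- volume$values[src1, src2, slices]
  structure(patch,
            center_slice = k,
            center_inplane = ctr,
            pad = c(left = max(0L, 1L - lo[1]),
                    right = max(0L, hi[1] - dm[1]),
                    top = max(0L, 1L - lo[2]),
                    bottom = max(0L, hi[2] - dm[2])))
}

#' Intensity preprocessing for the frozen networks
#'
#' Clips to the lung window `[-1700, 300]` HU (level -700, width 1500,
#' extended by half a width on each side) and min-max scales the window to
#' `[0, 1]`. The window is fixed, so the scaling is deterministic and
#' independent of patch content.
#'
#' @param patch Array from [extract_patch()].
#' @param clip Length-2 window in HU.
#' @return Array of the same shape with values in `[0, 1]`.
#' @export
preprocess_patch <- function(patch, clip = c(-1700, 300)) {
  (pmin(pmax(patch, clip[1]), clip[2]) - clip[1]) / (clip[2] - clip[1])
}

#' Bilinear in-plane upsampling of a patch
#'
#' Corner-aligned bilinear interpolation applied per slice; corner values
#' are preserved and linear ramps stay linear. Downscaling is refused.
#'
#' @param patch `H x W x C` array.
#' @param target Target in-plane size (>= input size).
#' @return `target x target x C` array.
#' @export
resize_patch <- function(patch, target) {
  d <- dim(patch)
  if (target < d[1] || target < d[2]) {
    stop_radguide("resize_patch only upsamples (", d[1], " -> ", target,
                  " requested)")
  }
  if (target == d[1] && target == d[2]) return(patch)
  interp_matrix <- function(n_in, n_out) {
    w <- matrix(0, n_out, n_in)
    if (n_in == 1) { w[, 1] <- 1; return(w) }
    src <- (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
    i0 <- pmin(floor(src), n_in - 2)
    f <- src - i0
    w[cbind(seq_len(n_out), i0 + 1)] <- 1 - f
    w[cbind(seq_len(n_out), i0 + 2)] <-
      w[cbind(seq_len(n_out), i0 + 2)] + f
    w
  }
  wr <- interp_matrix(d[1], target)
  wc <- interp_matrix(d[2], target)
  out <- array(0, dim = c(target, target, d[3]))
  for (ch in seq_len(d[3])) {
    out[, , ch] <- wr %*% patch[, , ch] %*% t(wc)
  }
  out
}
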