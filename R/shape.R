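shape_feature_names <- c(
  "Volume", "SurfaceArea", "SurfaceVolumeRatio", "Sphericity",
  "SphericalDisproportion", "MajorAxisLength", "MinorAxisLength",
  "LeastAxisLength", "Elongation", "Flatness", "Maximum3DDiameter",
  "Maximum2DDiameterSlice", "Maximum2DDiameterColumn", "Maximum2DDiameterRow")

max_pairwise_mm <- function(coords) {
  if (nrow(coords) < 2) return(0)
  # the diameter is attained on the planar convex hull
  if (ncol(coords) == 2 && nrow(coords) > 8) {
    hull <- grDevices::chull(coords[, 1], coords[, 2])
    coords <- coords[hull, , drop = FALSE]
  }
  max(stats::dist(coords))
}

# voxel faces exposed to background (or the grid edge), per axis
exposed_faces <- function(m, axis) {
  dm <- dim(m)
  n <- dm[axis]
  pick <- function(a, b) switch(axis,
    m[a:b, , , drop = FALSE],
    m[, a:b, , drop = FALSE],
    m[, , a:b, drop = FALSE])
  inner_lo <- pick(1, n - 1) & !pick(2, n)      # face towards +axis
  inner_hi <- pick(2, n) & !pick(1, n - 1)      # face towards -axis
  sum(inner_lo) + sum(inner_hi) + sum(pick(1, 1)) + sum(pick(n, n))
}

#' 3D shape features of a tumor mask
#'
#' Fourteen voxel-based shape descriptors: volume, surface area (sum of
#' mask faces exposed to background), surface-to-volume ratio, sphericity
#' and its reciprocal (spherical disproportion), the three principal axis
#' lengths (`4 * sqrt(eigenvalue)` of the voxel-center covariance) with
#' elongation and flatness ratios, the maximum 3D diameter (largest
#' pairwise distance between surface voxel centers), and the maximum 2D
#' diameters within axial slices and within coronal/sagittal planes.
#'
#' A single-voxel mask has zero diameters and axis lengths; its elongation
#' and flatness are defined as 1.
#'
#' @param mask A [roi_mask()].
#' @return Named numeric vector of length 14 (lengths in mm, volume in
#'   mm^3, area in mm^2).
#' @export
shape_features <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  m <- mask$values
  sp <- mask$spacing_mm
  idx <- which(m, arr.ind = TRUE)
  coords <- sweep(idx - 1, 2, sp, `*`)
  n <- nrow(idx)

  vol <- n * prod(sp)
  face_area <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  area <- sum(vapply(1:3, function(a) exposed_faces(m, a) * face_area[a], 1))
  iso_area <- (36 * pi * vol^2)^(1 / 3)

  if (n > 1) {
    ev <- sort(eigen(stats::cov(coords), only.values = TRUE)$values,
               decreasing = TRUE)
    ev <- pmax(ev, 0)
  } else {
    ev <- c(0, 0, 0)
  }
  axes <- 4 * sqrt(ev)
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1
  flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1

  # surface voxels only, for the 3D diameter
  surf <- m & !(erode6(m))
  scoords <- sweep(which(surf, arr.ind = TRUE) - 1, 2, sp, `*`)

  max2d <- function(plane_axis) {
    keep <- setdiff(1:3, plane_axis)
    planes <- split.data.frame(coords[, keep, drop = FALSE],
                               idx[, plane_axis])
    max(vapply(planes, max_pairwise_mm, 1))
  }

  setNames(c(
    vol, area, area / vol, iso_area / area, area / iso_area,
    axes[1], axes[2], axes[3], elong, flat,
    max_pairwise_mm(scoords),
    max2d(3), max2d(2), max2d(1)), shape_feature_names)
}

# 6-connectivity erosion (voxels whose 6 face neighbors are all foreground
# and that do not touch the grid edge)
erode6 <- function(m) {
  dm <- dim(m)
  out <- m
  pad <- array(FALSE, dm + 2)
  pad[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)] <- m
  ctr <- function(dx, dy, dz) {
    pad[(2 + dx):(dm[1] + 1 + dx), (2 + dy):(dm[2] + 1 + dy),
        (2 + dz):(dm[3] + 1 + dz)]
  }
  out & ctr(1, 0, 0) & ctr(-1, 0, 0) & ctr(0, 1, 0) & ctr(0, -1, 0) &
    ctr(0, 0, 1) & ctr(0, 0, -1)
}
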