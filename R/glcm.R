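#' Gray-level co-occurrence matrices
#'
#' `glcm_directions()` lists the 13 unique 3D voxel directions (each
#' opposite pair counted once; symmetrization covers the other half).
#' `glcm_matrix()` counts co-occurrences of discretized gray levels at one
#' offset within the mask, symmetrizes and normalizes to a probability
#' matrix. `glcm_matrices()` returns one matrix per direction at a given
#' voxel distance.
#'
#' @param binned Integer array from [discretize_roi()] (`NA` outside ROI).
#' @param offset Integer length 3 voxel offset `(dx, dy, dz)`.
#' @param n_bins Number of gray levels (defaults to the max label).
#' @param distance Chebyshev distance of the offsets, in voxels.
#' @param directions Matrix of direction rows, as from `glcm_directions()`.
#' @return `glcm_matrix()`: an `n_bins x n_bins` symmetric probability
#'   matrix; `glcm_matrices()`: a list of them (directions with no valid
#'   voxel pair are dropped).
#' @export
glcm_directions <- function() {
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = 0:1))
  keep <- d[, 3] > 0 | (d[, 3] == 0 & d[, 2] > 0) |
    (d[, 3] == 0 & d[, 2] == 0 & d[, 1] > 0)
  unname(d[keep, , drop = FALSE])
}

glcm_counts_all <- function(binned, directions, n_bins) {
  g <- binned
  g[is.na(g)] <- 0L
  dm <- dim(g)
  cpp_glcm_counts(as.integer(g), dm[1], dm[2], dm[3],
                  matrix(as.integer(directions), ncol = 3), n_bins)
}

#' @rdname glcm_directions
#' @export
glcm_matrix <- function(binned, offset, n_bins = max(binned, na.rm = TRUE)) {
  stopifnot(length(offset) == 3)
  counts <- glcm_counts_all(binned, matrix(offset, 1), n_bins)
  cm <- matrix(counts[, 1], n_bins, n_bins)
  cm <- cm + t(cm) # symmetrize
  if (sum(cm) == 0) return(cm)
  cm / sum(cm)
}

#' @rdname glcm_directions
#' @export
glcm_matrices <- function(binned, distance = 1,
                          directions = glcm_directions(),
                          n_bins = max(binned, na.rm = TRUE)) {
  counts <- glcm_counts_all(binned, directions * distance, n_bins)
  out <- list()
  for (i in seq_len(ncol(counts))) {
    cm <- matrix(counts[, i], n_bins, n_bins)
    cm <- cm + t(cm)
    if (sum(cm) > 0) out[[length(out) + 1L]] <- cm / sum(cm)
  }
  if (!length(out)) {
    stop_radguide("degenerate ROI: no co-occurring voxel pair in any ",
                  "direction")
  }
  out
}

# memoized level-index structures shared by repeated feature evaluations
glcm_structure_cache <- new.env(parent = emptyenv())
glcm_structures <- function(ng) {
  key <- as.character(ng)
  if (is.null(glcm_structure_cache[[key]])) {
    ii <- matrix(seq_len(ng), ng, ng)
    jj <- t(ii)
    glcm_structure_cache[[key]] <- list(
      ii = ii, jj = jj,
      diff_group = as.vector(abs(ii - jj)),      # 0 .. ng-1
      sum_group = as.vector(ii + jj))            # 2 .. 2 ng
  }
  glcm_structure_cache[[key]]
}

glcm_feature_names <- c(
  "Autocorrelation", "JointAverage", "ClusterProminence", "ClusterShade",
  "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
  "DifferenceEntropy", "DifferenceVariance", "JointEnergy", "JointEntropy",
  "IMC1", "IMC2", "IDM", "IDMN", "InverseDifference", "IDN",
  "InverseVariance", "MaximumProbability", "SumAverage", "SumEntropy",
  "SumSquares", "MCC")

#' GLCM texture features
#'
#' Computes the 24 co-occurrence features (autocorrelation, cluster
#' statistics, contrast, correlation, difference/sum statistics, the
#' informational measures of correlation, the inverse-difference family,
#' inverse variance, maximum probability, joint energy/entropy and the
#' maximal correlation coefficient) from one normalized symmetric GLCM.
#' Gray-level indices run `1..nrow(P)`; entropies are in bits.
#'
#' @param P Normalized symmetric co-occurrence probability matrix.
#' @return Named numeric vector of length 24.
#' @export
glcm_features <- function(P) {
  if (!is.matrix(P) || nrow(P) != ncol(P)) stop_radguide("P must be square")
  tot <- sum(P)
  if (tot <= 0) stop_radguide("zero co-occurrence matrix")
  P <- P / tot
  ng <- nrow(P)
  lv <- seq_len(ng)
  px <- rowSums(P)
  mu <- sum(lv * px)
  sig2 <- sum((lv - mu)^2 * px)

  st <- glcm_structures(ng)
  ii <- st$ii
  jj <- st$jj

  # difference and sum marginals via grouped sums
  kdiff <- 0:(ng - 1)
  pdiff <- as.vector(rowsum(as.vector(P), st$diff_group))
  ksum <- 2:(2 * ng)
  psum <- as.vector(rowsum(as.vector(P), st$sum_group))
  da <- sum(kdiff * pdiff)

  hxy <- entropy_bits(P)
  pxpy <- outer(px, px)
  pos <- P > 0
  hxy1 <- -sum(P[pos] * log2(pxpy[pos]))
  hxy2 <- entropy_bits(pxpy)
  hx <- entropy_bits(px)
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(1 - exp(pmin(0, -2 * (hxy2 - hxy))))

  # maximal correlation coefficient via the Q matrix on occupied levels
  occ <- which(px > 0)
  mcc <- 1
  if (length(occ) > 1) {
    Ps <- P[occ, occ, drop = FALSE]
    pxs <- px[occ]
    # Q[a, b] = sum_k P(a,k) P(b,k) / (px(a) px(k))
    Q <- (Ps / pxs) %*% t(sweep(Ps, 2, pxs, "/"))
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- sqrt(min(1, max(0, ev[2])))
  }

  corr <- if (sig2 > 0) (sum(ii * jj * P) - mu^2) / sig2 else 1
  offd <- abs(ii - jj) > 0

  setNames(c(
    sum(ii * jj * P),                                  # Autocorrelation
    mu,                                                # JointAverage
    sum((ii + jj - 2 * mu)^4 * P),                     # ClusterProminence
    sum((ii + jj - 2 * mu)^3 * P),                     # ClusterShade
    sum((ii + jj - 2 * mu)^2 * P),                     # ClusterTendency
    sum((ii - jj)^2 * P),                              # Contrast
    corr,                                              # Correlation
    da,                                                # DifferenceAverage
    entropy_bits(pdiff),                               # DifferenceEntropy
    sum((kdiff - da)^2 * pdiff),                       # DifferenceVariance
    sum(P^2),                                          # JointEnergy
    hxy,                                               # JointEntropy
    imc1, imc2,
    sum(P / (1 + (ii - jj)^2)),                        # IDM
    sum(P / (1 + ((ii - jj) / ng)^2)),                 # IDMN
    sum(P / (1 + abs(ii - jj))),                       # InverseDifference
    sum(P / (1 + abs(ii - jj) / ng)),                  # IDN
    sum(P[offd] / (ii[offd] - jj[offd])^2),            # InverseVariance
    max(P),                                            # MaximumProbability
    sum(ksum * psum),                                  # SumAverage
    entropy_bits(psum),                                # SumEntropy
    sum((ii - mu)^2 * P),                              # SumSquares
    mcc), glcm_feature_names)
}

# Per-direction features averaged over directions (feature-level averaging)
glcm_features_avg <- function(binned, distance = 1, n_bins) {
  mats <- glcm_matrices(binned, distance, n_bins = n_bins)
  vals <- vapply(mats, glcm_features, numeric(length(glcm_feature_names)))
  rowMeans(vals)
}
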