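# Independent brute-force oracles. Everything here is written as plain
# loops over definitions, deliberately sharing no code with the package.

# -- texture ----------------------------------------------------------------

# co-occurrence counts by scanning every voxel pair explicitly
oracle_glcm_matrix <- function(binned, offset, n_bins) {
  dm <- dim(binned)
  counts <- matrix(0, n_bins, n_bins)
  for (x in seq_len(dm[1])) {
    for (y in seq_len(dm[2])) {
      for (z in seq_len(dm[3])) {
        a <- binned[x, y, z]
        if (is.na(a)) next
        xx <- x + offset[1]; yy <- y + offset[2]; zz <- z + offset[3]
        if (xx < 1 || xx > dm[1] || yy < 1 || yy > dm[2] ||
            zz < 1 || zz > dm[3]) next
        b <- binned[xx, yy, zz]
        if (is.na(b)) next
        counts[a, b] <- counts[a, b] + 1
        counts[b, a] <- counts[b, a] + 1 # symmetric pair
      }
    }
  }
  if (sum(counts) == 0) return(counts)
  counts / sum(counts)
}

oracle_glcm_features <- function(P) {
  ng <- nrow(P)
  px <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) px[i] <- px[i] + P[i, j]
  mu <- 0
  for (i in 1:ng) mu <- mu + i * px[i]
  sig2 <- 0
  for (i in 1:ng) sig2 <- sig2 + (i - mu)^2 * px[i]

  pd <- numeric(ng)            # |i-j| = k, k = 0..ng-1 stored at k+1
  ps <- numeric(2 * ng - 1)    # i+j = k, k = 2..2ng stored at k-1
  for (i in 1:ng) for (j in 1:ng) {
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + P[i, j]
    ps[i + j - 1] <- ps[i + j - 1] + P[i, j]
  }
  da <- 0
  for (k in 0:(ng - 1)) da <- da + k * pd[k + 1]
  dvar <- 0
  for (k in 0:(ng - 1)) dvar <- dvar + (k - da)^2 * pd[k + 1]
  dent <- 0
  for (k in seq_along(pd)) if (pd[k] > 0) dent <- dent - pd[k] * log2(pd[k])
  sent <- 0
  for (k in seq_along(ps)) if (ps[k] > 0) sent <- sent - ps[k] * log2(ps[k])
  savg <- 0
  for (k in 2:(2 * ng)) savg <- savg + k * ps[k - 1]

  auto <- javg <- prom <- shade <- tend <- contrast <- 0
  energy <- ent <- idm <- idmn <- id <- idn <- invvar <- ssq <- 0
  hxy1 <- hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    auto <- auto + i * j * p
    prom <- prom + (i + j - 2 * mu)^4 * p
    shade <- shade + (i + j - 2 * mu)^3 * p
    tend <- tend + (i + j - 2 * mu)^2 * p
    contrast <- contrast + (i - j)^2 * p
    energy <- energy + p^2
    if (p > 0) ent <- ent - p * log2(p)
    idm <- idm + p / (1 + (i - j)^2)
    idmn <- idmn + p / (1 + ((i - j) / ng)^2)
    id <- id + p / (1 + abs(i - j))
    idn <- idn + p / (1 + abs(i - j) / ng)
    if (i != j) invvar <- invvar + p / (i - j)^2
    ssq <- ssq + (i - mu)^2 * p
    if (p > 0 && px[i] * px[j] > 0) {
      hxy1 <- hxy1 - p * log2(px[i] * px[j])
    }
    if (px[i] * px[j] > 0) {
      hxy2 <- hxy2 - px[i] * px[j] * log2(px[i] * px[j])
    }
  }
  hx <- 0
  for (i in 1:ng) if (px[i] > 0) hx <- hx - px[i] * log2(px[i])
  corr <- if (sig2 > 0) (auto - mu^2) / sig2 else 1
  imc1 <- if (hx > 0) (ent - hxy1) / hx else 0
  imc2 <- sqrt(1 - exp(min(0, -2 * (hxy2 - ent))))

  occ <- which(px > 0)
  mcc <- 1
  if (length(occ) > 1) {
    Q <- matrix(0, length(occ), length(occ))
    for (a in seq_along(occ)) for (b in seq_along(occ)) {
      s <- 0
      for (k in seq_along(occ)) {
        s <- s + P[occ[a], occ[k]] * P[occ[b], occ[k]] /
          (px[occ[a]] * px[occ[k]])
      }
      Q[a, b] <- s
    }
    ev <- sort(Re(eigen(Q)$values), decreasing = TRUE)
    mcc <- sqrt(min(1, max(0, ev[2])))
  }

  c(Autocorrelation = auto, JointAverage = mu, ClusterProminence = prom,
    ClusterShade = shade, ClusterTendency = tend, Contrast = contrast,
    Correlation = corr, DifferenceAverage = da, DifferenceEntropy = dent,
    DifferenceVariance = dvar, JointEnergy = energy, JointEntropy = ent,
    IMC1 = imc1, IMC2 = imc2, IDM = idm, IDMN = idmn,
    InverseDifference = id, IDN = idn, InverseVariance = invvar,
    MaximumProbability = max(P), SumAverage = savg, SumEntropy = sent,
    SumSquares = ssq, MCC = mcc)
}

# zone list by repeated flood fill with an explicit queue
oracle_glszm_zones <- function(binned) {
  dm <- dim(binned)
  visited <- array(FALSE, dm)
  zones <- list()
  for (x0 in seq_len(dm[1])) for (y0 in seq_len(dm[2])) {
    for (z0 in seq_len(dm[3])) {
      if (visited[x0, y0, z0] || is.na(binned[x0, y0, z0])) next
      lev <- binned[x0, y0, z0]
      queue <- list(c(x0, y0, z0))
      visited[x0, y0, z0] <- TRUE
      size <- 0
      while (length(queue)) {
        v <- queue[[1]]
        queue <- queue[-1]
        size <- size + 1
        for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
          if (dx == 0 && dy == 0 && dz == 0) next
          u <- v + c(dx, dy, dz)
          if (any(u < 1) || any(u > dm)) next
          if (visited[u[1], u[2], u[3]]) next
          if (is.na(binned[u[1], u[2], u[3]])) next
          if (binned[u[1], u[2], u[3]] != lev) next
          visited[u[1], u[2], u[3]] <- TRUE
          queue[[length(queue) + 1]] <- u
        }
      }
      zones[[length(zones) + 1]] <- c(gray = lev, size = size)
    }
  }
  do.call(rbind, zones)
}

oracle_glszm_features <- function(zones, n_voxels) {
  nz <- nrow(zones)
  sae <- lae <- lgl <- hgl <- salgl <- sahgl <- lalgl <- lahgl <- 0
  for (i in 1:nz) {
    g <- as.numeric(zones[i, "gray"]); s <- as.numeric(zones[i, "size"])
    sae <- sae + 1 / s^2; lae <- lae + s^2
    lgl <- lgl + 1 / g^2; hgl <- hgl + g^2
    salgl <- salgl + 1 / (g^2 * s^2); sahgl <- sahgl + g^2 / s^2
    lalgl <- lalgl + s^2 / g^2; lahgl <- lahgl + g^2 * s^2
  }
  gl_tab <- table(zones[, "gray"])
  sz_tab <- table(zones[, "size"])
  mug <- sum(zones[, "gray"]) / nz
  mus <- sum(zones[, "size"]) / nz
  glv <- sum((zones[, "gray"] - mug)^2) / nz
  zv <- sum((zones[, "size"] - mus)^2) / nz
  # zone entropy over the joint (gray, size) distribution
  key <- paste(zones[, "gray"], zones[, "size"])
  pj <- table(key) / nz
  ze <- -sum(pj * log2(pj))
  c(SmallAreaEmphasis = sae / nz, LargeAreaEmphasis = lae / nz,
    GrayLevelNonUniformity = sum(gl_tab^2) / nz,
    GrayLevelNonUniformityNormalized = sum(gl_tab^2) / nz^2,
    SizeZoneNonUniformity = sum(sz_tab^2) / nz,
    SizeZoneNonUniformityNormalized = sum(sz_tab^2) / nz^2,
    ZonePercentage = nz / n_voxels,
    GrayLevelVariance = glv, ZoneVariance = zv, ZoneEntropy = ze,
    LowGrayLevelZoneEmphasis = lgl / nz,
    HighGrayLevelZoneEmphasis = hgl / nz,
    SmallAreaLowGrayLevelEmphasis = salgl / nz,
    SmallAreaHighGrayLevelEmphasis = sahgl / nz,
    LargeAreaLowGrayLevelEmphasis = lalgl / nz,
    LargeAreaHighGrayLevelEmphasis = lahgl / nz)
}

oracle_firstorder <- function(x, bins, voxel_volume_mm3) {
  n <- length(x)
  m <- sum(x) / n
  m2 <- sum((x - m)^2) / n
  m3 <- sum((x - m)^3) / n
  m4 <- sum((x - m)^4) / n
  p <- as.vector(table(factor(bins, levels = seq_len(max(bins))))) / n
  p <- p[p > 0]
  q <- unname(quantile(x, c(.10, .25, .5, .75, .90)))
  robust <- x[x >= q[1] & x <= q[5]]
  c(Energy = sum(x^2), TotalEnergy = sum(x^2) * voxel_volume_mm3,
    Entropy = -sum(p * log2(p)), Minimum = min(x), Percentile10 = q[1],
    Percentile90 = q[5], Maximum = max(x), Mean = m, Median = q[3],
    InterquartileRange = q[4] - q[2], Range = max(x) - min(x),
    MeanAbsoluteDeviation = sum(abs(x - m)) / n,
    RobustMeanAbsoluteDeviation =
      sum(abs(robust - mean(robust))) / length(robust),
    RootMeanSquared = sqrt(sum(x^2) / n),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2, Uniformity = sum(p^2))
}

# -- survival ---------------------------------------------------------------

oracle_km <- function(time, event) {
  s <- 1
  out <- NULL
  for (t in sort(unique(time[event == 1]))) {
    n_at <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_at)
    out <- rbind(out, data.frame(time = t, survival = s))
  }
  out
}

oracle_logrank <- function(groups, time, event) {
  g1 <- groups == levels(factor(groups))[1]
  o1 <- e1 <- v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) {
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  stat <- (o1 - e1)^2 / v
  list(statistic = stat, p = pchisq(stat, 1, lower.tail = FALSE),
       o_minus_e = o1 - e1, v = v)
}

oracle_cindex <- function(scores, time, event) {
  num <- den <- 0
  n <- length(scores)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    if (time[i] < time[j] && event[i] == 1) {
      den <- den + 1
      if (scores[i] > scores[j]) num <- num + 1
      if (scores[i] == scores[j]) num <- num + 0.5
    }
  }
  num / den
}

# unpenalized Cox fit by Newton-Raphson on the Breslow partial likelihood
oracle_newton_cox <- function(x, time, event, iter = 60) {
  x <- as.matrix(x)
  p <- ncol(x)
  beta <- rep(0, p)
  for (it in 1:iter) {
    grad <- rep(0, p)
    hess <- matrix(0, p, p)
    eta <- as.vector(x %*% beta)
    w <- exp(eta)
    for (i in which(event == 1)) {
      at <- time >= time[i]
      s0 <- sum(w[at])
      s1 <- colSums(x[at, , drop = FALSE] * w[at])
      s2 <- t(x[at, , drop = FALSE] * w[at]) %*% x[at, , drop = FALSE]
      grad <- grad + x[i, ] - s1 / s0
      hess <- hess + s2 / s0 - (s1 %*% t(s1)) / s0^2
    }
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < 1e-12) break
  }
  beta
}

# -- screening --------------------------------------------------------------

oracle_screen <- function(dl, rad, r_threshold, alpha) {
  dn <- setdiff(names(dl), "patient_id")
  rn <- setdiff(names(rad), "patient_id")
  m <- length(dn) * length(rn)
  retained <- character(0)
  for (a in dn) {
    best <- 0; bestp <- 1
    for (b in rn) {
      ct <- suppressWarnings(cor.test(dl[[a]], rad[[b]]))
      if (is.na(ct$estimate)) next
      if (abs(ct$estimate) > abs(best)) {
        best <- ct$estimate
        bestp <- ct$p.value
      }
    }
    if (abs(best) > r_threshold && min(1, m * bestp) < alpha) {
      retained <- c(retained, a)
    }
  }
  retained
}

# -- fixtures ---------------------------------------------------------------

random_roi <- function(dims, n_bins, seed, p_mask = 0.8) {
  set.seed(seed)
  mask <- array(runif(prod(dims)) < p_mask, dims)
  if (!any(mask)) mask[1] <- TRUE
  vol <- array(rnorm(prod(dims), sd = 50), dims)
  list(volume = voxel_volume(vol), mask = roi_mask(mask),
       binned = discretize_roi(voxel_volume(vol), roi_mask(mask), n_bins))
}

small_phantom <- function(seed = 1, radius = 7, ...) {
  generate_phantom(phantom_spec(grid_shape = c(32, 32, 32),
                                tumor_radius_mm = radius, seed = seed, ...))
}
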