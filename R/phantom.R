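# Separable Gaussian smoothing with a truncated (4 sigma), renormalized
# kernel. With a normalized kernel the smoothed indicator of a region is
# exactly 1 wherever the kernel support lies fully inside the region.
gaussian_smooth_3d <- function(x, sigma_mm, spacing_mm) {
  if (sigma_mm <= 0) return(x)
  dm <- dim(x)
  for (axis in 1:3) {
    sig <- sigma_mm / spacing_mm[axis]
    r <- ceiling(4 * sig)
    if (r < 1) next
    w <- exp(-((-r:r)^2) / (2 * sig^2))
    w <- w / sum(w)
    x <- array(cpp_convolve_axis(x, dm[1], dm[2], dm[3], w, axis), dm)
  }
  x
}

#' Specification of a synthetic CT tumor phantom
#'
#' Describes one textured tumor blob on a background grid: a spherical
#' plateau of `tumor_level` pseudo-HU blurred to a margin of width
#' `margin_width_mm`, carrying a correlated Gaussian texture field inside
#' the (unblurred) tumor mask, plus i.i.d. voxel noise. The texture field
#' is white noise smoothed with a Gaussian kernel of standard deviation
#' `texture_correlation_length_mm` and rescaled to standard deviation
#' `texture_sd`, so both the spatial scale and the amplitude of
#' intra-tumoral heterogeneity are controllable.
#'
#' @param grid_shape Integer length 3, voxels per axis.
#' @param spacing_mm Numeric length 3, voxel size in mm.
#' @param tumor_radius_mm Tumor radius (mm); the sphere must fit inside the
#'   grid with at least one voxel of background border.
#' @param texture_correlation_length_mm Correlation length of the
#'   intra-tumoral texture field (mm); larger values give coarser,
#'   more homogeneous-looking texture.
#' @param texture_sd Amplitude (HU) of the texture field; 0 disables it.
#' @param margin_width_mm Gaussian blur sigma (mm) applied to the tumor
#'   plateau; larger values give a fuzzier margin. 0 gives a sharp edge.
#' @param background_level,tumor_level Intensities in pseudo-HU.
#' @param noise_sd Additive i.i.d. Gaussian noise (HU); 0 disables it.
#' @param seed Integer seed; identical spec + seed gives identical output.
#' @return A `phantom_spec` list.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(grid_shape = c(32, 32, 32),
#'                                     tumor_radius_mm = 8, seed = 7))
#' range(ph$volume$values)
phantom_spec <- function(grid_shape = c(48, 48, 48),
                         spacing_mm = c(1, 1, 1),
                         tumor_radius_mm = 10,
                         texture_correlation_length_mm = 2,
                         texture_sd = 30,
                         margin_width_mm = 1,
                         background_level = -800,
                         tumor_level = 0,
                         noise_sd = 10,
                         seed = 1L) {
  spec <- list(grid_shape = as.integer(grid_shape),
               spacing_mm = as.numeric(spacing_mm),
               tumor_radius_mm = tumor_radius_mm,
               texture_correlation_length_mm = texture_correlation_length_mm,
               texture_sd = texture_sd,
               margin_width_mm = margin_width_mm,
               background_level = background_level,
               tumor_level = tumor_level,
               noise_sd = noise_sd,
               seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (length(grid_shape) != 3 || any(grid_shape < 3)) {
      stop_radguide("grid_shape must be 3 axes of at least 3 voxels")
    }
    if (any(spacing_mm <= 0)) stop_radguide("spacing must be positive")
    if (tumor_radius_mm <= 0 || texture_correlation_length_mm <= 0) {
      stop_radguide("lengths must be positive")
    }
    if (margin_width_mm < 0 || noise_sd < 0 || texture_sd < 0) {
      stop_radguide("margin_width_mm, noise_sd and texture_sd must be >= 0")
    }
    # the sphere needs >= 1 voxel of background on every side
    half_extent <- (grid_shape - 1) / 2 * spacing_mm
    if (any(tumor_radius_mm > half_extent - spacing_mm)) {
      stop_radguide("tumor of radius ", tumor_radius_mm,
                    " mm does not fit inside the grid with a 1-voxel border")
    }
  })
  invisible(spec)
}

#' Generate one tumor phantom
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `volume` ([voxel_volume()]) and `mask`
#'   ([roi_mask()]); the mask is the unblurred sphere.
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  dims <- spec$grid_shape
  sp <- spec$spacing_mm
  cx <- lapply(1:3, function(a) {
    co <- axis_coords(dims[a], sp[a])
    co - co[ceiling(dims[a] / 2)] # center on the middle voxel
  })
  d2 <- outer(outer(cx[[1]]^2, cx[[2]]^2, `+`), cx[[3]]^2, `+`)
  mask <- d2 <= spec$tumor_radius_mm^2
  if (!any(mask)) stop_radguide("empty tumor mask; increase the radius")

  plateau <- gaussian_smooth_3d(array(as.numeric(mask), dims),
                                spec$margin_width_mm, sp)
  vol <- spec$background_level +
    (spec$tumor_level - spec$background_level) * plateau

  if (spec$texture_sd > 0) {
    tex <- with_seed(derive_seed(spec$seed, "texture"), {
      white <- array(rnorm(prod(dims)), dims)
      gaussian_smooth_3d(white, spec$texture_correlation_length_mm, sp)
    })
    s <- stats::sd(tex[mask])
    if (s > 0) vol <- vol + mask * (tex / s) * spec$texture_sd
  }
  if (spec$noise_sd > 0) {
    vol <- vol + with_seed(derive_seed(spec$seed, "noise"),
                           array(rnorm(prod(dims), sd = spec$noise_sd), dims))
  }
  list(volume = voxel_volume(vol, sp), mask = roi_mask(mask, sp))
}

#' Specification of the synthetic survival generator
#'
#' Event times follow a proportional-hazards model with an exponential
#' baseline: `T_i ~ Exp(rate = baseline_hazard * exp(lp_i))` where the
#' linear predictor `lp_i` is a weighted sum of cohort-standardized planted
#' phantom properties. Censoring is the minimum of an administrative cap
#' and, for a `dropout_rate` fraction of patients, a uniform dropout time.
#'
#' The default effect (`betas = c(texture_sd = 3)`) plants a strong
#' intra-tumoral heterogeneity effect: one cohort standard deviation of
#' texture amplitude triples the log-hazard. With the default ranges,
#' baseline hazard and censoring this yields roughly 20% observed events
#' over the 60-month follow-up.
#'
#' @param n_patients Cohort size.
#' @param betas Named effect sizes on planted phantom properties; names
#'   must be fields varied in the phantom ranges. Use `c(...)` of zeros
#'   (or an empty vector) for a null cohort.
#' @param baseline_hazard Exponential baseline hazard per month.
#' @param admin_time_months Administrative censoring time (months).
#' @param dropout_rate Fraction of patients with uniform dropout on
#'   `(0, admin_time_months)`.
#' @param seed Integer seed.
#' @return A `survival_spec` list.
#' @export
survival_spec <- function(n_patients,
                          betas = c(texture_sd = 3),
                          baseline_hazard = 5e-4,
                          admin_time_months = 60,
                          dropout_rate = 0.1,
                          seed = 1L) {
  stopifnot(n_patients >= 2, baseline_hazard > 0, admin_time_months > 0,
            dropout_rate >= 0, dropout_rate < 1)
  if (length(betas) && is.null(names(betas))) {
    stop_radguide("betas must be named after phantom properties")
  }
  structure(list(n_patients = as.integer(n_patients), betas = betas,
                 baseline_hazard = baseline_hazard,
                 admin_time_months = admin_time_months,
                 dropout_rate = dropout_rate, seed = as.integer(seed)),
            class = "survival_spec")
}

#' Default per-patient phantom parameter ranges for a synthetic cohort
#'
#' Uniform sampling ranges for the phantom properties that vary across
#' patients. The desk-scale defaults (40-voxel grid, 6-12 mm radius) keep a
#' whole cohort cheap to generate while spanning visibly different sizes,
#' heterogeneity and margin sharpness. The texture amplitude range
#' (20-200 HU) covers homogeneous solid nodules up to strongly mixed
#' attenuation patterns.
#'
#' @return Named list of `c(min, max)` ranges.
#' @export
cohort_phantom_ranges <- function() {
  list(tumor_radius_mm = c(6, 12),
       texture_correlation_length_mm = c(1, 3),
       texture_sd = c(20, 200),
       margin_width_mm = c(0.5, 2.5))
}

#' Generate a synthetic cohort of phantoms with survival outcomes
#'
#' Draws per-patient phantom parameters uniformly from `phantom_ranges`,
#' renders the phantoms, and samples right-censored survival times whose
#' hazard depends on the standardized planted properties (see
#' [survival_spec()]). The ground-truth linear predictor is returned so
#' recovery of the planted signal can be measured.
#'
#' @param surv A [survival_spec()].
#' @param phantom_ranges Named list of `c(min, max)` sampling ranges for
#'   numeric [phantom_spec()] fields.
#' @param base_spec Template [phantom_spec()] providing all non-varied
#'   fields (grid, spacing, intensity levels, noise).
#' @param keep_images If `FALSE`, skip rendering the phantom images and
#'   return only the cohort table and ground truth (useful for studying
#'   the survival generator alone).
#' @return List with `volumes`, `masks` (lists, `NULL` if
#'   `keep_images = FALSE`), `cohort` (tibble: `patient_id`,
#'   `time_months`, `event`, `split`), and `truth` (tibble of planted
#'   properties plus `lp`, the true linear predictor).
#' @export
generate_cohort <- function(surv,
                            phantom_ranges = cohort_phantom_ranges(),
                            base_spec = phantom_spec(
                              grid_shape = c(40, 40, 40),
                              tumor_radius_mm = 8),
                            keep_images = TRUE) {
  stopifnot(inherits(surv, "survival_spec"))
  if (!length(phantom_ranges) || is.null(names(phantom_ranges))) {
    stop_radguide("phantom_ranges must be a named list of c(min, max)")
  }
  bad <- setdiff(names(surv$betas), names(phantom_ranges))
  if (length(bad)) {
    stop_radguide("betas name properties not in phantom_ranges: ",
                  paste(bad, collapse = ", "))
  }
  n <- surv$n_patients

  props <- with_seed(derive_seed(surv$seed, "properties"), {
    vapply(phantom_ranges,
           function(rg) runif(n, rg[1], rg[2]), numeric(n))
  })
  props <- matrix(props, nrow = n,
                  dimnames = list(NULL, names(phantom_ranges)))

  # linear predictor on cohort-standardized properties
  lp <- rep(0, n)
  for (nm in names(surv$betas)) {
    s <- stats::sd(props[, nm])
    if (s > 0) {
      lp <- lp + surv$betas[[nm]] * (props[, nm] - mean(props[, nm])) / s
    }
  }

  out <- with_seed(derive_seed(surv$seed, "survival"), {
    t_event <- rexp(n, rate = surv$baseline_hazard * exp(lp))
    dropped <- which(runif(n) < surv$dropout_rate)
    t_drop <- rep(Inf, n)
    t_drop[dropped] <- runif(length(dropped), 0, surv$admin_time_months)
    t_cens <- pmin(surv$admin_time_months, t_drop)
    list(time = pmin(t_event, t_cens), event = as.integer(t_event <= t_cens))
  })
  if (all(out$event == 1L)) {
    warning("all patients experienced the event; consider a lower ",
            "baseline hazard", call. = FALSE)
  }
  if (all(out$event == 0L)) {
    warning("all patients are censored; consider a higher baseline hazard",
            call. = FALSE)
  }

  volumes <- masks <- NULL
  if (keep_images) {
    volumes <- vector("list", n)
    masks <- vector("list", n)
    for (i in seq_len(n)) {
      fields <- as.list(props[i, ])
      sp <- unclass(base_spec)
      sp[names(fields)] <- fields
      sp$seed <- derive_seed(surv$seed, 1000 + i)
      ph <- generate_phantom(do.call(phantom_spec, sp))
      volumes[[i]] <- ph$volume
      masks[[i]] <- ph$mask
    }
  }

  cohort <- tibble::tibble(
    patient_id = sprintf("P%04d", seq_len(n)),
    time_months = out$time,
    event = out$event,
    split = NA_character_)
  truth <- tibble::as_tibble(as.data.frame(props))
  truth$lp <- lp
  list(volumes = volumes, masks = masks, cohort = cohort, truth = truth)
}

#' Write a synthetic cohort to disk
#'
#' Volumes and masks are written as NIfTI (`<id>_vol.nii.gz`,
#' `<id>_mask.nii.gz`) and the cohort table as `cohort.csv`.
#'
#' @param cohort_obj Result of [generate_cohort()] with images.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort_obj, dir) {
  if (is.null(cohort_obj$volumes)) {
    stop_radguide("cohort was generated with keep_images = FALSE")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- cohort_obj$cohort$patient_id
  for (i in seq_along(ids)) {
    write_volume(cohort_obj$volumes[[i]],
                 file.path(dir, paste0(ids[i], "_vol.nii.gz")))
    write_volume(cohort_obj$masks[[i]],
                 file.path(dir, paste0(ids[i], "_mask.nii.gz")))
  }
  write.csv(cohort_obj$cohort, file.path(dir, "cohort.csv"),
            row.names = FALSE)
  invisible(dir)
}
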