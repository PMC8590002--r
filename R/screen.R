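#' Pearson correlation with a two-sided p-value
#'
#' The p-value comes from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom. Zero-variance inputs have no defined correlation and
#' return `NA` for both values.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @return Named numeric vector `c(r, p)`.
#' @export
pearson_with_p <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3) stop_radguide("need equal lengths, n >= 3")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop_radguide("non-finite values")
  }
  if (sd(x) == 0 || sd(y) == 0) return(c(r = NA_real_, p = NA_real_))
  r <- cor(x, y)
  c(r = r, p = r_to_p(r, n))
}

r_to_p <- function(r, n) {
  r2 <- pmin(r^2, 1)
  tval <- abs(r) * sqrt((n - 2) / pmax(1 - r2, .Machine$double.eps))
  2 * pt(tval, df = n - 2, lower.tail = FALSE)
}

#' Correlation-guided deep-feature screen
#'
#' Evaluates the Pearson correlation of every deep feature against every
#' radiomics feature on the training cohort and retains the deep features
#' whose strongest association has `|r|` strictly above `r_threshold` and a
#' Bonferroni-corrected p-value below `alpha`. The Bonferroni family is the
#' full set of deep x radiomics pairs (after removing zero-variance deep
#' features, whose correlation is undefined).
#'
#' @param dl Deep-feature tibble (`patient_id` + feature columns),
#'   z-scored on the training cohort.
#' @param rad Radiomics tibble for the same patients in the same order.
#' @param r_threshold Retention threshold on `|r|` (strict inequality).
#' @param alpha Family-wise error level for the Bonferroni test.
#' @param keep_all_pairs_for Character vector of deep features whose full
#'   association profile (all radiomics correlations and uncorrected
#'   p-values) is stored; defaults to the retained set, which downstream
#'   interpretation reads without recomputing correlations.
#' @return A `correlation_screen` object: `per_dl` (tibble: deep feature,
#'   best radiomics match, `r`, `p`, `p_bonf`, `retained`), `pairs`
#'   (sparse tibble of all pairs with `|r| > r_threshold`), `profiles`
#'   (full association rows for the kept features), the family size `m`,
#'   the number of patients `n`, and the excluded zero-variance features.
#' @export
correlation_screen <- function(dl, rad, r_threshold = 0.4, alpha = 0.05,
                               keep_all_pairs_for = NULL) {
  if (!identical(dl$patient_id, rad$patient_id)) {
    stop_radguide("deep and radiomics tables have different patients ",
                  "or ordering")
  }
  dm <- feature_matrix(dl)
  rm_ <- feature_matrix(rad)
  n <- nrow(dm)
  if (n < 3) stop_radguide("need >= 3 patients")

  dead <- colnames(dm)[apply(dm, 2, sd) == 0]
  if (length(dead)) {
    message("excluding ", length(dead),
            " zero-variance deep feature(s) from the screen")
    dm <- dm[, setdiff(colnames(dm), dead), drop = FALSE]
  }
  const_rad <- apply(rm_, 2, sd) == 0
  rmat <- matrix(NA_real_, ncol(dm), ncol(rm_),
                 dimnames = list(colnames(dm), colnames(rm_)))
  if (any(!const_rad)) {
    rmat[, !const_rad] <- cor(dm, rm_[, !const_rad, drop = FALSE])
  }
  m <- as.double(ncol(dm)) * ncol(rm_)
  pmat <- r_to_p(rmat, n)

  best_j <- apply(abs(rmat), 1, function(v) {
    if (all(is.na(v))) NA_integer_ else which.max(v)
  })
  ok <- !is.na(best_j)
  best_r <- rep(NA_real_, length(best_j))
  best_p <- rep(NA_real_, length(best_j))
  best_r[ok] <- rmat[cbind(which(ok), best_j[ok])]
  best_p[ok] <- pmat[cbind(which(ok), best_j[ok])]
  p_bonf <- pmin(1, m * best_p)
  retained <- ok & abs(best_r) > r_threshold & p_bonf < alpha

  per_dl <- tibble::tibble(
    dl_feature = colnames(dm),
    best_radiomics = unname(ifelse(ok, colnames(rm_)[best_j],
                                   NA_character_)),
    r = unname(best_r), p = unname(best_p), p_bonf = unname(p_bonf),
    retained = unname(retained))

  hit <- which(abs(rmat) > r_threshold, arr.ind = TRUE)
  pairs <- tibble::tibble(
    dl_feature = colnames(dm)[hit[, 1]],
    radiomics_feature = colnames(rm_)[hit[, 2]],
    r = rmat[hit],
    p = pmat[hit],
    p_bonf = pmin(1, m * pmat[hit]))
  pairs <- pairs[order(pairs$dl_feature, -abs(pairs$r),
                       pairs$radiomics_feature), ]

  keep <- keep_all_pairs_for %||% per_dl$dl_feature[retained]
  keep <- intersect(keep, colnames(dm))
  profiles <- tibble::tibble(
    dl_feature = rep(keep, each = ncol(rm_)),
    radiomics_feature = rep(colnames(rm_), times = length(keep)),
    r = as.numeric(t(rmat[keep, , drop = FALSE])),
    p = as.numeric(t(pmat[keep, , drop = FALSE])))

  structure(list(per_dl = per_dl, pairs = pairs, profiles = profiles,
                 m = m, n = n, r_threshold = r_threshold, alpha = alpha,
                 excluded = dead),
            class = "correlation_screen")
}

#' @exportS3Method base::print
print.correlation_screen <- function(x, ...) {
  cat("<correlation_screen>", sum(x$per_dl$retained), "of",
      nrow(x$per_dl), "deep features retained (|r| >", x$r_threshold,
      ", Bonferroni alpha", x$alpha, ", family size", format(x$m), ")\n")
  invisible(x)
}

#' Retained deep features of a screen
#'
#' @param screen A [correlation_screen()] result.
#' @return Character vector of retained deep-feature names.
#' @export
retained_features <- function(screen) {
  stopifnot(inherits(screen, "correlation_screen"))
  screen$per_dl$dl_feature[screen$per_dl$retained]
}

#' Retained-count sweep over correlation thresholds
#'
#' @param dl,rad As in [correlation_screen()].
#' @param thresholds Numeric thresholds to evaluate.
#' @param alpha Bonferroni level.
#' @return Tibble with `threshold` and `n_retained`; counts are weakly
#'   decreasing in the threshold.
#' @export
threshold_sweep <- function(dl, rad, thresholds = c(0.3, 0.4, 0.5),
                            alpha = 0.05) {
  counts <- vapply(thresholds, function(th) {
    sum(correlation_screen(dl, rad, th, alpha)$per_dl$retained)
  }, 1)
  tibble::tibble(threshold = thresholds, n_retained = as.integer(counts))
}

#' Write screen outputs
#'
#' The retained feature list goes to JSON, the sparse association map
#' (`dl_feature, radiomics_feature, r, p_corrected`) to CSV.
#'
#' @param screen A [correlation_screen()] result.
#' @param json_path,csv_path Output paths (`NULL` to skip either).
#' @export
write_screen <- function(screen, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(retained_features(screen), json_path)
  }
  if (!is.null(csv_path)) {
    out <- screen$pairs[c("dl_feature", "radiomics_feature", "r", "p_bonf")]
    names(out)[4] <- "p_corrected"
    write.csv(out, csv_path, row.names = FALSE)
  }
  invisible(screen)
}
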