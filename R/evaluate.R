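#' Kaplan-Meier estimate
#'
#' Product-limit estimator of the survival function; the curve steps only
#' at event times.
#'
#' @param time Follow-up times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @return Tibble with `time`, `n_risk`, `n_event`, `survival`.
#' @export
kaplan_meier <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  tibble::tibble(time = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, survival = fit$surv)
}

#' Two-group log-rank test
#'
#' @param groups Two-level factor (or vector) of group labels.
#' @param time,event Survival columns.
#' @return List with `statistic` (1-df chi-square) and `p`.
#' @export
logrank_test <- function(groups, time, event) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stop_radguide("need exactly two nonempty groups")
  fit <- survival::survdiff(survival::Surv(time, event) ~ groups)
  list(statistic = unname(fit$chisq),
       p = pchisq(fit$chisq, df = 1, lower.tail = FALSE))
}

#' Hazard ratio between risk groups
#'
#' Unpenalized Cox regression on the binary high-risk indicator. The
#' confidence interval and p-value are Wald-based. With no events in one
#' group the partial likelihood is monotone and the estimate is reported
#' as non-estimable (`NA`) with a warning.
#'
#' @param groups Factor with levels `low`, `high` (first level = reference).
#' @param time,event Survival columns.
#' @param conf_level Confidence level of the Wald interval.
#' @return List with `hr`, `ci` (length 2), `p`.
#' @export
hazard_ratio <- function(groups, time, event, conf_level = 0.95) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2) {
    stop_radguide("need exactly two nonempty groups")
  }
  ev <- tapply(event, groups, sum)
  if (any(ev == 0, na.rm = TRUE)) {
    warning("no events in one group; hazard ratio is non-estimable",
            call. = FALSE)
    return(list(hr = NA_real_, ci = c(NA_real_, NA_real_), p = NA_real_))
  }
  fit <- survival::coxph(survival::Surv(time, event) ~ groups)
  beta <- unname(coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  list(hr = exp(beta),
       ci = exp(beta + c(-1, 1) * zq * se),
       p = 2 * pnorm(-abs(beta / se)))
}

#' Harrell's concordance index
#'
#' Fraction of usable patient pairs in which the higher risk score belongs
#' to the patient who fails earlier. A pair is usable when the shorter
#' follow-up time ends in an event and the times differ; score ties count
#' 0.5.
#'
#' @param scores Risk scores (higher = riskier).
#' @param time,event Survival columns.
#' @return Concordance in `[0, 1]`.
#' @export
concordance_index <- function(scores, time, event) {
  n <- length(scores)
  stopifnot(length(time) == n, length(event) == n, n > 1)
  dt <- outer(time, time, `<`) # dt[i, j]: i fails strictly before j
  usable <- dt & (event == 1) # row i had the event at the shorter time
  if (!any(usable)) stop_radguide("no comparable pairs")
  ds <- outer(scores, scores, `-`)[usable] # score_i - score_j
  (sum(ds > 0) + 0.5 * sum(ds == 0)) / length(ds)
}

#' Intraclass correlation, two-way random effects, absolute agreement
#'
#' ICC(2,1) from the two-way ANOVA decomposition of an n-subjects by
#' two-raters table.
#'
#' @param values_a,values_b Paired measurements from the two raters.
#' @return ICC estimate; `NA` with a warning if all values are identical.
#' @export
icc_two_raters <- function(values_a, values_b) {
  stopifnot(length(values_a) == length(values_b))
  x <- cbind(values_a, values_b)
  n <- nrow(x)
  k <- 2
  if (n < 2) stop_radguide("need >= 2 subjects")
  grand <- mean(x)
  if (all(x == x[1])) {
    warning("zero variance everywhere; ICC is undefined", call. = FALSE)
    return(NA_real_)
  }
  ms_rows <- k * sum((rowMeans(x) - grand)^2) / (n - 1)
  ms_cols <- n * sum((colMeans(x) - grand)^2) / (k - 1)
  resid <- x - outer(rowMeans(x), rep(1, k)) -
    outer(rep(1, n), colMeans(x)) + grand
  ms_err <- sum(resid^2) / ((n - 1) * (k - 1))
  (ms_rows - ms_err) /
    (ms_rows + (k - 1) * ms_err + k * (ms_cols - ms_err) / n)
}

#' Cohen's kappa for two binary masks or label vectors
#'
#' @param mask_a,mask_b Congruent [roi_mask()]s, or equal-length label
#'   vectors.
#' @return Kappa in `[-1, 1]`; exact agreement with degenerate marginals
#'   returns 1.
#' @export
cohen_kappa <- function(mask_a, mask_b) {
  a <- if (inherits(mask_a, "roi_mask")) as.vector(mask_a$values) else mask_a
  b <- if (inherits(mask_b, "roi_mask")) as.vector(mask_b$values) else mask_b
  stopifnot(length(a) == length(b))
  po <- mean(a == b)
  lev <- union(unique(a), unique(b))
  pe <- sum(vapply(lev, function(l) mean(a == l) * mean(b == l), 1))
  if (pe == 1) return(if (po == 1) 1 else NA_real_)
  (po - pe) / (1 - pe)
}

#' Stratify a cohort by risk score and evaluate
#'
#' Applies the training-median cutoff, then computes per-group
#' Kaplan-Meier curves, the log-rank test, the hazard ratio with Wald CI,
#' and Harrell's C-index of the continuous score.
#'
#' @param scores Risk scores of the evaluated cohort.
#' @param cutoff Training-median cutoff ([median_stratify()]).
#' @param time,event Survival columns.
#' @return A `stratification_result`: `groups`, `km` (named list of
#'   per-group tibbles), `logrank`, `hazard_ratio`, `c_index`.
#' @export
stratify_evaluate <- function(scores, cutoff, time, event) {
  groups <- apply_cutoff(scores, cutoff)
  km <- lapply(split(seq_along(time), groups), function(i) {
    if (!length(i)) return(NULL)
    kaplan_meier(time[i], event[i])
  })
  two <- nlevels(droplevels(groups)) == 2
  structure(list(
    groups = groups,
    km = km,
    logrank = if (two) logrank_test(groups, time, event),
    hazard_ratio = if (two) hazard_ratio(groups, time, event),
    c_index = concordance_index(scores, time, event)),
    class = "stratification_result")
}

#' @exportS3Method base::print
print.stratification_result <- function(x, ...) {
  cat("<stratification_result>", sum(x$groups == "high"), "high /",
      sum(x$groups == "low"), "low risk\n")
  if (!is.null(x$logrank)) {
    cat("  log-rank chi-square", signif(x$logrank$statistic, 4),
        "p", signif(x$logrank$p, 4), "\n")
  }
  if (!is.null(x$hazard_ratio) && is.finite(x$hazard_ratio$hr)) {
    cat("  HR", signif(x$hazard_ratio$hr, 5), "(95% CI",
        signif(x$hazard_ratio$ci[1], 5), "-",
        signif(x$hazard_ratio$ci[2], 5), ")\n")
  }
  cat("  C-index", signif(x$c_index, 4), "\n")
  invisible(x)
}

#' Kaplan-Meier curves of a stratification as a plain table
#'
#' @param result A [stratify_evaluate()] result.
#' @return Tibble with `group`, `time`, `survival`, `n_risk` suitable for
#'   CSV export and plotting.
#' @export
km_table <- function(result) {
  stopifnot(inherits(result, "stratification_result"))
  rows <- lapply(names(result$km), function(g) {
    k <- result$km[[g]]
    if (is.null(k)) return(NULL)
    tibble::tibble(group = g, time = k$time, survival = k$survival,
                   n_risk = k$n_risk)
  })
  do.call(rbind, rows)
}
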