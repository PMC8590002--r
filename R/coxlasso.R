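# Breslow partial log-likelihood of linear predictors `lp`
breslow_pll <- function(lp, time, event) {
  if (!any(event == 1)) return(0)
  ord <- order(time)
  lp <- lp[ord]; time <- time[ord]; event <- event[ord]
  # risk set at t = all with time >= t; reverse cumulative sum of exp(lp)
  rev_cum <- rev(cumsum(rev(exp(lp))))
  ll <- 0
  for (t in unique(time[event == 1])) {
    at <- which(time == t & event == 1)
    d <- length(at)
    ll <- ll + sum(lp[at]) - d * log(rev_cum[min(which(time == t))])
  }
  ll
}

# event-stratified fold assignment; a fold with no events is redrawn once
make_folds <- function(event, k, seed) {
  draw <- function(s) {
    with_seed(s, {
      f <- integer(length(event))
      for (g in unique(event)) {
        i <- which(event == g)
        f[i] <- sample(rep_len(seq_len(k), length(i)))
      }
      f
    })
  }
  f <- draw(seed)
  if (any(tapply(event, f, sum) == 0)) {
    sub <- derive_seed(seed, "fold-redraw")
    message("a fold had no events; redrawing folds with sub-seed ", sub)
    f <- draw(sub)
    if (any(tapply(event, f, sum) == 0)) {
      stop_radguide("cannot build ", k, " folds that all contain events")
    }
  }
  f
}

# held-out partial-likelihood CV over a penalty grid; returns the grid
# value maximizing the summed held-out Breslow partial log-likelihood
choose_penalty <- function(x, time, event, grid, k, seed) {
  folds <- make_folds(event, k, seed)
  score <- numeric(length(grid))
  for (f in seq_len(k)) {
    tr <- folds != f
    # cap the active set near the event count: with an L1 path there is
    # no useful held-out likelihood beyond that, and the most-penalized
    # converged solution stands in for the clamped tail
    fit <- suppressWarnings(
      glmnet::glmnet(x[tr, , drop = FALSE],
                     survival::Surv(time[tr], event[tr]),
                     family = "cox", lambda = grid, standardize = FALSE,
                     pmax = max(10L, 2L * sum(event[tr])),
                     thresh = 1e-5))
    # if the solver stopped early (p >> n at tiny penalties), reuse the
    # most-penalized converged solution for the remaining grid values
    s_use <- pmax(grid, min(fit$lambda))
    lp <- predict(fit, newx = x[!tr, , drop = FALSE], s = s_use)
    for (j in seq_along(grid)) {
      score[j] <- score[j] + breslow_pll(lp[, j], time[!tr], event[!tr])
    }
  }
  list(penalty = grid[which.max(score)], score = score)
}

default_penalty_grid <- function(x, time, event, n = 50, decades = 4) {
  lmax <- suppressWarnings(
    glmnet::glmnet(x, survival::Surv(time, event), family = "cox",
                   nlambda = 3, standardize = FALSE))$lambda[1]
  10^seq(log10(lmax), log10(lmax) - decades, length.out = n)
}

#' Fit a sparse Cox risk model (Cox-LASSO with nested cross-validation)
#'
#' L1-penalized Cox proportional-hazards regression (Breslow ties,
#' via glmnet) on z-scored features. The penalty is chosen by 5-fold
#' cross-validated grid search maximizing the held-out Breslow partial
#' log-likelihood on a grid of 50 log-spaced values spanning 4 decades
#' below the data-derived maximal penalty; an outer 5-fold loop repeats the
#' search on outer-training subsets to report penalty-choice stability.
#' Folds are event-stratified and seeded. The final model is refit on the
#' full training set at the chosen penalty.
#'
#' The fitted model carries the risk-score definition
#' `score_i = h0 * exp(sum_j x_ij beta_j)` with `h0 = 1`, and the
#' training-median score cutoff used for risk-group stratification.
#'
#' @param X Feature tibble (`patient_id` + z-scored feature columns).
#' @param cohort Tibble with `patient_id`, `time_months`, `event`.
#' @param penalty_grid Optional penalty grid (decreasing).
#' @param outer_folds,inner_folds Fold counts of the nested search.
#' @param seed Integer seed for fold assignment.
#' @return A `risk_model`: selected features, nonzero coefficients,
#'   chosen penalty, per-outer-fold penalties, `h0`, and the training
#'   median cutoff.
#' @export
cox_lasso_fit <- function(X, cohort, penalty_grid = NULL,
                          outer_folds = 5, inner_folds = 5, seed = 1L) {
  stopifnot(identical(X$patient_id, cohort$patient_id))
  x <- feature_matrix(X)
  time <- cohort$time_months
  event <- cohort$event
  if (sum(event) < 2) stop_radguide("need >= 2 events to fit a Cox model")
  if (ncol(x) == 1) {
    # glmnet requires >= 2 columns; a zero column is inert under the
    # L1 penalty and is stripped from the result
    x <- cbind(x, `..pad..` = 0)
  }

  grid <- penalty_grid %||% default_penalty_grid(x, time, event)
  grid <- sort(grid, decreasing = TRUE)

  outer <- make_folds(event, outer_folds, derive_seed(seed, "outer"))
  outer_lambda <- vapply(seq_len(outer_folds), function(f) {
    tr <- outer != f
    if (sum(event[tr]) < inner_folds) return(NA_real_)
    choose_penalty(x[tr, , drop = FALSE], time[tr], event[tr], grid,
                   inner_folds, derive_seed(seed, paste0("inner", f)))$penalty
  }, 1)

  sel <- choose_penalty(x, time, event, grid, inner_folds,
                        derive_seed(seed, "inner-final"))
  fit <- suppressWarnings(
    glmnet::glmnet(x, survival::Surv(time, event), family = "cox",
                   lambda = grid, standardize = FALSE,
                   pmax = max(10L, 2L * sum(event))))
  beta <- as.numeric(coef(fit, s = max(sel$penalty, min(fit$lambda)),
                          exact = FALSE))
  names(beta) <- rownames(coef(fit))
  nz <- beta[beta != 0 & names(beta) != "..pad.."]

  lp <- as.numeric(x[, names(nz), drop = FALSE] %*% nz)
  scores <- exp(lp) # h0 = 1
  structure(list(features = names(nz),
                 coefficients = nz,
                 penalty = sel$penalty,
                 outer_penalties = outer_lambda,
                 h0 = 1,
                 cutoff = median(scores),
                 n_train = nrow(x),
                 n_events = sum(event),
                 seed = as.integer(seed)),
            class = "risk_model")
}

#' @exportS3Method base::print
print.risk_model <- function(x, ...) {
  cat("<risk_model>", length(x$features), "selected features, penalty",
      signif(x$penalty, 4), ", training median cutoff",
      signif(x$cutoff, 4), "\n")
  invisible(x)
}

#' Relative risk score of a fitted model
#'
#' `score_i = h0 * exp(sum_j x_ij beta_j)` over the model's selected
#' features; strictly positive and monotone in the linear predictor. The
#' feature table must be normalized with the training z-score parameters.
#'
#' @param model A `risk_model` from [cox_lasso_fit()].
#' @param X Feature tibble containing the selected feature columns.
#' @return Numeric score vector named by patient id.
#' @export
risk_score <- function(model, X) {
  stopifnot(inherits(model, "risk_model"))
  missing <- setdiff(model$features, names(X))
  if (length(missing)) {
    stop_radguide("feature table lacks selected feature(s): ",
                  paste(head(missing, 3), collapse = ", "))
  }
  if (!length(model$features)) {
    return(setNames(rep(model$h0, nrow(X)), X$patient_id))
  }
  lp <- as.matrix(X[model$features]) %*% model$coefficients
  setNames(model$h0 * exp(as.numeric(lp)), X$patient_id)
}

#' Median risk stratification
#'
#' The cutoff is the median training score; scores strictly above it are
#' high risk, and a score exactly at the cutoff is assigned to the
#' low-risk group.
#'
#' @param train_scores Numeric training scores.
#' @param scores Scores to classify.
#' @param cutoff A cutoff from `median_stratify()`.
#' @return `median_stratify()`: the cutoff; `apply_cutoff()`: factor with
#'   levels `low`, `high`.
#' @export
median_stratify <- function(train_scores) {
  if (!length(train_scores)) stop_radguide("no training scores")
  median(train_scores)
}

#' @rdname median_stratify
#' @export
apply_cutoff <- function(scores, cutoff) {
  factor(ifelse(scores > cutoff, "high", "low"), levels = c("low", "high"))
}

#' Serialize a risk model to JSON
#'
#' Field order and formatting are fixed, so identical models serialize to
#' identical bytes.
#'
#' @param model A `risk_model`.
#' @param path Optional output path.
#' @param normalization Optional [fit_zscore()] params stored alongside.
#' @return The JSON string, invisibly if written to `path`.
#' @export
model_to_json <- function(model, path = NULL, normalization = NULL) {
  payload <- list(
    features = as.list(model$features),
    coefficients = as.list(unname(model$coefficients)),
    penalty = model$penalty,
    h0 = model$h0,
    cutoff = model$cutoff,
    n_train = model$n_train,
    n_events = model$n_events,
    normalization = if (!is.null(normalization)) {
      list(features = as.list(names(normalization$mean)),
           mean = as.list(unname(normalization$mean)),
           sd = as.list(unname(normalization$sd)),
           dropped = as.list(normalization$dropped))
    })
  json <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                           null = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
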