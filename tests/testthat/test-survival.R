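sim_cox_data <- function(n, beta, seed, censor = 2) {
  set.seed(seed)
  x <- matrix(rnorm(n * length(beta)), n)
  colnames(x) <- paste0("f", seq_along(beta))
  lp <- as.vector(x %*% beta)
  t_ev <- rexp(n, exp(lp))
  t_c <- runif(n, 0, censor * 2)
  list(x = x, time = pmin(t_ev, t_c), event = as.integer(t_ev <= t_c))
}

as_tabs <- function(d) {
  ids <- sprintf("P%03d", seq_along(d$time))
  list(X = tibble::add_column(tibble::as_tibble(as.data.frame(d$x)),
                              patient_id = ids, .before = 1),
       cohort = tibble::tibble(patient_id = ids, time_months = d$time,
                               event = d$event))
}

test_that("an overwhelming penalty shrinks every coefficient to zero", {
  d <- sim_cox_data(60, c(1, 0.5), seed = 1)
  t <- as_tabs(d)
  fit <- cox_lasso_fit(t$X, t$cohort, penalty_grid = c(1e3, 9e2), seed = 2)
  expect_length(fit$features, 0)
  expect_true(all(risk_score(fit, t$X) == 1))
})

test_that("near-zero penalty reproduces the unpenalized Newton solution", {
  d <- sim_cox_data(150, 0.8, seed = 3, censor = 5)
  t <- as_tabs(d)
  fit <- cox_lasso_fit(t$X, t$cohort, penalty_grid = c(1e-8, 1e-9),
                       seed = 4)
  beta_newton <- oracle_newton_cox(d$x, d$time, d$event)
  expect_equal(unname(fit$coefficients["f1"]), unname(beta_newton[1]),
               tolerance = 1e-4)
})

test_that("the planted coefficient's support and sign are recovered", {
  hits <- vapply(1:20, function(s) {
    d <- sim_cox_data(500, c(1, 0, 0, 0, 0), seed = 100 + s, censor = 3)
    t <- as_tabs(d)
    fit <- cox_lasso_fit(t$X, t$cohort, seed = s)
    ("f1" %in% fit$features) && fit$coefficients["f1"] > 0
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("risk scores follow the exponential linear-predictor form", {
  model <- structure(list(features = "f", coefficients = c(f = 0.5),
                          h0 = 1, cutoff = 1), class = "risk_model")
  X <- tibble::tibble(patient_id = c("a", "b"), f = c(2, 0))
  s <- risk_score(model, X)
  expect_equal(unname(s), c(exp(1), 1))
  expect_error(risk_score(model, tibble::tibble(patient_id = "a", g = 1)),
               "lacks selected feature")

  # hand-computed 5-feature example
  beta <- c(a = 0.2, b = -0.4, c = 0.1, d = 0, e = 1.5)
  m5 <- structure(list(features = names(beta), coefficients = beta, h0 = 1,
                       cutoff = 1), class = "risk_model")
  X5 <- tibble::tibble(patient_id = "p", a = 1, b = 2, c = -1, d = 9,
                       e = 0.1)
  expect_equal(unname(risk_score(m5, X5)),
               exp(0.2 * 1 - 0.4 * 2 + 0.1 * -1 + 0 + 1.5 * 0.1))
})

test_that("median stratification sends exact-median scores to low risk", {
  cutoff <- median_stratify(c(1, 2, 3, 4))
  expect_equal(cutoff, 2.5)
  expect_equal(as.character(apply_cutoff(c(1, 2, 3, 4), cutoff)),
               c("low", "low", "high", "high"))
  # a score exactly at the cutoff goes low
  expect_equal(as.character(apply_cutoff(c(2.5, 2.6), 2.5)),
               c("low", "high"))
  # all-equal scores: everyone low
  expect_true(all(apply_cutoff(rep(3, 5), median_stratify(rep(3, 5))) ==
                    "low"))
})

test_that("Kaplan-Meier matches the hand product-limit computation", {
  km <- kaplan_meier(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$survival[km$time == 1], 2 / 3)
  expect_equal(km$survival[km$time == 3], 0)

  none <- kaplan_meier(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(none$survival == 1))

  two <- kaplan_meier(c(1, 5), c(1, 1))
  expect_equal(two$survival, c(0.5, 0))

  set.seed(8)
  t <- rexp(40); e <- rbinom(40, 1, 0.6)
  km2 <- kaplan_meier(t, e)
  hand <- oracle_km(t, e)
  expect_equal(km2$survival[km2$n_event > 0], hand$survival)

  # without censoring KM equals the empirical survival function
  km3 <- kaplan_meier(1:10, rep(1, 10))
  expect_equal(km3$survival, 1 - (1:10) / 10)
})

test_that("log-rank matches the O/E/V accumulation oracle", {
  # identical groups: statistic 0, p = 1
  t <- c(1, 2, 3, 1, 2, 3); e <- c(1, 1, 0, 1, 1, 0)
  g <- rep(c("a", "b"), each = 3)
  lr <- logrank_test(g, t, e)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)

  # single event: one risk-set table
  t1 <- c(2, 3, 4, 5); e1 <- c(1, 0, 0, 0); g1 <- c("a", "a", "b", "b")
  expect_equal(logrank_test(g1, t1, e1)$statistic,
               oracle_logrank(g1, t1, e1)$statistic, tolerance = 1e-12)

  for (seed in 1:6) {
    set.seed(seed)
    n <- 30
    t2 <- rexp(n); e2 <- rbinom(n, 1, 0.7)
    g2 <- sample(rep(c("a", "b"), n / 2))
    got <- logrank_test(g2, t2, e2)
    want <- oracle_logrank(g2, t2, e2)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-9)
    expect_equal(got$p, want$p, tolerance = 1e-9)
    # label swap invariance
    swapped <- logrank_test(ifelse(g2 == "a", "b", "a"), t2, e2)
    expect_equal(swapped$statistic, got$statistic, tolerance = 1e-9)
    expect_true(got$p >= 0 && got$p <= 1)
  }
})

test_that("hazard ratios bracket their CI and recover a true HR of 3", {
  t <- c(1, 2, 3, 1.5, 2.5, 3.5); e <- c(1, 1, 0, 1, 1, 0)
  g <- factor(rep(c("low", "high"), each = 3), levels = c("low", "high"))
  hr <- hazard_ratio(g, t, e)
  expect_true(hr$ci[1] < hr$hr && hr$hr < hr$ci[2])

  # two identical groups: HR near 1, CI contains 1
  gi <- factor(rep(c("low", "high"), 3), levels = c("low", "high"))
  ti <- rep(c(1, 2, 3), each = 2); ei <- rep(c(1, 1, 0), each = 2)
  hri <- hazard_ratio(gi, ti, ei)
  expect_equal(hri$hr, 1, tolerance = 1e-6)
  expect_true(hri$ci[1] <= 1 && 1 <= hri$ci[2])

  # no events in one group: non-estimable
  expect_warning(
    ne <- hazard_ratio(g, t, c(1, 1, 0, 0, 0, 0)), "non-estimable")
  expect_true(is.na(ne$hr))

  ok <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 400
    grp <- factor(rep(c("low", "high"), each = n / 2),
                  levels = c("low", "high"))
    rate <- ifelse(grp == "high", 3, 1)
    tt <- rexp(n, rate)
    cc <- runif(n, 0, 3)
    est <- hazard_ratio(grp, pmin(tt, cc), as.integer(tt <= cc))$hr
    abs(est - 3) / 3 < 0.2
  }, logical(1))
  expect_gte(sum(ok), 18)
})

test_that("the concordance index matches brute force and survival::concordance", {
  # perfect ordering, no censoring
  t <- c(1, 2, 3, 4); e <- rep(1, 4)
  expect_equal(concordance_index(c(4, 3, 2, 1), t, e), 1)
  expect_equal(concordance_index(c(1, 2, 3, 4), t, e), 0)

  for (seed in 1:6) {
    set.seed(seed)
    n <- 25
    s <- rnorm(n); tt <- rexp(n); ee <- rbinom(n, 1, 0.6)
    if (sum(ee) == 0) ee[1] <- 1L
    got <- concordance_index(s, tt, ee)
    expect_equal(got, oracle_cindex(s, tt, ee), tolerance = 1e-12)
    ref <- survival::concordance(survival::Surv(tt, ee) ~ s, reverse = TRUE)
    expect_equal(got, unname(ref$concordance), tolerance = 1e-12)
  }
  expect_error(concordance_index(c(1, 2), c(3, 4), c(0, 0)),
               "no comparable pairs")

  # the positive constant h0 never changes stratification or concordance
  set.seed(3)
  s <- runif(10); tt <- rexp(10); ee <- rbinom(10, 1, 0.8)
  expect_equal(concordance_index(s, tt, ee),
               concordance_index(100 * s, tt, ee))
  expect_equal(apply_cutoff(s, median_stratify(s)),
               apply_cutoff(7 * s, median_stratify(7 * s)))
})

test_that("ICC(2,1) and Cohen's kappa match their defining decompositions", {
  a <- c(9, 6, 8, 7, 10, 6)
  expect_equal(icc_two_raters(a, a), 1)

  b <- c(2, 1, 4, 1, 5, 2)
  got <- icc_two_raters(a, b)
  # ANOVA mean squares from aov as the independent decomposition
  long <- data.frame(y = c(a, b),
                     subj = factor(rep(1:6, 2)),
                     rater = factor(rep(1:2, each = 6)))
  ms <- summary(stats::aov(y ~ subj + rater, data = long))[[1]][["Mean Sq"]]
  icc_aov <- (ms[1] - ms[3]) /
    (ms[1] + ms[3] + 2 * (ms[2] - ms[3]) / 6)
  expect_equal(got, icc_aov, tolerance = 1e-12)
  expect_warning(icc_two_raters(rep(1, 5), rep(1, 5)), "undefined")

  m1 <- array(c(TRUE, TRUE, FALSE, FALSE), c(2, 2, 1))
  expect_equal(cohen_kappa(roi_mask(m1), roi_mask(m1)), 1)
  m2 <- array(c(FALSE, FALSE, TRUE, TRUE), c(2, 2, 1))
  expect_equal(cohen_kappa(roi_mask(m1), roi_mask(m2)), -1)
})

test_that("stratify_evaluate assembles a coherent result", {
  set.seed(12)
  n <- 60
  s <- exp(rnorm(n))
  tt <- rexp(n, 0.05 * s)
  ee <- as.integer(tt < 40); tt <- pmin(tt, 40)
  cutoff <- median_stratify(s)
  res <- stratify_evaluate(s, cutoff, tt, ee)
  expect_s3_class(res, "stratification_result")
  expect_equal(length(res$groups), n)
  expect_equal(sum(res$groups == "low") + sum(res$groups == "high"), n)
  for (g in c("low", "high")) {
    surv <- res$km[[g]]$survival
    expect_true(all(diff(surv) <= 1e-12))
    expect_true(all(surv <= 1))
  }
  expect_true(res$logrank$p >= 0 && res$logrank$p <= 1)
  tab <- km_table(res)
  expect_true(all(c("group", "time", "survival", "n_risk") %in% names(tab)))
})
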