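#' Random train/test cohort split
#'
#' Event-stratified random split (plain random available via
#' `stratify_event = FALSE`). The training size is `round(ratio * n)`,
#' allocated across event strata by largest remainder so the training
#' event fraction stays within one patient of the cohort's. A draw leaving
#' zero events in either side is redrawn once with a logged sub-seed.
#'
#' @param cohort Tibble with `patient_id` and `event`.
#' @param ratio Training fraction in (0, 1).
#' @param seed Integer seed.
#' @param stratify_event Stratify the split by event status.
#' @return Character vector of `"train"` / `"test"` labels.
#' @export
split_cohort <- function(cohort, ratio = 0.7, seed = 1L,
                         stratify_event = TRUE) {
  n <- nrow(cohort)
  if (n < 10) stop_radguide("need >= 10 patients to split")
  if (ratio <= 0 || ratio >= 1) stop_radguide("ratio must be in (0, 1)")
  target <- round(ratio * n)

  draw <- function(s) {
    with_seed(s, {
      lab <- rep("test", n)
      if (stratify_event) {
        strata <- split(seq_len(n), cohort$event)
        sizes <- vapply(strata, length, 1L)
        k <- floor(ratio * sizes)
        rem <- ratio * sizes - k
        extra <- target - sum(k)
        if (extra > 0) {
          k[order(rem, decreasing = TRUE)[seq_len(extra)]] <-
            k[order(rem, decreasing = TRUE)[seq_len(extra)]] + 1L
        }
        for (g in seq_along(strata)) {
          lab[sample(strata[[g]], k[g])] <- "train"
        }
      } else {
        lab[sample(n, target)] <- "train"
      }
      lab
    })
  }
  lab <- draw(seed)
  ev <- tapply(cohort$event, lab, sum)
  if (any(ev == 0, na.rm = TRUE) || length(ev) < 2) {
    sub <- derive_seed(seed, "split-redraw")
    message("split left a side without events; redrawing with sub-seed ",
            sub)
    lab <- draw(sub)
    ev <- tapply(cohort$event, lab, sum)
    if (any(ev == 0, na.rm = TRUE) || length(ev) < 2) {
      stop_radguide("cannot split: a side always lacks events")
    }
  }
  lab
}

#' Pipeline configuration
#'
#' Collects every stage's tunables: the split ratio and seed, radiomics
#' extraction parameters, the frozen-CNN extractor spec, the screen
#' thresholds, and the Cox-LASSO fold structure.
#'
#' @param split_ratio Training fraction.
#' @param seed Master seed; stage seeds are derived from it.
#' @param radiomics A [radiomics_config()].
#' @param extractor An [extractor_spec()] (deep-feature models only).
#' @param patch_size In-plane patch size extracted around the tumor.
#' @param r_threshold,alpha Correlation-screen parameters.
#' @param outer_folds,inner_folds Nested CV structure of the Cox-LASSO.
#' @param out_dir Optional output directory for reports.
#' @return A named list.
#' @export
pipeline_config <- function(split_ratio = 0.7, seed = 1L,
                            radiomics = radiomics_config(),
                            extractor = extractor_spec("random_cnn_test"),
                            patch_size = 128,
                            r_threshold = 0.4, alpha = 0.05,
                            outer_folds = 5, inner_folds = 5,
                            out_dir = NULL) {
  list(split_ratio = split_ratio, seed = as.integer(seed),
       radiomics = radiomics, extractor = extractor,
       patch_size = patch_size, r_threshold = r_threshold, alpha = alpha,
       outer_folds = outer_folds, inner_folds = inner_folds,
       out_dir = out_dir)
}

ensure_split <- function(cohort, config) {
  if (all(is.na(cohort$split))) {
    cohort$split <- split_cohort(cohort, config$split_ratio,
                                 derive_seed(config$seed, "split"))
  }
  if (!all(cohort$split %in% c("train", "test", "validation"))) {
    stop_radguide("split labels must be train/test/validation")
  }
  cohort
}

fit_and_evaluate <- function(features, cohort, config, stage) {
  tr <- cohort$split == "train"
  zfit <- fit_zscore(features[tr, ])
  ztab <- apply_zscore(features, zfit)

  model <- tryCatch(
    cox_lasso_fit(ztab[tr, ], cohort[tr, ],
                  outer_folds = config$outer_folds,
                  inner_folds = config$inner_folds,
                  seed = derive_seed(config$seed, "coxlasso")),
    error = function(e) stop_radguide("[", stage, "] ", conditionMessage(e)))

  scores <- risk_score(model, ztab)
  evaluations <- lapply(split(seq_len(nrow(cohort)), cohort$split),
                        function(i) {
    stratify_evaluate(scores[i], model$cutoff,
                      cohort$time_months[i], cohort$event[i])
  })
  list(model = model, normalization = zfit, scores = scores,
       evaluations = evaluations)
}

#' Run the baseline radiomics risk-score pipeline
#'
#' Extract the 78 radiomics features, z-score on the training cohort, fit
#' the Cox-LASSO risk model on the training split, stratify every split at
#' the training-median score, and evaluate with Kaplan-Meier/log-rank/HR/
#' C-index.
#'
#' @param volumes,masks Lists of congruent volume/mask pairs.
#' @param cohort Tibble with `patient_id`, `time_months`, `event` and
#'   optional `split` (assigned by [split_cohort()] when absent).
#' @param config A [pipeline_config()].
#' @param features Optional precomputed radiomics table (skips extraction).
#' @return List with `model`, `normalization`, `scores`, `evaluations`
#'   (one [stratify_evaluate()] result per split), `cohort`, and
#'   `features`.
#' @export
run_rrs <- function(volumes, masks, cohort, config = pipeline_config(),
                    features = NULL) {
  cohort <- ensure_split(cohort, config)
  features <- features %||%
    extract_features_table(volumes, masks, cohort$patient_id,
                           config$radiomics)
  out <- fit_and_evaluate(features, cohort, config, "rrs")
  out$cohort <- cohort
  out$features <- features
  if (!is.null(config$out_dir)) write_run(out, config, "rrs")
  out
}

#' Run the radiomics-guided deep risk-score pipeline
#'
#' Extracts 2.5D patches and frozen-CNN features, z-scores both feature
#' families on the training cohort, retains the deep features correlated
#' with radiomics on the training split (Bonferroni-controlled screen),
#' fits the Cox-LASSO risk model on the retained features, stratifies at
#' the training-median score, and attaches the radiomics-based
#' interpretation of the selected deep features.
#'
#' @inheritParams run_rrs
#' @param radiomics_features Optional precomputed radiomics table.
#' @param dl_features Optional precomputed deep-feature table.
#' @return As [run_rrs()], plus `screen`, `interpretation`, and
#'   `dl_features`.
#' @export
run_drs <- function(volumes, masks, cohort, config = pipeline_config(),
                    radiomics_features = NULL, dl_features = NULL) {
  cohort <- ensure_split(cohort, config)
  radiomics_features <- radiomics_features %||%
    extract_features_table(volumes, masks, cohort$patient_id,
                           config$radiomics)

  if (is.null(dl_features)) {
    ext <- build_extractor(config$extractor)
    patches <- lapply(seq_along(volumes), function(i) {
      p <- preprocess_patch(extract_patch(volumes[[i]], masks[[i]],
                                          size = config$patch_size))
      if (ext$input_shape[1] > config$patch_size) {
        p <- resize_patch(p, ext$input_shape[1])
      }
      p
    })
    rows <- vapply(patches, extract_dl_features, spec = ext,
                   numeric(prod(cnn_shapes(ext$arch, ext$input_shape)[[
                     length(ext$arch)]])))
    dl_features <- tibble::add_column(tibble::as_tibble(t(rows)),
                                      patient_id = cohort$patient_id,
                                      .before = 1)
  }

  tr <- cohort$split == "train"
  zrad <- fit_zscore(radiomics_features[tr, ])
  zdl <- fit_zscore(dl_features[tr, ])
  screen <- correlation_screen(
    apply_zscore(dl_features[tr, ], zdl),
    apply_zscore(radiomics_features[tr, ], zrad),
    r_threshold = config$r_threshold, alpha = config$alpha)
  kept <- retained_features(screen)
  if (!length(kept)) {
    stop_radguide("[screen] no deep feature passed the correlation screen")
  }

  out <- fit_and_evaluate(dl_features[c("patient_id", kept)], cohort,
                          config, "drs")
  out$screen <- screen
  out$interpretation <- if (length(out$model$features)) {
    associate(out$model$features, screen, config$r_threshold)
  }
  out$cohort <- cohort
  out$dl_features_retained <- kept
  if (!is.null(config$out_dir)) write_run(out, config, "drs")
  out
}

# serialize a run: model JSON, evaluation JSON, KM curves CSV, manifest
write_run <- function(run, config, label) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  pfx <- function(f) file.path(config$out_dir, paste0(label, "_", f))
  model_to_json(run$model, pfx("model.json"), run$normalization)

  ev <- lapply(run$evaluations, function(e) {
    list(n = length(e$groups),
         n_high = sum(e$groups == "high"),
         logrank_statistic = e$logrank$statistic,
         logrank_p = e$logrank$p,
         hr = e$hazard_ratio$hr,
         hr_ci = e$hazard_ratio$ci,
         hr_p = e$hazard_ratio$p,
         c_index = e$c_index)
  })
  jsonlite::write_json(ev, pfx("evaluation.json"), digits = NA,
                       auto_unbox = TRUE, null = "null")
  for (s in names(run$evaluations)) {
    write.csv(km_table(run$evaluations[[s]]),
              pfx(paste0("km_", s, ".csv")), row.names = FALSE)
  }

  cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "out_dir")],
                               auto_unbox = TRUE, force = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  manifest <- list(label = label,
                   config = jsonlite::fromJSON(cfg_json,
                                               simplifyVector = FALSE),
                   config_md5 = unname(tools::md5sum(tmp)),
                   seed = config$seed,
                   n_selected = length(run$model$features),
                   package_version =
                     as.character(utils::packageVersion("radguide")))
  unlink(tmp)
  jsonlite::write_json(manifest, pfx("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(run)
}
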