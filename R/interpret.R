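#' Explain selected deep features through correlated radiomics features
#'
#' For each selected deep feature, lists the radiomics features whose
#' stored training-cohort correlation exceeds the threshold in absolute
#' value (sorted by `|r|` descending, ties by feature name), together with
#' the count of radiomics features significantly correlated at uncorrected
#' `p < 0.05` and the top correlate. Everything is read from the screen's
#' stored association profiles; no correlation is recomputed.
#'
#' @param selected_dl Character vector of deep-feature names (typically the
#'   Cox-LASSO-selected features); must have stored profiles in `screen`.
#' @param screen A [correlation_screen()] result.
#' @param threshold Absolute-correlation threshold for listing.
#' @return An `association_report`: tibble `associations` (`dl_feature`,
#'   `radiomics_feature`, `category`, `r`), tibble `summary`
#'   (`dl_feature`, `n_significant`, `top_radiomics`, `top_r`), and the
#'   threshold.
#' @export
associate <- function(selected_dl, screen, threshold = 0.4) {
  stopifnot(inherits(screen, "correlation_screen"))
  have <- unique(screen$profiles$dl_feature)
  missing <- setdiff(selected_dl, have)
  if (length(missing)) {
    stop_radguide("no stored screen profile for deep feature(s): ",
                  paste(missing, collapse = ", "))
  }
  roster <- radiomics_feature_info()
  cat_of <- setNames(roster$category, roster$name)

  assoc <- list()
  summ <- list()
  for (f in selected_dl) {
    prof <- screen$profiles[screen$profiles$dl_feature == f, ]
    hit <- prof[!is.na(prof$r) & abs(prof$r) > threshold, ]
    hit <- hit[order(-abs(hit$r), hit$radiomics_feature), ]
    assoc[[f]] <- tibble::tibble(
      dl_feature = f,
      radiomics_feature = hit$radiomics_feature,
      category = unname(cat_of[hit$radiomics_feature]),
      r = hit$r)
    top <- which.max(abs(prof$r))
    summ[[f]] <- tibble::tibble(
      dl_feature = f,
      n_significant = sum(prof$p < 0.05, na.rm = TRUE),
      top_radiomics = prof$radiomics_feature[top],
      top_r = prof$r[top])
  }
  structure(list(associations = do.call(rbind, assoc),
                 summary = do.call(rbind, summ),
                 threshold = threshold),
            class = "association_report")
}

#' @exportS3Method base::print
print.association_report <- function(x, ...) {
  cat("<association_report>", nrow(x$summary), "deep feature(s), |r| >",
      x$threshold, "\n")
  print(x$summary)
  invisible(x)
}

#' Category composition of each deep feature's radiomics associates
#'
#' Fraction of a deep feature's above-threshold radiomics associates
#' falling in each of the five categories (shape, first-order, GLCM,
#' GLSZM, margin). Rows with no associations are all zero and flagged.
#'
#' @param report An [associate()] result.
#' @param roster Feature roster with `name` and `category` columns.
#' @return Tibble: `dl_feature`, one column per category, `n_associations`.
#' @export
category_proportions <- function(report,
                                 roster = radiomics_feature_info()) {
  stopifnot(inherits(report, "association_report"))
  cats <- c("shape", "first-order", "GLCM", "GLSZM", "margin")
  unknown <- setdiff(report$associations$radiomics_feature, roster$name)
  if (length(unknown)) {
    stop_radguide("features missing from the roster: ",
                  paste(head(unknown, 3), collapse = ", "))
  }
  rows <- lapply(unique(report$summary$dl_feature), function(f) {
    a <- report$associations[report$associations$dl_feature == f, ]
    counts <- vapply(cats, function(cc) sum(a$category == cc), 1)
    n <- sum(counts)
    prop <- if (n > 0) counts / n else counts * 0
    out <- tibble::as_tibble(as.list(prop))
    out$dl_feature <- f
    out$n_associations <- as.integer(n)
    out[, c("dl_feature", cats, "n_associations")]
  })
  do.call(rbind, rows)
}

#' Write an interpretation report
#'
#' @param report An [associate()] result.
#' @param csv_path Association table CSV path.
#' @param proportions_csv_path Category-proportion CSV path (optional).
#' @export
write_association_report <- function(report, csv_path,
                                     proportions_csv_path = NULL) {
  write.csv(report$associations, csv_path, row.names = FALSE)
  if (!is.null(proportions_csv_path)) {
    write.csv(category_proportions(report), proportions_csv_path,
              row.names = FALSE)
  }
  invisible(report)
}
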