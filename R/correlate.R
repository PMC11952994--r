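# Per-subject Pearson screening of biomarker traces against the FEV1 trace.

#' Absolute Pearson correlation with its p-value
#'
#' Product-moment correlation between two equal-length traces, returned as
#' its absolute value (the direction of the association is deliberately
#' ignored: a biomarker that falls when FEV1 falls and one that rises are
#' equally informative), with the two-sided p-value from the t-transform on
#' n - 2 degrees of freedom.
#'
#' @param x,y numeric traces of equal length n >= 3, both with nonzero
#'   variance.
#' @return A list `(abs_rho, p_value, n)`.
#' @export
pearson_abs <- function(x, y) {
  if (length(x) != length(y)) stop_validation("traces differ in length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop_validation("need at least 3 paired steps")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop_undefined_feature("constant trace: correlation undefined")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(abs_rho = abs(unname(ct$estimate)), p_value = ct$p.value, n = n)
}

#' Correlate all 80 biomarkers of a subject against FEV1
#'
#' Takes one subject's biomarker table rows (one row per challenge step, see
#' [write_biomarker_table()] for the schema) and computes the absolute
#' Pearson correlation of every biomarker trace with the FEV1 trace.
#' Biomarkers with missing steps are correlated on pairwise-complete steps
#' when at least 3 remain; constant or too-short traces are skipped. A
#' Bonferroni-adjusted p-value over the tests actually performed is reported
#' alongside the raw one for transparency (the screening itself is
#' exploratory and ranks by `abs_rho`).
#'
#' @param subject_rows data frame of one subject's steps with `fev1_l` and
#'   `mu_1..mu_40`, `sigma_1..sigma_40` columns.
#' @return A data frame with columns `biomarker`, `abs_rho`, `p_value`,
#'   `p_bonferroni`, `n`, sorted by decreasing `abs_rho`.
#' @export
correlate_all <- function(subject_rows) {
  ids <- biomarker_ids()
  miss <- setdiff(c("fev1_l", ids), names(subject_rows))
  if (length(miss))
    stop_validation(paste("missing column(s):", paste(utils::head(miss, 3), collapse = ", ")))
  if (sum(!is.na(subject_rows$fev1_l)) < 3L)
    stop_validation("session too short: need at least 3 usable steps")
  res <- lapply(ids, function(b) {
    r <- tryCatch(pearson_abs(subject_rows[[b]], subject_rows$fev1_l),
                  vocalmct_undefined_feature = function(e) NULL,
                  vocalmct_validation_error = function(e) NULL)
    if (is.null(r)) NULL else
      data.frame(biomarker = b, abs_rho = r$abs_rho, p_value = r$p_value,
                 n = r$n)
  })
  out <- do.call(rbind, res)
  if (is.null(out) || !nrow(out))
    stop_validation("no biomarker has a defined correlation for this subject")
  out$p_bonferroni <- pmin(1, p.adjust(out$p_value, method = "bonferroni"))
  out <- out[order(-out$abs_rho, !startsWith(out$biomarker, "mu_"),
                   biomarker_index(out$biomarker)), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("biomarker", "abs_rho", "p_value", "p_bonferroni", "n")]
}

biomarker_index <- function(ids) as.integer(sub("^(mu|sigma)_", "", ids))

#' Best biomarker of a subject
#'
#' The biomarker with the maximal defined `abs_rho`. Ties are broken
#' deterministically: mean (`mu`) biomarkers before variation (`sigma`)
#' biomarkers, then the lower parameter id.
#'
#' @param corr data frame from [correlate_all()].
#' @param subject_id,mct_result carried into the summary row.
#' @return A one-row data frame: `subject_id`, `parameter`, `abs_rho`,
#'   `p_value`, `mct_result`.
#' @export
best_biomarker <- function(corr, subject_id = "unknown",
                           mct_result = NA_character_) {
  if (is.null(corr) || !nrow(corr))
    stop_validation("no defined correlations to rank")
  ord <- order(-corr$abs_rho, !startsWith(corr$biomarker, "mu_"),
               biomarker_index(corr$biomarker))
  top <- corr[ord[1], ]
  data.frame(subject_id = subject_id, parameter = top$biomarker,
             abs_rho = top$abs_rho, p_value = top$p_value,
             mct_result = mct_result, stringsAsFactors = FALSE)
}

#' Cross-subject summary of one biomarker
#'
#' Mean and standard deviation (sample convention: the cohort is a sample of
#' subjects) of the per-subject `abs_rho` of a given biomarker.
#'
#' @param correlations named list of [correlate_all()] outputs, one per
#'   subject.
#' @param biomarker_id biomarker name, e.g. `"mu_40"`.
#' @return A list `(mean_abs_rho, sd_abs_rho, n_subjects)`.
#' @export
cross_subject_feature_summary <- function(correlations, biomarker_id) {
  vals <- vapply(correlations, function(co) {
    hit <- co$abs_rho[co$biomarker == biomarker_id]
    if (length(hit)) hit[1] else NA_real_
  }, numeric(1))
  vals <- vals[!is.na(vals)]
  if (length(vals) < 2L)
    stop_validation(paste0("biomarker ", biomarker_id,
                           " defined in fewer than 2 sessions"))
  list(mean_abs_rho = mean(vals), sd_abs_rho = sd(vals),
       n_subjects = length(vals))
}

#' Build the cohort report
#'
#' One best-biomarker row per subject (subject / parameter / `abs_rho` /
#' p-value / MCT result) plus the cross-subject per-feature table (mean and
#' SD of `abs_rho` for every biomarker defined in at least 2 subjects).
#'
#' @param biomarker_table biomarker data frame (all subjects, one sound
#'   type; see [write_biomarker_table()]).
#' @param mct_results optional named character vector of `"positive"` /
#'   `"negative"` per subject; when missing, each subject's trace is
#'   classified from its own FEV1 fall via [compute_pd20()] and
#'   [classify_mct()].
#' @param out_dir optional directory; when given, `report.csv` and
#'   `feature_summary.csv` are written there.
#' @return A list of class `vb_report`: `subjects` (one row per subject),
#'   `features` (per-biomarker cross-subject table), `correlations` (the
#'   per-subject screening tables).
#' @export
build_report <- function(biomarker_table, mct_results = NULL, out_dir = NULL) {
  if (is.null(biomarker_table) || !nrow(biomarker_table))
    stop_validation("empty biomarker table")
  by_subject <- split(biomarker_table, biomarker_table$subject_id)
  correlations <- list()
  subjects <- NULL
  for (sid in names(by_subject)) {
    rows <- by_subject[[sid]][order(by_subject[[sid]]$step_index), ]
    mct <- if (!is.null(mct_results) && sid %in% names(mct_results))
      mct_results[[sid]]
    else classify_mct(compute_pd20(data.frame(
      cumulative_dose_mcg = rows$cumulative_dose_mcg,
      fev1_l = rows$fev1_l), baseline_fev1_l = rows$fev1_l[1]))
    co <- tryCatch(correlate_all(rows),
                   vocalmct_validation_error = function(e) NULL)
    if (is.null(co)) next
    correlations[[sid]] <- co
    subjects <- rbind(subjects, best_biomarker(co, sid, mct))
  }
  if (is.null(subjects))
    stop_validation("no analyzable session in the biomarker table")
  features <- do.call(rbind, lapply(biomarker_ids(), function(b) {
    fs <- tryCatch(cross_subject_feature_summary(correlations, b),
                   vocalmct_validation_error = function(e) NULL)
    if (is.null(fs)) NULL else
      data.frame(parameter = b, mean_abs_rho = fs$mean_abs_rho,
                 sd_abs_rho = fs$sd_abs_rho, n_subjects = fs$n_subjects)
  }))
  if (!is.null(features)) {
    features <- features[order(-features$mean_abs_rho), ]
    rownames(features) <- NULL
  }
  rownames(subjects) <- NULL
  rep <- structure(list(subjects = subjects, features = features,
                        correlations = correlations), class = "vb_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(subjects, file.path(out_dir, "report.csv"), row.names = FALSE,
              quote = FALSE)
    if (!is.null(features))
      write.csv(features, file.path(out_dir, "feature_summary.csv"),
                row.names = FALSE, quote = FALSE)
  }
  rep
}

#' @export
print.vb_report <- function(x, ...) {
  cat(sprintf("<vb_report> %d subjects analyzed\n", nrow(x$subjects)))
  print(x$subjects)
  invisible(x)
}
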