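# Orchestration: labels -> quality gate -> segmentation -> enhancement ->
# feature extraction -> aggregation -> correlation report.

#' Extract biomarker tables from recordings in memory
#'
#' Runs the full extraction stage: each recording is quality-gated (failures
#' are logged with their reasons and excluded), segmented by its labels,
#' grouped by sound type, and summarised into the 80 mu/sigma biomarkers per
#' sound type. Session covariates (cumulative dose, FEV1) are joined by
#' (subject, step).
#'
#' @param recordings named list of [recording()]s (names are recording ids).
#' @param labels data frame of labels for all recordings (with
#'   `recording_id`), or a named list as returned by [read_labels()].
#' @param session_table session data frame (see [read_session_table()]).
#' @param cfg a [feature_config()].
#' @param thresholds a [quality_thresholds()].
#' @param verbose log rejected recordings and progress via `message()`.
#' @return A data frame with columns `sound_type`, `subject_id`,
#'   `step_index`, `cumulative_dose_mcg`, `fev1_l`, `mu_1..mu_40`,
#'   `sigma_1..sigma_40`, plus an attribute `rejected` (data frame of
#'   recording ids and reasons). Errors if no recording passes the gate.
#' @export
extract_biomarkers <- function(recordings, labels, session_table,
                               cfg = feature_config(),
                               thresholds = quality_thresholds(),
                               verbose = FALSE) {
  if (is.data.frame(labels)) labels <- split(labels, labels$recording_id)
  rows <- list()
  rejected <- data.frame(recording_id = character(), reasons = character())
  for (rec_id in names(recordings)) {
    rec <- recordings[[rec_id]]
    labs <- labels[[rec_id]]
    if (is.null(labs)) {
      rejected[nrow(rejected) + 1L, ] <- list(rec_id, "no_labels")
      next
    }
    qr <- evaluate_quality(rec, labs, thresholds)
    if (!qr$passed) {
      rejected[nrow(rejected) + 1L, ] <-
        list(rec_id, paste(qr$reasons, collapse = ";"))
      if (verbose)
        message("rejected ", rec_id, ": ", paste(qr$reasons, collapse = ", "))
      next
    }
    groups <- group_events(segment_events(rec, labs))
    sess <- session_table[session_table$subject_id == rec$subject_id &
                            session_table$step_index == rec$step_index, ]
    dose <- if (nrow(sess)) sess$cumulative_dose_mcg[1] else NA_real_
    fev1 <- if (nrow(sess)) sess$fev1_l[1] else NA_real_
    for (tp in names(groups)) {
      bm <- biomarkers_for_type(groups[[tp]], cfg)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(sound_type = tp, subject_id = rec$subject_id,
                   step_index = rec$step_index, cumulative_dose_mcg = dose,
                   fev1_l = fev1),
        as.data.frame(as.list(c(bm$mu, bm$sigma))))
    }
    if (verbose) message("extracted ", rec_id)
  }
  if (!length(rows))
    stop_validation("no recording passed the quality gate: empty output")
  out <- do.call(rbind, rows)
  out <- out[order(out$sound_type, out$subject_id, out$step_index), ]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Extract biomarkers from an on-disk cohort
#'
#' Reads the layout written by [write_cohort()] — `audio/<recording_id>.wav`,
#' `labels.tsv`, `sessions.csv`, where recording ids follow
#' `<subject_id>_step<NN>` — runs [extract_biomarkers()], and optionally
#' writes one biomarker CSV per sound type
#' (`biomarkers_<sound_type>.csv`).
#'
#' @param input_dir cohort directory.
#' @param out_dir optional output directory for the biomarker CSVs.
#' @param cfg,thresholds,verbose see [extract_biomarkers()].
#' @return The biomarker data frame (all sound types).
#' @export
run_extract <- function(input_dir, out_dir = NULL, cfg = feature_config(),
                        thresholds = quality_thresholds(), verbose = FALSE) {
  labels_path <- file.path(input_dir, "labels.tsv")
  session_path <- file.path(input_dir, "sessions.csv")
  if (!file.exists(session_path)) stop("extract stage: missing ", session_path)
  if (!file.exists(labels_path)) stop("extract stage: missing ", labels_path)
  labels <- read_labels(labels_path)
  session_table <- read_session_table(session_path)
  wavs <- list.files(file.path(input_dir, "audio"), pattern = "\\.wav$",
                     full.names = TRUE)
  if (!length(wavs)) stop("extract stage: no WAV files under ",
                          file.path(input_dir, "audio"))
  recordings <- list()
  for (w in wavs) {
    rec_id <- sub("\\.wav$", "", basename(w))
    m <- regmatches(rec_id, regexec("^(.*)_step([0-9]+)$", rec_id))[[1]]
    if (length(m) != 3L)
      stop("extract stage: recording id '", rec_id,
           "' does not follow <subject_id>_step<NN>")
    recordings[[rec_id]] <- read_wav(w, subject_id = m[2],
                                     step_index = as.integer(m[3]),
                                     task_id = rec_id)
  }
  out <- extract_biomarkers(recordings, labels, session_table, cfg,
                            thresholds, verbose = verbose)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (tp in unique(out$sound_type))
      write_biomarker_table(out[out$sound_type == tp, , drop = FALSE],
                            file.path(out_dir, paste0("biomarkers_", tp, ".csv")))
  }
  out
}

#' Run the full pipeline: extraction, correlation, report
#'
#' Single-invocation composition of the pipeline stages on an on-disk
#' cohort. The analyzed sound type defaults to exhalation (the sound type
#' with the strongest FEV1 association); inhalation and vowel analyses are
#' available via `sound_type`. Identical inputs and configuration produce
#' byte-identical outputs.
#'
#' @param input_dir cohort directory (see [run_extract()]).
#' @param out_dir optional directory for biomarker CSVs, `report.csv` and
#'   `feature_summary.csv`.
#' @param sound_type sound type to analyze.
#' @param cfg,thresholds,verbose see [extract_biomarkers()].
#' @return A `vb_report` (see [build_report()]).
#' @export
run_full <- function(input_dir, out_dir = NULL, sound_type = "exhalation",
                     cfg = feature_config(),
                     thresholds = quality_thresholds(), verbose = FALSE) {
  sound_type <- match.arg(sound_type, EVENT_TYPES)
  table <- run_extract(input_dir, out_dir, cfg, thresholds, verbose = verbose)
  sel <- table[table$sound_type == sound_type, , drop = FALSE]
  if (!nrow(sel))
    stop("correlate stage: no '", sound_type, "' rows in the biomarker table")
  build_report(sel, out_dir = out_dir)
}

#' Biomarker table of a simulated cohort (in memory)
#'
#' Convenience bridge from [simulate_cohort()] to [extract_biomarkers()]
#' without touching disk.
#'
#' @param cohort a `vb_cohort`.
#' @param cfg,thresholds,verbose see [extract_biomarkers()].
#' @return The biomarker data frame (all sound types).
#' @export
cohort_biomarkers <- function(cohort, cfg = feature_config(),
                              thresholds = quality_thresholds(),
                              verbose = FALSE) {
  recordings <- do.call(c, unname(lapply(cohort, function(s) s$recordings)))
  labels <- do.call(rbind, lapply(cohort, function(s) s$labels))
  sessions <- do.call(rbind, lapply(cohort, function(s) s$session))
  extract_biomarkers(recordings, labels, sessions, cfg, thresholds,
                     verbose = verbose)
}
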