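#' Methacholine-challenge protocol configuration
#'
#' Defaults follow the standard dosimeter protocol: a saline step, then
#' cumulative methacholine doses doubling from 100 mcg up to 1600 mcg,
#' stopping at a 20\% FEV1 fall; a PD20 at or below 800 mcg is read as a
#' positive test.
#'
#' @param initial_dose_mcg first cumulative methacholine dose.
#' @param max_cumulative_mcg largest cumulative dose.
#' @param fall_threshold_pct FEV1 fall (percent of baseline) that stops the
#'   test and defines PD20.
#' @param positive_threshold_mcg PD20 at or below this is positive.
#' @return A list of class `vb_mct_config`.
#' @export
mct_config <- function(initial_dose_mcg = 100, max_cumulative_mcg = 1600,
                       fall_threshold_pct = 20, positive_threshold_mcg = 800) {
  stopifnot(initial_dose_mcg > 0, max_cumulative_mcg >= initial_dose_mcg,
            fall_threshold_pct > 0, positive_threshold_mcg > 0)
  structure(list(initial_dose_mcg = initial_dose_mcg,
                 max_cumulative_mcg = max_cumulative_mcg,
                 fall_threshold_pct = fall_threshold_pct,
                 positive_threshold_mcg = positive_threshold_mcg),
            class = "vb_mct_config")
}

mct_dose_schedule <- function(cfg) {
  doses <- cfg$initial_dose_mcg
  while (utils::tail(doses, 1) * 2 <= cfg$max_cumulative_mcg)
    doses <- c(doses, utils::tail(doses, 1) * 2)
  doses
}

#' Run the methacholine-challenge protocol
#'
#' Drives a dose-response function through the protocol: a saline step
#' (cumulative dose 0) first — the test is discontinued if FEV1 already falls
#' by the threshold — then cumulative doses 100, 200, 400, 800, 1600 mcg
#' until the FEV1 fall reaches the threshold or the schedule is exhausted.
#' PD20 (the provocative cumulative dose causing a 20\% fall) is computed by
#' log-linear interpolation and the test classified positive when PD20 is at
#' most 800 mcg.
#'
#' @param response_fn function mapping cumulative dose (mcg) to FEV1 (L);
#'   called once per step in order, so stochastic responses are reproducible
#'   under a fixed RNG state.
#' @param cfg a [mct_config()].
#' @param baseline_fev1_l baseline FEV1; defaults to `response_fn(0)`
#'   evaluated once before the saline step.
#' @return A list of class `vb_mct_outcome` with `steps` (data frame:
#'   `step_index`, `cumulative_dose_mcg`, `fev1_l`, `fall_pct`),
#'   `baseline_fev1_l`, `pd20_mcg` (`NA` if the fall threshold was never
#'   reached), `positive`, and `discontinued` (saline abort).
#' @export
run_protocol <- function(response_fn, cfg = mct_config(),
                         baseline_fev1_l = NULL) {
  if (is.null(baseline_fev1_l)) baseline_fev1_l <- response_fn(0)
  if (!is.finite(baseline_fev1_l) || baseline_fev1_l <= 0)
    stop_validation("baseline FEV1 must be positive")
  doses <- c(0, mct_dose_schedule(cfg))
  steps <- data.frame(step_index = integer(), cumulative_dose_mcg = numeric(),
                      fev1_l = numeric(), fall_pct = numeric())
  discontinued <- FALSE
  for (i in seq_along(doses)) {
    fev1 <- response_fn(doses[i])
    fall <- 100 * (baseline_fev1_l - fev1) / baseline_fev1_l
    steps[i, ] <- list(i - 1L, doses[i], fev1, fall)
    if (fall >= cfg$fall_threshold_pct) {
      if (doses[i] == 0) discontinued <- TRUE
      break
    }
  }
  pd20 <- if (discontinued) NA_real_ else
    compute_pd20(steps, baseline_fev1_l, cfg$fall_threshold_pct)
  structure(list(steps = steps, baseline_fev1_l = baseline_fev1_l,
                 pd20_mcg = pd20,
                 positive = classify_mct(pd20, cfg$positive_threshold_mcg) == "positive",
                 discontinued = discontinued),
            class = "vb_mct_outcome")
}

#' @export
print.vb_mct_outcome <- function(x, ...) {
  cat(sprintf("<vb_mct_outcome> %d steps, baseline %.2f L, PD20 %s mcg (%s)%s\n",
              nrow(x$steps), x$baseline_fev1_l,
              if (is.na(x$pd20_mcg)) "-" else sprintf("%.1f", x$pd20_mcg),
              if (x$positive) "positive" else "negative",
              if (x$discontinued) " [discontinued at saline]" else ""))
  invisible(x)
}

#' Compute PD20 from challenge steps
#'
#' The provocative cumulative dose at which the FEV1 fall reaches
#' `fall_threshold_pct` (20\%), by log-linear interpolation between the last
#' dosed step below the threshold (dose D1, fall R1) and the first step at or
#' above it (D2, R2):
#' `PD20 = exp(log D1 + (log D2 - log D1) * (20 - R1) / (R2 - R1))`.
#' If the first dosed step already reaches the threshold there is no left
#' bracket and PD20 equals that dose; if the threshold is never reached, PD20
#' is undefined (`NA`, test negative).
#'
#' @param steps data frame with `cumulative_dose_mcg` and either `fall_pct`
#'   or `fev1_l`.
#' @param baseline_fev1_l baseline FEV1, used to derive `fall_pct` when
#'   absent.
#' @param fall_threshold_pct threshold fall (default 20).
#' @return PD20 in mcg, or `NA_real_`.
#' @export
compute_pd20 <- function(steps, baseline_fev1_l = NULL,
                         fall_threshold_pct = 20) {
  if (is.null(steps$fall_pct)) {
    if (is.null(baseline_fev1_l)) stop("need fall_pct or baseline_fev1_l")
    steps$fall_pct <- 100 * (baseline_fev1_l - steps$fev1_l) / baseline_fev1_l
  }
  dosed <- steps[steps$cumulative_dose_mcg > 0, , drop = FALSE]
  hit <- which(dosed$fall_pct >= fall_threshold_pct)
  if (!length(hit)) return(NA_real_)
  i <- hit[1]
  d2 <- dosed$cumulative_dose_mcg[i]; r2 <- dosed$fall_pct[i]
  if (r2 == fall_threshold_pct || i == 1L) return(d2)
  d1 <- dosed$cumulative_dose_mcg[i - 1L]; r1 <- dosed$fall_pct[i - 1L]
  exp(log(d1) + (log(d2) - log(d1)) *
        (fall_threshold_pct - r1) / (r2 - r1))
}

#' Classify an MCT outcome from its PD20
#'
#' @param pd20_mcg PD20 in mcg, or `NA` when the fall threshold was never
#'   reached.
#' @param threshold_mcg positivity threshold (default 800).
#' @return `"positive"` or `"negative"`.
#' @export
classify_mct <- function(pd20_mcg, threshold_mcg = 800) {
  stopifnot(threshold_mcg > 0)
  if (!is.na(pd20_mcg) && pd20_mcg <= threshold_mcg) "positive" else "negative"
}
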