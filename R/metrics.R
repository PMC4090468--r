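#' Per-recording evaluation container
#'
#' @param n_seizures_tested number of annotated onsets evaluated.
#' @param n_predicted number of those preceded by a qualifying alarm.
#' @param sensitivity_pct percentage predicted (computed when omitted).
#' @param false_alarms number of alarms resolved as false.
#' @param interictal_hours hours of interictal recording underlying `fpr`.
#' @param fpr_per_h false alarms per interictal hour (computed when omitted).
#' @param advance_min advance prediction time in minutes, one entry per
#'   tested seizure; 0 means the seizure was not predicted.
#' @return object of class `patient_eval`.
#' @export
patient_eval <- function(n_seizures_tested, n_predicted = NULL,
                         sensitivity_pct = NULL, false_alarms = NA_integer_,
                         interictal_hours = NA_real_, fpr_per_h = NULL,
                         advance_min) {
  if (is.null(sensitivity_pct))
    sensitivity_pct <- if (n_seizures_tested > 0)
      100 * n_predicted / n_seizures_tested else NA_real_
  if (is.null(fpr_per_h)) fpr_per_h <- false_alarms / interictal_hours
  if (length(advance_min) != n_seizures_tested)
    stop_validation("advance_min needs one entry per tested seizure")
  if (!is.na(sensitivity_pct) && (sensitivity_pct < 0 || sensitivity_pct > 100))
    stop_validation("sensitivity must lie in [0, 100]")
  if (!is.na(fpr_per_h) && fpr_per_h < 0) stop_validation("fpr must be >= 0")
  structure(list(n_seizures_tested = n_seizures_tested,
                 n_predicted = if (is.null(n_predicted)) NA_integer_ else n_predicted,
                 sensitivity_pct = sensitivity_pct,
                 false_alarms = false_alarms,
                 interictal_hours = interictal_hours,
                 fpr_per_h = fpr_per_h,
                 advance_min = advance_min),
            class = "patient_eval")
}

#' Event-based evaluation of a prediction log
#'
#' A seizure counts as predicted when at least one alarm (whatever its later
#' resolution) occurred within the prediction horizon before its onset, i.e.
#' in `(onset - H_time, onset)`; the advance time is taken from the *first*
#' such alarm, and missed seizures contribute an advance of 0.  False alarms
#' are counted from the log's resolutions.  The interictal hours underlying
#' the false-positive rate are the streamed span minus, per seizure, the
#' preictal exclusion (`preictal_excl_min` before onset), the ictal period
#' and the postictal skip.
#'
#' @param log a `prediction_log` from [process_stream()], or any list with
#'   `alarms` (`time_s`, `resolved`), `span`, `annotations`.
#' @param annotations override the log's annotations.
#' @param H_time_min override the log's configured horizon (minutes).
#' @param preictal_excl_min preictal span excluded from interictal time
#'   (default 50, the minimum preictal period assumed available).
#' @param postictal_min postictal span excluded (default from the log's
#'   config, else 10).
#' @return a [patient_eval()].
#' @export
evaluate_predictions <- function(log, annotations = NULL, H_time_min = NULL,
                                 preictal_excl_min = 50, postictal_min = NULL) {
  if (is.null(annotations)) annotations <- log$annotations
  if (is.null(H_time_min)) H_time_min <- log$config$H_time_min
  if (is.null(postictal_min))
    postictal_min <- if (!is.null(log$config)) log$config$postictal_min else 10
  ann <- validate_annotations(annotations)
  span <- log$span
  H_s <- H_time_min * 60
  alarm_t <- log$alarms$time_s

  n_tested <- nrow(ann)
  advance <- numeric(n_tested)
  predicted <- logical(n_tested)
  for (j in seq_len(n_tested)) {
    onset <- ann$onset_s[j]
    qual <- alarm_t[alarm_t > onset - H_s & alarm_t < onset]
    if (length(qual) > 0L) {
      predicted[j] <- TRUE
      advance[j] <- (onset - min(qual)) / 60
    }
  }
  false_alarms <- sum(log$alarms$resolved == "false_alarm")

  excl <- 0
  for (j in seq_len(n_tested)) {
    pre_lo <- max(span[1L], ann$onset_s[j] - preictal_excl_min * 60)
    post_hi <- min(span[2L], ann$offset_s[j] + postictal_min * 60)
    excl <- excl + (min(span[2L], ann$onset_s[j]) - pre_lo) +
      (post_hi - min(span[2L], ann$onset_s[j]))
  }
  interictal_h <- (span[2L] - span[1L] - excl) / 3600
  if (interictal_h <= 0) stop_validation("no interictal time left in the span")

  patient_eval(n_seizures_tested = n_tested, n_predicted = sum(predicted),
               false_alarms = false_alarms, interictal_hours = interictal_h,
               advance_min = advance)
}

#' Aggregate per-patient evaluations into group means
#'
#' Sensitivities and false-positive rates are averaged across patients; the
#' mean advance time is taken over the concatenation of all per-seizure
#' advance entries, zeros (missed seizures) included.  The group performance
#' index is computed from the mean sensitivity and mean fpr.
#'
#' @param evals non-empty list of [patient_eval()] objects.
#' @return object of class `group_eval`: `mean_sensitivity_pct`,
#'   `mean_fpr_per_h`, `mean_advance_min`, `P`.
#' @export
aggregate_evals <- function(evals) {
  if (length(evals) == 0L) stop_validation("no evaluations to aggregate")
  sens <- mean(vapply(evals, `[[`, numeric(1), "sensitivity_pct"))
  fpr <- mean(vapply(evals, `[[`, numeric(1), "fpr_per_h"))
  adv <- mean(unlist(lapply(evals, `[[`, "advance_min")))
  structure(list(mean_sensitivity_pct = sens, mean_fpr_per_h = fpr,
                 mean_advance_min = adv,
                 P = performance_index(sens, fpr)),
            class = "group_eval")
}

#' @export
print.group_eval <- function(x, ...) {
  cat(sprintf("<group_eval> sensitivity %.1f%%, fpr %.2f /h, advance %.1f min, P = %.2f\n",
              x$mean_sensitivity_pct, x$mean_fpr_per_h, x$mean_advance_min, x$P))
  invisible(x)
}

#' Performance index combining sensitivity and false-positive rate
#'
#' `P = sqrt((se^2 + sp^2) / 2)` with `se` the mean sensitivity as a
#' fraction and `sp = 1 - fpr` the specificity rate (`sp = 0` when the mean
#' fpr exceeds 1 per hour).
#'
#' @param mean_sensitivity_pct mean sensitivity in percent (0-100).
#' @param mean_fpr_per_h mean false-positive rate per hour.
#' @return `P` in `[0, 1]` (unrounded; round to 2 decimals for reporting).
#' @export
performance_index <- function(mean_sensitivity_pct, mean_fpr_per_h) {
  if (mean_sensitivity_pct < 0 || mean_sensitivity_pct > 100)
    stop_validation("sensitivity must lie in [0, 100]")
  if (mean_fpr_per_h < 0) stop_validation("fpr must be >= 0")
  se <- mean_sensitivity_pct / 100
  sp <- if (mean_fpr_per_h > 1) 0 else 1 - mean_fpr_per_h
  sqrt((se^2 + sp^2) / 2)
}

#' Reference per-patient results shipped with the package
#'
#' Reads the bundled table of per-patient seizure-prediction results from the
#' reported Freiburg evaluation (9 patients, 3 tested seizures each, under
#' the static and the dynamic-update system) and converts each row to a
#' [patient_eval()].  Used to validate [aggregate_evals()] and
#' [performance_index()].
#'
#' @param system `"dynamic"` or `"no_update"`.
#' @return list of [patient_eval()] objects.
#' @export
reference_patient_evals <- function(system = c("dynamic", "no_update")) {
  system <- match.arg(system)
  path <- system.file("extdata", "reference_patient_results.csv",
                      package = "seizpred", mustWork = TRUE)
  tab <- utils::read.csv(path)
  tab <- tab[tab$system == system, , drop = FALSE]
  lapply(seq_len(nrow(tab)), function(i) {
    adv <- as.numeric(tab[i, c("advance1_min", "advance2_min", "advance3_min")])
    patient_eval(n_seizures_tested = 3L,
                 sensitivity_pct = tab$sensitivity_pct[i],
                 fpr_per_h = tab$fpr_per_h[i],
                 advance_min = adv)
  })
}
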