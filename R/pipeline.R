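#' Build the initial sample pools from training recordings
#'
#' Follows the pool-construction design of the evaluation: the preictal pool
#' is filled from the `preictal_train_min` (default 37.6 min) immediately
#' preceding each of the first `n_train` seizures, windowed at 10 s with 50%
#' overlap (450 windows per seizure); the interictal pool from
#' `interictal_train_min` (default 150 min) of the seizure-free recording,
#' windowed at 10 s without overlap (900 windows).  Recordings are
#' notch-filtered before feature extraction.
#'
#' @param dataset a [gen_dataset()] result, or any list with `seizure_runs`
#'   (each holding a `recording` with one annotation) and `interictal`.
#' @param cfg a [predictor_config()].
#' @param n_train number of seizures used for the preictal pool (default 2).
#' @param preictal_train_min preictal minutes harvested per training seizure.
#' @param interictal_train_min interictal minutes harvested.
#' @param verbose print progress.
#' @return list with `pre` and `inter` [sample_pool()]s and the shared
#'   feature `hidden` layer.
#' @export
build_pools <- function(dataset, cfg, n_train = 2L, preictal_train_min = 37.6,
                        interictal_train_min = 150, verbose = FALSE) {
  d <- ncol(dataset$interictal$recording$data)
  hidden <- feature_hidden_of(cfg, d)
  fpar <- elm_params(cfg$feature_L, seed = cfg$seed, ridge = cfg$feature_ridge)

  pre_feats <- list()
  for (k in seq_len(n_train)) {
    rec <- preprocess(dataset$seizure_runs[[k]]$recording, cfg)
    onset <- rec$annotations$onset_s[1L]
    segs <- segment_windows(rec, window_spec(cfg$window$length_s, cfg$window$overlap_frac),
                            t0 = onset - preictal_train_min * 60, t1 = onset)
    if (verbose) message("preictal windows, training seizure ", k, ": ", length(segs))
    pre_feats[[k]] <- extract_feature_batch(segs, hidden, fpar, cfg$max_imf,
                                            verbose = verbose)$features
  }

  rec_i <- preprocess(dataset$interictal$recording, cfg)
  segs_i <- segment_windows(rec_i, window_spec(cfg$window$length_s, 0),
                            t0 = 0, t1 = interictal_train_min * 60)
  if (verbose) message("interictal windows: ", length(segs_i))
  inter_feats <- extract_feature_batch(segs_i, hidden, fpar, cfg$max_imf,
                                       verbose = verbose)$features

  pre_mat <- do.call(rbind, pre_feats)
  list(pre = sample_pool(pre_mat, capacity = nrow(pre_mat), role = "pre"),
       inter = sample_pool(inter_feats, capacity = nrow(inter_feats), role = "inter"),
       hidden = hidden)
}

preprocess <- function(rec, cfg) {
  if (is.null(cfg$notch_hz)) rec else notch_filter(rec, cfg$notch_hz)
}

#' Run the full prediction pipeline over a synthetic dataset
#'
#' Builds the pools from the first `n_train` seizures, trains the classifier,
#' then streams the remaining seizure recordings in order.  Pools and
#' classifier persist across recordings, so updates made during one recording
#' carry into the next.
#'
#' @param dataset a [gen_dataset()] result.
#' @param cfg a [predictor_config()].
#' @param n_train training seizures (default 2).
#' @param pools optional pre-built pools (a [build_pools()] result), reused
#'   to compare update/no-update runs on identical initial conditions.
#' @param verbose print progress.
#' @return list with `logs` (one `prediction_log` per streamed recording),
#'   `eval` (a [patient_eval()] accumulated over all streamed recordings),
#'   final `pools` and `model`.
#' @export
run_prediction <- function(dataset, cfg, n_train = 2L, pools = NULL,
                           verbose = FALSE) {
  if (is.null(pools)) pools <- build_pools(dataset, cfg, n_train, verbose = verbose)
  model <- train_classifier(pools$pre, pools$inter, clf_params_of(cfg))
  pre <- pools$pre
  inter <- pools$inter
  test_runs <- dataset$seizure_runs[-seq_len(n_train)]
  logs <- vector("list", length(test_runs))
  for (i in seq_along(test_runs)) {
    rec <- preprocess(test_runs[[i]]$recording, cfg)
    if (verbose) message("streaming test recording ", i, "/", length(test_runs))
    log <- process_stream(rec, cfg, pre, inter, model,
                          feature_hidden = pools$hidden, verbose = verbose)
    pre <- log$pools$pre
    inter <- log$pools$inter
    model <- log$model
    logs[[i]] <- log
  }
  list(logs = logs, eval = evaluate_runs(logs),
       pools = list(pre = pre, inter = inter), model = model)
}

#' Accumulate an evaluation over several prediction logs
#'
#' Like [evaluate_predictions()], but sums seizure counts, advance entries,
#' false alarms and interictal time over a list of logs (e.g. one log per
#' streamed recording of the same patient) before forming rates.  Interictal
#' time is clamped at zero per recording rather than raising an error, so
#' short pre-onset-only recordings simply contribute no denominator.
#'
#' @param logs list of `prediction_log`s.
#' @param preictal_excl_min,postictal_min exclusion spans, as in
#'   [evaluate_predictions()].
#' @return a [patient_eval()].
#' @export
evaluate_runs <- function(logs, preictal_excl_min = 50, postictal_min = NULL) {
  n_tested <- 0L; n_pred <- 0L
  advance <- numeric(0)
  fa <- 0L
  inter_s <- 0
  for (log in logs) {
    post <- if (is.null(postictal_min)) log$config$postictal_min else postictal_min
    ann <- log$annotations
    H_s <- log$config$H_time_min * 60
    for (j in seq_len(nrow(ann))) {
      onset <- ann$onset_s[j]
      qual <- log$alarms$time_s[log$alarms$time_s > onset - H_s &
                                  log$alarms$time_s < onset]
      n_tested <- n_tested + 1L
      if (length(qual) > 0L) {
        n_pred <- n_pred + 1L
        advance <- c(advance, (onset - min(qual)) / 60)
      } else advance <- c(advance, 0)
    }
    fa <- fa + sum(log$alarms$resolved == "false_alarm")
    span <- log$span
    excl <- 0
    for (j in seq_len(nrow(ann))) {
      pre_lo <- max(span[1L], ann$onset_s[j] - preictal_excl_min * 60)
      post_hi <- min(span[2L], ann$offset_s[j] + post * 60)
      excl <- excl + (min(span[2L], ann$onset_s[j]) - pre_lo) +
        (post_hi - min(span[2L], ann$onset_s[j]))
    }
    inter_s <- inter_s + max(0, span[2L] - span[1L] - excl)
  }
  if (inter_s <= 0) stop_validation("no interictal time across the logs")
  patient_eval(n_seizures_tested = n_tested, n_predicted = n_pred,
               false_alarms = fa, interictal_hours = inter_s / 3600,
               advance_min = advance)
}
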