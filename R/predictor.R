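#' Configuration of the streaming predictor
#'
#' Defaults follow the design parameters of the method: 10 s windows with 50%
#' overlap, a 110 min prediction horizon, a 1.5 min observation window with
#' density threshold 0.7, abnormality multiplier `lam = 1`, preictal-pool
#' harvesting from 30-40 min before a missed onset, feature ELM with 10
#' hidden neurons and classifier ELM with 1000.
#'
#' @param H_time_min prediction horizon in minutes: a seizure must begin
#'   within this time after an alarm for the alarm to be correct.
#' @param win_os_min observation window (minutes) over which the preictal
#'   density is computed.
#' @param gamma density threshold in (0, 1); an alarm requires `Den > gamma`.
#' @param lam abnormality multiplier for [is_abnormal()].
#' @param preonset_lo_min,preonset_hi_min bounds of the span
#'   `[onset - lo, onset - hi]` whose windows refresh the preictal pool after
#'   a missed seizure.
#' @param postictal_min minutes skipped after each seizure offset.
#' @param update_enabled logical; `FALSE` reduces the system to the static
#'   basic model (pools and classifier stay fixed).
#' @param window a [window_spec()].
#' @param sort_order retention order for pool updates (`"asc"` or `"desc"`).
#' @param notch_hz mains frequency removed during preprocessing (`NULL` to
#'   skip).
#' @param max_imf IMFs per channel for the phase matrix.
#' @param feature_L,clf_L hidden-neuron counts of the feature and classifier
#'   ELMs.
#' @param feature_ridge,clf_ridge ridge regularization of the two ELMs.
#' @param seed global seed; the feature hidden layer uses `seed` and the
#'   classifier hidden layer `seed + 1`.
#' @return object of class `predictor_config`.
#' @export
predictor_config <- function(H_time_min = 110, win_os_min = 1.5, gamma = 0.7,
                             lam = 1, preonset_lo_min = 40, preonset_hi_min = 30,
                             postictal_min = 10, update_enabled = TRUE,
                             window = window_spec(10, 0.5), sort_order = "asc",
                             notch_hz = 50, max_imf = 3L, feature_L = 10L,
                             clf_L = 1000L, feature_ridge = 0, clf_ridge = 1e-6,
                             seed = 1L) {
  if (!(gamma > 0 && gamma < 1)) stop_validation("gamma must lie in (0, 1)")
  if (H_time_min <= win_os_min) stop_validation("H_time_min must exceed win_os_min")
  if (preonset_hi_min >= preonset_lo_min)
    stop_validation("preonset_hi_min must be < preonset_lo_min")
  structure(list(H_time_min = H_time_min, win_os_min = win_os_min,
                 gamma = gamma, lam = lam,
                 preonset_lo_min = preonset_lo_min,
                 preonset_hi_min = preonset_hi_min,
                 postictal_min = postictal_min,
                 update_enabled = isTRUE(update_enabled),
                 window = window, sort_order = sort_order, notch_hz = notch_hz,
                 max_imf = as.integer(max_imf),
                 feature_L = as.integer(feature_L), clf_L = as.integer(clf_L),
                 feature_ridge = feature_ridge, clf_ridge = clf_ridge,
                 seed = as.integer(seed)),
            class = "predictor_config")
}

feature_hidden_of <- function(cfg, d) {
  elm_init_hidden(d * cfg$max_imf,
                  elm_params(cfg$feature_L, seed = cfg$seed, ridge = cfg$feature_ridge))
}

clf_params_of <- function(cfg) {
  elm_params(cfg$clf_L, seed = cfg$seed + 1L, ridge = cfg$clf_ridge)
}

#' Train the preictal/interictal classifier on the sample pools
#'
#' Fits an ELM on the pooled feature vectors with target 1 for preictal and
#' 0 for interictal samples.
#'
#' @param pre,inter the two `sample_pool`s.
#' @param params classifier [elm_params()] (1000 sigmoid hidden neurons by
#'   default pipeline settings).
#' @param hidden optional fixed hidden layer, reused across retrains so that
#'   only the output weights are refit.
#' @return a fitted `elm`.
#' @export
train_classifier <- function(pre, inter, params, hidden = NULL) {
  if (nrow(pre$features) == 0L || nrow(inter$features) == 0L)
    stop_validation("both pools must be non-empty")
  S <- rbind(pre$features, inter$features)
  O <- c(rep(1, nrow(pre$features)), rep(0, nrow(inter$features)))
  elm_fit(S, O, params, hidden = hidden)
}

#' Binary preictal decision for feature vectors
#' @param model fitted classifier `elm`.
#' @param f feature vector or matrix of feature rows.
#' @return integer 0/1 per row: 1 iff the raw output strictly exceeds 0.5.
#' @export
classify <- function(model, f) {
  f <- if (is.matrix(f)) f else matrix(as.numeric(f), nrow = 1L)
  as.integer(predict(model, f)[, 1L] > 0.5)
}

#' Preictal density of a decision buffer
#' @param decisions non-empty vector of 0/1 window decisions inside the
#'   observation window.
#' @return fraction of preictal (1) decisions, in `[0, 1]`.
#' @export
preictal_density <- function(decisions) {
  if (length(decisions) == 0L) stop_validation("empty decision list")
  mean(decisions)
}

#' Alarm rule
#' @param den preictal density.
#' @param gamma density threshold.
#' @return `TRUE` iff `den > gamma` (strict).
#' @export
step_alarm <- function(den, gamma) {
  den > gamma
}

#' Stream a recording through the predictor
#'
#' Slides overlapping windows over `[t0, t1]`, classifies each window that
#' lies wholly outside ictal/postictal skips, maintains the trailing
#' observation-window decision buffer, and raises an alarm whenever the
#' buffer is full, no alarm is pending, and the preictal density strictly
#' exceeds `gamma`.  A pending alarm resolves as a true positive when a
#' seizure begins within the prediction horizon, and as a false alarm when
#' the horizon lapses.  With updates enabled, a lapsed false alarm whose
#' observation-window samples are not abnormal refreshes the interictal pool
#' (Condition A), and a missed seizure refreshes the preictal pool from the
#' configured pre-onset span and suspends observation until
#' `offset + postictal + H_time` (Condition B); the classifier output weights
#' are refit after either update.
#'
#' @param rec a `recording` (annotations drive seizure events; apply
#'   [notch_filter()] beforehand, as the high-level drivers do).
#' @param cfg a [predictor_config()].
#' @param pre,inter initialized `sample_pool`s.
#' @param model trained classifier from [train_classifier()].
#' @param feature_hidden shared feature hidden layer; built from `cfg` when
#'   omitted.
#' @param t0,t1 streamed span (seconds; defaults to the whole recording).
#' @param classify_fun optional override `function(start_s, feature) -> 0/1`
#'   used instead of the classifier (for diagnostics and scripted traces);
#'   when supplied together with `update_enabled = FALSE`, feature extraction
#'   is skipped entirely.
#' @param verbose print progress.
#' @return object of class `prediction_log`: `windows` (data frame with
#'   `start_s`, `end_s`, `decision`, `density`; skipped windows have `NA`
#'   decision), `alarms` (`time_s`, `density`, `resolved`), `events`
#'   (`time_s`, `type`), final `pools` and `model`, the streamed `span`,
#'   `annotations` and `config`.
#' @export
process_stream <- function(rec, cfg, pre, inter, model = NULL,
                           feature_hidden = NULL, t0 = 0, t1 = NULL,
                           classify_fun = NULL, verbose = FALSE) {
  if (is.null(t1)) t1 <- duration_s(rec)
  len <- cfg$window$length_s
  step <- cfg$window$step_s
  if (t1 - t0 < len) stop_validation("recording span shorter than one window")
  if (is.null(model) && is.null(classify_fun))
    stop_validation("either a trained model or classify_fun is required")
  need_features <- is.null(classify_fun) || cfg$update_enabled
  if (need_features && is.null(feature_hidden))
    feature_hidden <- feature_hidden_of(cfg, ncol(rec$data))
  fpar <- elm_params(cfg$feature_L, seed = cfg$seed, ridge = cfg$feature_ridge)
  cpar <- clf_params_of(cfg)
  H_s <- cfg$H_time_min * 60
  buf_n <- n_windows(cfg$win_os_min * 60, cfg$window)
  ann <- rec$annotations
  base_skips <- if (nrow(ann) > 0L)
    cbind(ann$onset_s, ann$offset_s + cfg$postictal_min * 60) else
    matrix(numeric(0), ncol = 2L)

  k <- n_windows(t1 - t0, cfg$window)
  starts <- t0 + (seq_len(k) - 1L) * step
  decisions <- rep(NA_integer_, k)
  densities <- rep(NA_real_, k)
  feats <- vector("list", k)

  alarms <- list()       # each: list(time_s, density, resolved, obs)
  events <- list()       # each: list(time_s, type)
  pending <- NULL        # index into alarms
  buffer <- integer(0)
  buffer_idx <- integer(0)
  skip_until <- -Inf
  onset_done <- rep(FALSE, nrow(ann))
  prev_end <- t0

  add_event <- function(time_s, type) {
    events[[length(events) + 1L]] <<- list(time_s = time_s, type = type)
  }

  retrain <- function(time_s) {
    model <<- train_classifier(pre, inter, cpar,
                               hidden = list(W = model$W, b = model$b))
    add_event(time_s, "retrain")
  }

  resolve_false <- function(time_s) {
    a <- alarms[[pending]]
    alarms[[pending]]$resolved <<- "false_alarm"
    add_event(time_s, "false_alarm")
    if (cfg$update_enabled && !is.null(a$obs) && nrow(a$obs) > 0L) {
      if (!is_abnormal(a$obs, pre, inter, cfg$lam)) {
        inter <<- update_pool_inter(inter, a$obs, pre, cfg$sort_order)
        add_event(time_s, "update_inter")
        retrain(time_s)
      }
    }
    pending <<- NULL
  }

  handle_onset <- function(j, now_s) {
    onset <- ann$onset_s[j]
    qual <- vapply(alarms, function(a) a$time_s > onset - H_s && a$time_s < onset,
                   logical(1))
    if (!is.null(pending) && qual[pending]) {
      alarms[[pending]]$resolved <<- "true_positive"
      add_event(now_s, "true_positive")
      pending <<- NULL
    }
    if (!any(qual)) {                       # missed seizure: Condition B
      add_event(now_s, "missed_seizure")
      if (cfg$update_enabled) {
        lo <- onset - cfg$preonset_lo_min * 60
        hi <- onset - cfg$preonset_hi_min * 60
        idx <- which(starts >= lo - 1e-9 & starts + len <= hi + 1e-9 &
                       !vapply(feats, is.null, logical(1)))
        if (length(idx) > 0L) {
          obs <- do.call(rbind, feats[idx])
          pre <<- update_pool_pre(pre, obs, inter, cfg$sort_order)
          add_event(now_s, "update_pre")
          retrain(now_s)
        }
        skip_until <<- max(skip_until,
                           ann$offset_s[j] + cfg$postictal_min * 60 + H_s)
      }
    }
    onset_done[j] <<- TRUE
  }

  process_events_before <- function(now_s) {
    repeat {
      t_lapse <- if (!is.null(pending)) alarms[[pending]]$time_s + H_s else Inf
      j <- which(!onset_done & ann$onset_s <= now_s)
      t_on <- if (length(j) > 0L) ann$onset_s[j[1L]] else Inf
      if (t_lapse >= now_s && t_on >= now_s) break
      if (t_lapse < t_on) resolve_false(t_lapse)
      else handle_onset(j[1L], t_on)
    }
  }

  for (w in seq_len(k)) {
    s <- starts[w]
    e <- s + len
    process_events_before(e)
    in_skip <- s < skip_until - 1e-9 ||
      (nrow(base_skips) > 0L &&
         any(s < base_skips[, 2L] - 1e-9 & e > base_skips[, 1L] + 1e-9))
    if (in_skip) {
      buffer <- integer(0); buffer_idx <- integer(0)
      prev_end <- e
      next
    }
    f <- NULL
    if (need_features) {
      i0 <- as.integer(round(s * rec$fs)) + 1L
      ws <- as.integer(round(len * rec$fs))
      seg <- structure(list(start_s = s,
                            data = rec$data[i0:(i0 + ws - 1L), , drop = FALSE],
                            fs = rec$fs, label = "unlabeled"),
                       class = "segment")
      f <- extract_features(seg, feature_hidden, fpar, cfg$max_imf)
      feats[[w]] <- as.numeric(f)
    }
    dec <- if (!is.null(classify_fun)) as.integer(classify_fun(s, f))
           else classify(model, f)
    decisions[w] <- dec
    buffer <- c(buffer, dec); buffer_idx <- c(buffer_idx, w)
    if (length(buffer) > buf_n) {
      buffer <- buffer[-1L]; buffer_idx <- buffer_idx[-1L]
    }
    if (length(buffer) == buf_n) {
      den <- preictal_density(buffer)
      densities[w] <- den
      if (is.null(pending) && step_alarm(den, cfg$gamma)) {
        obs <- if (need_features) do.call(rbind, feats[buffer_idx]) else NULL
        alarms[[length(alarms) + 1L]] <- list(time_s = e, density = den,
                                              resolved = "pending", obs = obs)
        pending <- length(alarms)
        add_event(e, "alarm")
      }
    }
    if (verbose && w %% 200L == 0L)
      message("  window ", w, "/", k, " (t=", round(e), " s)")
    prev_end <- e
  }

  # end-of-stream: remaining onsets, then any pending alarm
  process_events_before(t1 + 1e-9)
  if (!is.null(pending)) {
    if (alarms[[pending]]$time_s + H_s <= t1) resolve_false(t1)
    else {
      # horizon extends past the stream: no seizure was observed, so the
      # alarm is closed out as a false alarm without a Condition-A update
      alarms[[pending]]$resolved <- "false_alarm"
      add_event(t1, "false_alarm")
      pending <- NULL
    }
  }

  alarms_df <- if (length(alarms) > 0L)
    data.frame(time_s = vapply(alarms, `[[`, numeric(1), "time_s"),
               density = vapply(alarms, `[[`, numeric(1), "density"),
               resolved = vapply(alarms, `[[`, character(1), "resolved"))
  else data.frame(time_s = numeric(0), density = numeric(0), resolved = character(0))
  events_df <- if (length(events) > 0L)
    data.frame(time_s = vapply(events, `[[`, numeric(1), "time_s"),
               type = vapply(events, `[[`, character(1), "type"))
  else data.frame(time_s = numeric(0), type = character(0))

  structure(list(windows = data.frame(start_s = starts, end_s = starts + len,
                                      decision = decisions, density = densities),
                 alarms = alarms_df, events = events_df,
                 pools = list(pre = pre, inter = inter), model = model,
                 span = c(t0, t1), annotations = ann, config = cfg),
            class = "prediction_log")
}

#' @export
print.prediction_log <- function(x, ...) {
  cat(sprintf("<prediction_log> span %.0f-%.0f s, %d windows, %d alarm(s) [%s]\n",
              x$span[1L], x$span[2L], nrow(x$windows), nrow(x$alarms),
              paste(x$alarms$resolved, collapse = ", ")))
  invisible(x)
}
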