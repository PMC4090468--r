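#' HHT-ELM feature vector of one window
#'
#' Runs the one-step phase prediction that defines the per-window feature:
#' the multichannel phase matrix of the segment (see [window_phases()]) is
#' regressed one sample ahead by an ELM with a shared random hidden layer,
#' and the fitted output-weight matrix `B`, flattened row-major, is the
#' feature vector.  The hidden layer must be created once per run and shared
#' across windows, otherwise output weights from different windows would live
#' in different random bases and be incomparable.
#'
#' @param segment a `segment` (or matrix with `fs`).
#' @param hidden shared hidden layer from [elm_init_hidden()] with input
#'   dimension `d * max_imf`.
#' @param params [elm_params()] for the feature ELM (default `L = 10`,
#'   no ridge).
#' @param max_imf IMFs per channel (default 3).
#' @param fs sampling rate for bare matrices.
#' @return numeric feature vector of length `L * d * max_imf`, with
#'   attributes `window_start_s` and `label` when the input is a segment.
#' @export
extract_features <- function(segment, hidden, params = elm_params(L = 10),
                             max_imf = 3L, fs = NULL) {
  phi <- window_phases(segment, max_imf = max_imf, fs = fs)
  T_len <- nrow(phi)
  if (T_len < 2L) stop_validation("window must contain at least 2 samples")
  S <- phi[-T_len, , drop = FALSE]
  O <- phi[-1L, , drop = FALSE]
  model <- elm_fit(S, O, params, hidden = hidden)
  v <- as.vector(t(model$B))
  if (inherits(segment, "segment")) {
    attr(v, "window_start_s") <- segment$start_s
    attr(v, "label") <- segment$label
  }
  v
}

#' Feature matrix of a list of windows
#'
#' @param segments non-empty list of segments.
#' @param hidden shared hidden layer (see [extract_features()]).
#' @param params,max_imf passed to [extract_features()].
#' @param verbose print progress every 100 windows.
#' @return list with `features` (one row per segment, order preserved),
#'   `start_s`, `label`.
#' @export
extract_feature_batch <- function(segments, hidden, params = elm_params(L = 10),
                                  max_imf = 3L, verbose = FALSE) {
  if (length(segments) == 0L) stop_validation("empty segment list")
  rows <- vector("list", length(segments))
  for (i in seq_along(segments)) {
    rows[[i]] <- tryCatch(
      extract_features(segments[[i]], hidden, params, max_imf),
      error = function(e) stop("feature extraction failed at window ", i, ": ",
                               conditionMessage(e)))
    if (verbose && i %% 100L == 0L)
      message("  extracted ", i, "/", length(segments), " windows")
  }
  list(features = do.call(rbind, lapply(rows, as.numeric)),
       start_s = vapply(segments, function(s) s$start_s, numeric(1)),
       label = vapply(segments, function(s) s$label, character(1)))
}

#' Persist / load a feature table as CSV
#'
#' The table layout is `window_start_s`, `label`, then one column per feature
#' component (`f1`, `f2`, ...).
#'
#' @param batch a list with `features`, `start_s`, `label` (an
#'   [extract_feature_batch()] result).
#' @param path CSV path.
#' @return `read_features` returns a batch-shaped list; `write_features`
#'   returns `path` invisibly.
#' @export
write_features <- function(batch, path) {
  df <- as.data.frame(batch$features)
  names(df) <- paste0("f", seq_len(ncol(df)))
  out <- cbind(data.frame(window_start_s = batch$start_s, label = batch$label),
               df)
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  list(features = as.matrix(df[, -(1:2), drop = FALSE]),
       start_s = df$window_start_s, label = df$label)
}
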