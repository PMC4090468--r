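#' Multichannel EEG recording
#'
#' Container for a multichannel time series with sampling rate, optional
#' seizure annotations and a patient identifier.  Times are 0-based seconds
#' from the start of the recording.
#'
#' @param data numeric matrix, samples in rows, channels in columns (microvolts).
#' @param fs sampling rate in Hz.
#' @param channel_names optional character vector, one name per channel.
#' @param annotations data frame with columns `onset_s`, `offset_s`; sorted by
#'   onset, non-overlapping, contained within the recording span.
#' @param patient_id string identifier.
#' @return an object of class `recording`.
#' @export
recording <- function(data, fs, channel_names = NULL,
                      annotations = empty_annotations(), patient_id = "unknown") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is_scalar_num(fs) || fs <= 0) stop_validation("fs must be a positive number")
  if (ncol(data) < 2L) stop_validation("a recording needs at least 2 channels")
  if (any(!is.finite(data)))
    stop_validation("recording contains non-finite values (first at row ",
                    which(!is.finite(data))[1L] %% nrow(data), ")")
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(ncol(data)))
  annotations <- validate_annotations(annotations, nrow(data) / fs)
  structure(list(data = data, fs = fs, channel_names = as.character(channel_names),
                 annotations = annotations, patient_id = patient_id),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> patient=%s  %d samples x %d channels @ %g Hz (%.1f min), %d seizure(s)\n",
              x$patient_id, nrow(x$data), ncol(x$data), x$fs,
              nrow(x$data) / x$fs / 60, nrow(x$annotations)))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec a `recording`.
#' @return duration in seconds.
#' @export
duration_s <- function(rec) nrow(rec$data) / rec$fs

empty_annotations <- function() {
  data.frame(onset_s = numeric(0), offset_s = numeric(0))
}

validate_annotations <- function(ann, duration = Inf) {
  if (is.null(ann)) return(empty_annotations())
  ann <- as.data.frame(ann)
  if (nrow(ann) == 0L) return(empty_annotations())
  if (!all(c("onset_s", "offset_s") %in% names(ann)))
    stop_validation("annotations need columns onset_s and offset_s")
  ann <- ann[order(ann$onset_s), c("onset_s", "offset_s"), drop = FALSE]
  rownames(ann) <- NULL
  if (any(ann$onset_s < 0) || any(ann$offset_s <= ann$onset_s))
    stop_validation("annotations must satisfy 0 <= onset_s < offset_s")
  if (any(ann$offset_s > duration + 1e-9))
    stop_validation("annotation extends past the end of the recording")
  if (nrow(ann) > 1L && any(ann$onset_s[-1L] < ann$offset_s[-nrow(ann)]))
    stop_validation("annotations overlap")
  ann
}

#' Read a recording from CSV (one header row of channel names, one column per
#' channel) plus an optional annotation CSV with columns `onset_s`, `offset_s`.
#'
#' @param path path to the signal file.
#' @param fs sampling rate in Hz (CSV carries no rate, so it must be supplied;
#'   ignored for EDF, which encodes it).
#' @param annotations_path optional path to the annotation CSV.
#' @param patient_id string identifier.
#' @param format `"csv"` (canonical) or `"edf"` (see [read_edf_recording()]);
#'   inferred from the file extension by default.
#' @return a [recording()].
#' @export
read_recording <- function(path, fs = NULL, annotations_path = NULL,
                           patient_id = "unknown", format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  format <- match.arg(format, c("csv", "edf"))
  if (format == "edf")
    return(read_edf_recording(path, annotations_path,
                              if (identical(patient_id, "unknown")) NULL
                              else patient_id))
  if (is.null(fs)) stop_validation("fs must be supplied for CSV recordings")
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  m <- as.matrix(dt)
  suppressWarnings(storage.mode(m) <- "double")
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop_validation("non-numeric or non-finite value at data row ", bad[1L, 1L],
                    ", column '", colnames(dt)[bad[1L, 2L]], "' of ", path)
  ann <- if (!is.null(annotations_path)) read_annotations(annotations_path)
         else empty_annotations()
  recording(m, fs, channel_names = colnames(dt), annotations = ann,
            patient_id = patient_id)
}

#' Read seizure annotations (CSV with columns `onset_s`, `offset_s`)
#' @param path path to the annotation CSV.
#' @return data frame with columns `onset_s`, `offset_s`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  validate_annotations(data.table::fread(path, data.table = FALSE))
}

#' Write a recording (and its annotations) to CSV
#' @param rec a `recording`.
#' @param path output path for the signal CSV.
#' @param annotations_path optional output path for the annotation CSV.
#' @return `rec`, invisibly.
#' @export
write_recording <- function(rec, path, annotations_path = NULL) {
  df <- as.data.frame(rec$data)
  names(df) <- rec$channel_names
  data.table::fwrite(df, path)
  if (!is.null(annotations_path))
    data.table::fwrite(rec$annotations, annotations_path)
  invisible(rec)
}

#' Zero-phase power-line notch filter
#'
#' Second-order IIR notch (quality factor `q`) applied forward-backward with
#' [signal::filtfilt()], so there is no group delay and annotation times stay
#' aligned with the filtered samples.
#'
#' @param rec a `recording`.
#' @param f0 notch frequency in Hz (default 50, the mains frequency).
#' @param q quality factor; the -3 dB notch width is about `f0/q` Hz.
#' @return the filtered `recording`.
#' @export
notch_filter <- function(rec, f0 = 50, q = 30) {
  if (rec$fs <= 2 * f0)
    stop_config("sampling rate (", rec$fs, " Hz) must exceed twice the notch frequency")
  w0 <- 2 * pi * f0 / rec$fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  out <- rec
  for (j in seq_len(ncol(rec$data)))
    out$data[, j] <- signal::filtfilt(b, a, rec$data[, j])
  out
}

#' Window specification
#' @param length_s window length in seconds (default 10).
#' @param overlap_frac overlap fraction in `[0, 1)` (default 0.5).
#' @return an object of class `window_spec` with the derived `step_s`.
#' @export
window_spec <- function(length_s = 10, overlap_frac = 0.5) {
  if (!is_scalar_num(length_s) || length_s <= 0) stop_validation("length_s must be > 0")
  if (!is_scalar_num(overlap_frac) || overlap_frac < 0 || overlap_frac >= 1)
    stop_validation("overlap_frac must lie in [0, 1)")
  structure(list(length_s = length_s, overlap_frac = overlap_frac,
                 step_s = length_s * (1 - overlap_frac)),
            class = "window_spec")
}

#' Number of whole windows fitting in a span
#' @param span_s span length in seconds.
#' @param spec a [window_spec()].
#' @return integer window count.
#' @export
n_windows <- function(span_s, spec) {
  if (span_s < spec$length_s - 1e-9) return(0L)
  as.integer(floor((span_s - spec$length_s) / spec$step_s + 1e-9)) + 1L
}

#' Segment a recording into overlapping windows
#'
#' Windows start at `t0, t0 + step, ...` and are emitted only if they fit
#' entirely inside `[t0, t1]` (windows crossing `t1` are dropped, not
#' truncated).
#'
#' @param rec a `recording`.
#' @param spec a [window_spec()].
#' @param t0,t1 span to segment, seconds from the recording start; `t1`
#'   defaults to the recording duration.
#' @return list of `segment` objects (fields `start_s`, `data`, `label`).
#' @export
segment_windows <- function(rec, spec = window_spec(), t0 = 0, t1 = NULL) {
  if (is.null(t1)) t1 <- duration_s(rec)
  if (t0 < 0 || t0 >= t1 || t1 > duration_s(rec) + 1e-9)
    stop_validation("need 0 <= t0 < t1 <= duration")
  k <- n_windows(t1 - t0, spec)
  if (k == 0L) return(list())
  ws <- as.integer(round(spec$length_s * rec$fs))
  lapply(seq_len(k) - 1L, function(i) {
    start_s <- t0 + i * spec$step_s
    i0 <- as.integer(round(start_s * rec$fs)) + 1L
    structure(list(start_s = start_s,
                   data = rec$data[i0:(i0 + ws - 1L), , drop = FALSE],
                   fs = rec$fs, label = "unlabeled"),
              class = "segment")
  })
}

#' Label windows as preictal / interictal / ictal
#'
#' A window is `ictal` if it overlaps any annotated `[onset, offset]` (ictal
#' takes precedence), `preictal` if it ends within `(onset - preictal_span_s,
#' onset]`, and `interictal` otherwise.
#'
#' @param segments list of segments from [segment_windows()].
#' @param annotations annotation data frame (`onset_s`, `offset_s`).
#' @param preictal_span_s length of the preictal period before each onset, s.
#' @return the segments with labels filled in.
#' @export
label_windows <- function(segments, annotations, preictal_span_s) {
  if (!is_scalar_num(preictal_span_s) || preictal_span_s <= 0)
    stop_validation("preictal_span_s must be > 0")
  ann <- validate_annotations(annotations)
  lapply(segments, function(seg) {
    s <- seg$start_s
    e <- s + nrow(seg$data) / seg$fs
    lab <- "interictal"
    if (nrow(ann) > 0L) {
      if (any(s < ann$offset_s & e > ann$onset_s)) lab <- "ictal"
      else if (any(e > ann$onset_s - preictal_span_s & e <= ann$onset_s)) lab <- "preictal"
    }
    seg$label <- lab
    seg
  })
}
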