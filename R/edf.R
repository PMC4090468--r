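# Minimal European Data Format (EDF) support: continuous recordings with the
# same sampling rate on every signal.  EDF is a fixed-layout binary format
# (256-byte main header, 256 bytes per signal of field blocks, then 16-bit
# little-endian samples grouped record by record).

read_edf_header <- function(con) {
  fld <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  h <- list(version = fld(8), patient = fld(80), recording = fld(80),
            startdate = fld(8), starttime = fld(8),
            header_bytes = as.integer(fld(8)))
  fld(44)                                   # reserved
  h$n_records <- as.integer(fld(8))
  h$record_dur_s <- as.numeric(fld(8))
  ns <- as.integer(fld(4))
  sig <- function(n) vapply(seq_len(ns), function(i) fld(n), character(1))
  h$label <- sig(16)
  sig(80)                                   # transducer
  h$dim <- sig(8)
  h$phys_min <- as.numeric(sig(8))
  h$phys_max <- as.numeric(sig(8))
  h$dig_min <- as.numeric(sig(8))
  h$dig_max <- as.numeric(sig(8))
  sig(80)                                   # prefiltering
  h$samples_per_record <- as.integer(sig(8))
  sig(32)                                   # reserved
  h$n_signals <- ns
  h
}

#' Read an EDF recording
#'
#' Supports continuous EDF files in which every signal shares one sampling
#' rate (the layout used for the digitized EEG this package consumes).
#' Digital values are rescaled to physical units per signal.
#'
#' @param path path to the `.edf` file.
#' @param annotations_path optional annotation CSV (`onset_s`, `offset_s`).
#' @param patient_id defaults to the EDF patient field.
#' @return a [recording()].
#' @export
read_edf_recording <- function(path, annotations_path = NULL, patient_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  if (length(unique(h$samples_per_record)) != 1L)
    stop_validation("EDF signals with differing sampling rates are not supported")
  spr <- h$samples_per_record[1L]
  fs <- spr / h$record_dur_s
  n <- h$n_records * spr
  ns <- h$n_signals
  out <- matrix(0, nrow = n, ncol = ns)
  scale <- (h$phys_max - h$phys_min) / (h$dig_max - h$dig_min)
  for (r in seq_len(h$n_records)) {
    block <- readBin(con, "integer", n = spr * ns, size = 2L, signed = TRUE,
                     endian = "little")
    rows <- ((r - 1L) * spr + 1L):(r * spr)
    for (j in seq_len(ns))
      out[rows, j] <- (block[((j - 1L) * spr + 1L):(j * spr)] - h$dig_min[j]) *
        scale[j] + h$phys_min[j]
  }
  ann <- if (!is.null(annotations_path)) read_annotations(annotations_path)
         else empty_annotations()
  if (is.null(patient_id))
    patient_id <- if (nzchar(h$patient)) h$patient else "unknown"
  recording(out, fs, channel_names = h$label, annotations = ann,
            patient_id = patient_id)
}
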