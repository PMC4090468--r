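#' Configuration of the synthetic EEG generator
#'
#' The generator emulates the features the pipeline is built to detect:
#' per-channel narrowband oscillators with weak inter-channel phase coupling
#' at baseline, a linear coupling ramp over the preictal period before each
#' annotated onset (the preictal synchronization the feature extractor keys
#' on), a high-amplitude common-rhythm ictal discharge, 50 Hz line
#' contamination, white noise, and an optional slow drift of the interictal
#' spectral content.
#'
#' @param d number of channels (default 6).
#' @param fs sampling rate in Hz (default 256).
#' @param duration_min recording length in minutes.
#' @param seizure_onsets_min onset times in minutes (sorted).
#' @param preictal_ramp_min length of the coupling ramp before each onset
#'   (default 30).
#' @param ictal_len_s length of each ictal discharge in seconds (default 60).
#' @param base_freqs_hz per-channel oscillator frequencies (defaults evenly
#'   spread over 6-12 Hz).
#' @param coupling_inter,coupling_pre dimensionless phase-coupling strengths
#'   at baseline and at full preictal synchronization (defaults 0.05 / 0.8).
#' @param coupling_scale_hz converts the dimensionless coupling to a pull
#'   rate of `coupling * 2 * pi * coupling_scale_hz` rad/s (default 5 Hz, so
#'   the full preictal pull exceeds the largest oscillator detuning while the
#'   baseline pull does not).
#' @param amplitude_uv oscillator amplitude in microvolts (default 50).
#' @param line_amp 50 Hz line amplitude in microvolts (default 10).
#' @param drift_rate slow shift of all oscillator frequencies, Hz per hour
#'   (default 0).
#' @param noise_sd white-noise standard deviation in microvolts (default 5).
#' @param phase_noise_sd phase diffusion, rad per sqrt(second) (default 1.5).
#' @param seed RNG seed.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(d = 6L, fs = 256, duration_min = 30,
                         seizure_onsets_min = numeric(0),
                         preictal_ramp_min = 30, ictal_len_s = 60,
                         base_freqs_hz = NULL,
                         coupling_inter = 0.05, coupling_pre = 0.8,
                         coupling_scale_hz = 5, amplitude_uv = 50,
                         line_amp = 10, drift_rate = 0, noise_sd = 5,
                         phase_noise_sd = 1.5, seed = 1L) {
  if (is.null(base_freqs_hz)) base_freqs_hz <- seq(6, 12, length.out = d)
  if (length(base_freqs_hz) != d) stop_validation("need one base frequency per channel")
  if (coupling_pre <= coupling_inter)
    stop_validation("coupling_pre must exceed coupling_inter")
  onsets <- sort(as.numeric(seizure_onsets_min))
  if (any(onsets * 60 + ictal_len_s > duration_min * 60))
    stop_validation("seizure extends beyond the recording duration")
  if (length(onsets) > 1L && any(diff(onsets) * 60 < preictal_ramp_min * 60 + ictal_len_s))
    stop_validation("onsets too close together for the preictal ramp")
  structure(list(d = as.integer(d), fs = fs, duration_min = duration_min,
                 seizure_onsets_min = onsets,
                 preictal_ramp_min = preictal_ramp_min,
                 ictal_len_s = ictal_len_s, base_freqs_hz = base_freqs_hz,
                 coupling_inter = coupling_inter, coupling_pre = coupling_pre,
                 coupling_scale_hz = coupling_scale_hz,
                 amplitude_uv = amplitude_uv, line_amp = line_amp,
                 drift_rate = drift_rate, noise_sd = noise_sd,
                 phase_noise_sd = phase_noise_sd, seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic multichannel EEG recording
#'
#' Integrates, per channel, a phase oscillator pulled toward a common
#' reference oscillator with a coupling gain that ramps linearly from the
#' interictal to the preictal value over the `preictal_ramp_min` before each
#' onset.  During ictal periods all channels emit a common 4 Hz rhythm at
#' four times the baseline amplitude.  Deterministic given `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @return list with `recording` (a [recording()] with annotations) and
#'   `truth` (per-sample regime labels `interictal`/`preictal`/`ictal` and
#'   the realized coupling trajectory `kappa`, rad/s).
#' @export
gen_recording <- function(cfg) {
  n <- as.integer(round(cfg$duration_min * 60 * cfg$fs))
  dt <- 1 / cfg$fs
  t_s <- (seq_len(n) - 1L) * dt
  onset_s <- cfg$seizure_onsets_min * 60
  offset_s <- onset_s + cfg$ictal_len_s

  kappa_dimless <- rep(cfg$coupling_inter, n)
  regime <- rep("interictal", n)
  for (j in seq_along(onset_s)) {
    ramp <- t_s >= onset_s[j] - cfg$preictal_ramp_min * 60 & t_s < onset_s[j]
    frac <- (t_s[ramp] - (onset_s[j] - cfg$preictal_ramp_min * 60)) /
      (cfg$preictal_ramp_min * 60)
    kappa_dimless[ramp] <- cfg$coupling_inter +
      frac * (cfg$coupling_pre - cfg$coupling_inter)
    regime[ramp] <- "preictal"
    ict <- t_s >= onset_s[j] & t_s < offset_s[j]
    regime[ict] <- "ictal"
  }
  kappa <- kappa_dimless * 2 * pi * cfg$coupling_scale_hz
  ictal <- regime == "ictal"
  amp_scale <- ifelse(ictal, 4, 1)

  m <- with_seed(cfg$seed,
    gen_signal_cpp(n, dt, cfg$base_freqs_hz, cfg$drift_rate, kappa,
                   mean(cfg$base_freqs_hz), cfg$phase_noise_sd, amp_scale,
                   cfg$amplitude_uv, 0.3, cfg$line_amp, 50, cfg$noise_sd,
                   ictal, 4))
  ann <- data.frame(onset_s = onset_s, offset_s = offset_s)
  rec <- recording(m, cfg$fs, annotations = ann,
                   patient_id = paste0("synth-", cfg$seed))
  list(recording = rec,
       truth = list(regime = regime, kappa = kappa, config = cfg))
}

#' Generate a multi-seizure dataset for pool building and streaming
#'
#' Produces one single-seizure recording per seizure (onset late enough that
#' the 37.6 min of preictal data used for pool construction fit before it,
#' with an interictal tail after the postictal skip so false alarms can be
#' measured) plus one seizure-free interictal recording long enough for the
#' 150 min of non-overlapping interictal training windows.  The convention
#' mirrors the evaluation design: the first two seizures initialize the
#' preictal pool, the rest are streamed.
#'
#' @param cfg_template a [synth_config()]; its `duration_min` and
#'   `seizure_onsets_min` are overridden per recording.
#' @param n_seizures total number of seizures (>= 3).
#' @param seed dataset seed; recording `k` uses `seed * 100 + k`.
#' @param onset_min onset time within each seizure recording (default 40).
#' @param tail_min interictal tail after the seizure (default 45, so streamed
#'   runs retain measurable interictal time after the postictal skip).
#' @param interictal_min length of the seizure-free recording (default 155).
#' @return list with `seizure_runs` (list of [gen_recording()] results) and
#'   `interictal` (one [gen_recording()] result).
#' @export
gen_dataset <- function(cfg_template, n_seizures, seed = cfg_template$seed,
                        onset_min = 40, tail_min = 45, interictal_min = 155) {
  if (n_seizures < 3L) stop_validation("need at least 3 seizures (2 train + 1 test)")
  if (onset_min <= 0) stop_validation("onset_min must be positive")
  seizure_runs <- lapply(seq_len(n_seizures), function(k) {
    cfg <- synth_config_modify(cfg_template,
      duration_min = onset_min + cfg_template$ictal_len_s / 60 + tail_min,
      seizure_onsets_min = onset_min,
      seed = as.integer(seed * 100 + k))
    gen_recording(cfg)
  })
  cfg_i <- synth_config_modify(cfg_template, duration_min = interictal_min,
                               seizure_onsets_min = numeric(0),
                               seed = as.integer(seed * 100))
  list(seizure_runs = seizure_runs, interictal = gen_recording(cfg_i))
}

#' Derive a modified copy of a synthetic-generator configuration
#' @param cfg a [synth_config()].
#' @param ... fields to override.
#' @return a revalidated [synth_config()].
#' @export
synth_config_modify <- function(cfg, ...) {
  do.call(synth_config, utils::modifyList(unclass(cfg), list(...)))
}
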