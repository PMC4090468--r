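#' One sifting pass of empirical mode decomposition
#'
#' Computes upper and lower envelopes as natural cubic splines through the
#' interior maxima and minima (mirror-extended by two extrema at each end),
#' and subtracts their mean from the signal.
#'
#' @param x numeric series of length >= 4.
#' @return list with `detail` (`x` minus the mean envelope) and `mean_env`;
#'   `detail + mean_env` reproduces `x` exactly.  Signals with fewer than two
#'   interior maxima or minima raise a condition of class
#'   `seizpred_monotonic` (the caller stops decomposing).
#' @export
sift_once <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 4L) stop_validation("series too short to sift")
  if (all(x == x[1L])) stop_monotonic("constant series has no extrema")
  res <- sift_once_cpp(x)
  if (res$status == 1L)
    stop_monotonic("fewer than 2 interior maxima or minima; series is monotonic-like")
  list(detail = res$detail, mean_env = res$mean_env)
}

#' Empirical mode decomposition
#'
#' Decomposes `x` into intrinsic mode functions (IMFs) by iterated sifting.
#' Sifting of each IMF stops when the relative change between consecutive
#' sift iterates drops below `sd_tol` and the IMF criteria hold (extrema
#' counts balanced within one, zero crossings within one of the extrema
#' count), or after `max_sift` passes.  The residual is defined by
#' subtraction, so `Reduce("+", imfs) + residual` reconstructs `x` exactly.
#'
#' @param x finite numeric series, length >= 16.
#' @param max_imf maximum number of IMFs to extract.
#' @param sd_tol sifting stop tolerance (default 0.25).
#' @param max_sift maximum sift passes per IMF (default 100).
#' @return object of class `imf_decomposition`: list with `imfs` (list of
#'   series, possibly empty), `residual`, `sift_counts`.
#' @export
emd <- function(x, max_imf = 10L, sd_tol = 0.25, max_sift = 100L) {
  x <- as.numeric(x)
  if (length(x) < 16L) stop_validation("series too short for EMD (need >= 16 samples)")
  if (any(!is.finite(x))) stop_validation("series contains non-finite values")
  res <- emd_cpp(x, as.integer(max_imf), sd_tol, as.integer(max_sift))
  structure(list(imfs = res$imfs, residual = res$residual,
                 sift_counts = res$sift_counts),
            class = "imf_decomposition")
}

#' @export
print.imf_decomposition <- function(x, ...) {
  cat(sprintf("<imf_decomposition> %d IMF(s), %d samples\n",
              length(x$imfs), length(x$residual)))
  invisible(x)
}

# discrete Hilbert transform via the frequency-domain method
hilbert_transform <- function(x) {
  n <- length(x)
  Im(fft(fft(x) * hilbert_weights(n), inverse = TRUE) / n)
}

#' Analytic signal of an IMF: instantaneous amplitude, phase and frequency
#'
#' Forms the analytic signal `imf + i H[imf]` by the frequency-domain Hilbert
#' transform.  The phase is the four-quadrant arctangent wrapped to
#' `(-pi, pi]`; the instantaneous angular frequency is the discrete derivative
#' of the unwrapped phase (central differences in the interior, one-sided at
#' the ends), in rad/s.
#'
#' @param imf numeric series, length >= 8.
#' @param fs sampling rate in Hz.
#' @return object of class `analytic_series`: list with `amplitude`, `phase`,
#'   `frequency`.
#' @export
analytic <- function(imf, fs) {
  imf <- as.numeric(imf)
  if (length(imf) < 8L) stop_validation("series too short for the Hilbert transform")
  h <- hilbert_transform(imf)
  amplitude <- sqrt(imf^2 + h^2)
  phase <- wrap_phase(atan2(h, imf))
  phi_u <- unwrap_phase(phase)
  n <- length(phi_u)
  freq <- numeric(n)
  freq[2:(n - 1L)] <- (phi_u[3:n] - phi_u[1:(n - 2L)]) / 2
  freq[1L] <- phi_u[2L] - phi_u[1L]
  freq[n] <- phi_u[n] - phi_u[n - 1L]
  structure(list(amplitude = amplitude, phase = phase, frequency = freq * fs),
            class = "analytic_series")
}

# unwrap a wrapped phase series (remove 2*pi jumps)
unwrap_phase <- function(phi) {
  d <- diff(phi)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(phi[1L], phi[1L] + cumsum(d))
}

#' Per-window multichannel phase matrix
#'
#' For each channel of the segment: EMD with at most `max_imf` IMFs, then the
#' Hilbert instantaneous phase of each IMF.  Columns are channel-major
#' (ch1/imf1, ch1/imf2, ..., ch2/imf1, ...).  Channels yielding fewer than
#' `max_imf` IMFs (including constant channels, which yield none) have the
#' missing columns zero-filled, so the matrix shape is fixed across windows.
#'
#' @param segment a `segment` (from [segment_windows()]) or a numeric matrix
#'   (samples x channels); in the latter case `fs` must be given.
#' @param max_imf IMFs per channel (default 3).
#' @param fs sampling rate, taken from the segment when available.
#' @return numeric matrix, `window_samples` x `(d * max_imf)`.
#' @export
window_phases <- function(segment, max_imf = 3L, fs = NULL) {
  if (inherits(segment, "segment")) {
    m <- segment$data
    fs <- segment$fs
  } else {
    m <- as.matrix(segment)
    if (is.null(fs)) stop_validation("fs must be supplied for a bare matrix")
  }
  d <- ncol(m)
  if (d < 2L) stop_validation("need at least 2 channels")
  n <- nrow(m)
  out <- matrix(0, nrow = n, ncol = d * max_imf)
  cols <- integer(0)
  imfs <- list()
  for (j in seq_len(d)) {
    xj <- m[, j]
    if (all(xj == xj[1L])) next  # constant channel: columns stay zero
    dec <- emd(xj, max_imf = max_imf)
    for (k in seq_along(dec$imfs)) {
      imf <- dec$imfs[[k]]
      if (all(imf == 0)) next
      cols <- c(cols, (j - 1L) * max_imf + k)
      imfs[[length(imfs) + 1L]] <- imf
    }
  }
  if (length(cols) == 0L) return(out)
  # batched Hilbert phases: one forward/inverse FFT over all IMFs at once
  im <- do.call(cbind, imfs)
  u <- hilbert_weights(n)
  h <- Im(stats::mvfft(stats::mvfft(im) * u, inverse = TRUE) / n)
  out[, cols] <- wrap_phase(atan2(h, im))
  out
}

# atan2 returns [-pi, pi]; the phase convention here is (-pi, pi]
wrap_phase <- function(phi) {
  phi[phi <= -pi] <- pi
  phi
}

hilbert_weights <- function(n) {
  u <- numeric(n)
  if (n %% 2L == 0L) {
    u[1L] <- 1; u[n / 2L + 1L] <- 1
    u[2:(n / 2L)] <- 2
  } else {
    u[1L] <- 1
    u[2:((n + 1L) / 2L)] <- 2
  }
  u
}
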