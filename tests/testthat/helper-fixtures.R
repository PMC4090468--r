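# shared fixtures, all generated in code

tone <- function(freq, fs = 256, dur_s = 4, phase = 0, amp = 1) {
  amp * cos(2 * pi * freq * seq_len(round(dur_s * fs)) / fs + phase)
}

interior <- function(n, frac = 0.8) {
  lo <- ceiling(n * (1 - frac) / 2)
  seq(lo, n - lo)
}

# tiny 2-channel recording with optional annotations, deterministic
tiny_recording <- function(dur_s = 600, fs = 32, d = 2, seed = 1,
                           annotations = NULL) {
  set.seed(seed)
  t <- seq_len(dur_s * fs) / fs
  m <- sapply(seq_len(d), function(j)
    cos(2 * pi * (5 + j) * t) + 0.3 * cos(2 * pi * 13 * t + j) +
      0.2 * rnorm(length(t)))
  recording(m, fs, annotations = annotations)
}

# independent quadrature-filter Hilbert oracle for tones:
# H[cos(w t + p)] = sin(w t + p) = cos(w t + p - pi/2)
quadrature_tone <- function(freq, fs, dur_s, phase = 0, amp = 1) {
  amp * sin(2 * pi * freq * seq_len(round(dur_s * fs)) / fs + phase)
}

# two small, well-separated feature pools for classifier/pool tests
toy_pools <- function(n = 40, p = 6, gap = 4, seed = 1) {
  set.seed(seed)
  pre <- matrix(rnorm(n * p, mean = gap), n, p)
  inter <- matrix(rnorm(n * p, mean = 0), n, p)
  list(pre = sample_pool(pre, role = "pre"),
       inter = sample_pool(inter, role = "inter"))
}

# brute-force window count by enumerating start times
count_windows_brute <- function(span, len, step) {
  n <- 0L
  s <- 0
  while (s + len <= span + 1e-9) {
    n <- n + 1L
    s <- s + step
  }
  n
}
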