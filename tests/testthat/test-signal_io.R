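test_that("CSV recordings parse, reject bad cells, and round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2", "3,4", "5,6"), path)
  rec <- read_recording(path, fs = 4)
  expect_equal(dim(rec$data), c(3L, 2L))
  expect_equal(rec$channel_names, c("a", "b"))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2", "NaN,4", "5,6"), bad)
  expect_error(read_recording(bad, fs = 4), "row 2", class = "seizpred_validation")

  set.seed(3)
  rec2 <- recording(matrix(rnorm(600), ncol = 3), fs = 20,
                    annotations = data.frame(onset_s = 3, offset_s = 5))
  sig <- withr::local_tempfile(fileext = ".csv")
  ann <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec2, sig, ann)
  back <- read_recording(sig, fs = 20, annotations_path = ann)
  expect_lt(max(abs(back$data - rec2$data)), 1e-9)
  expect_equal(back$annotations, rec2$annotations)
})

test_that("EDF recordings parse back to the signal that was encoded", {
  # write a tiny 2-signal EDF by hand (independent encoder oracle)
  fs <- 32; n_rec <- 3L; spr <- fs
  set.seed(4)
  x <- matrix(round(runif(fs * n_rec * 2, -500, 500)), ncol = 2)  # digital units
  path <- withr::local_tempfile(fileext = ".edf")
  con <- file(path, "wb")
  pad <- function(s, n) writeChar(formatC(s, width = -n), con, n, eos = NULL)
  pad("0", 8); pad("test patient", 80); pad("test rec", 80)
  pad("01.01.24", 8); pad("00.00.00", 8); pad(as.character(256 * 3), 8)
  pad("", 44); pad(as.character(n_rec), 8); pad("1", 8); pad("2", 4)
  for (s in c("ch1", "ch2")) pad(s, 16)
  for (i in 1:2) pad("", 80)
  for (i in 1:2) pad("uV", 8)
  for (v in c(-1000, -1000)) pad(as.character(v), 8)   # phys min
  for (v in c(1000, 1000)) pad(as.character(v), 8)     # phys max
  for (v in c(-1000, -1000)) pad(as.character(v), 8)   # dig min
  for (v in c(1000, 1000)) pad(as.character(v), 8)     # dig max
  for (i in 1:2) pad("", 80)
  for (i in 1:2) pad(as.character(spr), 8)
  for (i in 1:2) pad("", 32)
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1) * spr + 1):(r * spr)
    writeBin(as.integer(c(x[rows, 1], x[rows, 2])), con, size = 2,
             endian = "little")
  }
  close(con)

  rec <- read_recording(path)
  expect_equal(rec$fs, fs)
  expect_equal(rec$channel_names, c("ch1", "ch2"))
  # phys range == dig range here, so values round-trip exactly
  expect_equal(rec$data, x, ignore_attr = TRUE)
  expect_equal(rec$patient_id, "test patient")
})

test_that("recording and annotation invariants are enforced", {
  expect_error(recording(matrix(1:10, ncol = 1), fs = 4), "channels",
               class = "seizpred_validation")
  expect_error(recording(matrix(1:10, ncol = 2), fs = -1),
               class = "seizpred_validation")
  expect_error(recording(matrix(1:12, ncol = 2), fs = 1,
                         annotations = data.frame(onset_s = 5, offset_s = 9)),
               "past the end", class = "seizpred_validation")
  expect_error(recording(matrix(1:40, ncol = 2), fs = 1,
                         annotations = data.frame(onset_s = c(1, 3),
                                                  offset_s = c(4, 6))),
               "overlap", class = "seizpred_validation")
})

test_that("notch filter suppresses the mains tone and spares the passband", {
  fs <- 256
  rec <- recording(cbind(tone(50, fs, 8), tone(10, fs, 8)), fs)
  out <- notch_filter(rec, 50)
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(out$data[, 1]), 0.1 * rms(rec$data[, 1]))          # >= 20 dB at f0
  expect_lt(abs(rms(out$data[, 2]) / rms(rec$data[, 2]) - 1), 0.01) # < 1% at 10 Hz

  zero <- recording(matrix(0, 1024, 2), fs)
  expect_equal(notch_filter(zero)$data, zero$data)

  # idempotence: a second pass changes the passband by < 1 dB
  twice <- notch_filter(out, 50)
  r1 <- rms(out$data[, 2]); r2 <- rms(twice$data[, 2])
  expect_lt(abs(20 * log10(r2 / r1)), 1)

  expect_error(notch_filter(recording(matrix(rnorm(200), ncol = 2), fs = 90)),
               class = "seizpred_config")
})

test_that("window counts match the pool-construction arithmetic and brute force", {
  expect_identical(n_windows(2256, window_spec(10, 0.5)), 450L)
  expect_identical(n_windows(9000, window_spec(10, 0)), 900L)
  expect_identical(n_windows(9, window_spec(10, 0.5)), 0L)

  set.seed(42)
  for (i in 1:1000) {
    len <- runif(1, 0.5, 30)
    ov <- runif(1, 0, 0.9)
    span <- runif(1, 0, 400)
    spec <- window_spec(len, ov)
    expect_identical(n_windows(span, spec),
                     count_windows_brute(span, len, spec$step_s))
  }
})

test_that("segment_windows emits whole windows only, with correct starts", {
  rec <- tiny_recording(dur_s = 120, fs = 32)
  segs <- segment_windows(rec, window_spec(10, 0.5), t0 = 0, t1 = 47)
  expect_length(segs, 8L)                      # floor((47-10)/5)+1
  expect_equal(vapply(segs, `[[`, numeric(1), "start_s"), seq(0, 35, by = 5))
  expect_true(all(vapply(segs, function(s) nrow(s$data), integer(1)) == 320L))
  expect_length(segment_windows(rec, window_spec(10, 0.5), 0, 9), 0L)
})

test_that("labelling is exhaustive with ictal precedence over preictal", {
  rec <- tiny_recording(dur_s = 4000, fs = 2,
                        annotations = data.frame(onset_s = 3600, offset_s = 3660))
  segs <- segment_windows(rec, window_spec(10, 0.5), 3540, 3700)
  lab <- label_windows(segs, rec$annotations, preictal_span_s = 3000)
  labs <- vapply(lab, `[[`, character(1), "label")
  expect_true(all(labs %in% c("preictal", "interictal", "ictal")))

  # window [3550, 3560] ends inside the preictal span
  w <- which(vapply(lab, `[[`, numeric(1), "start_s") == 3550)
  expect_equal(labs[w], "preictal")
  # any window overlapping [onset, offset] is ictal, even inside the span
  overlap <- vapply(lab, function(s) s$start_s < 3660 && s$start_s + 10 > 3600,
                    logical(1))
  expect_true(all(labs[overlap] == "ictal"))
  # enumeration: exactly one class per window
  expect_equal(sum(labs == "ictal") + sum(labs == "preictal") +
                 sum(labs == "interictal"), length(labs))

  none <- label_windows(segs, NULL, preictal_span_s = 3000)
  expect_true(all(vapply(none, `[[`, character(1), "label") == "interictal"))
})
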