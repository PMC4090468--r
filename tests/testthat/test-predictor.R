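test_that("preictal density and the alarm rule follow their definitions", {
  expect_equal(preictal_density(c(1, 1, 1, 1, 1, 1, 1, 0, 0)), 7 / 9)
  expect_equal(preictal_density(rep(0, 5)), 0)
  expect_equal(preictal_density(rep(1, 5)), 1)
  expect_error(preictal_density(integer(0)), class = "seizpred_validation")

  expect_true(step_alarm(7 / 9, 0.7))
  expect_false(step_alarm(0.7, 0.7))     # strict inequality
  expect_true(step_alarm(0.01, 0))
})

test_that("classifier training separates toy pools and thresholds at 0.5", {
  tp <- toy_pools(n = 50, gap = 4, seed = 31)
  params <- elm_params(L = 200, seed = 31, ridge = 1e-6)
  m <- train_classifier(tp$pre, tp$inter, params)
  acc <- mean(c(classify(m, tp$pre$features) == 1,
                classify(m, tp$inter$features) == 0))
  expect_gte(acc, 0.95)

  # label swap inverts the decisions
  m_sw <- train_classifier(
    sample_pool(tp$inter$features, role = "pre"),
    sample_pool(tp$pre$features, role = "inter"), params)
  acc_sw <- mean(c(classify(m_sw, tp$pre$features) == 1,
                   classify(m_sw, tp$inter$features) == 0))
  expect_equal(acc_sw, 1 - acc, tolerance = 1e-12)

  # deterministic given the seed
  expect_identical(train_classifier(tp$pre, tp$inter, params)$B, m$B)

  # explicit threshold rule, including the boundary
  m2 <- m
  m2$B <- m$B * 0
  expect_identical(classify(m2, tp$pre$features[1, ]), 0L)  # raw 0 -> 0, not 1
})

scripted_stream <- function(decide, dur_s = 900, cfg = NULL, ann = NULL,
                            seed = 41) {
  rec <- tiny_recording(dur_s = dur_s, fs = 32, seed = seed, annotations = ann)
  if (is.null(cfg))
    cfg <- predictor_config(H_time_min = 5, update_enabled = FALSE, seed = seed)
  tp <- toy_pools(n = 20, p = 60, seed = seed)
  process_stream(rec, cfg, tp$pre, tp$inter, model = NULL,
                 classify_fun = decide)
}

test_that("alarm fires exactly when the trailing buffer first exceeds gamma", {
  # decisions: 1 for the first 17 windows (starts 0..80 s), then 0.
  # buffer (17 windows of 10 s at 5 s step inside 1.5 min) is first full at
  # the window ending at 90 s with density 1 > 0.7 -> single alarm at 90 s.
  log <- scripted_stream(function(s, f) as.integer(s <= 80))
  expect_equal(nrow(log$alarms), 1L)
  expect_equal(log$alarms$time_s, 90)
  expect_equal(log$alarms$density, 1)
  # the refractory period and falling density prevent further alarms
  expect_equal(sum(log$events$type == "alarm"), 1L)
  # horizon (5 min) lapses at 390 s with no seizure -> false alarm
  expect_equal(log$alarms$resolved, "false_alarm")
  expect_true(any(log$events$type == "false_alarm" & log$events$time_s == 390))

  # hand-traced partial density: 12 ones then zeros -> first full buffer has
  # density 12/17 > 0.7, still one alarm at 90 s
  log2 <- scripted_stream(function(s, f) as.integer(s <= 55))
  expect_equal(log2$alarms$time_s, 90)
  expect_equal(log2$alarms$density, 12 / 17)

  # 11 ones: 11/17 < 0.7 and decaying -> never alarms
  log3 <- scripted_stream(function(s, f) as.integer(s <= 50))
  expect_equal(nrow(log3$alarms), 0L)
})

test_that("a silent classifier produces no alarms and no updates", {
  log <- scripted_stream(function(s, f) 0L)
  expect_equal(nrow(log$alarms), 0L)
  expect_false(any(log$events$type %in% c("update_inter", "update_pre", "retrain")))
  expect_true(all(log$windows$decision == 0, na.rm = TRUE))
})

test_that("a pending alarm followed by an onset resolves as a true positive", {
  ann <- data.frame(onset_s = 300, offset_s = 310)
  log <- scripted_stream(function(s, f) as.integer(s <= 80), dur_s = 900,
                         ann = ann)
  expect_equal(log$alarms$resolved, "true_positive")
  expect_true(any(log$events$type == "true_positive"))
  # ictal and postictal windows are never classified
  post_end <- 310 + 10 * 60
  masked <- log$windows$start_s + 10 > 300 & log$windows$start_s < post_end
  expect_true(all(is.na(log$windows$decision[masked])))
})

test_that("a missed seizure triggers Condition B: pool update, retrain, long skip", {
  fs <- 32
  ann <- data.frame(onset_s = 720, offset_s = 730)
  rec <- tiny_recording(dur_s = 1200, fs = fs, seed = 43, annotations = ann)
  cfg <- predictor_config(H_time_min = 5, win_os_min = 1.5, postictal_min = 1,
                          preonset_lo_min = 4, preonset_hi_min = 3,
                          update_enabled = TRUE, seed = 43)
  hid <- elm_init_hidden(6, elm_params(10, seed = 43))
  segs <- segment_windows(rec, window_spec(10, 0.5), 0, 200)
  feats <- extract_feature_batch(segs, hid)$features
  pre <- sample_pool(feats[1:15, ] + 5, role = "pre")    # displaced surrogate class
  inter <- sample_pool(feats[16:38, ], role = "inter")
  model <- train_classifier(pre, inter, seizpred:::clf_params_of(cfg))

  log <- process_stream(rec, cfg, pre, inter, model, feature_hidden = hid,
                        classify_fun = function(s, f) 0L)
  expect_equal(sum(log$events$type == "missed_seizure"), 1L)
  expect_equal(sum(log$events$type == "update_pre"), 1L)
  expect_equal(sum(log$events$type == "retrain"), 1L)
  expect_false(identical(log$pools$pre$features, pre$features))
  expect_identical(log$pools$inter$features, inter$features)
  expect_false(identical(log$model$B, model$B))
  # observation resumes only at offset + postictal + H_time = 1090 s
  after <- log$windows$start_s > 720 & !is.na(log$windows$decision)
  expect_true(all(log$windows$start_s[after] >= 730 + 60 + 300))
})

test_that("a lapsed false alarm triggers Condition A when the set is normal", {
  fs <- 32
  rec <- tiny_recording(dur_s = 900, fs = fs, seed = 44)
  cfg <- predictor_config(H_time_min = 5, update_enabled = TRUE, seed = 44)
  hid <- elm_init_hidden(6, elm_params(10, seed = 44))
  segs <- segment_windows(rec, window_spec(10, 0.5), 400, 700)
  feats <- extract_feature_batch(segs, hid)$features
  pre <- sample_pool(feats[1:15, ] + 5, role = "pre")    # far from real features
  inter <- sample_pool(feats[16:45, ], role = "inter")
  model <- train_classifier(pre, inter, seizpred:::clf_params_of(cfg))

  log <- process_stream(rec, cfg, pre, inter, model, feature_hidden = hid,
                        classify_fun = function(s, f) as.integer(s <= 80))
  expect_equal(log$alarms$resolved, "false_alarm")
  expect_equal(sum(log$events$type == "update_inter"), 1L)
  expect_equal(sum(log$events$type == "retrain"), 1L)
  expect_equal(nrow(log$pools$inter$features), nrow(inter$features))
  expect_identical(log$pools$pre$features, pre$features)

  # with an abnormal observation set (features near the preictal pool is
  # emulated by swapping pool roles) no update happens
  pre2 <- sample_pool(feats[16:45, ] , role = "pre")     # near real features
  inter2 <- sample_pool(feats[1:15, ] + 5, role = "inter")
  model2 <- train_classifier(pre2, inter2, seizpred:::clf_params_of(cfg))
  log2 <- process_stream(rec, cfg, pre2, inter2, model2, feature_hidden = hid,
                         classify_fun = function(s, f) as.integer(s <= 80))
  expect_equal(sum(log2$events$type == "update_inter"), 0L)
  expect_identical(log2$pools$inter$features, inter2$features)
})

test_that("disabling updates freezes pools and model; reruns are identical", {
  ann <- data.frame(onset_s = 700, offset_s = 710)
  rec <- tiny_recording(dur_s = 900, fs = 32, seed = 45, annotations = ann)
  cfg <- predictor_config(H_time_min = 5, update_enabled = FALSE, seed = 45)
  tp <- toy_pools(n = 20, p = 60, seed = 45)
  model <- train_classifier(tp$pre, tp$inter,
                            elm_params(100, seed = 45, ridge = 1e-6))
  log <- process_stream(rec, cfg, tp$pre, tp$inter, model)
  expect_identical(log$pools$pre$features, tp$pre$features)
  expect_identical(log$pools$inter$features, tp$inter$features)
  expect_identical(log$model$B, model$B)
  expect_false(any(log$events$type %in% c("update_inter", "update_pre", "retrain")))

  log2 <- process_stream(rec, cfg, tp$pre, tp$inter, model)
  expect_identical(log$windows, log2$windows)
  expect_identical(log$alarms, log2$alarms)
  expect_identical(log$events, log2$events)
})
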