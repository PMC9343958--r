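test_that("artifact screening applies amplitude and flatline rules", {
  cfg <- synth_config(duration_s = 2, seed = 37)
  clean <- generate_recording(cfg, "water", 1, 1)
  pc <- preprocess_config()
  res <- screen_artifacts(clean, pc)
  expect_true(res$accept)
  expect_length(res$report, 0)

  spiked <- inject_artifacts(clean, 3, 500, seed = 2)
  res <- screen_artifacts(spiked, pc)
  expect_false(res$accept)
  expect_match(res$report, "amplitude", all = FALSE)

  flat <- clean
  flat$samples[] <- 0
  res <- screen_artifacts(flat, preprocess_config(flatline_run = 512))
  expect_false(res$accept)
  expect_match(res$report, "flatline", all = FALSE)

  # idempotent and side-effect-free
  before <- clean$samples
  r1 <- screen_artifacts(clean, pc)
  r2 <- screen_artifacts(clean, pc)
  expect_identical(r1, r2)
  expect_identical(clean$samples, before)
})

test_that("windowing reproduces the fractional-stride arithmetic", {
  # 16-s recording at 512 Hz, window 1028, stride 0.1 s -> 140 windows
  starts <- sweetEEG:::window_starts(8192, 1028, 0.1, 512)
  expect_length(starts, 140)
  expect_equal(starts[1:4], c(0, 51, 102, 153))  # floor(51.2 k)
  # window 1024 (the "2 s x 512 Hz" reading) gives 141, not 140
  expect_length(sweetEEG:::window_starts(8192, 1024, 0.1, 512), 141)
  # recording length == window_len -> exactly one window
  expect_length(sweetEEG:::window_starts(1028, 1028, 0.1, 512), 1)
  # 3-s recording: brute-force enumeration oracle
  expect_length(sweetEEG:::window_starts(1536, 1028, 0.1, 512),
                oracle_window_count(1536, 1028, 51.2))
})

test_that("window counts match brute-force enumeration on random configs", {
  set.seed(101)
  for (i in 1:200) {
    fs <- sample(c(128, 250, 256, 512, 1000), 1)
    n <- sample(512:16384, 1)
    wl <- sample(32:min(n, 4096), 1)
    stride_s <- runif(1, 0.01, 1.5)
    expect_length(sweetEEG:::window_starts(n, wl, stride_s, fs),
                  oracle_window_count(n, wl, stride_s * fs))
  }
})

test_that("window_recordings propagates labels, groups and both channels", {
  cfg <- synth_config(n_subjects = 2, n_sessions_per_subject = 1,
                      duration_s = 4, seed = 41)
  rs <- generate_dataset(cfg)
  pc <- preprocess_config(window_len = 256, stride_s = 0.25)
  wm <- window_recordings(rs, pc)
  per_rec <- oracle_window_count(2048, 256, 0.25 * 512)
  expect_equal(dim(wm$windows), c(8 * per_rec, 256, 2))
  expect_equal(length(wm$labels), 8 * per_rec)
  expect_equal(unique(table(wm$groups)), per_rec)
  # first window of first recording is the raw signal head, channels aligned
  expect_equal(wm$windows[1, , 1], rs$recordings[[1]]$samples[1, 1:256])
  expect_equal(wm$windows[1, , 2], rs$recordings[[1]]$samples[2, 1:256])
  # single-channel ablation mode
  wm1 <- window_recordings(rs, pc, channels = 1)
  expect_equal(dim(wm1$windows)[3], 1)
  # too-short recording is a labelled error naming the recording
  short <- rs$recordings[[1]]
  short$samples <- short$samples[, 1:100]
  expect_error(window_recordings(list(short), pc), short$recording_id)
})

test_that("normalization z-scores per window-channel and handles edge cases", {
  cfg <- synth_config(n_subjects = 1, n_sessions_per_subject = 1,
                      duration_s = 2, seed = 43)
  wm <- window_recordings(generate_dataset(cfg),
                          preprocess_config(window_len = 256, stride_s = 0.5))
  z <- normalize_windows(wm, "zscore")
  for (ch in 1:2) {
    expect_equal(max(abs(rowMeans(z$windows[, , ch]))), 0, tolerance = 1e-6)
    expect_equal(max(abs(apply(z$windows[, , ch], 1, sd) - 1)), 0,
                 tolerance = 1e-6)
  }
  # constant window maps to zeros, not NaN
  wm$windows[1, , 1] <- 7
  z <- normalize_windows(wm, "zscore")
  expect_equal(z$windows[1, , 1], rep(0, 256))
  # "none" is the identity; unknown methods are labelled errors
  expect_identical(normalize_windows(wm, "none"), wm)
  expect_error(normalize_windows(wm, "minmax"), "unknown normalization")
})

test_that("splits are stratified, disjoint, deterministic", {
  sp <- tiny_split()
  wm <- memo("tiny_wm", {
    rs <- generate_dataset(tiny_synth_config())
    preprocess(rs, tiny_preprocess_config(), screen = FALSE)$wm
  })
  n <- length(wm$labels)
  expect_setequal(c(sp$train_idx, sp$test_idx), seq_len(n))
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)
  # group mode: no recording id on both sides
  expect_length(intersect(unique(sp$train$groups), unique(sp$test$groups)), 0)
  # determinism
  sp2 <- split_windows(wm, 0.7, "group", seed = 5)
  expect_identical(sp$train_idx, sp2$train_idx)
  # segment mode: per-class floor/ceil allocation
  sg <- split_windows(wm, 0.7, "segment", seed = 8)
  for (cl in wm$class_order) {
    n_cl <- sum(wm$labels == cl)
    expect_lte(abs(sum(sg$train$labels == cl) - 0.7 * n_cl), 1)
  }
  expect_error(split_windows(wm, 1.2, "group"), "fraction")
  # absent class is a labelled error
  wm_sub <- subset_windows(wm, which(wm$labels != "water"))
  expect_error(split_windows(wm_sub, 0.7, "group"), "absent")
})

test_that("preprocess chain = screen + filter + window + normalize, in order", {
  cfg <- synth_config(n_subjects = 1, n_sessions_per_subject = 1,
                      duration_s = 4, seed = 47, artifact_rate = 0)
  rs <- generate_dataset(cfg)
  # plant one bad recording; it must be dropped with a report
  rs$recordings[[2]] <- inject_artifacts(rs$recordings[[2]], 4, 400, seed = 1)
  pc <- preprocess_config(window_len = 256, stride_s = 0.5)
  pp <- preprocess(rs, pc)
  expect_length(pp$rejected, 1)
  expect_named(pp$screen_reports, pp$rejected)
  expect_equal(length(unique(pp$wm$groups)), 3)
  # manual chain reproduces the pipeline output (fixed order: filter first)
  manual <- lapply(rs$recordings[-2], bandpass)
  wm2 <- normalize_windows(window_recordings(manual, pc), "zscore")
  expect_equal(pp$wm$windows, wm2$windows)
})
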