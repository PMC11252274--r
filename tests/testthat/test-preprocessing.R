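make_tone_rec <- function(freq, fs = 250L, dur_s = 10) {
  tt <- (0:(dur_s * fs - 1)) / fs
  x <- sin(2 * pi * freq * tt)
  structure(list(signal = matrix(rep(x, each = 8), nrow = 8),
                 fs_hz = fs, layout = channel_layout(), events = NULL,
                 session_id = "tone"), class = "raw_recording")
}

fft_amp <- function(x, freq, fs = 250) {
  n <- length(x)
  2 * abs(stats::fft(x))[round(freq * n / fs) + 1] / n
}

test_that("filtering attenuates 60 Hz by >= 30 dB and passes 10 Hz within 1 dB", {
  r60 <- make_tone_rec(60)
  f60 <- filter_raw(r60)
  att <- 20 * log10(fft_amp(f60$signal[1, ], 60) / fft_amp(r60$signal[1, ], 60))
  expect_lt(att, -30)
  r10 <- make_tone_rec(10)
  f10 <- filter_raw(r10)
  chg <- 20 * log10(fft_amp(f10$signal[1, ], 10) / fft_amp(r10$signal[1, ], 10))
  expect_lt(abs(chg), 1)
})

test_that("highpass removes a constant offset", {
  rec <- make_tone_rec(10)
  rec$signal <- rec$signal + 40
  out <- filter_raw(rec)
  expect_lt(abs(mean(out$signal[1, ])), 0.05)
})

test_that("zero-phase filtering preserves the latency of a symmetric pulse", {
  fs <- 250L
  tt <- (0:(10 * fs - 1)) / fs
  pulse <- exp(-(tt - 5)^2 / (2 * 0.05^2))       # 50 ms Gaussian at t = 5 s
  rec <- structure(list(signal = matrix(rep(pulse, each = 8), nrow = 8),
                        fs_hz = fs, layout = channel_layout(), events = NULL,
                        session_id = "p"), class = "raw_recording")
  out <- filter_raw(rec)
  expect_lte(abs(which.max(out$signal[1, ]) - which.max(pulse)), 1)
})

test_that("NaNs stay confined to their original positions through filtering", {
  s <- tiny_session()
  rec <- s$rec
  rec$signal[2, 50:55] <- NaN
  out <- filter_raw(rec)
  expect_true(all(is.nan(out$signal[2, 50:55])))
  expect_false(anyNA(out$signal[-2, ]))
  expect_false(anyNA(out$signal[2, -(50:55)]))
})

test_that("segmentation yields 500-sample stimulus-locked epochs", {
  s <- tiny_session()
  ep <- segment_trials(s$rec)
  expect_equal(dim(ep$data), c(nrow(s$events), 8L, 500L))
  expect_equal(ep$labels, s$events$class_id)
  # a unit impulse at an onset sample lands at epoch index 1 (0-based 0)
  rec <- s$rec
  rec$signal[] <- 0
  rec$signal[1, s$events$onset_sample[3] + 1L] <- 1   # 0-based onset -> R index
  ep2 <- segment_trials(rec)
  expect_equal(which(ep2$data[3, 1, ] == 1), 1L)
  # window past the end of the recording is a hard, named error
  short <- s$rec
  short$signal <- short$signal[, 1:(nrow(s$events) - 1) * s$spec$step_samps]
  expect_error(segment_trials(short), "event")
})

test_that("bad-trial detection flags crafted artifacts with the right reasons", {
  s <- tiny_session()
  art <- data.frame(trial = c(2L, 5L, 9L), kind = c("nan", "flat", "clone_channel"))
  rec <- inject_artifacts(s$rec, art, seed = 3)
  mask <- detect_bad_trials(segment_trials(rec))
  expect_true(mask$flags[2] && "nan" %in% mask$reasons[[2]])
  expect_true(mask$flags[5] && "flat" %in% mask$reasons[[5]])
  expect_true(mask$flags[9] && "corr_high" %in% mask$reasons[[9]])
  expect_false(any(mask$flags[-c(2, 5, 9)]))
})

test_that("independent white-noise trials are never flagged under defaults", {
  spec <- session_spec(2L, 50L)                   # 100 trials
  m <- vep_model(spec, snr = 0, pink_sd_uv = 0, white_sd_uv = 3, line_amp_uv = 0)
  rec <- synthesize_recording(make_session_events(spec, 1), m, seed = 8)
  mask <- detect_bad_trials(segment_trials(rec))
  expect_false(any(mask$flags))
})

test_that("normalization gives zero mean, unit SD, and clamps at the bound", {
  s <- tiny_session()
  ep <- segment_trials(filter_raw(s$rec))
  nz <- normalize_clamp(ep)
  for (ch in 1:8) {
    v <- nz$data[, ch, ]
    expect_lt(abs(mean(v)), 1e-9)
    expect_lt(abs(stats::sd(as.vector(v)) - 1), 1e-6)
  }
  # an injected extreme sample saturates at +/- 20
  ep2 <- ep
  ep2$data[1, 1, 1] <- mean(ep$data[, 1, ]) + 25 * stats::sd(as.vector(ep$data[, 1, ]))
  nz2 <- normalize_clamp(ep2)
  expect_lt(max(abs(nz2$data)), 20 + 1e-9)
  expect_gt(nz2$data[1, 1, 1], 19.5)
  # constant channel is a hard error
  ep3 <- ep
  ep3$data[, 4, ] <- 1.5
  expect_error(normalize_clamp(ep3), "SD")
})

test_that("the session pipeline drops flagged trials and bounds the output", {
  s <- tiny_session()
  art <- data.frame(trial = c(1L, 6L, 13L), kind = rep("nan", 3))
  rec <- inject_artifacts(s$rec, art, seed = 2)
  ep <- preprocess_session(rec)
  n_total <- nrow(s$events)
  expect_equal(dim(ep$data)[1], n_total - 3L)
  expect_equal(sum(!ep$retained), 3L)
  expect_equal(ep$drop_rate, 3 / n_total)
  expect_false(anyNA(ep$data))
  expect_lte(max(abs(ep$data)), 20)
  # clean high-SNR session: zero drops; pipeline deterministic
  ep_clean <- preprocess_session(s$rec)
  expect_equal(ep_clean$drop_rate, 0)
  ep_clean2 <- preprocess_session(s$rec)
  expect_identical(ep_clean$data, ep_clean2$data)
  rep <- drop_report(list(ep, ep_clean))
  expect_equal(rep$n_dropped, c(3L, 0L))
  expect_equal(rep$pct_dropped, c(300 / n_total, 0))
})

test_that("over 50% dropped trials raises a warning but still returns", {
  spec <- session_spec(2L, 3L)
  m <- vep_model(spec, snr = 1)
  rec <- synthesize_recording(make_session_events(spec, 1), m, seed = 1)
  art <- data.frame(trial = 1:4, kind = rep("nan", 4))
  expect_warning(ep <- preprocess_session(inject_artifacts(rec, art, seed = 1)),
                 "dropped")
  expect_equal(dim(ep$data)[1], 2L)
})
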