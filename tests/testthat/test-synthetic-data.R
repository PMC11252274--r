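test_that("event schedules are shuffled permutations on an exact grid", {
  spec <- session_spec()
  ev <- make_session_events(spec, seed = 1)
  expect_equal(nrow(ev), 600L)
  expect_equal(session_duration_min(ev), 30)
  expect_true(all(diff(ev$onset_sample) == spec$step_samps))
  # label multiset: every (class, image) pair exactly once
  expect_equal(sort(ev$class_id * 30 + ev$image_id), 0:599)
  ev2 <- make_session_events(spec, seed = 2)
  expect_false(all(ev2$class_id == ev$class_id & ev2$image_id == ev$image_id))
  expect_equal(sort(ev2$class_id), sort(ev$class_id))
  expect_identical(make_session_events(spec, seed = 1), ev)
})

test_that("non-integer sample spacing is rejected", {
  expect_error(session_spec(stim_dur_s = 2.0013), "integer")
  expect_error(session_spec(isi_s = 1.0007), "integer")
})

test_that("zero-noise synthesis reproduces the class template exactly", {
  spec <- tiny_spec()
  m0 <- vep_model(spec, snr = 2, pink_sd_uv = 0, white_sd_uv = 0,
                  line_amp_uv = 0, shape_jitter_sd = 0, trial_amp_jitter_sd = 0)
  ev <- make_session_events(spec, seed = 3)
  rec <- synthesize_recording(ev, m0, seed = 4)
  ep <- segment_trials(rec)
  for (i in c(1L, 7L, nrow(ev))) {
    expect_equal(max(abs(ep$data[i, , ] - class_template(m0, ev$class_id[i]))), 0)
  }
  # inter-trial gray periods carry no evoked component
  gap <- rec$signal[, ev$onset_sample[1] + spec$stim_samps + seq_len(spec$step_samps - spec$stim_samps)]
  expect_equal(max(abs(gap)), 0)
})

test_that("N1 trough precedes P2 peak in every clean class-mean waveform", {
  spec <- tiny_spec()
  m0 <- vep_model(spec, snr = 2, pink_sd_uv = 0, white_sd_uv = 0,
                  line_amp_uv = 0, shape_jitter_sd = 0, trial_amp_jitter_sd = 0)
  for (k in 0:(spec$n_classes - 1)) {
    tpl <- class_template(m0, k)
    w <- colMeans(tpl)
    expect_lt(which.min(w), which.max(w))
    expect_lt(min(w), 0)
    expect_gt(max(w), 0)
  }
})

test_that("noise-only synthesis matches configured variance (Welch oracle)", {
  spec <- session_spec(2L, 10L)
  sigma <- 3
  m <- vep_model(spec, snr = 0, pink_sd_uv = 0, white_sd_uv = sigma, line_amp_uv = 0)
  rec <- synthesize_recording(make_session_events(spec, 1), m, seed = 5)
  v <- apply(rec$signal, 1, stats::var)
  expect_true(all(abs(v - sigma^2) / sigma^2 < 0.05))
  # pink + line contributions add in quadrature
  m2 <- vep_model(spec, snr = 0, pink_sd_uv = 2, white_sd_uv = sigma, line_amp_uv = 1)
  rec2 <- synthesize_recording(make_session_events(spec, 1), m2, seed = 5)
  expected <- 2^2 + sigma^2 + 1 / 2
  v2 <- apply(rec2$signal, 1, stats::var)
  expect_true(all(abs(v2 - expected) / expected < 0.12))
})

test_that("synthesis is bit-identical under a fixed seed", {
  s <- tiny_session()
  rec2 <- synthesize_recording(s$events, s$model, seed = 12, session_id = "T01")
  expect_identical(s$rec$signal, rec2$signal)
})

test_that("artifact injection corrupts exactly the named trials", {
  s <- tiny_session()
  spec <- s$spec
  art <- data.frame(trial = c(7L, 3L, 11L, 15L),
                    kind = c("nan", "flat", "clone_channel", "burst"))
  rec <- inject_artifacts(s$rec, art, seed = 6)
  ep <- segment_trials(rec)
  expect_true(any(is.nan(ep$data[7, , ])))
  expect_true(any(apply(ep$data[3, , ], 1, function(x) diff(range(x))) == 0))
  cm <- abs(stats::cor(t(ep$data[11, , ])))
  expect_gte(max(cm[upper.tri(cm)]), 0.999999)
  expect_gt(max(abs(ep$data[15, , ])), 300)
  # all other samples untouched
  touched <- unlist(lapply(art$trial, function(tr) {
    s$rec$events$onset_sample[tr] + seq_len(spec$stim_samps)
  }))
  expect_identical(rec$signal[, -touched], s$rec$signal[, -touched])
  expect_error(inject_artifacts(s$rec, data.frame(trial = 999L, kind = "nan")),
               "out of range")
  expect_identical(inject_artifacts(s$rec, NULL), s$rec)
})

test_that("stimulus sets have within-class-coherent luminance", {
  spec <- session_spec()
  set <- generate_stimulus_images(spec, side_px = 16L, seed = 9)
  expect_length(set$images, 20L)
  expect_true(all(lengths(set$images) == 30L))
  lum <- stimulus_luminance(set)
  within_sd <- mean(tapply(lum$luminance, lum$class_id, stats::sd))
  between_sd <- stats::sd(tapply(lum$luminance, lum$class_id, mean))
  expect_lt(within_sd, between_sd)
  rng <- range(unlist(lapply(set$images, function(cl) vapply(cl, range, c(0, 0)))))
  expect_gte(rng[1], 0)
  expect_lte(rng[2], 1)
  set2 <- generate_stimulus_images(spec, side_px = 16L, seed = 9)
  expect_identical(set$images, set2$images)
  expect_error(generate_stimulus_images(spec, side_px = 8L), "side_px")
})
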