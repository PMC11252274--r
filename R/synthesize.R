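# Class-conditional VEP simulator: N1-P2 template sessions over 1/f +
# line-noise background, with injectable artifacts.

#' Class-conditional N1-P2 VEP model
#'
#' Parameterizes the evoked response of each image class as the sum of two
#' Gaussian-windowed lobes -- a negative N1 near 100 ms and a positive P2
#' near 200 ms -- projected onto the 8 channels by a class-specific spatial
#' signature. Class identity is carried by deterministic per-class
#' perturbations of the lobe latencies, amplitudes and the signature; their
#' overall magnitude relative to the background noise is governed by a
#' single `snr` knob (template peak amplitude divided by total noise SD).
#'
#' @param spec a [session_spec()].
#' @param snr signal-to-noise amplitude ratio; 0 disables the evoked
#'   component entirely (noise-only sessions).
#' @param model_seed seed fixing the per-class parameter draws (kept apart
#'   from session seeds so all sessions of a "subject" share one model).
#' @param n1_latency_ms,p2_latency_ms base lobe centers in ms.
#' @param n1_amp_uv,p2_amp_uv base lobe amplitudes in microvolt (N1 negative).
#' @param n1_width_ms,p2_width_ms Gaussian lobe SDs in ms.
#' @param latency_spread_ms SD of the per-class latency perturbation.
#' @param shape_jitter_sd per-trial latency jitter SD in ms.
#' @param trial_amp_jitter_sd per-trial multiplicative amplitude jitter SD.
#' @param pink_exponent spectral exponent of the 1/f background.
#' @param pink_sd_uv SD of the 1/f background per channel.
#' @param white_sd_uv SD of the white sensor-noise floor per channel.
#' @param line_amp_uv amplitude of the 60 Hz line component per channel.
#' @return an object of class `vep_model` carrying per-class parameter
#'   tables and noise settings.
#' @export
vep_model <- function(spec, snr = 1, model_seed = 909,
                      n1_latency_ms = 100, n1_amp_uv = -5,
                      p2_latency_ms = 200, p2_amp_uv = 8,
                      n1_width_ms = 22, p2_width_ms = 40,
                      latency_spread_ms = 12,
                      shape_jitter_sd = 4,
                      trial_amp_jitter_sd = 0.1,
                      pink_exponent = 1, pink_sd_uv = 4,
                      white_sd_uv = 2, line_amp_uv = 1) {
  stopifnot(inherits(spec, "session_spec"))
  abort_if(snr < 0, "snr must be >= 0")
  abort_if(pink_sd_uv < 0 || white_sd_uv < 0 || line_amp_uv < 0 ||
             shape_jitter_sd < 0 || trial_amp_jitter_sd < 0,
           "noise parameters must be >= 0")
  k <- spec$n_classes
  pc <- with_seed(model_seed, {
    list(
      n1_lat = pmax(20, n1_latency_ms + rnorm(k, 0, latency_spread_ms)),
      p2_lat = pmin(spec$stim_dur_s * 1000 - 50,
                    p2_latency_ms + rnorm(k, 0, 1.6 * latency_spread_ms)),
      n1_amp = n1_amp_uv * exp(rnorm(k, 0, 0.25)),
      p2_amp = p2_amp_uv * exp(rnorm(k, 0, 0.25)),
      # positive-leaning occipital topography, one 8-vector per class
      signature = {
        s <- matrix(abs(rnorm(k * 8, 1, 0.45)), nrow = k)
        s / apply(s, 1, max)
      }
    )
  })
  # keep N1 strictly before P2 in every class
  bad <- pc$p2_lat - pc$n1_lat < 40
  pc$p2_lat[bad] <- pc$n1_lat[bad] + 60
  noise_sd <- sqrt(pink_sd_uv^2 + white_sd_uv^2 + line_amp_uv^2 / 2)
  base_peak <- max(abs(c(n1_amp_uv, p2_amp_uv)))
  amp_scale <- if (base_peak > 0 && noise_sd > 0) snr * noise_sd / base_peak else snr
  structure(list(
    spec = spec, snr = snr, amp_scale = amp_scale, per_class = pc,
    n1_width_ms = n1_width_ms, p2_width_ms = p2_width_ms,
    shape_jitter_sd = shape_jitter_sd,
    trial_amp_jitter_sd = trial_amp_jitter_sd,
    pink_exponent = pink_exponent, pink_sd_uv = pink_sd_uv,
    white_sd_uv = white_sd_uv, line_amp_uv = line_amp_uv
  ), class = "vep_model")
}

# evoked waveform of one class at given jitters, length = stim window
vep_waveform <- function(model, class_id, lat_shift_ms = 0, amp_factor = 1) {
  spec <- model$spec
  i <- class_id + 1L
  t_ms <- (seq_len(spec$stim_samps) - 1L) / spec$fs_hz * 1000
  pc <- model$per_class
  w <- pc$n1_amp[i] * exp(-(t_ms - (pc$n1_lat[i] + lat_shift_ms))^2 / (2 * model$n1_width_ms^2)) +
    pc$p2_amp[i] * exp(-(t_ms - (pc$p2_lat[i] + lat_shift_ms))^2 / (2 * model$p2_width_ms^2))
  w * model$amp_scale * amp_factor
}

#' Clean evoked template of one class
#'
#' @param model a [vep_model()].
#' @param class_id 0-based class index.
#' @return an 8 x stim_samps matrix in microvolt (no noise, no jitter).
#' @export
class_template <- function(model, class_id) {
  outer(model$per_class$signature[class_id + 1L, ], vep_waveform(model, class_id))
}

# 1/f noise by spectral shaping of white noise, unit SD
pink_noise <- function(n, exponent) {
  x <- rnorm(n)
  if (exponent == 0) return(x)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)  # symmetric frequency index, DC mapped to 1
  shaped <- Re(stats::fft(stats::fft(x) * f^(-exponent / 2), inverse = TRUE)) / n
  s <- stats::sd(shaped)
  if (s > 0) shaped / s else shaped
}

#' Synthesize one continuous 8-channel recording session
#'
#' Renders the event schedule into a continuous microvolt signal: each
#' stimulus window receives its class template (scaled by the class spatial
#' signature, with per-trial latency/amplitude jitter), inter-trial gray
#' periods carry noise only, and a 1/f + white + 60 Hz line background runs
#' through the whole session.
#'
#' @param events an `event_list` from [make_session_events()].
#' @param model a [vep_model()].
#' @param seed integer seed; output is bit-identical for identical inputs.
#' @param session_id identifier stored in the recording.
#' @return an object of class `raw_recording` with fields `signal`
#'   (8 x N matrix, microvolt), `fs_hz`, `layout`, `events`, `session_id`.
#' @export
synthesize_recording <- function(events, model, seed, session_id = "S01") {
  spec <- attr(events, "spec")
  stopifnot(inherits(model, "vep_model"))
  abort_if(spec$fs_hz != model$spec$fs_hz, "events and model sampling rates differ")
  n_samp <- max(events$onset_sample) + spec$step_samps
  sig <- with_seed(seed, {
    s <- matrix(0, nrow = 8, ncol = n_samp)
    for (ch in 1:8) {
      if (model$pink_sd_uv > 0) s[ch, ] <- model$pink_sd_uv * pink_noise(n_samp, model$pink_exponent)
      if (model$white_sd_uv > 0) s[ch, ] <- s[ch, ] + rnorm(n_samp, 0, model$white_sd_uv)
      if (model$line_amp_uv > 0) {
        tt <- (seq_len(n_samp) - 1) / spec$fs_hz
        s[ch, ] <- s[ch, ] + model$line_amp_uv * sin(2 * pi * 60 * tt + 2 * pi * ch / 8)
      }
    }
    if (model$amp_scale > 0) {
      lat_j <- rnorm(nrow(events), 0, model$shape_jitter_sd)
      amp_j <- pmax(0.2, 1 + rnorm(nrow(events), 0, model$trial_amp_jitter_sd))
      for (i in seq_len(nrow(events))) {
        w <- vep_waveform(model, events$class_id[i], lat_j[i], amp_j[i])
        idx <- events$onset_sample[i] + seq_len(spec$stim_samps)
        s[, idx] <- s[, idx] + outer(model$per_class$signature[events$class_id[i] + 1L, ], w)
      }
    }
    s
  })
  structure(list(signal = sig, fs_hz = spec$fs_hz, layout = channel_layout(),
                 events = events, session_id = session_id),
            class = "raw_recording")
}

#' Corrupt selected trials of a recording
#'
#' Injects the artifact kinds the quality-control stage screens for:
#' `nan` (missing samples), `flat` (a dead channel), `clone_channel`
#' (a bridged electrode pair, inter-channel r = 1), `burst` (a
#' high-amplitude transient).
#'
#' @param rec a `raw_recording`.
#' @param artifacts data.frame with columns `trial` (1-based trial index in
#'   event order) and `kind` (one of nan, flat, clone_channel, burst).
#' @param seed seed controlling which channels/samples are hit.
#' @return the corrupted `raw_recording`; samples outside the named trial
#'   windows are untouched.
#' @export
inject_artifacts <- function(rec, artifacts, seed = 1) {
  stopifnot(inherits(rec, "raw_recording"))
  if (is.null(artifacts) || nrow(artifacts) == 0L) return(rec)
  spec <- attr(rec$events, "spec")
  abort_if(any(artifacts$trial < 1 | artifacts$trial > nrow(rec$events)),
           "artifact trial index out of range")
  abort_if(!all(artifacts$kind %in% c("nan", "flat", "clone_channel", "burst")),
           "unknown artifact kind")
  with_seed(seed, {
    for (i in seq_len(nrow(artifacts))) {
      tr <- artifacts$trial[i]
      idx <- rec$events$onset_sample[tr] + seq_len(spec$stim_samps)
      switch(artifacts$kind[i],
        nan = {
          ch <- sample.int(8, 1)
          hit <- sample(idx, max(3L, length(idx) %/% 50))
          rec$signal[ch, hit] <- NaN
        },
        flat = {
          ch <- sample.int(8, 1)
          rec$signal[ch, idx] <- rec$signal[ch, idx[1]]
        },
        clone_channel = {
          pair <- sample.int(8, 2)
          rec$signal[pair[2], idx] <- rec$signal[pair[1], idx]
        },
        burst = {
          ch <- sample.int(8, 1)
          tt <- seq_along(idx) / rec$fs_hz
          rec$signal[ch, idx] <- rec$signal[ch, idx] + 400 * sin(2 * pi * 7 * tt)
        })
    }
    rec
  })
}
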