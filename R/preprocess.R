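# Per-session preprocessing: bad-trial mask on unfiltered epochs,
# zero-phase filtering of the continuous signal, re-segmentation, mask
# application, channel-wise z-normalization and clamping.

#' Filter settings
#'
#' Highpass 1 Hz, lowpass 95 Hz and a 60 Hz notch, applied to the
#' continuous (unsegmented) signal to avoid edge artifacts. High/low pass
#' are Butterworth (order `order`, applied as two cascaded half-order
#' sections for numerical robustness at low corner frequencies); the notch
#' is an IIR biquad of quality factor `notch_q`. All stages run
#' forward-backward when `zero_phase` is set, preserving latencies.
#'
#' @param hp_hz,lp_hz,notch_hz corner/center frequencies in Hz.
#' @param order Butterworth order (per pass, before the zero-phase doubling).
#' @param notch_q notch quality factor.
#' @param zero_phase apply each filter forward-backward.
#' @export
filter_spec <- function(hp_hz = 1, lp_hz = 95, notch_hz = 60, order = 4,
                        notch_q = 30, zero_phase = TRUE) {
  abort_if(!(0 < hp_hz && hp_hz < notch_hz && notch_hz < lp_hz),
           "need 0 < hp_hz < notch_hz < lp_hz")
  structure(list(hp_hz = hp_hz, lp_hz = lp_hz, notch_hz = notch_hz,
                 order = order, notch_q = notch_q, zero_phase = zero_phase),
            class = "filter_spec")
}

#' Bad-trial criteria
#'
#' A trial is flagged when it contains non-finite samples (`nan`), a
#' channel whose peak-to-peak amplitude is below `flat_ptp_uv` (`flat`), a
#' channel pair with absolute Pearson correlation above `corr_high`
#' (bridged/cloned electrodes), or a mean absolute pairwise correlation
#' below `corr_low` (disconnected channel). The numeric thresholds are
#' explicit package defaults, exposed here.
#'
#' The `corr_low` default sits well below the null expectation of the
#' mean absolute pairwise correlation for 500-sample epochs
#' (`sqrt(2 / (pi * 499)) ~ 0.036`), so statistically independent
#' channels are never rejected while a disconnected (near-constant-plus-
#' noise, decorrelated) montage still trips it.
#'
#' @param flat_ptp_uv minimum acceptable peak-to-peak, microvolt.
#' @param corr_low minimum acceptable mean inter-channel `|r|`.
#' @param corr_high maximum acceptable pairwise `|r|`.
#' @param nan_check screen for non-finite samples.
#' @export
bad_trial_criteria <- function(flat_ptp_uv = 0.01, corr_low = 0.01,
                               corr_high = 0.99, nan_check = TRUE) {
  abort_if(!(0 <= corr_low && corr_low < corr_high && corr_high <= 1),
           "need 0 <= corr_low < corr_high <= 1")
  structure(list(flat_ptp_uv = flat_ptp_uv, corr_low = corr_low,
                 corr_high = corr_high, nan_check = nan_check),
            class = "bad_trial_criteria")
}

butter_sos <- function(order, w, type) {
  # two cascaded half-order sections: stable tf realisation at low corners
  half <- max(1L, as.integer(round(order / 2)))
  b <- signal::butter(half, w, type)
  list(b = b, passes = 2L)
}

# zero-phase filtering with reflection padding to suppress edge transients
filtfilt_padded <- function(flt, x) {
  n <- length(x)
  np <- min(n - 1L, 500L)
  head_pad <- 2 * x[1] - x[(np + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - np)]
  y <- signal::filtfilt(flt, c(head_pad, x, tail_pad))
  y[np + seq_len(n)]
}

apply_filt <- function(x, flt, zero_phase) {
  for (i in seq_len(flt$passes)) {
    x <- if (zero_phase) filtfilt_padded(flt$b, x) else as.numeric(signal::filter(flt$b, x))
  }
  x
}

notch_biquad <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  signal::Arma(b = b / a[1], a = a / a[1])
}

#' Zero-phase filter a continuous recording
#'
#' Applies highpass, lowpass and notch channel-wise to the continuous
#' signal. Non-finite samples are zero-imputed for the filter pass and
#' restored afterwards, so NaNs stay confined to their original positions
#' (trials containing them are rejected by the mask computed beforehand).
#'
#' @param rec a `raw_recording`.
#' @param spec a [filter_spec()].
#' @return the filtered `raw_recording`.
#' @export
filter_raw <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "raw_recording"), inherits(spec, "filter_spec"))
  fs <- rec$fs_hz
  abort_if(fs <= 2 * spec$lp_hz, "sampling rate must exceed twice the lowpass corner")
  hp <- butter_sos(spec$order, spec$hp_hz / (fs / 2), "high")
  lp <- butter_sos(spec$order, spec$lp_hz / (fs / 2), "low")
  nf <- notch_biquad(spec$notch_hz, fs, spec$notch_q)
  for (ch in seq_len(nrow(rec$signal))) {
    x <- rec$signal[ch, ]
    bad <- !is.finite(x)
    if (any(bad)) x[bad] <- 0
    x <- apply_filt(x, hp, spec$zero_phase)
    x <- apply_filt(x, lp, spec$zero_phase)
    x <- if (spec$zero_phase) filtfilt_padded(nf, x) else as.numeric(signal::filter(nf, x))
    if (any(bad)) x[bad] <- NaN
    rec$signal[ch, ] <- x
  }
  rec
}

new_epoch_set <- function(data, labels, retained, session_id, fs_hz,
                          normalized = FALSE, provenance = character(),
                          image_ids = NULL) {
  structure(list(data = data, labels = as.integer(labels), retained = retained,
                 session_id = session_id, fs_hz = fs_hz,
                 normalized = normalized, provenance = provenance,
                 image_ids = if (is.null(image_ids)) rep(0L, length(labels)) else as.integer(image_ids)),
            class = "epoch_set")
}

#' Cut a continuous recording into stimulus-locked trials
#'
#' Each event yields one epoch covering the half-open window
#' `[onset, onset + stim_samps)` -- the 500 samples after image onset at
#' the 250 Hz / 2 s defaults.
#'
#' @param rec a `raw_recording`.
#' @param events an `event_list`; defaults to the recording's own events.
#' @return an `epoch_set` with `data` of dim `trials x 8 x stim_samps`.
#' @export
segment_trials <- function(rec, events = rec$events) {
  stopifnot(inherits(rec, "raw_recording"))
  spec <- attr(events, "spec")
  n <- nrow(events)
  last_needed <- max(events$onset_sample) + spec$stim_samps
  if (last_needed > ncol(rec$signal)) {
    over <- which(events$onset_sample + spec$stim_samps > ncol(rec$signal))[1]
    stop(sprintf("event %d (onset sample %d) exceeds recording length %d",
                 over, events$onset_sample[over], ncol(rec$signal)), call. = FALSE)
  }
  data <- array(0, dim = c(n, nrow(rec$signal), spec$stim_samps))
  for (i in seq_len(n)) {
    data[i, , ] <- rec$signal[, events$onset_sample[i] + seq_len(spec$stim_samps)]
  }
  new_epoch_set(data, events$class_id, rep(TRUE, n), rec$session_id, rec$fs_hz,
                provenance = "segmented", image_ids = events$image_id)
}

#' Flag bad trials on unfiltered epochs
#'
#' @param epochs an `epoch_set` (unnormalized).
#' @param criteria a [bad_trial_criteria()].
#' @return a `bad_trial_mask`: `flags` (logical per trial) and `reasons`
#'   (per-trial character subsets of nan/flat/corr_low/corr_high).
#' @export
detect_bad_trials <- function(epochs, criteria = bad_trial_criteria()) {
  stopifnot(inherits(epochs, "epoch_set"))
  abort_if(isTRUE(epochs$normalized), "bad-trial detection runs on unnormalized epochs")
  n <- dim(epochs$data)[1]
  reasons <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- epochs$data[i, , ]
    r <- character()
    if (criteria$nan_check && any(!is.finite(tr))) r <- c(r, "nan")
    ptp <- apply(tr, 1, function(x) {
      x <- x[is.finite(x)]
      if (!length(x)) 0 else diff(range(x))
    })
    if (any(ptp < criteria$flat_ptp_uv)) r <- c(r, "flat")
    ok <- ptp >= criteria$flat_ptp_uv & apply(tr, 1, function(x) all(is.finite(x)))
    if (sum(ok) >= 2) {
      cm <- abs(stats::cor(t(tr[ok, , drop = FALSE])))
      off <- cm[upper.tri(cm)]
      if (any(off > criteria$corr_high)) r <- c(r, "corr_high")
      if (mean(off) < criteria$corr_low) r <- c(r, "corr_low")
    }
    reasons[[i]] <- r
  }
  structure(list(flags = lengths(reasons) > 0L, reasons = reasons),
            class = "bad_trial_mask")
}

#' Channel-wise z-normalization with clamping
#'
#' Standardizes each channel to zero mean and unit SD over all samples of
#' the session's retained trials, then saturates values beyond
#' `clamp_sd` standard deviations at the bound.
#'
#' @param epochs an `epoch_set` of retained, finite trials.
#' @param clamp_sd clamp bound in SD units (default 20).
#' @return the normalized `epoch_set`.
#' @export
normalize_clamp <- function(epochs, clamp_sd = 20) {
  stopifnot(inherits(epochs, "epoch_set"))
  n_ch <- dim(epochs$data)[2]
  for (ch in seq_len(n_ch)) {
    v <- epochs$data[, ch, ]
    mu <- mean(v); s <- stats::sd(as.vector(v))
    abort_if(!is.finite(s) || s == 0,
             sprintf("channel %d has zero or undefined SD (flat channel not rejected?)", ch))
    z <- (v - mu) / s
    epochs$data[, ch, ] <- pmin(pmax(z, -clamp_sd), clamp_sd)
  }
  epochs$normalized <- TRUE
  epochs$provenance <- c(epochs$provenance, sprintf("z-normalized+clamped(%g)", clamp_sd))
  epochs
}

#' Preprocessing configuration
#' @param filter a [filter_spec()].
#' @param criteria a [bad_trial_criteria()].
#' @param clamp_sd clamp bound in SD units.
#' @export
preprocess_config <- function(filter = filter_spec(),
                              criteria = bad_trial_criteria(), clamp_sd = 20) {
  structure(list(filter = filter, criteria = criteria, clamp_sd = clamp_sd),
            class = "preprocess_config")
}

#' Full per-session preprocessing pipeline
#'
#' Fixed stage order: (1) segment the unfiltered signal and compute the
#' bad-trial mask; (2) filter the continuous signal; (3) re-segment;
#' (4) drop flagged trials; (5) z-normalize per channel and clamp. The
#' mask is always the pre-filter mask.
#'
#' @param rec a `raw_recording` with events.
#' @param config a [preprocess_config()].
#' @return an `epoch_set` containing only retained trials; `retained` keeps
#'   the full-length mask, and attribute fields `drop_rate`/`n_total`
#'   record the rejection statistics.
#' @export
preprocess_session <- function(rec, config = preprocess_config()) {
  stopifnot(inherits(rec, "raw_recording"))
  raw_epochs <- segment_trials(rec)
  mask <- detect_bad_trials(raw_epochs, config$criteria)
  filtered <- filter_raw(rec, config$filter)
  epochs <- segment_trials(filtered)
  keep <- !mask$flags
  if (mean(mask$flags) > 0.5) {
    warning(sprintf("session %s: %.0f%% of trials dropped", rec$session_id,
                    100 * mean(mask$flags)))
  }
  out <- new_epoch_set(epochs$data[keep, , , drop = FALSE], epochs$labels[keep],
                       keep, rec$session_id, rec$fs_hz,
                       provenance = c("segmented", "masked", "filtered", "re-segmented"),
                       image_ids = epochs$image_ids[keep])
  out <- normalize_clamp(out, config$clamp_sd)
  out$drop_rate <- mean(mask$flags)
  out$n_total <- length(mask$flags)
  out$mask <- mask
  out
}

#' Drop-rate report across sessions
#' @param epoch_sets list of preprocessed `epoch_set`s.
#' @return data.frame with session_id, n_total, n_dropped, pct_dropped.
#' @export
drop_report <- function(epoch_sets) {
  do.call(rbind, lapply(epoch_sets, function(e) {
    data.frame(session_id = e$session_id, n_total = e$n_total,
               n_dropped = as.integer(e$n_total - sum(e$retained)),
               pct_dropped = 100 * e$drop_rate)
  }))
}

#' Write an epochs container (header JSON + float32 blob)
#' @param epochs an `epoch_set`.
#' @param dir output directory.
#' @export
write_epochs <- function(epochs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- list(shape = dim(epochs$data), fs_hz = epochs$fs_hz,
              channels = channel_layout()$names, labels = epochs$labels,
              retained = epochs$retained, session_id = epochs$session_id,
              image_ids = epochs$image_ids,
              normalized = epochs$normalized, provenance = epochs$provenance,
              drop_rate = epochs$drop_rate, n_total = epochs$n_total,
              order = "C (samples fastest)", dtype = "float32-le")
  jsonlite::write_json(hdr, file.path(dir, "header.json"), auto_unbox = TRUE, digits = NA)
  con <- file(file.path(dir, "data.f32"), "wb")
  writeBin(as.numeric(aperm(epochs$data, c(3, 2, 1))), con, size = 4, endian = "little")
  close(con)
  invisible(dir)
}

#' Read an epochs container written by [write_epochs()]
#' @param dir container directory.
#' @return an `epoch_set`.
#' @export
read_epochs <- function(dir) {
  hdr <- jsonlite::read_json(file.path(dir, "header.json"), simplifyVector = TRUE)
  con <- file(file.path(dir, "data.f32"), "rb")
  v <- readBin(con, numeric(), n = prod(hdr$shape), size = 4, endian = "little")
  close(con)
  data <- aperm(array(v, dim = rev(hdr$shape)), c(3, 2, 1))
  out <- new_epoch_set(data, hdr$labels, hdr$retained, hdr$session_id, hdr$fs_hz,
                       hdr$normalized, hdr$provenance, image_ids = hdr$image_ids)
  out$drop_rate <- hdr$drop_rate
  out$n_total <- hdr$n_total
  out
}
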