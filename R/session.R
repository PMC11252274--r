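# Session geometry, channel layout and event schedules for simulated
# VEP recording sessions.

#' Occipito-parietal 8-channel layout
#'
#' The default montage covers the occipito-parietal sites most predictive
#' for visual decoding: PO8, O2, O1, PO7, PO3, POZ, PO4 and Pz (10-20
#' system), in this fixed order.
#'
#' @param names character vector of exactly 8 unique channel labels.
#' @return an object of class `channel_layout`.
#' @export
channel_layout <- function(names = c("PO8", "O2", "O1", "PO7", "PO3", "POZ", "PO4", "Pz")) {
  abort_if(length(names) != 8L, "a channel layout must have exactly 8 labels")
  abort_if(anyDuplicated(names) > 0L, "channel labels must be unique")
  structure(list(names = as.character(names)), class = "channel_layout")
}

#' Define the geometry of one recording session
#'
#' A session presents `n_classes * images_per_class` stimuli, each shown for
#' `stim_dur_s` seconds and separated by `isi_s` seconds of uniform gray.
#'
#' @param n_classes number of image classes (default 20).
#' @param images_per_class stimuli per class (default 30).
#' @param stim_dur_s stimulus exposure in seconds (default 2).
#' @param isi_s inter-stimulus gray-screen interval in seconds (default 1).
#' @param fs_hz sampling rate in Hz (default 250).
#' @return an object of class `session_spec` with derived fields
#'   `n_trials`, `stim_samps` (samples per stimulus window) and
#'   `step_samps` (onset-to-onset spacing in samples).
#' @export
session_spec <- function(n_classes = 20L, images_per_class = 30L,
                         stim_dur_s = 2.0, isi_s = 1.0, fs_hz = 250L) {
  abort_if(!is_count(n_classes) || !is_count(images_per_class),
           "n_classes and images_per_class must be positive integers")
  abort_if(!(stim_dur_s > 0 && isi_s > 0 && fs_hz > 0), "durations and fs must be positive")
  stim_samps <- stim_dur_s * fs_hz
  step_samps <- (stim_dur_s + isi_s) * fs_hz
  abort_if(abs(stim_samps - round(stim_samps)) > 1e-9,
           "stim_dur_s * fs_hz must be an integer number of samples")
  abort_if(abs(step_samps - round(step_samps)) > 1e-9,
           "(stim_dur_s + isi_s) * fs_hz must be an integer number of samples")
  structure(list(
    n_classes = as.integer(n_classes),
    images_per_class = as.integer(images_per_class),
    stim_dur_s = stim_dur_s, isi_s = isi_s, fs_hz = as.integer(fs_hz),
    n_trials = as.integer(n_classes) * as.integer(images_per_class),
    stim_samps = as.integer(round(stim_samps)),
    step_samps = as.integer(round(step_samps))
  ), class = "session_spec")
}

#' Randomized stimulus presentation schedule
#'
#' Draws a fresh random permutation of the full stimulus set (every image of
#' every class exactly once) and lays the onsets out on the fixed
#' stimulus + gray grid. Shuffling the order anew for every session is what
#' prevents block-level temporal correlations from leaking class information.
#'
#' @param spec a [session_spec()].
#' @param seed integer seed; the schedule is a pure function of `(spec, seed)`.
#' @return a data.frame of class `event_list` with 0-based `onset_sample`,
#'   `onset_s`, `duration_s`, `class_id` (0-based), `image_id` (0-based
#'   within class).
#' @export
make_session_events <- function(spec, seed) {
  stopifnot(inherits(spec, "session_spec"))
  class_id <- rep(seq_len(spec$n_classes) - 1L, each = spec$images_per_class)
  image_id <- rep(seq_len(spec$images_per_class) - 1L, times = spec$n_classes)
  ord <- with_seed(seed, sample.int(spec$n_trials))
  ev <- data.frame(
    onset_sample = (seq_len(spec$n_trials) - 1L) * spec$step_samps,
    onset_s = (seq_len(spec$n_trials) - 1L) * (spec$stim_dur_s + spec$isi_s),
    duration_s = spec$stim_dur_s,
    class_id = class_id[ord],
    image_id = image_id[ord]
  )
  class(ev) <- c("event_list", "data.frame")
  attr(ev, "spec") <- spec
  ev
}

#' Total duration of a session's stimulus sequence, in minutes
#' @param events an `event_list`.
#' @return duration in minutes from first onset to end of last gray period.
#' @export
session_duration_min <- function(events) {
  spec <- attr(events, "spec")
  nrow(events) * (spec$stim_dur_s + spec$isi_s) / 60
}
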