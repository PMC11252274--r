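#!/usr/bin/env Rscript
# Simulate one synthetic "subject": a session set of 8-channel VEP
# recordings (EDF + events TSV) plus the parametric stimulus image set.
# Writes results/subject01/sessions and results/subject01/stimuli.

library(vepdecode)

seed <- 1L
out <- "results/subject01"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spec <- session_spec()                       # 20 classes x 30 images, 2 s + 1 s, 250 Hz
model <- vep_model(spec, snr = 3, model_seed = derive_seed(seed, "vep-model"))

n_sessions <- 6L
for (i in seq_len(n_sessions)) {
  ev <- make_session_events(spec, derive_seed(seed, paste0("events", i)))
  rec <- synthesize_recording(ev, model, derive_seed(seed, paste0("signal", i)),
                              session_id = sprintf("S%02d", i))
  write_session(rec, file.path(out, "sessions"))
  message(sprintf("session S%02d: %d trials, %.0f min",
                  i, nrow(ev), session_duration_min(ev)))
}

stimuli <- generate_stimulus_images(spec, side_px = 32L,
                                    seed = derive_seed(seed, "stimuli"))
man <- write_stimulus_images(stimuli, file.path(out, "stimuli"))
message(sprintf("wrote %d stimulus images across %d classes",
                nrow(man), spec$n_classes))
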