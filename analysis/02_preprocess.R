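#!/usr/bin/env Rscript
# Quality control and epoching for every recorded session: bad-trial mask
# on raw epochs, zero-phase filtering, re-segmentation, z-normalization
# with clamping. Writes epochs containers and the drop-rate table.

library(vepdecode)

out <- "results/subject01"
edfs <- sort(list.files(file.path(out, "sessions"), pattern = "\\.edf$",
                        full.names = TRUE))
stopifnot(length(edfs) > 0)

eps <- lapply(edfs, function(f) {
  ep <- preprocess_session(read_session(f))
  write_epochs(ep, file.path(out, "epochs", ep$session_id))
  ep
})

tab <- drop_report(eps)
write.csv(tab, file.path(out, "epochs", "drop_report.csv"), row.names = FALSE)
print(tab)
message(sprintf("retained %d / %d trials overall",
                sum(tab$n_total - tab$n_dropped), sum(tab$n_total)))
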