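#!/usr/bin/env Rscript
# Train the EEGNet classifier on the hold-out split (test = session with
# fewest dropped trials), evaluate once on the test recording, and run
# the k-fold cross-validation over the non-test sessions.

library(vepdecode)

out <- "results/subject01"
sess <- sort(list.files(file.path(out, "epochs"),
                        pattern = "^S", full.names = TRUE))
eps <- lapply(sess, read_epochs)

split <- make_split(eps)
jsonlite::write_json(split, file.path(out, "split.json"), auto_unbox = TRUE)
message(sprintf("split: train=%s val=%d test=%d",
                paste(split$train, collapse = ","), split$val, split$test))

cfg <- eegnet_config(f1 = 8L, temporal_kernel = 32L)     # desk-scale filter bank
tcfg <- train_config(epochs = 8L, max_lr = 1e-2, seed = 2L)

res <- train_classifier(build_eegnet(cfg, seed = 1), concat_epochs(eps[split$train]),
                        eps[[split$val]], tcfg, verbose = TRUE)
save_model_handle(res$handle, file.path(out, "classifier"))
write.csv(res$history, file.path(out, "classifier", "history.csv"), row.names = FALSE)

rep <- evaluate(res$handle, eps[[split$test]])
jsonlite::write_json(list(accuracy = rep$accuracy, per_class = rep$per_class),
                     file.path(out, "evaluation.json"), auto_unbox = TRUE, digits = NA)
write.csv(rep$confusion, file.path(out, "confusion.csv"))
message(sprintf("test accuracy: %.1f%% (chance %.1f%%)",
                rep$accuracy, 100 / cfg$n_classes))

# lighter epoch budget for the k-fold selection-bias estimate
cv <- cross_validate(cfg, eps, train_config(epochs = 4L, max_lr = 1e-2, seed = 2L),
                     split = split)
jsonlite::write_json(cv, file.path(out, "cross_validation.json"),
                     auto_unbox = TRUE, digits = NA)
message(sprintf("cross-validation mean: %.1f%% over %d folds",
                cv$mean_acc, length(cv$fold_acc)))

cmp <- wilcoxon_compare(rep(rep$accuracy, length(cv$fold_acc)), cv$fold_acc,
                        alternative = "greater")
jsonlite::write_json(unclass(cmp), file.path(out, "comparison.json"),
                     auto_unbox = TRUE, digits = NA)
message(sprintf("test vs CV signed-rank p = %.4f", cmp$p_value))
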