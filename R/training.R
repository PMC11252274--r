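# Training protocol: AdamW + one-cycle LR on cross-entropy, hold-out
# splitting by missing-trial count, grid search, k-fold cross-validation
# and evaluation reports.

#' Training configuration
#'
#' @param max_lr peak learning rate of the one-cycle schedule.
#' @param epochs training epochs (default 30).
#' @param batch_size mini-batch size.
#' @param weight_decay decoupled L2 penalty.
#' @param one_cycle use one-cycle scheduling (constant `max_lr` otherwise).
#' @param pct_start,div_factor,final_div_factor one-cycle shape parameters.
#' @param seed run seed (shuffling, dropout).
#' @export
train_config <- function(max_lr = 2e-3, epochs = 30L, batch_size = 64L,
                         weight_decay = 1e-4, one_cycle = TRUE,
                         pct_start = 0.3, div_factor = 25, final_div_factor = 1e4,
                         seed = 1L) {
  abort_if(epochs < 1 || max_lr <= 0, "need epochs >= 1 and max_lr > 0")
  structure(list(max_lr = max_lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), weight_decay = weight_decay,
                 one_cycle = one_cycle, pct_start = pct_start,
                 div_factor = div_factor, final_div_factor = final_div_factor,
                 seed = as.integer(seed)),
            class = "train_config")
}

# weight-decay applies to weights, not biases / norm parameters
decay_params <- function(params) {
  names(params)[grepl("_w$", names(params))]
}

#' Train a classifier on epoched EEG
#'
#' Minimizes cross-entropy with AdamW under one-cycle LR scheduling.
#' Validation accuracy is computed once per epoch in evaluation mode and
#' the best-validation-epoch weights are retained.
#'
#' @param handle a `model_handle` from [build_eegnet()] / [build_eegnet_plus()].
#' @param train,val `epoch_set`s with disjoint trials.
#' @param cfg a [train_config()].
#' @param verbose print per-epoch progress.
#' @return list with `handle` (best-validation weights) and `history`
#'   (data.frame: epoch, lr, train_loss, train_acc, val_loss, val_acc).
#' @export
train_classifier <- function(handle, train, val = NULL, cfg = train_config(),
                             verbose = FALSE) {
  stopifnot(inherits(handle, "model_handle"))
  n <- dim(train$data)[1]
  abort_if(n == 0, "empty training set")
  labels <- train$labels + 1L
  steps_per_epoch <- max(1L, n %/% cfg$batch_size)
  total_steps <- steps_per_epoch * cfg$epochs
  state <- adamw_init(handle$params)
  dmask <- decay_params(handle$params)
  hist <- data.frame()
  best_val <- -Inf; best <- handle
  step <- 0L
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      tl <- 0; tc <- 0; nb <- 0L
      for (bs in seq_len(steps_per_epoch)) {
        idx <- ord[((bs - 1L) * cfg$batch_size + 1L):min(n, bs * cfg$batch_size)]
        xb <- train$data[idx, , , drop = FALSE]
        yb <- labels[idx]
        step <- step + 1L
        lr <- if (cfg$one_cycle) {
          one_cycle_lr(step, total_steps, cfg$max_lr, cfg$pct_start,
                       cfg$div_factor, cfg$final_div_factor)
        } else cfg$max_lr
        fw <- eegnet_forward(handle, xb, training = TRUE)
        handle$running <- fw$running
        sx <- softmax_xent(fw$logits, yb)
        g <- eegnet_backward(handle, fw$cache, sx$dlogits)
        upd <- adamw_step(handle$params, g, state, lr, cfg$weight_decay,
                          decay_mask = dmask)
        handle$params <- upd$params; state <- upd$state
        tl <- tl + sx$loss
        tc <- tc + mean(max.col(sx$probs) == yb)
        nb <- nb + 1L
      }
      va <- NA_real_; vl <- NA_real_
      if (!is.null(val) && dim(val$data)[1] > 0) {
        lg <- predict_logits(handle, val)
        sv <- softmax_xent(lg, val$labels + 1L)
        vl <- sv$loss
        va <- mean(max.col(lg) == val$labels + 1L)
        if (va > best_val) { best_val <- va; best <- handle }
      }
      hist <- rbind(hist, data.frame(epoch = ep, lr = lr, train_loss = tl / nb,
                                     train_acc = tc / nb, val_loss = vl, val_acc = va))
      if (verbose) {
        message(sprintf("epoch %d: loss %.3f acc %.3f val %.3f", ep,
                        tl / nb, tc / nb, va))
      }
    }
  })
  if (is.null(val)) best <- handle
  best$mode <- "eval"
  list(handle = best, history = hist)
}

#' Hold-out split by missing-trial count
#'
#' The recording with the fewest dropped trials becomes the test set (ties
#' broken by lowest session index); the next-fewest becomes validation;
#' the rest train.
#'
#' @param recordings list of preprocessed `epoch_set`s (>= 3).
#' @return list with integer indices `train`, `val`, `test`.
#' @export
make_split <- function(recordings) {
  abort_if(length(recordings) < 3, "need at least 3 recordings")
  drops <- vapply(recordings, function(e) {
    if (!is.null(e$n_total)) e$n_total - sum(e$retained) else 0L
  }, 0)
  test <- which.min(drops)                       # which.min takes lowest index on ties
  rest <- setdiff(seq_along(recordings), test)
  val <- rest[which.min(drops[rest])]
  list(train = setdiff(rest, val), val = val, test = test)
}

#' Concatenate epoch sets
#' @param sets list of `epoch_set`s with identical geometry.
#' @return one combined `epoch_set`.
#' @export
concat_epochs <- function(sets) {
  data <- do.call(abind_first, list(lapply(sets, function(e) e$data)))
  new_epoch_set(data, unlist(lapply(sets, function(e) e$labels)),
                unlist(lapply(sets, function(e) e$retained)),
                paste(vapply(sets, function(e) e$session_id, ""), collapse = "+"),
                sets[[1]]$fs_hz, sets[[1]]$normalized, sets[[1]]$provenance,
                image_ids = unlist(lapply(sets, function(e) e$image_ids)))
}

abind_first <- function(arrs) {
  d <- dim(arrs[[1]])
  n <- sum(vapply(arrs, function(a) dim(a)[1], 0))
  out <- array(0, dim = c(n, d[2], d[3]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' Evaluate a trained classifier on a held-out epoch set
#'
#' @param handle trained `model_handle`.
#' @param test an `epoch_set`.
#' @return an `evaluation_report`: `accuracy` (%), `per_class` accuracy
#'   vector (%), `confusion` matrix (rows = truth, columns = prediction),
#'   `n` trials.
#' @export
evaluate <- function(handle, test) {
  n <- dim(test$data)[1]
  abort_if(n == 0, "empty test set")
  k <- handle$config$n_classes
  pred <- max.col(predict_logits(handle, test)) - 1L
  truth <- test$labels
  confusion <- matrix(0L, k, k, dimnames = list(truth = 0:(k - 1), pred = 0:(k - 1)))
  for (i in seq_len(n)) confusion[truth[i] + 1L, pred[i] + 1L] <- confusion[truth[i] + 1L, pred[i] + 1L] + 1L
  per_class <- ifelse(rowSums(confusion) > 0, 100 * diag(confusion) / rowSums(confusion), NA)
  structure(list(accuracy = 100 * sum(diag(confusion)) / n,
                 per_class = per_class, confusion = confusion, n = n),
            class = "evaluation_report")
}

#' Grid search over model configurations
#'
#' Trains every candidate on the training set, scores it on validation,
#' picks the best (ties broken by smaller parameter count) and retrains it
#' on train + validation before the single test-set evaluation.
#'
#' @param grid list of [eegnet_config()]s.
#' @param recordings list of preprocessed `epoch_set`s.
#' @param split a [make_split()] result.
#' @param cfg a [train_config()].
#' @param builder model constructor (default [build_eegnet()]).
#' @return list: `best_config`, `table` (one row per config), `handle`
#'   (final model retrained on train+validation).
#' @export
grid_search <- function(grid, recordings, split, cfg = train_config(),
                        builder = build_eegnet) {
  abort_if(length(grid) == 0, "empty grid")
  tr <- concat_epochs(recordings[split$train])
  va <- recordings[[split$val]]
  rows <- lapply(seq_along(grid), function(i) {
    h <- builder(grid[[i]], seed = cfg$seed + i)
    res <- train_classifier(h, tr, va, cfg)
    data.frame(config = i, n_params = n_parameters(h),
               val_acc = max(res$history$val_acc, na.rm = TRUE))
  })
  tab <- do.call(rbind, rows)
  ord <- order(-tab$val_acc, tab$n_params)
  best_i <- tab$config[ord[1]]
  final <- train_classifier(builder(grid[[best_i]], seed = cfg$seed + best_i),
                            concat_epochs(recordings[c(split$train, split$val)]),
                            val = NULL, cfg = cfg)
  list(best_config = grid[[best_i]], table = tab, handle = final$handle)
}

#' k-fold cross-validation over non-test recordings
#'
#' Every non-test recording is held out exactly once (k = number of
#' non-test recordings, folds assigned by session index); the model is
#' trained on the remaining k-1 recordings and scored on the held-out one.
#'
#' @param config an [eegnet_config()].
#' @param recordings list of preprocessed `epoch_set`s.
#' @param cfg a [train_config()].
#' @param split optional [make_split()] result (recomputed otherwise).
#' @param builder model constructor.
#' @return list with `fold_acc` (%, one per fold) and `mean_acc` (%).
#' @export
cross_validate <- function(config, recordings, cfg = train_config(),
                           split = NULL, builder = build_eegnet) {
  if (is.null(split)) split <- make_split(recordings)
  folds <- sort(c(split$train, split$val))
  abort_if(length(folds) < 2, "need >= 2 non-test recordings")
  accs <- vapply(folds, function(f) {
    tr <- concat_epochs(recordings[setdiff(folds, f)])
    h <- builder(config, seed = cfg$seed)
    res <- train_classifier(h, tr, val = NULL, cfg = cfg)
    evaluate(res$handle, recordings[[f]])$accuracy
  }, 0)
  list(fold_acc = accs, mean_acc = mean(accs))
}
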