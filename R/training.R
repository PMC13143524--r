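# Training protocol: inverse-frequency weighted cross-entropy, Adam,
# per-fold early stopping on validation loss, checkpoint on best validation
# macro-F1, and stratified k-fold cross-validation.

#' Training configuration
#'
#' Defaults follow the study protocol: at most 50 epochs, batch size 16,
#' Adam with learning rate 1e-4 (beta 0.9/0.999, eps 1e-8, no weight decay,
#' no schedule), early stopping with patience 10 monitoring validation
#' loss (strict improvement, min_delta 0), checkpoint selection on
#' validation macro-F1.
#'
#' @param epochs_max Maximum epochs.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement); must not exceed `epochs_max`.
#' @param seed Integer seed controlling split, init, shuffling, augmentation
#'   and dropout.
#' @param augment Apply training-time augmentation (flip / rotate / jitter).
#' @param min_delta Improvement margin for early stopping (default 0).
#' @return A `train_config` list.
#' @export
train_config <- function(epochs_max = 50L, batch_size = 16L, lr = 1e-4,
                         patience = 10L, seed = 1L, augment = TRUE,
                         min_delta = 0) {
  stopifnot(epochs_max >= 1, batch_size >= 1, lr > 0, patience >= 1,
            patience <= epochs_max)
  structure(list(epochs_max = as.integer(epochs_max),
                 batch_size = as.integer(batch_size), lr = lr,
                 patience = as.integer(patience), seed = as.integer(seed),
                 augment = augment, min_delta = min_delta),
            class = "train_config")
}

#' Inverse-frequency weighted cross-entropy loss
#'
#' L = -(1/N) sum_n w_(y_n) log softmax(z_n)_(y_n). The normalization is by
#' the batch size N exactly (not by the weight sum), so uniform unit
#' weights recover the standard mean cross-entropy.
#'
#' @param logits N x C matrix of raw scores.
#' @param labels Integer class ids in 1..C.
#' @param weights Length-C class weights (default: all 1).
#' @return Scalar loss.
#' @export
weighted_cross_entropy <- function(logits, labels,
                                   weights = rep(1, ncol(logits))) {
  ce_forward_backward(logits, labels, weights)$loss
}

# loss plus gradient w.r.t. logits: dz_n = w_(y_n) (p_n - onehot_n) / N
ce_forward_backward <- function(logits, labels, weights) {
  if (!all(is.finite(logits))) stop("non-finite logits in loss computation")
  N <- nrow(logits); C <- ncol(logits)
  stopifnot(length(labels) == N, all(labels >= 1), all(labels <= C),
            length(weights) == C)
  zs <- logits - apply(logits, 1, max)
  lse <- log(rowSums(exp(zs)))
  logp <- zs - lse
  wy <- weights[labels]
  loss <- -mean(wy * logp[cbind(seq_len(N), labels)])
  p <- exp(logp)
  onehot <- matrix(0, N, C)
  onehot[cbind(seq_len(N), labels)] <- 1
  grad <- wy * (p - onehot) / N
  list(loss = loss, grad = grad)
}

#' Early-stopping rule on a validation-loss trajectory
#'
#' Improvement means a strictly lower loss than the best seen so far (by
#' more than `min_delta`); training stops once `patience` consecutive
#' epochs have passed without improvement.
#'
#' @param val_losses Numeric vector of per-epoch validation losses.
#' @param patience Number of tolerated non-improving epochs.
#' @param min_delta Required improvement margin.
#' @return The epoch (index) after which training stops, or
#'   `length(val_losses)` if the rule never triggers.
#' @export
early_stop_epoch <- function(val_losses, patience, min_delta = 0) {
  best <- Inf
  since <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best - min_delta) {
      best <- val_losses[e]
      since <- 0L
    } else {
      since <- since + 1L
      if (since >= patience) return(e)
    }
  }
  length(val_losses)
}

## ---- data plumbing ---------------------------------------------------------

# stack multi_color_image objects into the channel-first batch layout
# [3, S, S, N] the network consumes
mci_batch <- function(mcis) {
  S <- dim(mcis[[1]]$rgb)[1]
  n <- length(mcis)
  out <- list()
  for (space in c("rgb", "hsv", "ycbcr")) {
    a <- array(0, c(3, S, S, n))
    for (i in seq_len(n)) a[, , , i] <- aperm(mcis[[i]][[space]], c(3, 1, 2))
    out[[space]] <- a
  }
  out
}

# load raw RGB images at working resolution (augmentation input)
load_raw_images <- function(filepaths, image_size) {
  lapply(filepaths, function(f)
    resize_bilinear(read_image(f), image_size, image_size))
}

# forward a precomputed tensor set in evaluation mode, batched
predict_logits <- function(model, tensors, batch_size = 64L) {
  n <- dim(tensors$rgb)[4]
  out <- NULL
  for (s in seq(1, n, by = batch_size)) {
    e <- min(s + batch_size - 1, n)
    spaces <- if (length(model$branches) == 1L) "rgb"
              else c("rgb", "hsv", "ycbcr")
    sub <- lapply(tensors[spaces], function(a) a[, , , s:e, drop = FALSE])
    out <- rbind(out, model_forward(model, sub, training = FALSE))
  }
  out
}

## ---- per-fold training loop ------------------------------------------------

#' Train a model on one fold
#'
#' Computes normalization statistics from the fold's training split only,
#' runs minibatch Adam with weighted cross-entropy for at most
#' `config$epochs_max` epochs, evaluates the validation split each epoch,
#' applies early stopping on validation loss, and checkpoints whenever the
#' validation macro-F1 improves (the previous checkpoint file is deleted).
#'
#' @param model A `csfnet_model` (freshly initialized).
#' @param manifest A `csf_manifest`.
#' @param train_idx,val_idx Row indices of the training / validation split.
#' @param config A [train_config()].
#' @param run_dir Directory for the checkpoint, history CSV and stats
#'   sidecar.
#' @param fold Fold id (used in file names and logs).
#' @param verbose Print per-epoch log lines.
#' @return A `train_run_state`: per-epoch `history` data.frame, best
#'   macro-F1 / epoch, `checkpoint` path, `norm_stats`.
#' @export
train_fold <- function(model, manifest, train_idx, val_idx, config,
                       run_dir = tempfile("csfnet-run-"), fold = 1L,
                       verbose = FALSE) {
  if (length(train_idx) == 0L || length(val_idx) == 0L)
    stop("empty train or validation split")
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  S <- model$config$image_size
  weights <- compute_class_weights(
    as.integer(table(factor(manifest$class_id[train_idx],
                            levels = seq_along(model$class_names)))))
  raw_train <- load_raw_images(manifest$filepath[train_idx], S)
  stats <- stats_from_images(raw_train, S, fold = fold, split = "train")
  save_norm_stats(stats, file.path(run_dir,
                                   sprintf("fold%02d_norm_stats.json", fold)))
  y_train <- manifest$class_id[train_idx]
  val_tensors <- mci_batch(lapply(load_raw_images(manifest$filepath[val_idx], S),
                                  decompose_and_normalize, stats = stats))
  y_val <- manifest$class_id[val_idx]
  C <- length(model$class_names)

  params <- model_params(model)
  opt <- opt_adam(params, lr = config$lr)
  best_loss <- Inf; since <- 0L
  best_f1 <- -Inf; best_epoch <- NA_integer_
  ckpt <- NULL
  history <- NULL

  for (epoch in seq_len(config$epochs_max)) {
    ord <- sample.int(length(train_idx))
    tr_loss <- 0; tr_pred <- integer(length(train_idx))
    for (s in seq(1, length(ord), by = config$batch_size)) {
      e <- min(s + config$batch_size - 1, length(ord))
      bi <- ord[s:e]
      mcis <- lapply(bi, function(i) {
        img <- raw_train[[i]]
        if (isTRUE(config$augment)) img <- augment_rgb(img)
        decompose_and_normalize(img, stats)
      })
      batch <- mci_batch(mcis)
      logits <- model_forward(model, batch, training = TRUE)
      fb <- ce_forward_backward(logits, y_train[bi], weights)
      if (!is.finite(fb$loss))
        stop("non-finite training loss at epoch ", epoch, "; aborting")
      zero_grads(params)
      model_backward(model, fb$grad)
      opt_step(opt)
      tr_loss <- tr_loss + fb$loss * length(bi)
      tr_pred[s:e] <- max.col(logits)
    }
    tr_loss <- tr_loss / length(train_idx)
    tr_cm <- confusion_matrix(y_train[ord], tr_pred, C)
    tr_m <- macro_metrics(tr_cm)

    val_logits <- predict_logits(model, val_tensors,
                                 batch_size = max(config$batch_size, 64L))
    val_fb <- ce_forward_backward(val_logits, y_val, weights)
    val_cm <- confusion_matrix(y_val, max.col(val_logits), C)
    val_m <- macro_metrics(val_cm)

    history <- rbind(history, data.frame(
      epoch = epoch,
      train_loss = tr_loss, train_accuracy = tr_m$accuracy,
      train_precision = tr_m$precision, train_recall = tr_m$recall,
      train_f1 = tr_m$f1,
      val_loss = val_fb$loss, val_accuracy = val_m$accuracy,
      val_precision = val_m$precision, val_recall = val_m$recall,
      val_f1 = val_m$f1))
    if (verbose)
      message(sprintf(
        "[fold %d] epoch %02d  train loss %.4f acc %.3f | val loss %.4f acc %.3f F1 %.3f",
        fold, epoch, tr_loss, tr_m$accuracy, val_fb$loss, val_m$accuracy,
        val_m$f1))

    if (val_m$f1 > best_f1) {
      best_f1 <- val_m$f1
      best_epoch <- epoch
      new_ckpt <- file.path(run_dir,
                            sprintf("fold%02d_epoch%03d.rds", fold, epoch))
      save_checkpoint(model, new_ckpt, norm_stats = stats,
                      extra = list(fold = fold, epoch = epoch,
                                   val_f1 = best_f1))
      if (!is.null(ckpt) && file.exists(ckpt)) unlink(ckpt)
      ckpt <- new_ckpt
    }
    if (val_fb$loss < best_loss - config$min_delta) {
      best_loss <- val_fb$loss
      since <- 0L
    } else {
      since <- since + 1L
      if (since >= config$patience) break
    }
  }
  utils::write.csv(history,
                   file.path(run_dir, sprintf("fold%02d_history.csv", fold)),
                   row.names = FALSE)
  structure(list(history = history, best_f1 = best_f1,
                 best_epoch = best_epoch, checkpoint = ckpt,
                 norm_stats = stats, epochs_run = nrow(history),
                 run_dir = run_dir, fold = fold),
            class = "train_run_state")
}

#' Stratified k-fold cross-validation of one model variant
#'
#' For each fold: re-initialize the model from scratch (seeded), compute
#' normalization statistics on the fold's training split, train with early
#' stopping, restore the best-macro-F1 checkpoint, and evaluate on the
#' fold's validation split.
#'
#' @param manifest A `csf_manifest`.
#' @param variant Variant tag for [build_variant()].
#' @param mconfig A [model_config()].
#' @param tconfig A [train_config()].
#' @param k Number of folds.
#' @param run_dir Output directory.
#' @param verbose Print progress.
#' @return A `cv_result`: `fold_reports` (per-fold evaluation reports),
#'   `aggregate` (mean ± sd table), `folds`, `run_dir`, `variant`.
#' @export
run_cross_validation <- function(manifest, variant = "csfnet",
                                 mconfig = model_config(),
                                 tconfig = train_config(), k = 5L,
                                 run_dir = tempfile("csfnet-cv-"),
                                 verbose = FALSE) {
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  folds <- stratified_kfold(manifest, k = k, seed = tconfig$seed)
  export_folds(manifest, folds, file.path(run_dir, "folds.csv"))
  fold_reports <- vector("list", k)
  for (fold in seq_len(k)) {
    idx <- fold_indices(folds, fold)
    set.seed(derive_seed(tconfig$seed, fold, 4242L))
    model <- build_variant(variant, mconfig)
    state <- train_fold(model, manifest, idx$train, idx$val, tconfig,
                        run_dir = run_dir, fold = fold, verbose = verbose)
    best <- load_checkpoint(state$checkpoint)
    stats <- attr(best, "norm_stats")
    val_mcis <- lapply(manifest$filepath[idx$val], function(f)
      decompose_and_normalize(read_image(f), stats))
    probs <- softmax_rows(predict_logits(best, mci_batch(val_mcis)))
    fold_reports[[fold]] <- eval_report(manifest$class_id[idx$val], probs,
                                        class_names = best$class_names,
                                        fold = fold)
    fold_reports[[fold]]$train_state <- state
  }
  metrics_df <- do.call(rbind, lapply(fold_reports, function(r)
    data.frame(fold = r$fold, accuracy = r$metrics$accuracy,
               precision = r$metrics$precision, recall = r$metrics$recall,
               f1 = r$metrics$f1, mauc = r$metrics$mauc)))
  utils::write.csv(metrics_df, file.path(run_dir, "fold_metrics.csv"),
                   row.names = FALSE)
  agg <- aggregate_folds(metrics_df[, -1, drop = FALSE])
  utils::write.csv(agg, file.path(run_dir, "aggregate_metrics.csv"),
                   row.names = FALSE)
  structure(list(fold_reports = fold_reports, fold_metrics = metrics_df,
                 aggregate = agg, folds = folds, run_dir = run_dir,
                 variant = variant),
            class = "cv_result")
}
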