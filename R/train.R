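# Training loops (MAE pre-training and classifier fine-tuning), the
# warmup + cosine-annealing schedule, AdamW, and evaluation metrics.

#' Learning-rate schedule configuration
#'
#' @param base_lr Peak learning rate reached at the end of warmup.
#' @param warmup_epochs Epochs of linear per-epoch warmup.
#' @param total_epochs Total training epochs.
#' @param weight_decay Decoupled weight-decay coefficient.
#' @param min_lr Floor of the cosine-annealing phase.
#' @return A `schedule_config` list.
#' @export
schedule_config <- function(base_lr = 6.25e-5, warmup_epochs = 20L,
                            total_epochs = 400L, weight_decay = 5e-4,
                            min_lr = 0) {
  if (warmup_epochs >= total_epochs) stopf("warmup_epochs must be < total_epochs")
  if (base_lr <= 0 || total_epochs <= 0) stopf("base_lr and total_epochs must be positive")
  structure(
    list(base_lr = base_lr, warmup_epochs = as.integer(warmup_epochs),
         total_epochs = as.integer(total_epochs),
         weight_decay = weight_decay, min_lr = min_lr),
    class = "schedule_config"
  )
}

#' Learning rate at a given (0-based) epoch
#'
#' Linear ramp from `base_lr / warmup_epochs` up to `base_lr` over the
#' warmup epochs, then cosine annealing from `base_lr` down to `min_lr`
#' over the remaining epochs. Continuous at the boundary and non-increasing
#' afterwards.
#'
#' @param epoch 0-based epoch index, `0 <= epoch < total_epochs`.
#' @param cfg A [schedule_config()].
#' @return The learning rate.
#' @export
lr_at <- function(epoch, cfg) {
  if (epoch < 0 || epoch >= cfg$total_epochs) {
    stopf("epoch %d out of range [0, %d)", epoch, cfg$total_epochs)
  }
  if (cfg$warmup_epochs > 0L && epoch < cfg$warmup_epochs) {
    return(cfg$base_lr * (epoch + 1) / cfg$warmup_epochs)
  }
  t <- epoch - cfg$warmup_epochs
  T <- cfg$total_epochs - cfg$warmup_epochs
  cfg$min_lr + (cfg$base_lr - cfg$min_lr) * (1 + cos(pi * t / T)) / 2
}

# --- AdamW -------------------------------------------------------------------

adamw_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

# Decoupled weight decay applied to all updated parameters; keys listed in
# `fixed_keys` (and keys with no gradient) are left untouched.
adamw_step <- function(params, grads, state, lr, weight_decay,
                       fixed_keys = character(), beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (key in names(grads)) {
    if (key %in% fixed_keys) next
    g <- grads[[key]]
    state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
    state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g^2
    mhat <- state$m[[key]] / bc1
    vhat <- state$v[[key]] / bc2
    params[[key]] <- params[[key]] -
      lr * (mhat / (sqrt(vhat) + eps) + weight_decay * params[[key]])
  }
  list(params = params, state = state)
}

accumulate_grads <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (key in names(g)) {
    acc[[key]] <- if (is.null(acc[[key]])) g[[key]] else acc[[key]] + g[[key]]
  }
  acc
}

scale_grads <- function(g, f) lapply(g, function(x) x * f)

# --- MAE pre-training --------------------------------------------------------

#' Pre-train an MAE on image records
#'
#' Each step draws a batch, resizes/standardizes the images, draws a fresh
#' masking plan per image, and takes one AdamW step on the masked-patch
#' reconstruction loss.
#'
#' @param mae A model from [build_mae()].
#' @param records Image records (any split; pre-training is unsupervised).
#' @param steps Optimizer steps.
#' @param batch_size Images per step.
#' @param mask_ratio Masked patch fraction.
#' @param schedule A [schedule_config()]; the schedule is applied per step
#'   (each step treated as one epoch of the schedule, suitable for
#'   step-scale toy runs).
#' @param seed Integer seed covering batch sampling and masking.
#' @param norm_pix Use per-patch-normalized reconstruction targets
#'   (default); raw-pixel targets are the alternative.
#' @return List `(model, log)`; `log` is a data frame with per-step loss.
#' @export
train_mae <- function(mae, records, steps = 200L, batch_size = 16L,
                      mask_ratio = 0.75,
                      schedule = schedule_config(base_lr = 1e-3,
                                                 warmup_epochs = 10L,
                                                 total_epochs = steps,
                                                 weight_decay = 0.05),
                      seed = 1L, norm_pix = TRUE) {
  size <- mae$cfg$image_size
  with_seed(as.integer(seed), {
    imgs <- lapply(records, function(r) patchify(
      preprocess_eval(r$pixels, size), mae$cfg$patch_size))
    state <- adamw_init(mae$params)
    losses <- numeric(steps)
    N <- mae$cfg$n_patches
    for (step in seq_len(steps)) {
      idx <- sample.int(length(imgs), min(batch_size, length(imgs)))
      acc <- NULL
      tot <- 0
      for (i in idx) {
        plan <- random_mask(N, mask_ratio)
        lg <- mae_loss_and_grads(mae, imgs[[i]], plan, norm_pix = norm_pix)
        tot <- tot + lg$loss
        acc <- accumulate_grads(acc, lg$grads)
      }
      acc <- scale_grads(acc, 1 / length(idx))
      lr <- lr_at(step - 1L, schedule)
      st <- adamw_step(mae$params, acc, state, lr, schedule$weight_decay,
                       mae$fixed_keys)
      mae$params <- st$params
      state <- st$state
      losses[step] <- tot / length(idx)
    }
    list(model = mae, log = data.frame(step = seq_len(steps), loss = losses))
  })
}

# --- classifier training -----------------------------------------------------

predict_scores <- function(model, feature, margin_cfg = loss_config()) {
  if (model$head == "dsa") {
    subcenter_cosines(feature, model$params[["subcenters"]],
                      model$n_subcenters, margin_cfg$eps)$cosines
  } else {
    as.vector(feature %*% model$params[["head.weight"]]) +
      model$params[["head.bias"]]
  }
}

#' Train the fusion classifier
#'
#' AdamW with the warmup + cosine schedule; per-class margins are computed
#' once from the training-split class counts. Augmentation is re-drawn
#' every epoch; the best-validation-accuracy checkpoint is retained (ties
#' broken towards the earlier epoch). Deterministic for a given seed.
#'
#' @param model A model from [build_classifier()] (optionally after
#'   [transfer_weights()]).
#' @param train_records,val_records Image records.
#' @param loss_type One of `"dynamic-subcenter"`, `"subcenter"`,
#'   `"arcface"`, `"ce"`: the loss-ablation axis. `arcface` uses
#'   K = 1 behaviorally (only sub-center 1 ever selected at K = 1 models);
#'   static variants use a fixed 0.5 margin; `ce` requires a
#'   `head = "linear"` model.
#' @param epochs,batch_size Training length and batch size.
#' @param schedule A [schedule_config()] (its `total_epochs` should be
#'   >= `epochs`).
#' @param augment An [augment_config()] whose `target_size` matches the
#'   backbone input size.
#' @param loss_cfg A [loss_config()].
#' @param margin_a,margin_b,margin_lambda Dynamic-margin parameters.
#' @param seed Integer seed covering shuffling and augmentation.
#' @return List `(model, last_model, log, margins)`: best and final models
#'   and the per-epoch data frame of loss, validation accuracy and lr.
#' @export
train_classifier <- function(model, train_records, val_records,
                             loss_type = c("dynamic-subcenter", "subcenter",
                                           "arcface", "ce"),
                             epochs = 30L, batch_size = 32L,
                             schedule = schedule_config(base_lr = 1e-3,
                                                        warmup_epochs = 3L,
                                                        total_epochs = epochs,
                                                        weight_decay = 5e-4),
                             augment = augment_config(target_size = model$cfg$image_size),
                             loss_cfg = loss_config(),
                             margin_a = 0.5, margin_b = 0.05,
                             margin_lambda = -0.5, seed = 1L) {
  loss_type <- match.arg(loss_type)
  labels <- vapply(train_records, `[[`, integer(1), "label")
  if (length(unique(labels)) < 2L) stopf("training split must contain at least 2 classes")
  if ((loss_type == "ce") != (model$head == "linear")) {
    stopf("loss_type '%s' requires a model with head = '%s'", loss_type,
          if (loss_type == "ce") "linear" else "dsa")
  }
  C <- model$n_classes
  counts <- tabulate(labels, nbins = C)
  margins <- if (loss_type == "dynamic-subcenter") {
    compute_margins(pmax(counts, 1L), margin_a, margin_b, margin_lambda)
  } else {
    structure(list(margins = rep(if (loss_type == "ce") 0 else margin_a, C),
                   class_counts = counts, a = margin_a, b = margin_b,
                   lambda = margin_lambda), class = "margin_table")
  }
  if (length(val_records) == 0L) {
    warning("validation split is empty; the last checkpoint will be kept",
            call. = FALSE)
  }

  with_seed(as.integer(seed), {
    state <- adamw_init(model$params)
    best <- list(acc = -Inf, epoch = NA_integer_, model = model)
    log <- data.frame(epoch = integer(), loss = numeric(), val_acc = numeric(),
                      lr = numeric())
    for (epoch in seq_len(epochs)) {
      lr <- lr_at(epoch - 1L, schedule)
      ord <- sample.int(length(train_records))
      ep_loss <- 0
      n_batches <- 0L
      for (start in seq(1L, length(ord), by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, length(ord))]
        fwds <- vector("list", length(idx))
        feats <- matrix(0, length(idx), model$cfg$dim)
        for (j in seq_along(idx)) {
          r <- train_records[[idx[j]]]
          img <- preprocess_train(r$pixels, augment)
          fwds[[j]] <- forward_features(model, img, keep_caches = TRUE)
          feats[j, ] <- fwds[[j]]$feature
        }
        blabels <- vapply(train_records[idx], `[[`, integer(1), "label")
        acc <- NULL
        if (model$head == "dsa") {
          hl <- dsa_loss(feats, blabels, model$params[["subcenters"]],
                         margins, loss_cfg, model$n_subcenters, grads = TRUE)
          acc <- list("subcenters" = hl$dW)
        } else {
          hl <- ce_head_loss(feats, blabels, model$params[["head.weight"]],
                             model$params[["head.bias"]], grads = TRUE)
          acc <- list("head.weight" = hl$dWh, "head.bias" = hl$dbh)
        }
        for (j in seq_along(idx)) {
          acc <- accumulate_grads(
            acc, features_backward(model, fwds[[j]], hl$dembeddings[j, ]))
        }
        st <- adamw_step(model$params, acc, state, lr, schedule$weight_decay,
                         model$fixed_keys)
        model$params <- st$params
        state <- st$state
        ep_loss <- ep_loss + hl$loss
        n_batches <- n_batches + 1L
      }
      val_acc <- if (length(val_records) > 0L) {
        evaluate(model, val_records)$accuracy
      } else {
        NA_real_
      }
      log <- rbind(log, data.frame(epoch = epoch, loss = ep_loss / n_batches,
                                   val_acc = val_acc, lr = lr))
      if (!is.na(val_acc) && val_acc > best$acc) {
        best <- list(acc = val_acc, epoch = epoch, model = model)
      }
    }
    if (is.infinite(best$acc)) best$model <- model
    list(model = best$model, last_model = model, log = log, margins = margins,
         best_epoch = best$epoch)
  })
}

#' Evaluate a classifier on labeled records
#'
#' Predictions score each class by its best sub-center cosine (`dsa` head)
#' or by linear logits (`linear` head). Reports overall accuracy, per-class
#' precision/recall/F1 and their macro averages (all in percent), and the
#' confusion matrix with true classes as rows. A class absent from the
#' records has recall reported as 0 and is flagged in `undefined_recall`.
#'
#' @param model A trained model.
#' @param records Labeled image records.
#' @return An `eval_report` list; see [classification_report()].
#' @export
evaluate <- function(model, records) {
  preds <- integer(length(records))
  truth <- vapply(records, `[[`, integer(1), "label")
  for (i in seq_along(records)) {
    img <- preprocess_eval(records[[i]]$pixels, model$cfg$image_size)
    f <- forward_features(model, img)
    preds[i] <- which.max(predict_scores(model, f$feature))
  }
  classification_report(truth, preds, model$n_classes)
}

#' Per-class classification metrics from labels and predictions
#'
#' @param truth,predictions 1-based class index vectors of equal length.
#' @param n_classes Number of classes.
#' @return An `eval_report`: overall accuracy, per-class
#'   precision/recall/F1 and their macro averages (percent), the confusion
#'   matrix (rows = true classes), and `undefined_recall` flagging classes
#'   absent from `truth` (whose recall is reported as 0).
#' @export
classification_report <- function(truth, predictions, n_classes) {
  C <- as.integer(n_classes)
  confusion <- matrix(0L, C, C)
  for (i in seq_along(truth)) {
    confusion[truth[i], predictions[i]] <- confusion[truth[i], predictions[i]] + 1L
  }
  tp <- diag(confusion)
  row_tot <- rowSums(confusion)   # true-class counts
  col_tot <- colSums(confusion)   # predicted-class counts
  precision <- ifelse(col_tot > 0, tp / col_tot, 0) * 100
  recall <- ifelse(row_tot > 0, tp / row_tot, 0) * 100
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  structure(
    list(accuracy = sum(tp) / length(truth) * 100,
         precision = precision, recall = recall, f1 = f1,
         macro_precision = mean(precision), macro_recall = mean(recall),
         macro_f1 = mean(f1), confusion = confusion,
         undefined_recall = which(row_tot == 0), n = length(truth),
         predictions = predictions, truth = truth),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("accuracy: %.2f%% (n = %d)\n", x$accuracy, x$n))
  cat(sprintf("macro precision / recall / F1: %.2f%% / %.2f%% / %.2f%%\n",
              x$macro_precision, x$macro_recall, x$macro_f1))
  cat("confusion matrix (rows = true):\n")
  print(x$confusion)
  invisible(x)
}

#' Export classification features
#'
#' One row per record: the D-dimensional fused feature plus the label.
#'
#' @param model A trained model.
#' @param records Image records.
#' @param path Optional TSV output path (written with a header).
#' @return Data frame with columns `f1..fD` and `label`.
#' @export
export_embeddings <- function(model, records, path = NULL) {
  D <- model$cfg$dim
  M <- matrix(0, length(records), D)
  for (i in seq_along(records)) {
    img <- preprocess_eval(records[[i]]$pixels, model$cfg$image_size)
    M[i, ] <- forward_features(model, img)$feature
  }
  df <- as.data.frame(M)
  names(df) <- paste0("f", seq_len(D))
  df$label <- vapply(records, `[[`, integer(1), "label")
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  df
}
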