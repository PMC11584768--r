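# Seeded training and evaluation loops. Defaults follow the reference
# training configuration: Adam (weight decay 1e-4), learning rate 1e-3
# cosine-annealed to 1e-5, batch size 4, 400 epochs, 224 px inputs,
# rotate/flip/contrast augmentation.

#' Training configuration
#'
#' @param lr,lr_min initial and final learning rate of the cosine schedule.
#' @param weight_decay Adam weight decay.
#' @param batch_size images per optimization step.
#' @param epochs training epochs.
#' @param input_size square input resolution (pixels).
#' @param augment apply rotate/flip/contrast augmentation.
#' @param contrast contrast jitter fraction.
#' @param val_fraction fraction of training images held out for best-Dice
#'   checkpoint selection.
#' @param precision `"single"` runs the convolution gemms in single
#'   precision (the usual working precision for network training);
#'   `"double"` keeps everything in double, as all non-training code paths
#'   do.
#' @param seed master seed driving shuffling, augmentation and weight init.
#' @return a `train_config` list.
#' @export
train_config <- function(lr = 1e-3, lr_min = 1e-5, weight_decay = 1e-4,
                         batch_size = 4L, epochs = 400L, input_size = 224L,
                         augment = TRUE, contrast = 0.2,
                         val_fraction = 0.1,
                         precision = c("single", "double"), seed = 42L) {
  stopifnot(lr > lr_min, lr_min > 0, epochs >= 1L, batch_size >= 1L)
  structure(list(lr = lr, lr_min = lr_min, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 input_size = as.integer(input_size),
                 augment = isTRUE(augment), contrast = contrast,
                 val_fraction = val_fraction,
                 precision = match.arg(precision),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Cosine-annealed learning rate
#'
#' `lr` at epoch 0 and exactly `lr_min` at the final epoch.
#'
#' @param epoch 0-based epoch index; @param cfg a [train_config()].
#' @return the learning rate for that epoch.
#' @export
cosine_lr <- function(epoch, cfg) {
  if (cfg$epochs == 1L) return(cfg$lr)
  t <- epoch / (cfg$epochs - 1L)
  cfg$lr_min + 0.5 * (cfg$lr - cfg$lr_min) * (1 + cos(pi * t))
}

deep_copy <- function(params) lapply(params, function(a) a + 0)

zero_like <- function(params) lapply(params, function(a) {
  z <- numeric(length(a)); dim(z) <- dim(a); z
})

# mean Dice (%) of a model over a sample list
mean_dice <- function(model, samples, batch_size = 4L) {
  if (!length(samples)) return(NA_real_)
  ds <- vapply(samples, function(s) {
    pred <- model_forward(model, array(s$image, c(dim(s$image), 1L)))
    evaluate_metrics(pred[, , 1, 1], s$mask)$dice
  }, numeric(1))
  mean(ds)
}

#' Train a segmentation model
#'
#' Runs seeded Adam optimization of the compound BCE+Dice loss with a
#' cosine-annealed learning rate, logging per-epoch training loss and
#' held-out Dice, and keeping the best-Dice weights.
#'
#' @param model_cfg a [model_config()]; @param train_cfg a [train_config()];
#' @param data_root dataset directory (see [load_dataset()]); alternatively
#'   pass a ready sample list via `samples`.
#' @param samples optional list of `segmentation_sample`s overriding
#'   `data_root`.
#' @param checkpoint optional path; the best-Dice checkpoint is written
#'   there each time it improves.
#' @param verbose print one line per epoch.
#' @return list: `model` (best weights), `final_model`, `history`
#'   (data.frame epoch/lr/loss/val_dice), `epoch1_model`.
#' @export
train <- function(model_cfg, train_cfg, data_root = NULL, samples = NULL,
                  checkpoint = NULL, verbose = TRUE) {
  if (is.null(samples))
    samples <- load_dataset(data_root, "train", train_cfg$input_size)
  if (!length(samples)) stop("no training samples")
  if (identical(train_cfg$precision, "single")) {
    oldopt <- options(dranet.fp32 = TRUE)
    on.exit(options(oldopt), add = TRUE)
  }
  set.seed(train_cfg$seed)
  model <- assemble(model_cfg)
  nval <- max(0L, round(train_cfg$val_fraction * length(samples)))
  if (nval > 0L && length(samples) - nval >= 1L) {
    vidx <- sample(seq_along(samples), nval)
    val <- samples[vidx]; tr <- samples[-vidx]
  } else { val <- list(); tr <- samples }

  params <- deep_copy(flatten_params(model))
  model <- set_params(model, params)
  mstate <- zero_like(params); vstate <- zero_like(params)
  step <- 0L
  history <- data.frame()
  best <- list(dice = -Inf, params = NULL)
  epoch1 <- NULL

  for (epoch in seq_len(train_cfg$epochs) - 1L) {
    lr <- cosine_lr(epoch, train_cfg)
    idx <- sample(seq_along(tr))
    losses <- c()
    for (start in seq(1L, length(idx), by = train_cfg$batch_size)) {
      bidx <- idx[start:min(start + train_cfg$batch_size - 1L, length(idx))]
      bs <- lapply(tr[bidx], function(s) {
        if (train_cfg$augment) augment_sample(s$image, s$mask, train_cfg$contrast)
        else list(image = s$image, mask = s$mask)
      })
      b <- stack_batch(bs)
      fw <- model_forward(model, b$x, training = TRUE)
      loss <- total_loss(fw$y, b$y)
      if (!is.finite(loss))
        stop(sprintf("non-finite loss at epoch %d (batch starting %d): %g",
                     epoch, start, loss))
      gy <- total_loss_grad(fw$y, b$y)
      grads <- model_backward(model, fw$cache, gy)
      grads <- grads[names(params)]
      step <- step + 1L
      cpp_adam_step(params, grads, mstate, vstate, lr, 0.9, 0.999, 1e-8,
                    train_cfg$weight_decay, step)
      losses <- c(losses, loss)
    }
    vdice <- mean_dice(model, val)
    history <- rbind(history, data.frame(epoch = epoch, lr = lr,
                                         loss = mean(losses),
                                         val_dice = vdice))
    if (verbose)
      message(sprintf("epoch %3d  lr %.2e  loss %.4f  val Dice %s",
                      epoch, lr, mean(losses),
                      if (is.na(vdice)) "-" else sprintf("%.2f%%", vdice)))
    if (epoch == 0L) epoch1 <- set_params(model, deep_copy(params))
    score <- if (is.na(vdice)) -mean(losses) else vdice
    if (score > best$dice) {
      best$dice <- score
      best$params <- deep_copy(params)
      if (!is.null(checkpoint)) {
        bm <- set_params(model, best$params)
        save_checkpoint(bm, checkpoint,
                        extra = list(seed = train_cfg$seed, epoch = epoch,
                                     history = history))
      }
    }
  }
  best_model <- set_params(model, best$params %||% params)
  list(model = best_model, final_model = model, history = history,
       epoch1_model = epoch1)
}

#' Evaluate a model (or checkpoint) on a dataset split
#'
#' Writes per-image and aggregate metrics (JSON + CSV) and, optionally, the
#' predicted masks as PNGs.
#'
#' @param model a `dranet_model` or a checkpoint path.
#' @param data_root dataset directory; @param split split name.
#' @param out_dir optional output directory for reports and predictions.
#' @param input_size evaluation resolution (defaults to the model's config).
#' @param mode `"per_image"` (metrics per image, then averaged) or
#'   `"pooled"` (confusion counts pooled over all pixels of the split).
#' @param samples optional ready sample list overriding `data_root`.
#' @return list: `aggregate` (metrics_report), `per_image` (data.frame).
#' @export
evaluate <- function(model, data_root = NULL, split = "test", out_dir = NULL,
                     input_size = NULL, mode = c("per_image", "pooled"),
                     samples = NULL) {
  mode <- match.arg(mode)
  if (is.character(model)) model <- load_checkpoint(model)$model
  if (is.null(input_size)) input_size <- model$cfg$input_size
  if (is.null(samples))
    samples <- load_dataset(data_root, split, input_size)
  rows <- data.frame()
  pool <- list(tp = 0, tn = 0, fp = 0, fn = 0)
  if (!is.null(out_dir))
    dir.create(file.path(out_dir, "predictions"), recursive = TRUE,
               showWarnings = FALSE)
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    pred <- model_forward(model, array(s$image, c(dim(s$image), 1L)))[, , 1, 1]
    cc <- confusion_counts(pred, s$mask)
    pool <- Map(`+`, pool, cc)
    id <- s$path %||% sprintf("sample_%03d", i)
    rows <- rbind(rows, metrics_row(metrics_from_counts(cc), id))
    if (!is.null(out_dir))
      png::writePNG(matrix(as.numeric(pred >= 0.5), nrow(pred), ncol(pred)),
                    file.path(out_dir, "predictions", paste0(basename(id), ".png")))
  }
  agg <- if (mode == "pooled") metrics_from_counts(pool)
         else metrics_from_counts(pool) # counts kept; percentages replaced below
  if (mode == "per_image") {
    for (f in c("iou", "dice", "recall", "specificity", "precision"))
      agg[[f]] <- mean(rows[[f]])
  }
  if (!is.null(out_dir)) {
    allrows <- rbind(rows, cbind(metrics_row(agg, "aggregate")))
    write.csv(allrows, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    jsonlite::write_json(list(mode = mode, aggregate = agg[c("iou", "dice",
                              "recall", "specificity", "precision")],
                              per_image = rows),
                         file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  list(aggregate = agg, per_image = rows)
}

#' Sweep the DRA region count k
#'
#' Trains and evaluates one model per k under identical seeds and identical
#' non-k configuration, mirroring the published k-sweep protocol (grid
#' steps of 5 by default).
#'
#' @param base_cfg a [model_config()]; @param train_cfg a [train_config()];
#' @param k_values region counts to sweep.
#' @param data_root dataset directory (train + test splits), or pass
#'   `train_samples` / `test_samples` directly.
#' @param train_samples,test_samples optional ready sample lists.
#' @param verbose print progress.
#' @return data.frame: one row per k with the five metrics and the shared
#'   configuration fingerprint.
#' @export
sweep_k <- function(base_cfg, train_cfg, k_values = c(5L, 10L, 15L, 20L, 25L),
                    data_root = NULL, train_samples = NULL,
                    test_samples = NULL, verbose = TRUE) {
  if (!length(k_values)) stop("k_values must be nonempty")
  if (is.null(train_samples))
    train_samples <- load_dataset(data_root, "train", train_cfg$input_size)
  if (is.null(test_samples))
    test_samples <- load_dataset(data_root, "test", train_cfg$input_size)
  fingerprint <- paste0("mode=", base_cfg$dra$mode, ",epochs=", train_cfg$epochs,
                        ",seed=", train_cfg$seed, ",size=", train_cfg$input_size)
  out <- data.frame()
  for (k in k_values) {
    cfg <- base_cfg
    cfg$dra$k <- as.integer(k)
    if (verbose) message("sweep-k: training k = ", k)
    tr <- train(cfg, train_cfg, samples = train_samples, verbose = FALSE)
    ev <- evaluate(tr$model, samples = test_samples)
    out <- rbind(out, cbind(data.frame(k = k), metrics_row(ev$aggregate)[-1],
                            config = fingerprint))
  }
  out
}
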