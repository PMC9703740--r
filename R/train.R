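# Training protocol: Adam over mini-batches of augmented frames, per-epoch
# exponential learning-rate decay, per-epoch validation Dice, and selection
# of the checkpoint with the highest mean validation DSC.

#' Training configuration
#'
#' @param learning_rate initial Adam step size (default 1e-4).
#' @param batch_size frames per mini-batch (default 4).
#' @param max_epochs epoch cap (default 60); an epoch is one pass over all
#'   training frames.
#' @param lr_decay per-epoch exponential decay rate:
#'   `lr(e) = learning_rate * (1 - lr_decay)^e` (default 0.04).
#' @param seed integer seed covering data order, augmentation draws and any
#'   other randomness in the loop.
#' @param augment an [augment_params()].
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 4L,
                         max_epochs = 60L, lr_decay = 0.04, seed = 1L,
                         augment = augment_params()) {
  if (lr_decay <= 0 || lr_decay >= 1) stop_cfg("lr_decay must lie in (0, 1)")
  if (batch_size < 1) stop_cfg("batch_size must be at least 1")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), lr_decay = lr_decay,
                 seed = as.integer(seed), augment = augment),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Exponential decay: `lr(e) = learning_rate * (1 - lr_decay)^e`, strictly
#' decreasing in the epoch index (0-based).
#'
#' @param epoch 0-based epoch index.
#' @param config a [train_config()].
#' @return the learning rate.
#' @export
lr_schedule <- function(epoch, config = train_config()) {
  stopifnot(all(epoch >= 0))
  config$learning_rate * (1 - config$lr_decay)^epoch
}

#' Index of the model-selection epoch
#'
#' The selected checkpoint attains the maximum mean validation DSC; the
#' earliest such epoch wins ties.
#'
#' @param val_dsc numeric vector of per-epoch mean validation DSC.
#' @return 1-based index of the best epoch.
#' @export
best_epoch <- function(val_dsc) which.max(val_dsc)

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    mhat <- opt$m[[nm]] / bc1
    vhat <- opt$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, opt = opt)
}

# flatten per-study stacks into a frame list for mini-batching
stacks_to_frames <- function(studies) {
  frames <- list()
  for (st in studies) {
    for (ph in c("ed", "es")) {
      img <- st[[paste0(ph, "_image")]]
      msk <- st[[paste0(ph, "_mask")]]
      for (s in seq_len(dim(img)[3])) {
        frames[[length(frames) + 1L]] <-
          list(image = img[, , s], mask = msk[, , s])
      }
    }
  }
  frames
}

# mean per-class volume-level DSC over validation studies (hard labels,
# foreground classes only); also returns the per-class means
validation_dsc <- function(model, studies) {
  per_class <- matrix(NA_real_, length(studies) * 2L, 3L)
  r <- 0L
  for (st in studies) {
    for (ph in c("ed", "es")) {
      pred <- predict(model, st[[paste0(ph, "_image")]])$labels
      ref <- st[[paste0(ph, "_mask")]]
      r <- r + 1L
      per_class[r, ] <- vapply(1:3, function(cl) dice(pred, ref, cl), 0)
    }
  }
  cls <- colMeans(per_class)
  list(mean = mean(cls), lv = cls[1], lvm = cls[2], rv = cls[3])
}

#' Train a segmentation model
#'
#' Runs mini-batch Adam over augmented training frames for at most
#' `max_epochs` epochs, evaluating the mean validation DSC (volume-level,
#' over the three cardiac structures) after every epoch and keeping the
#' parameters of the best epoch. Fully seeded: data order, augmentation
#' draws and initialization are reproducible.
#'
#' @param model a freshly built [build_model()] (or a model to fine-tune).
#' @param train_studies,val_studies per-study lists as returned by
#'   [load_split()] (fields `ed_image`, `es_image`, `ed_mask`, `es_mask`).
#' @param config a [train_config()].
#' @param loss a [loss_config()]; when `class_weights` is `NULL` they are
#'   set to inverse median frequency over the training split.
#' @param verbose print one line per epoch.
#' @return an object of class `unet_fit`: `model` (best checkpoint),
#'   `history` (per-epoch tibble), `best_epoch`, `loss`, `config`.
#' @export
train_model <- function(model, train_studies, val_studies,
                        config = train_config(), loss = loss_config(),
                        verbose = FALSE) {
  if (!length(train_studies) || !length(val_studies))
    stop_cfg("training and validation splits must be non-empty")
  frames <- stacks_to_frames(train_studies)
  n_frames <- length(frames)
  if (is.null(loss$class_weights))
    loss$class_weights <- median_frequency_weights(
      lapply(frames, `[[`, "mask"), model$spec$n_classes)
  h <- nrow(frames[[1]]$image); w <- ncol(frames[[1]]$image)
  opt <- adam_init(model$params)
  set.seed(config$seed)
  best <- list(dsc = -Inf, params = model$params, state = model$state,
               epoch = 0L)
  hist_rows <- vector("list", config$max_epochs)
  for (epoch in seq_len(config$max_epochs)) {
    lr <- lr_schedule(epoch - 1L, config)
    ord <- sample.int(n_frames)
    epoch_loss <- 0
    n_batches <- 0L
    for (start in seq(1L, n_frames, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n_frames)]
      b <- length(idx)
      x <- matrix(0, b * h * w, 1L)
      yv <- integer(b * h * w)
      for (j in seq_along(idx)) {
        fr <- frames[[idx[j]]]
        if (isTRUE(config$augment$enabled)) {
          fr <- apply_augment(fr$image, fr$mask, augment_draws(config$augment))
        }
        rows <- (j - 1L) * h * w + seq_len(h * w)
        x[rows, 1L] <- as.vector(fr$image)
        yv[rows] <- as.integer(fr$mask)
      }
      fwd <- unet_forward(model, x, h, w, b, training = TRUE)
      model$state <- fwd$state
      batch_loss <- combined_loss(fwd$probs, yv, loss)
      if (!is.finite(batch_loss))
        stop_cfg("non-finite loss at epoch %d, batch %d", epoch, n_batches + 1L)
      dlogits <- combined_loss_grad_logits(fwd$probs, yv, loss)
      grads <- unet_backward(model, fwd, dlogits)
      upd <- adam_step(model$params, grads, opt, lr)
      model$params <- upd$params
      opt <- upd$opt
      epoch_loss <- epoch_loss + batch_loss
      n_batches <- n_batches + 1L
    }
    vd <- validation_dsc(model, val_studies)
    hist_rows[[epoch]] <- tibble::tibble(
      epoch = epoch, lr = lr, train_loss = epoch_loss / n_batches,
      val_dsc_lv = vd$lv, val_dsc_lvm = vd$lvm, val_dsc_rv = vd$rv,
      val_dsc_mean = vd$mean)
    if (verbose)
      message(sprintf("epoch %2d  lr %.2e  loss %.4f  val DSC %.4f (lv %.3f lvm %.3f rv %.3f)",
                      epoch, lr, epoch_loss / n_batches, vd$mean, vd$lv, vd$lvm, vd$rv))
    if (vd$mean > best$dsc)
      best <- list(dsc = vd$mean, params = model$params, state = model$state,
                   epoch = epoch)
  }
  history <- dplyr::bind_rows(hist_rows)
  model$params <- best$params
  model$state <- best$state
  structure(list(model = model, history = history, best_epoch = best$epoch,
                 loss = loss, config = config),
            class = "unet_fit")
}

#' @export
print.unet_fit <- function(x, ...) {
  cat(sprintf("<unet_fit> %d epochs, best epoch %d (mean val DSC %.4f)\n",
              nrow(x$history), x$best_epoch,
              x$history$val_dsc_mean[x$best_epoch]))
  invisible(x)
}

#' @export
tidy.unet_fit <- function(x, ...) x$history

#' @export
glance.unet_fit <- function(x, ...) {
  b <- x$best_epoch
  tibble::tibble(epochs = nrow(x$history), best_epoch = b,
                 best_val_dsc = x$history$val_dsc_mean[b],
                 final_train_loss = x$history$train_loss[nrow(x$history)])
}

#' Training curves for a fitted model
#'
#' @param object a `unet_fit`.
#' @param ... unused.
#' @return a ggplot object showing training loss and validation DSC per
#'   epoch, with the selected epoch marked.
#' @export
autoplot.unet_fit <- function(object, ...) {
  hh <- object$history |>
    tidyr::pivot_longer(c("train_loss", "val_dsc_mean"),
                        names_to = "series", values_to = "value")
  ggplot2::ggplot(hh, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dotted") +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "Epoch", y = NULL)
}

#' Save / load a fitted model
#'
#' The checkpoint is an RDS of the parameters plus a JSON sidecar recording
#' the architecture and training seed.
#'
#' @param fit a `unet_fit` (or bare `unet_model`).
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
save_checkpoint <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model <- if (inherits(fit, "unet_fit")) fit$model else fit
  model$geom <- NULL  # regenerable cache; keep the checkpoint lean
  saveRDS(model, file.path(dir, "model.rds"))
  jsonlite::write_json(
    list(spec = unclass(model$spec), seed = model$seed,
         in_channels = model$in_channels),
    file.path(dir, "model_spec.json"), auto_unbox = TRUE, digits = NA)
  if (inherits(fit, "unet_fit")) {
    write.csv(fit$history, file.path(dir, "history.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname save_checkpoint
#' @param dir directory written by [save_checkpoint()].
#' @export
load_checkpoint <- function(dir) {
  model <- readRDS(file.path(dir, "model.rds"))
  model$geom <- new_geom_cache()
  model
}
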