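#' Training configuration
#'
#' Defaults follow the reference recipe for this task: plain stochastic
#' gradient descent with learning rate 1e-4 and momentum 0.99, minimising the
#' sum-of-Jaccard loss over all classes, with inputs resized to a square
#' (512 px for the full-scale model). No learning-rate schedule and no early
#' stopping are used; the checkpoint with the best validation mIoU is kept.
#'
#' @param learning_rate SGD learning rate.
#' @param momentum SGD momentum in `[0,1)`.
#' @param epochs number of passes over the training set.
#' @param batch_size minibatch size.
#' @param input_size_px training resolution (images bilinear, masks
#'   nearest-neighbour).
#' @param seed master seed controlling initialisation, shuffling and
#'   augmentation draws.
#' @param augment an [augment_config()]; `augment_none()` disables.
#' @param smooth_eps epsilon smoothing in the soft-Jaccard denominators.
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, momentum = 0.99, epochs = 15L,
                         batch_size = 8L, input_size_px = 512L, seed = 1L,
                         augment = augment_none(), smooth_eps = 1e-6) {
  check_number(learning_rate, "learning_rate", 0, open_lower = TRUE)
  check_number(momentum, "momentum", 0, 1, open_upper = TRUE)
  epochs <- check_count(epochs, "epochs")
  batch_size <- check_count(batch_size, "batch_size")
  input_size_px <- check_count(input_size_px, "input_size_px", min = 32L)
  seed <- check_count(seed, "seed", min = 0L)
  check_number(smooth_eps, "smooth_eps", 0, open_lower = TRUE)
  stopifnot(inherits(augment, "augment_config"))
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 epochs = epochs, batch_size = batch_size,
                 input_size_px = input_size_px, seed = seed,
                 augment = augment, smooth_eps = smooth_eps),
            class = "train_config")
}

load_pairs <- function(manifest, input_size_px) {
  m <- if (is.character(manifest)) read_manifest(manifest) else tibble::as_tibble(manifest)
  if (nrow(m) == 0) {
    stop_ctrseg("manifest is empty", "ctrseg_parameter_error")
  }
  if (!all(c("image_path", "mask_path") %in% names(m))) {
    stop_ctrseg("manifest needs image_path and mask_path columns", "ctrseg_format_error")
  }
  missing <- c(m$image_path[!file.exists(m$image_path)],
               m$mask_path[!file.exists(m$mask_path)])
  if (length(missing) > 0) {
    stop_ctrseg(paste0("missing file(s): ", paste(head(missing, 5), collapse = ", ")),
                "ctrseg_io_error")
  }
  imgs <- lapply(m$image_path, function(p) resize_image(read_image(p), input_size_px, input_size_px))
  msks <- lapply(m$mask_path, function(p) resize_mask(read_mask(p), input_size_px, input_size_px))
  list(images = imgs, masks = msks, manifest = m)
}

make_batch <- function(imgs, msks, S) {
  N <- length(imgs)
  x <- array(0, c(S, S, 3, N))
  y <- array(0L, c(S, S, N))
  for (i in seq_len(N)) {
    x[, , 1, i] <- imgs[[i]]
    x[, , 2, i] <- imgs[[i]]
    x[, , 3, i] <- imgs[[i]]
    y[, , i] <- msks[[i]]
  }
  list(x = x, y = y)
}

# per-image sum-of-Jaccard loss and gradient for a forward pass over a batch
batch_loss_grad <- function(probs_mat, target, nc, eps, want_grad = TRUE) {
  HW <- dim(target)[1] * dim(target)[2]
  N <- dim(target)[3]
  dP <- if (want_grad) matrix(0, nrow(probs_mat), nc) else NULL
  losses <- numeric(N)
  for (n in seq_len(N)) {
    rows <- (n - 1L) * HW + seq_len(HW)
    G <- one_hot_mat(as.vector(target[, , n]), nc)
    Pm <- probs_mat[rows, , drop = FALSE]
    losses[n] <- jaccard_terms(Pm, G, eps)$loss
    # batch objective is the SUM over images (and classes); the reported
    # loss stays a per-image mean for interpretability
    if (want_grad) dP[rows, ] <- jaccard_grad(Pm, G, eps)
  }
  list(loss = mean(losses), dP = dP)
}

sgd_step <- function(P, V, grads, lr, mu) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (!is.null(g$dW)) {
      V[[nm]]$W <- mu * V[[nm]]$W + g$dW
      V[[nm]]$b <- mu * V[[nm]]$b + g$db
      P[[nm]]$W <- P[[nm]]$W - lr * V[[nm]]$W
      P[[nm]]$b <- P[[nm]]$b - lr * V[[nm]]$b
    } else {
      V[[nm]]$gamma <- mu * V[[nm]]$gamma + g$dgamma
      V[[nm]]$beta <- mu * V[[nm]]$beta + g$dbeta
      P[[nm]]$gamma <- P[[nm]]$gamma - lr * V[[nm]]$gamma
      P[[nm]]$beta <- P[[nm]]$beta - lr * V[[nm]]$beta
    }
  }
  list(P = P, V = V)
}

apply_bn_stats <- function(P, stats) {
  for (nm in names(stats)) {
    P[[nm]]$run_mean <- stats[[nm]]$run_mean
    P[[nm]]$run_var <- stats[[nm]]$run_var
  }
  P
}

eval_pass <- function(model, pairs, batch_size, eps) {
  nc <- model$cfg$n_classes
  N <- length(pairs$images)
  losses <- numeric(0)
  conf <- matrix(0, nc, nc)
  for (start in seq(1, N, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, N)
    bt <- make_batch(pairs$images[idx], pairs$masks[idx], model$cfg$input_size_px)
    fwd <- net_forward(model, bt$x, training = FALSE)
    bl <- batch_loss_grad(fwd$probs_mat, bt$y, nc, eps, want_grad = FALSE)
    losses <- c(losses, bl$loss * length(idx))
    # ties.method = "first": deterministic argmax (the default resolves
    # exact probability ties through the global RNG)
    pred <- max.col(fwd$probs_mat, ties.method = "first") - 1L
    conf <- conf + table(factor(pred, levels = 0:(nc - 1)),
                         factor(as.vector(bt$y), levels = 0:(nc - 1)))
  }
  iou <- vapply(seq_len(nc), function(k) {
    tp <- conf[k, k]
    denom <- sum(conf[k, ]) + sum(conf[, k]) - tp
    if (denom == 0) NA_real_ else tp / denom
  }, numeric(1))
  list(loss = sum(losses) / N, miou = mean(iou[-1], na.rm = TRUE))
}

#' Train the segmentation network
#'
#' Minimises the soft-Jaccard loss with SGD + momentum over a phantom (or
#' real) dataset: images resized bilinearly and masks nearest-neighbour to
#' the training resolution, optional augmentation drawn from a seeded stream
#' independent of batch composition, per-epoch train/validation loss and
#' validation mIoU history, and best-validation-mIoU checkpointing. Fully
#' reproducible for a fixed seed in single-threaded mode.
#'
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()].
#' @param train_manifest,val_manifest manifest CSV paths or tibbles with
#'   `image_path` and `mask_path` columns.
#' @param verbose print one line per epoch.
#' @return an object of class `ctr_checkpoint`: the best-validation model,
#'   both configs, the epoch history (tibble: epoch, train_loss, val_loss,
#'   val_miou) and training metadata.
#' @export
train_segnet <- function(model_cfg, train_cfg, train_manifest, val_manifest,
                         verbose = FALSE) {
  stopifnot(inherits(model_cfg, "model_config"), inherits(train_cfg, "train_config"))
  if (train_cfg$input_size_px != model_cfg$input_size_px) {
    stop_ctrseg("train_cfg and model_cfg disagree on input_size_px", "ctrseg_config_error")
  }
  tr <- load_pairs(train_manifest, train_cfg$input_size_px)
  va <- load_pairs(val_manifest, train_cfg$input_size_px)
  model <- build_model(model_cfg, seed = train_cfg$seed)
  nc <- model_cfg$n_classes
  V <- lapply(model$P, function(p) {
    if (!is.null(p$W)) list(W = p$W * 0, b = p$b * 0)
    else list(gamma = p$gamma * 0, beta = p$beta * 0)
  })
  n_tr <- length(tr$images)
  epoch_seeds <- derive_seeds(train_cfg$seed, train_cfg$epochs, salt = 101L)
  history <- vector("list", train_cfg$epochs)
  best <- list(miou = -Inf, P = NULL)
  aug_on <- length(train_cfg$augment$enabled) > 0
  for (ep in seq_len(train_cfg$epochs)) {
    ord <- with_seed(epoch_seeds[ep], sample.int(n_tr))
    aug_seeds <- derive_seeds(epoch_seeds[ep], n_tr, salt = 7L)
    ep_losses <- numeric(0)
    for (start in seq(1, n_tr, by = train_cfg$batch_size)) {
      idx <- ord[start:min(start + train_cfg$batch_size - 1, n_tr)]
      imgs <- tr$images[idx]; msks <- tr$masks[idx]
      if (aug_on) {
        for (j in seq_along(idx)) {
          a <- augment_pair(imgs[[j]], msks[[j]], train_cfg$augment,
                            seed = aug_seeds[idx[j]])
          imgs[[j]] <- a$image; msks[[j]] <- a$mask
        }
      }
      bt <- make_batch(imgs, msks, train_cfg$input_size_px)
      fwd <- net_forward(model, bt$x, training = TRUE)
      model$P <- apply_bn_stats(model$P, fwd$stats)
      bl <- batch_loss_grad(fwd$probs_mat, bt$y, nc, train_cfg$smooth_eps)
      grads <- net_backward(model, fwd, bl$dP)
      upd <- sgd_step(model$P, V, grads, train_cfg$learning_rate, train_cfg$momentum)
      model$P <- upd$P; V <- upd$V
      ep_losses <- c(ep_losses, bl$loss)
    }
    ev <- eval_pass(model, va, train_cfg$batch_size, train_cfg$smooth_eps)
    history[[ep]] <- tibble::tibble(epoch = ep, train_loss = mean(ep_losses),
                                    val_loss = ev$loss, val_miou = ev$miou)
    if (verbose) {
      message(sprintf("epoch %2d  train %.4f  val %.4f  val mIoU %.4f",
                      ep, mean(ep_losses), ev$loss, ev$miou))
    }
    if (ev$miou > best$miou) best <- list(miou = ev$miou, P = model$P, epoch = ep)
  }
  history <- dplyr::bind_rows(history)
  model$P <- best$P
  structure(list(model = model, model_cfg = model_cfg, train_cfg = train_cfg,
                 history = history,
                 training_meta = list(epochs = train_cfg$epochs,
                                      final_train_loss = history$train_loss[nrow(history)],
                                      best_val_miou = best$miou,
                                      best_epoch = best$epoch,
                                      seed = train_cfg$seed)),
            class = "ctr_checkpoint")
}

#' Save / load a model checkpoint
#'
#' Single-file serialized weights + configuration + training metadata.
#' Reloading reproduces identical forward outputs on identical input.
#'
#' @param ckpt a `ctr_checkpoint`.
#' @param path file path.
#' @export
save_checkpoint <- function(ckpt, path) {
  stopifnot(inherits(ckpt, "ctr_checkpoint"))
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) {
    stop_ctrseg(sprintf("checkpoint '%s' does not exist", path), "ctrseg_io_error")
  }
  ckpt <- readRDS(path)
  if (!inherits(ckpt, "ctr_checkpoint")) {
    stop_ctrseg("file is not a ctrseg checkpoint", "ctrseg_format_error")
  }
  ckpt
}

#' Predict a label mask for an image
#'
#' Resizes the image to the model's input resolution (bilinear), runs the
#' network, takes the per-pixel argmax, and upscales the label map back to
#' the original resolution with nearest-neighbour resampling. The CTR is
#' meant to be computed on this original-resolution map.
#'
#' @param ckpt a `ctr_checkpoint` (or bare `ctr_segnet`).
#' @param image numeric image matrix in `[0,1]`, or a path readable by
#'   [read_image()].
#' @return integer label mask at the original image resolution.
#' @export
predict_mask <- function(ckpt, image) {
  model <- if (inherits(ckpt, "ctr_checkpoint")) ckpt$model else ckpt
  stopifnot(inherits(model, "ctr_segnet"))
  if (is.character(image)) image <- read_image(image)
  S <- model$cfg$input_size_px
  orig <- dim(image)
  probs <- forward(model, resize_image(image, S, S))
  lab <- matrix(max.col(matrix(probs, ncol = dim(probs)[3]),
                        ties.method = "first") - 1L, S, S)
  resize_mask(lab, orig[1], orig[2])
}

#' @export
print.ctr_checkpoint <- function(x, ...) {
  cat(sprintf("<ctr_checkpoint> %d epochs (best val mIoU %.4f at epoch %d), seed %d\n",
              x$training_meta$epochs, x$training_meta$best_val_miou,
              x$training_meta$best_epoch, x$training_meta$seed))
  print(x$model)
  invisible(x)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
#' @rdname train_segnet
#' @param x a `ctr_checkpoint`.
#' @param ... unused.
tidy.ctr_checkpoint <- function(x, ...) x$history

#' @export
#' @rdname train_segnet
glance.ctr_checkpoint <- function(x, ...) {
  tibble::tibble(epochs = x$training_meta$epochs,
                 final_train_loss = x$training_meta$final_train_loss,
                 best_val_miou = x$training_meta$best_val_miou,
                 best_epoch = x$training_meta$best_epoch,
                 n_params = n_params(x$model),
                 seed = x$training_meta$seed)
}
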