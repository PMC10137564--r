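#' Segmentation model configuration
#'
#' Describes a U-Net-style encoder-decoder with a residual (ResNet-type)
#' encoder. The default layout is the 34-layer residual encoder
#' (stage depths 3/4/6/3, stage-1 width 64): a 7x7 stride-2 stem, a stride-2
#' max-pool, four residual stages, and a terminal 2x2 max-pool
#' (`extra_pool`) after the last stage, for six downsamplings in total, so
#' the bottleneck feature map is 1/64 the input resolution. The decoder
#' upsamples six times (nearest-neighbour + 3x3 convolutions) with U-Net
#' concatenation skip connections mirroring encoder widths, and the head is
#' a 3x3 convolution with one filter per class followed by a per-pixel
#' softmax. `base_width` and `encoder_depth` scale the model down for
#' CPU-only work without changing its shape.
#'
#' @param n_classes number of mutually exclusive classes (default 3:
#'   background, lung, heart).
#' @param input_size_px square input resolution; must be divisible by 64
#'   when `extra_pool` is `TRUE` (else 32).
#' @param encoder_depth residual block counts for the four encoder stages.
#' @param base_width channel count of stage 1 (stages use 1/2/4/8 x this).
#' @param extra_pool include the sixth downsampling (a 2x2 max-pool after
#'   the last encoder stage).
#' @param skip_mode skip-connection merge; only `"concatenate"` is
#'   implemented.
#' @return an object of class `model_config`.
#' @export
model_config <- function(n_classes = 3L, input_size_px = 512L,
                         encoder_depth = c(3L, 4L, 6L, 3L),
                         base_width = 64L, extra_pool = TRUE,
                         skip_mode = "concatenate") {
  n_classes <- check_count(n_classes, "n_classes", min = 2L)
  input_size_px <- check_count(input_size_px, "input_size_px", min = 32L)
  base_width <- check_count(base_width, "base_width", min = 1L)
  if (length(encoder_depth) != 4L || any(encoder_depth < 1)) {
    stop_ctrseg("encoder_depth must give 4 positive stage depths",
                "ctrseg_config_error")
  }
  if (!identical(skip_mode, "concatenate")) {
    stop_ctrseg("only skip_mode = 'concatenate' is implemented", "ctrseg_config_error")
  }
  div <- if (isTRUE(extra_pool)) 64L else 32L
  if (input_size_px %% div != 0L) {
    stop_ctrseg(sprintf("input_size_px must be divisible by %d for %d downsamplings",
                        div, if (isTRUE(extra_pool)) 6L else 5L),
                "ctrseg_config_error")
  }
  structure(list(n_classes = n_classes, input_size_px = input_size_px,
                 encoder_depth = as.integer(encoder_depth),
                 base_width = base_width, extra_pool = isTRUE(extra_pool),
                 skip_mode = skip_mode),
            class = "model_config")
}

stage_widths <- function(cfg) cfg$base_width * c(1L, 2L, 4L, 8L)

decoder_plan <- function(cfg) {
  w <- cfg$base_width
  if (cfg$extra_pool) {
    list(skip_ch = c(8L * w, 4L * w, 2L * w, w, w, 0L),
         out_ch = c(8L * w, 4L * w, 2L * w, w, w, w),
         in_top = 8L * w)
  } else {
    list(skip_ch = c(4L * w, 2L * w, w, w, 0L),
         out_ch = c(4L * w, 2L * w, w, w, w),
         in_top = 8L * w)
  }
}

#' Build a segmentation model
#'
#' Instantiates all parameters of the network described by a
#' [model_config()]: He-initialised convolutions, batch-normalisation layers
#' with unit scale, and zero-initialised final convolutions inside residual
#' blocks so every block starts near the identity.
#'
#' @param cfg a [model_config()].
#' @param seed seed for weight initialisation (deterministic builds).
#' @return an object of class `ctr_segnet` holding the configuration and a
#'   named parameter list.
#' @export
build_model <- function(cfg, seed = 0L) {
  stopifnot(inherits(cfg, "model_config"))
  with_seed(seed, build_model_impl(cfg))
}

build_model_impl <- function(cfg) {
  P <- list()
  w <- stage_widths(cfg)
  P[["stem.conv"]] <- conv_init(7L, 3L, w[1])
  P[["stem.bn"]] <- bn_init(w[1])
  cin <- w[1]
  for (s in 1:4) {
    for (b in seq_len(cfg$encoder_depth[s])) {
      pre <- sprintf("enc%d.%d", s, b)
      stride <- if (s > 1 && b == 1) 2L else 1L
      cout <- w[s]
      P[[paste0(pre, ".conv1")]] <- conv_init(3L, cin, cout)
      P[[paste0(pre, ".bn1")]] <- bn_init(cout)
      # zero-init the last conv of each block: blocks start as identities
      P[[paste0(pre, ".conv2")]] <- conv_init(3L, cout, cout, zero = TRUE)
      P[[paste0(pre, ".bn2")]] <- bn_init(cout)
      if (stride == 2L || cin != cout) {
        P[[paste0(pre, ".down.conv")]] <- conv_init(1L, cin, cout)
        P[[paste0(pre, ".down.bn")]] <- bn_init(cout)
      }
      cin <- cout
    }
  }
  dp <- decoder_plan(cfg)
  cin <- dp$in_top
  for (t in seq_along(dp$out_ch)) {
    pre <- sprintf("dec%d", t)
    cc <- cin + dp$skip_ch[t]
    P[[paste0(pre, ".conv1")]] <- conv_init(3L, cc, dp$out_ch[t])
    P[[paste0(pre, ".bn1")]] <- bn_init(dp$out_ch[t])
    P[[paste0(pre, ".conv2")]] <- conv_init(3L, dp$out_ch[t], dp$out_ch[t])
    P[[paste0(pre, ".bn2")]] <- bn_init(dp$out_ch[t])
    cin <- dp$out_ch[t]
  }
  P[["head"]] <- conv_init(3L, cin, cfg$n_classes)
  structure(list(cfg = cfg, P = P), class = "ctr_segnet")
}

#' Number of trainable parameters
#' @param model a `ctr_segnet`.
#' @return integer count (running batch-norm statistics excluded).
#' @export
n_params <- function(model) {
  sum(vapply(model$P, function(p) {
    length(p$W %||% numeric()) + length(p$b %||% numeric()) +
      length(p$gamma %||% numeric()) + length(p$beta %||% numeric())
  }, numeric(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- forward / backward ----------------------------------------------------

cbr_f <- function(x, P, pre, training, k = 3L, stride = 1L) {
  cv <- conv_f(x, P[[paste0(pre, ".conv")]], k, stride,
               pad = (k - 1L) %/% 2L)
  bn <- bn_f(cv$y, P[[paste0(pre, ".bn")]], training)
  rl <- relu_f(bn$y)
  list(y = rl$y,
       cache = list(cv = cv$cache, bn = bn$cache, rl = rl$cache),
       stats = stats_entry(pre, bn))
}

stats_entry <- function(pre, bn) {
  stats <- list()
  stats[[paste0(pre, ".bn")]] <- list(run_mean = bn$run_mean, run_var = bn$run_var)
  stats
}

block_f <- function(x, P, pre, stride, training) {
  down <- !is.null(P[[paste0(pre, ".down.conv")]])
  c1 <- conv_f(x, P[[paste0(pre, ".conv1")]], 3L, stride)
  b1 <- bn_f(c1$y, P[[paste0(pre, ".bn1")]], training)
  r1 <- relu_f(b1$y)
  c2 <- conv_f(r1$y, P[[paste0(pre, ".conv2")]], 3L, 1L)
  b2 <- bn_f(c2$y, P[[paste0(pre, ".bn2")]], training)
  stats <- c(stats_entry(paste0(pre, ".bn1"), b1)[1],
             stats_entry(paste0(pre, ".bn2"), b2)[1])
  names(stats) <- c(paste0(pre, ".bn1"), paste0(pre, ".bn2"))
  if (down) {
    sc <- conv_f(x, P[[paste0(pre, ".down.conv")]], 1L, stride, pad = 0L)
    sb <- bn_f(sc$y, P[[paste0(pre, ".down.bn")]], training)
    stats[[paste0(pre, ".down.bn")]] <- list(run_mean = sb$run_mean,
                                             run_var = sb$run_var)
    shortcut <- sb$y
    sc_cache <- list(sc = sc$cache, sb = sb$cache)
  } else {
    shortcut <- x
    sc_cache <- NULL
  }
  ro <- relu_f(b2$y + shortcut)
  list(y = ro$y,
       cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                    c2 = c2$cache, b2 = b2$cache, sc = sc_cache,
                    ro = ro$cache, down = down),
       stats = stats)
}

block_b <- function(dy, P, pre, cache) {
  g <- list()
  ds <- relu_b(dy, cache$ro)
  bb2 <- bn_b(ds, P[[paste0(pre, ".bn2")]], cache$b2)
  g[[paste0(pre, ".bn2")]] <- list(dgamma = bb2$dgamma, dbeta = bb2$dbeta)
  cb2 <- conv_b(bb2$dx, P[[paste0(pre, ".conv2")]], cache$c2)
  g[[paste0(pre, ".conv2")]] <- list(dW = cb2$dW, db = cb2$db)
  dr1 <- relu_b(cb2$dx, cache$r1)
  bb1 <- bn_b(dr1, P[[paste0(pre, ".bn1")]], cache$b1)
  g[[paste0(pre, ".bn1")]] <- list(dgamma = bb1$dgamma, dbeta = bb1$dbeta)
  cb1 <- conv_b(bb1$dx, P[[paste0(pre, ".conv1")]], cache$c1)
  g[[paste0(pre, ".conv1")]] <- list(dW = cb1$dW, db = cb1$db)
  dx <- cb1$dx
  if (cache$down) {
    sb <- bn_b(ds, P[[paste0(pre, ".down.bn")]], cache$sc$sb)
    g[[paste0(pre, ".down.bn")]] <- list(dgamma = sb$dgamma, dbeta = sb$dbeta)
    sc <- conv_b(sb$dx, P[[paste0(pre, ".down.conv")]], cache$sc$sc)
    g[[paste0(pre, ".down.conv")]] <- list(dW = sc$dW, db = sc$db)
    dx <- dx + sc$dx
  } else {
    dx <- dx + ds
  }
  list(dx = dx, grads = g)
}

dec_f <- function(x, skip, P, pre, training) {
  up <- upsample_f(x)
  if (!is.null(skip)) {
    cc <- concat_f(up$y, skip)
    z <- cc$y
    cc_cache <- cc$cache
  } else {
    z <- up$y
    cc_cache <- NULL
  }
  c1 <- conv_f(z, P[[paste0(pre, ".conv1")]], 3L, 1L)
  b1 <- bn_f(c1$y, P[[paste0(pre, ".bn1")]], training)
  r1 <- relu_f(b1$y)
  c2 <- conv_f(r1$y, P[[paste0(pre, ".conv2")]], 3L, 1L)
  b2 <- bn_f(c2$y, P[[paste0(pre, ".bn2")]], training)
  r2 <- relu_f(b2$y)
  stats <- c(stats_entry(paste0(pre, ".bn1"), b1)[1],
             stats_entry(paste0(pre, ".bn2"), b2)[1])
  names(stats) <- c(paste0(pre, ".bn1"), paste0(pre, ".bn2"))
  list(y = r2$y,
       cache = list(up = up$cache, cc = cc_cache, c1 = c1$cache, b1 = b1$cache,
                    r1 = r1$cache, c2 = c2$cache, b2 = b2$cache, r2 = r2$cache),
       stats = stats)
}

dec_b <- function(dy, P, pre, cache) {
  g <- list()
  d <- relu_b(dy, cache$r2)
  bb2 <- bn_b(d, P[[paste0(pre, ".bn2")]], cache$b2)
  g[[paste0(pre, ".bn2")]] <- list(dgamma = bb2$dgamma, dbeta = bb2$dbeta)
  cb2 <- conv_b(bb2$dx, P[[paste0(pre, ".conv2")]], cache$c2)
  g[[paste0(pre, ".conv2")]] <- list(dW = cb2$dW, db = cb2$db)
  d <- relu_b(cb2$dx, cache$r1)
  bb1 <- bn_b(d, P[[paste0(pre, ".bn1")]], cache$b1)
  g[[paste0(pre, ".bn1")]] <- list(dgamma = bb1$dgamma, dbeta = bb1$dbeta)
  cb1 <- conv_b(bb1$dx, P[[paste0(pre, ".conv1")]], cache$c1)
  g[[paste0(pre, ".conv1")]] <- list(dW = cb1$dW, db = cb1$db)
  if (!is.null(cache$cc)) {
    sp <- concat_b(cb1$dx, cache$cc)
    dx <- upsample_b(sp$da, cache$up)
    dskip <- sp$db
  } else {
    dx <- upsample_b(cb1$dx, cache$up)
    dskip <- NULL
  }
  list(dx = dx, dskip = dskip, grads = g)
}

# Full forward pass. x: array (H, W, 3, N) at cfg$input_size_px.
# Returns per-pixel class probabilities (H, W, n_classes, N), plus caches and
# batch-norm running-stat updates when training.
net_forward <- function(model, x, training = FALSE) {
  cfg <- model$cfg; P <- model$P
  d <- dim(x)
  if (d[1] != cfg$input_size_px || d[2] != cfg$input_size_px || d[3] != 3L) {
    stop_ctrseg(sprintf("forward expects %dx%dx3 input, got %dx%dx%d",
                        cfg$input_size_px, cfg$input_size_px, d[1], d[2], d[3]),
                "ctrseg_shape_error")
  }
  stats <- list(); caches <- list()
  st <- cbr_f(x, P, "stem", training, k = 7L, stride = 2L)
  stats <- c(stats, st$stats); caches$stem <- st$cache
  f0 <- st$y
  p0 <- pool_f(f0)
  caches$pool0 <- p0$cache
  h <- p0$y
  skips <- list()
  for (s in 1:4) {
    for (b in seq_len(cfg$encoder_depth[s])) {
      pre <- sprintf("enc%d.%d", s, b)
      bl <- block_f(h, P, pre, stride = if (s > 1 && b == 1) 2L else 1L,
                    training = training)
      stats <- c(stats, bl$stats)
      caches[[pre]] <- bl$cache
      h <- bl$y
    }
    skips[[s]] <- h
  }
  if (cfg$extra_pool) {
    pe <- pool_f(h)
    caches$pool_extra <- pe$cache
    h <- pe$y
    dec_skips <- list(skips[[4]], skips[[3]], skips[[2]], skips[[1]], f0, NULL)
  } else {
    dec_skips <- list(skips[[3]], skips[[2]], skips[[1]], f0, NULL)
  }
  for (t in seq_along(dec_skips)) {
    pre <- sprintf("dec%d", t)
    dc <- dec_f(h, dec_skips[[t]], P, pre, training)
    stats <- c(stats, dc$stats)
    caches[[pre]] <- dc$cache
    h <- dc$y
  }
  hd <- conv_f(h, P[["head"]], 3L, 1L)
  caches$head <- hd$cache
  logits <- hd$y
  ld <- dim(logits)
  M <- matrix(aperm(logits, c(1, 2, 4, 3)), ncol = cfg$n_classes)
  probs_mat <- softmax_rows(M)
  probs <- aperm(array(probs_mat, c(ld[1], ld[2], ld[4], ld[3])), c(1, 2, 4, 3))
  list(probs = probs, probs_mat = probs_mat, caches = caches, stats = stats,
       ldim = ld)
}

# Backward pass from the gradient w.r.t. the softmax probabilities (matrix
# view, pixels x classes). Returns the named gradient list.
net_backward <- function(model, fwd, dprobs_mat) {
  cfg <- model$cfg; P <- model$P; caches <- fwd$caches
  Pm <- fwd$probs_mat
  dlog_mat <- Pm * (dprobs_mat - rowSums(dprobs_mat * Pm))
  ld <- fwd$ldim
  dlogits <- aperm(array(dlog_mat, c(ld[1], ld[2], ld[4], ld[3])), c(1, 2, 4, 3))
  g <- list()
  hb <- conv_b(dlogits, P[["head"]], caches$head)
  g[["head"]] <- list(dW = hb$dW, db = hb$db)
  dh <- hb$dx
  n_dec <- if (cfg$extra_pool) 6L else 5L
  dskips <- vector("list", n_dec)
  for (t in rev(seq_len(n_dec))) {
    pre <- sprintf("dec%d", t)
    db <- dec_b(dh, P, pre, caches[[pre]])
    g <- c(g, db$grads)
    dskips[[t]] <- db$dskip
    dh <- db$dx
  }
  # map decoder skip grads back to encoder features
  if (cfg$extra_pool) {
    denc <- list(dskips[[4]], dskips[[3]], dskips[[2]], dskips[[1]])
    df0 <- dskips[[5]]
    dh <- pool_b(dh, caches$pool_extra)
  } else {
    denc <- list(dskips[[3]], dskips[[2]], dskips[[1]], NULL)
    df0 <- dskips[[4]]
  }
  for (s in 4:1) {
    if (!is.null(denc[[s]])) dh <- dh + denc[[s]]
    for (b in rev(seq_len(cfg$encoder_depth[s]))) {
      pre <- sprintf("enc%d.%d", s, b)
      bb <- block_b(dh, P, pre, caches[[pre]])
      g <- c(g, bb$grads)
      dh <- bb$dx
    }
  }
  dh <- pool_b(dh, caches$pool0)
  if (!is.null(df0)) dh <- dh + df0
  ds <- relu_b(dh, caches$stem$rl)
  sb <- bn_b(ds, P[["stem.bn"]], caches$stem$bn)
  g[["stem.bn"]] <- list(dgamma = sb$dgamma, dbeta = sb$dbeta)
  sc <- conv_b(sb$dx, P[["stem.conv"]], caches$stem$cv)
  g[["stem.conv"]] <- list(dW = sc$dW, db = sc$db)
  g
}

#' Run the network forward on one image
#'
#' The image must already be at the configured input resolution; no silent
#' resizing happens here (use [predict_mask()] for the full pipeline). The
#' single gray channel is replicated to the three channels the encoder
#' expects.
#'
#' @param model a `ctr_segnet` (fresh or from a checkpoint).
#' @param image numeric matrix in `[0,1]` of size
#'   `input_size_px x input_size_px`.
#' @return array `(H, W, n_classes)` of per-pixel class probabilities
#'   (summing to 1 over classes); `argmax` over the third dimension gives a
#'   label mask.
#' @export
forward <- function(model, image) {
  stopifnot(inherits(model, "ctr_segnet"))
  if (!is.matrix(image)) {
    stop_ctrseg("image must be a matrix", "ctrseg_shape_error")
  }
  x <- array(rep(image, 3), c(dim(image), 3, 1))
  out <- net_forward(model, x, training = FALSE)
  out$probs[, , , 1]
}

#' @export
print.ctr_segnet <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf("<ctr_segnet> input %d, classes %d, base width %d, stages %s, %s downsamplings, %d parameters\n",
              cfg$input_size_px, cfg$n_classes, cfg$base_width,
              paste(cfg$encoder_depth, collapse = "/"),
              if (cfg$extra_pool) "6" else "5", n_params(x)))
  invisible(x)
}
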