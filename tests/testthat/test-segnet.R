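test_that("configuration validates downsampling compatibility", {
  expect_no_error(model_config())
  expect_error(model_config(input_size_px = 100), class = "ctrseg_config_error")
  expect_no_error(model_config(input_size_px = 96, extra_pool = FALSE))
  expect_error(model_config(input_size_px = 96, extra_pool = TRUE),
               class = "ctrseg_config_error")
  expect_error(model_config(n_classes = 1), class = "ctrseg_parameter_error")
  expect_error(model_config(skip_mode = "add"), class = "ctrseg_config_error")
})

test_that("bottleneck resolution is 1/64 of the input with six downsamplings", {
  cfg <- model_config(input_size_px = 64, base_width = 4,
                      encoder_depth = c(1, 1, 1, 1))
  model <- build_model(cfg, seed = 1)
  x <- array(runif(64 * 64 * 3 * 1), c(64, 64, 3, 1))
  fwd <- ctrseg:::net_forward(model, x)
  # the sixth downsampling (terminal max-pool) receives 2x2 and emits 1x1
  expect_equal(fwd$caches$pool_extra$dims[1:2], c(2, 2))
  d1_in <- fwd$caches$dec1$up[1:2]
  expect_equal(d1_in, c(64 / 64, 64 / 64))
  expect_equal(dim(fwd$probs)[1:2], c(64, 64))
})

test_that("forward yields normalized probabilities of the right shape", {
  cfg <- model_config(input_size_px = 64, base_width = 4,
                      encoder_depth = c(1, 1, 1, 1))
  model <- build_model(cfg, seed = 2)
  img <- matrix(runif(64 * 64), 64, 64)
  pr <- forward(model, img)
  expect_equal(dim(pr), c(64, 64, 3))
  expect_true(all(pr >= 0 & pr <= 1))
  expect_lt(max(abs(apply(pr, c(1, 2), sum) - 1)), 1e-6)
  # eval-mode determinism
  expect_identical(pr, forward(model, img))
  # no silent resize
  expect_error(forward(model, matrix(0.5, 32, 32)), class = "ctrseg_shape_error")
})

test_that("halving base_width shrinks the parameter count about fourfold", {
  cfg8 <- model_config(input_size_px = 64, base_width = 8)
  cfg4 <- model_config(input_size_px = 64, base_width = 4)
  ratio <- n_params(build_model(cfg8)) / n_params(build_model(cfg4))
  expect_gte(ratio, 3)
  expect_lte(ratio, 5)
})

test_that("checkpoint round trip reproduces forward outputs exactly", {
  cfg <- model_config(input_size_px = 64, base_width = 4,
                      encoder_depth = c(1, 1, 1, 1))
  model <- build_model(cfg, seed = 5)
  ck <- structure(list(model = model, model_cfg = cfg, train_cfg = NULL,
                       history = tibble::tibble(),
                       training_meta = list(epochs = 0, best_val_miou = NA,
                                            best_epoch = NA, seed = 5)),
                  class = "ctr_checkpoint")
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(ck, f)
  re <- load_checkpoint(f)
  img <- matrix(runif(64 * 64), 64, 64)
  expect_identical(forward(model, img), forward(re$model, img))
  expect_error(load_checkpoint("no/such/file.rds"), class = "ctrseg_io_error")
})

test_that("analytic gradients agree with finite differences through the net", {
  # small config exercising every layer type (residual downsampling included)
  cfg <- model_config(input_size_px = 32, base_width = 2,
                      encoder_depth = c(1, 1, 1, 1), extra_pool = FALSE)
  model <- build_model(cfg, seed = 3)
  withr::with_seed(42, {
    for (nm in names(model$P)) {
      if (!is.null(model$P[[nm]]$W)) {
        model$P[[nm]]$W <- model$P[[nm]]$W +
          matrix(rnorm(length(model$P[[nm]]$W), 0, 0.05), nrow(model$P[[nm]]$W))
      }
    }
    x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
    y <- array(sample(0:2, 32 * 32 * 2, TRUE), c(32, 32, 2))
    eps <- 1e-6
    loss_of <- function(m) {
      fw <- ctrseg:::net_forward(m, x, training = TRUE)
      ctrseg:::batch_loss_grad(fw$probs_mat, y, 3, eps, want_grad = FALSE)$loss * 2
    }
    fwd <- ctrseg:::net_forward(model, x, training = TRUE)
    bl <- ctrseg:::batch_loss_grad(fwd$probs_mat, y, 3, eps)
    grads <- ctrseg:::net_backward(model, fwd, bl$dP)
    h <- 1e-5
    rels <- c()
    for (nm in names(grads)) {
      for (fld in names(grads[[nm]])) {
        pf <- sub("^d", "", fld)
        id <- sample(length(model$P[[nm]][[pf]]), 1)
        m2 <- model
        m2$P[[nm]][[pf]][id] <- model$P[[nm]][[pf]][id] + h
        lp <- loss_of(m2)
        m2$P[[nm]][[pf]][id] <- model$P[[nm]][[pf]][id] - h
        lm <- loss_of(m2)
        num <- (lp - lm) / (2 * h)
        ana <- grads[[nm]][[fld]][id]
        rels <- c(rels, abs(num - ana) / max(1e-6, abs(num) + abs(ana)))
      }
    }
    # ReLU/max-pool kinks can spoil individual finite differences; the bulk
    # of the parameters must agree tightly
    expect_lt(median(rels), 1e-6)
    expect_lt(mean(rels > 1e-3), 0.06)
  })
})
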