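make_eval_setup <- function(n = 8, env = parent.frame()) {
  p <- tiny_phantom_params()
  d <- withr::local_tempdir(.local_envir = env)
  man <- attr(generate_dataset(n, p, seed = 55, out_dir = d), "manifest")
  masks <- lapply(man$mask_path, read_mask)
  list(manifest = man, masks = masks)
}

test_that("evaluating predictions equal to references gives perfect scores", {
  st <- make_eval_setup()
  # reference CTRs recomputed from the masks so agreement is exact
  man <- st$manifest
  man$true_ctr <- vapply(st$masks, function(m) compute_ctr(m)$ctr, numeric(1))
  ev <- evaluate_run(man, st$masks)
  expect_equal(ev$seg$miou, 1)
  expect_equal(ev$seg$adc, 1)
  expect_equal(ev$agreement$mean_abs_diff_pct, 0)
  expect_equal(ev$agreement$n_bias_ge_threshold, 0)
  expect_equal(ev$diagnostic$accuracy, 1)
  expect_equal(length(ev$excluded), 0)
})

test_that("dataset aggregation equals the per-image sum of confusion counts", {
  st <- make_eval_setup()
  preds <- lapply(seq_along(st$masks), function(i) {
    m <- st$masks[[i]]
    if (i %% 2 == 0) m[1:5, ] <- 0L  # perturb half the predictions
    m
  })
  ev <- evaluate_run(st$manifest, preds)
  total <- NULL
  for (i in seq_along(preds)) {
    cf <- confusion(preds[[i]], st$masks[[i]])
    total <- if (is.null(total)) cf else {
      cf2 <- total
      cf2$tp <- cf2$tp + cf$tp; cf2$fp <- cf2$fp + cf$fp
      cf2$fn <- cf2$fn + cf$fn; cf2$tn <- cf2$tn + cf$tn
      cf2
    }
  }
  expect_equal(ev$seg$miou, seg_metrics(total)$miou)
  expect_equal(ev$seg$adc, seg_metrics(total)$adc)
  # macro average differs in general but stays in [0,1]
  evm <- evaluate_run(st$manifest, preds, aggregate = "macro")
  expect_true(evm$seg$miou >= 0 && evm$seg$miou <= 1)
})

test_that("failed CTR extractions are excluded and listed, not fatal", {
  st <- make_eval_setup()
  preds <- st$masks
  preds[[2]][preds[[2]] == 2L] <- 0L  # remove the heart from one prediction
  ev <- evaluate_run(st$manifest, preds)
  expect_equal(length(ev$excluded), 1)
  expect_equal(ev$agreement$n, nrow(st$manifest) - 1)
  expect_true(all(is.finite(unlist(glance(ev)[, c("miou", "adc", "r2", "accuracy", "auc")]))))
})

test_that("the report bundle writes consistent CSV + JSON", {
  st <- make_eval_setup()
  ev <- evaluate_run(st$manifest, st$masks)
  out <- withr::local_tempdir()
  write_report(ev, out)
  expect_true(all(file.exists(file.path(out, c("report.json", "metrics.csv",
                                               "ctr.csv", "roc.csv",
                                               "bland_altman.csv")))))
  js <- jsonlite::read_json(file.path(out, "report.json"))
  expect_equal(js$miou, ev$seg$miou)
  expect_equal(js$accuracy, ev$diagnostic$accuracy)
  mt <- readr::read_csv(file.path(out, "metrics.csv"), show_col_types = FALSE)
  expect_true(all(c("metric", "value") %in% names(mt)))
  expect_equal(mt$value[mt$metric == "miou"], ev$seg$miou)
})

test_that("autoplot methods return ggplot objects", {
  st <- make_eval_setup()
  ev <- evaluate_run(st$manifest, st$masks)
  expect_s3_class(ggplot2::autoplot(ev), "ggplot")
  expect_s3_class(ggplot2::autoplot(ev$diagnostic), "ggplot")
  expect_s3_class(ggplot2::autoplot(ev$agreement$bland_altman), "ggplot")
})
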