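test_that("confusion counts match the brute-force per-pixel loop", {
  withr::with_seed(5, {
    for (rep in 1:10) {
      pred <- random_mask(8, 8)
      ref <- random_mask(8, 8)
      got <- confusion(pred, ref)
      want <- oracle_confusion(pred, ref)
      for (k in 1:3) {
        expect_identical(unname(unlist(got[k, c("tp", "fp", "fn", "tn")])),
                         as.numeric(want[[k]]))
      }
      expect_true(all(got$tp + got$fp + got$fn + got$tn == 64))
    }
  })
  p <- random_mask(6, 6)
  same <- confusion(p, p)
  expect_true(all(same$fp == 0) && all(same$fn == 0))
  ref <- matrix(0L, 6, 6); ref[2:3, 2:4] <- 2L
  allbg <- confusion(matrix(0L, 6, 6), ref)
  expect_equal(allbg$fn[allbg$class == "heart"], 6)
  expect_error(confusion(p, random_mask(5, 5)), class = "ctrseg_shape_error")
})

test_that("IoU and Dice follow their defining formulas and identity", {
  counts <- tibble::tibble(class = c("background", "lung", "heart"),
                           tp = c(50, 8, 8), fp = c(2, 1, 1),
                           fn = c(3, 1, 1), tn = c(45, 90, 90))
  sm <- seg_metrics(counts)
  lung <- sm$per_class[sm$per_class$class == "lung", ]
  expect_equal(lung$iou, 0.8)
  expect_equal(lung$dice, 2 * 0.8 / 1.8)
  # dice from PPV/TPR: ppv = tpr = 8/9
  expect_equal(lung$dice, 2 * (8 / 9) * (8 / 9) / (8 / 9 + 8 / 9))
  # hand evaluation with ppv 0.9, tpr 0.8: dice = 1.44/1.7
  expect_equal(2 * 0.9 * 0.8 / (0.9 + 0.8), 1.44 / 1.7)
  # perfect prediction
  perfect <- tibble::tibble(class = c("background", "lung", "heart"),
                            tp = c(10, 10, 10), fp = 0, fn = 0, tn = 20)
  smp <- seg_metrics(perfect)
  expect_equal(smp$miou, 1)
  expect_equal(smp$adc, 1)
  expect_error(seg_metrics(counts, classes_to_average = character()),
               class = "ctrseg_parameter_error")
})

test_that("dice = 2*iou/(1+iou) and miou <= adc on random confusions", {
  withr::with_seed(9, {
    for (rep in 1:50) {
      pred <- random_mask(12, 12)
      ref <- random_mask(12, 12)
      sm <- seg_metrics(confusion(pred, ref))
      ok <- !is.na(sm$per_class$iou)
      expect_equal(sm$per_class$dice[ok],
                   2 * sm$per_class$iou[ok] / (1 + sm$per_class$iou[ok]),
                   tolerance = 1e-12)
      expect_lte(sm$miou, sm$adc + 1e-12)
    }
  })
})

test_that("empty classes are excluded from the averages and recorded", {
  ref <- matrix(0L, 8, 8); ref[2:4, 2:4] <- 1L
  pred <- ref  # no heart pixels anywhere
  sm <- seg_metrics(confusion(pred, ref))
  expect_identical(sm$class_set_averaged, "lung")
  expect_equal(sm$miou, 1)
})

test_that("regression R2 equals the brute-force 1 - SSres/SStot", {
  ref <- c(0.42, 0.51, 0.48, 0.55, 0.61, 0.45)
  expect_equal(regression_r2(ref, ref), 1.0)
  expect_equal(regression_r2(ref, 2 * ref + 5), 1.0)
  withr::with_seed(2, {
    test <- ref + rnorm(6, 0, 0.02)
    fit <- coef(lm(test ~ ref))
    ssres <- sum((test - (fit[1] + fit[2] * ref))^2)
    sstot <- sum((test - mean(test))^2)
    expect_equal(regression_r2(ref, test), 1 - ssres / sstot)
  })
  expect_error(regression_r2(rep(0.5, 5), ref[1:5]), class = "ctrseg_degenerate_error")
  expect_error(regression_r2(ref[1:2], ref[1:2]), class = "ctrseg_parameter_error")
})

test_that("difference statistics use percentage points and inclusive threshold", {
  d <- difference_stats(c(0.50, 0.52), c(0.51, 0.51))
  expect_equal(d$mean_abs_diff_pct, 1.0)
  expect_equal(d$sd_abs_diff_pct, 0.0)
  expect_equal(d$n_ge_threshold, 0)
  z <- difference_stats(c(0.5, 0.6, 0.7), c(0.5, 0.6, 0.7))
  expect_equal(unlist(z[1, 1:3], use.names = FALSE), c(0, 0, 0))
  # inclusive >=: a difference of exactly 2 pp counts
  expect_equal(difference_stats(c(0.50, 0.60), c(0.52, 0.60))$n_ge_threshold, 1)
  withr::with_seed(4, {
    a <- runif(20, 0.4, 0.6); b <- a + rnorm(20, 0, 0.03)
    d2 <- difference_stats(a, b)
    expect_equal(d2$mean_abs_diff_pct, mean(abs(b - a)) * 100)
    expect_equal(d2$sd_abs_diff_pct, sd(abs(b - a)) * 100)
    expect_equal(d2$n_ge_threshold, sum(abs(b - a) >= 0.02))
  })
})

test_that("Bland-Altman bias and limits behave as defined", {
  ref <- c(0.5, 0.52, 0.48, 0.55)
  ba <- bland_altman(ref, ref + 0.01)
  expect_equal(ba$bias, 0.01)
  expect_equal(ba$lower_loa, 0.01)
  expect_equal(ba$upper_loa, 0.01)
  ba0 <- bland_altman(ref, ref)
  expect_equal(c(ba0$bias, ba0$lower_loa, ba0$upper_loa), c(0, 0, 0))
  expect_error(bland_altman(0.5, 0.5), class = "ctrseg_parameter_error")
})

test_that("ROC/AUC equals the pairwise counting oracle, with ties", {
  sep <- roc_auc(c(1, 2, 3, 10, 11, 12), c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(sep$auc, 1.0)
  withr::with_seed(31, {
    for (rep in 1:25) {
      n <- sample(5:30, 1)
      scores <- sample(seq(0.3, 0.7, by = 0.05), n, replace = TRUE)  # many ties
      labels <- runif(n) < 0.5
      if (!any(labels) || all(labels)) next
      r <- roc_auc(scores, labels)
      expect_equal(r$auc, oracle_auc(scores, labels))
      # curve properties: monotone from (0,0) to (1,1); AUC = trapezoid
      expect_equal(c(r$roc_points$fpr[1], r$roc_points$tpr[1]), c(0, 0))
      expect_equal(c(tail(r$roc_points$fpr, 1), tail(r$roc_points$tpr, 1)), c(1, 1))
      expect_true(all(diff(r$roc_points$fpr) >= 0))
      expect_true(all(diff(r$roc_points$tpr) >= 0))
    }
  })
  expect_error(roc_auc(1:4, rep(TRUE, 4)), class = "ctrseg_degenerate_error")
})

test_that("AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(8, {
    scores <- round(runif(60, 0.3, 0.7), 2)
    labels <- runif(60) < 0.4
    got <- roc_auc(scores, labels)$auc
    want <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                           direction = "<")))
    expect_equal(got, want, tolerance = 1e-12)
  })
})

test_that("diagnostic performance equals 2x2 contingency brute force", {
  ref <- c(0.45, 0.52, 0.55, 0.48, 0.60, 0.40)
  expect_equal(diagnostic_performance(ref, ref)$accuracy, 1)
  allpos <- diagnostic_performance(rep(0.9, 6), ref)
  expect_equal(allpos$sensitivity, 1)
  expect_equal(allpos$specificity, 0)
  withr::with_seed(12, {
    test <- ref + rnorm(6, 0, 0.05)
    dp <- diagnostic_performance(test, ref)
    truth <- ref > 0.5; call <- test > 0.5
    tp <- sum(call & truth); tn <- sum(!call & !truth)
    fp <- sum(call & !truth); fn <- sum(!call & truth)
    expect_equal(dp$accuracy, (tp + tn) / 6)
    expect_equal(dp$sensitivity, tp / (tp + fn))
    expect_equal(dp$specificity, tn / (tn + fp))
  })
})

test_that("paired t-test matches the closed-form example and rejects degenerate input", {
  r <- paired_t_test(c(1, 2, 3), c(0, 0, 0))
  expect_equal(r$t_stat, 2 / (1 / sqrt(3)), tolerance = 1e-4)
  expect_equal(r$df, 2)
  expect_equal(r$p_value, 2 * pt(-r$t_stat, df = 2))
  expect_equal(round(r$p_value, 4), 0.0742)
  expect_error(paired_t_test(c(1, 2, 3), c(1, 2, 3)), class = "ctrseg_degenerate_error")
  expect_error(paired_t_test(1:2, 1:2), class = "ctrseg_parameter_error")
})
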