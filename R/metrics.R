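#' Per-class confusion counts between two label masks
#'
#' One-vs-rest pixel tallies: for each class, a pixel is a true positive if
#' both masks assign that class, a false positive if only the prediction
#' does, a false negative if only the reference does, and a true negative
#' otherwise. `TP + FP + FN + TN` equals the total pixel count for every
#' class.
#'
#' @param pred,ref integer label masks of identical dimensions.
#' @return a tibble with columns `class, tp, fp, fn, tn`.
#' @export
confusion <- function(pred, ref) {
  if (!all(dim(pred) == dim(ref))) {
    stop_ctrseg("mask dimensions differ", "ctrseg_shape_error")
  }
  tab <- table(factor(as.vector(pred), levels = CLASS_LEVELS),
               factor(as.vector(ref), levels = CLASS_LEVELS))
  confusion_from_table(tab)
}

confusion_from_table <- function(tab) {
  total <- sum(tab)
  tibble::tibble(
    class = names(CLASS_LEVELS),
    tp = vapply(1:3, function(k) tab[k, k], numeric(1)),
    fp = vapply(1:3, function(k) sum(tab[k, ]) - tab[k, k], numeric(1)),
    fn = vapply(1:3, function(k) sum(tab[, k]) - tab[k, k], numeric(1))
  ) |>
    dplyr::mutate(tn = total - .data$tp - .data$fp - .data$fn)
}

#' Segmentation metrics from confusion counts
#'
#' Per class: `IoU = TP / (TP + FP + FN)`; `Dice = 2*PPV*TPR / (PPV + TPR)`
#' with `PPV = TP/(TP+FP)` and `TPR = TP/(TP+FN)` (algebraically
#' `2TP / (2TP + FP + FN)`, i.e. `2*IoU / (1 + IoU)`). The mean IoU (mIoU)
#' and average Dice coefficient (ADC) are unweighted means over
#' `classes_to_average`; by default background is excluded so the averages
#' describe the anatomy. A class with `TP + FP + FN = 0` is excluded from the
#' averages and recorded as such.
#'
#' @param counts a confusion tibble from [confusion()] (or summed over
#'   images for micro-averaged dataset metrics).
#' @param classes_to_average classes entering mIoU/ADC (names or codes).
#' @return an object of class `seg_metrics`: a list with `per_class`
#'   (tibble: class, iou, dice, ppv, tpr), `miou`, `adc` and
#'   `class_set_averaged`.
#' @export
seg_metrics <- function(counts, classes_to_average = c("lung", "heart")) {
  codes <- class_codes(classes_to_average)
  if (length(codes) == 0) {
    stop_ctrseg("classes_to_average must not be empty", "ctrseg_parameter_error")
  }
  per <- counts |>
    dplyr::mutate(
      iou = ifelse(.data$tp + .data$fp + .data$fn == 0, NA_real_,
                   .data$tp / (.data$tp + .data$fp + .data$fn)),
      ppv = ifelse(.data$tp + .data$fp == 0, NA_real_, .data$tp / (.data$tp + .data$fp)),
      tpr = ifelse(.data$tp + .data$fn == 0, NA_real_, .data$tp / (.data$tp + .data$fn)),
      dice = ifelse(.data$tp + .data$fp + .data$fn == 0, NA_real_,
                    2 * .data$tp / (2 * .data$tp + .data$fp + .data$fn))
    )
  avg_names <- names(CLASS_LEVELS)[CLASS_LEVELS %in% codes]
  rows <- per |>
    dplyr::filter(.data$class %in% avg_names, .data$tp + .data$fp + .data$fn > 0)
  if (nrow(rows) == 0) {
    stop_ctrseg("no class with any pixels to average", "ctrseg_parameter_error")
  }
  structure(list(per_class = dplyr::select(per, "class", "iou", "dice", "ppv", "tpr"),
                 miou = mean(rows$iou), adc = mean(rows$dice),
                 class_set_averaged = rows$class),
            class = "seg_metrics")
}

#' @export
print.seg_metrics <- function(x, ...) {
  cat(sprintf("<seg_metrics> mIoU %.4f, ADC %.4f (averaged over %s)\n",
              x$miou, x$adc, paste(x$class_set_averaged, collapse = ", ")))
  print(x$per_class)
  invisible(x)
}

#' @export
#' @rdname seg_metrics
#' @param x a `seg_metrics` object.
#' @param ... unused.
tidy.seg_metrics <- function(x, ...) x$per_class

#' @export
#' @rdname seg_metrics
glance.seg_metrics <- function(x, ...) {
  tibble::tibble(miou = x$miou, adc = x$adc,
                 classes_averaged = paste(x$class_set_averaged, collapse = "+"))
}

#' Coefficient of determination between two CTR series
#'
#' R-squared of the ordinary least-squares regression of the test method's
#' CTRs on the reference CTRs.
#'
#' @param reference_ctrs,test_ctrs numeric vectors of equal length
#'   (`n >= 3`).
#' @return single number `<= 1`.
#' @export
regression_r2 <- function(reference_ctrs, test_ctrs) {
  check_paired(reference_ctrs, test_ctrs, min_n = 3L)
  if (var(reference_ctrs) == 0) {
    stop_ctrseg("reference CTRs are constant; R^2 undefined", "ctrseg_degenerate_error")
  }
  fit <- lm(test_ctrs ~ reference_ctrs)
  # exact agreement triggers lm's "essentially perfect fit" warning; R^2 = 1
  # is the correct answer there, so keep it quiet
  suppressWarnings(summary(fit)$r.squared)
}

check_paired <- function(a, b, min_n = 2L) {
  if (length(a) != length(b)) {
    stop_ctrseg("vectors must have equal length", "ctrseg_parameter_error")
  }
  if (length(a) < min_n) {
    stop_ctrseg(sprintf("need at least %d pairs", min_n), "ctrseg_parameter_error")
  }
  invisible(TRUE)
}

#' Absolute CTR difference statistics
#'
#' Mean and standard deviation (n-1 denominator) of `|test - reference|` in
#' CTR percentage points, plus the count of images whose absolute difference
#' meets the bias threshold (inclusive `>=`, default 2 percentage points).
#'
#' @param reference_ctrs,test_ctrs CTR vectors on the 0-1 scale.
#' @param bias_threshold threshold on the 0-1 scale (default 0.02).
#' @return a tibble with `mean_abs_diff_pct, sd_abs_diff_pct, n_ge_threshold,
#'   n`.
#' @export
difference_stats <- function(reference_ctrs, test_ctrs, bias_threshold = 0.02) {
  check_paired(reference_ctrs, test_ctrs, min_n = 2L)
  d <- abs(test_ctrs - reference_ctrs)
  tibble::tibble(mean_abs_diff_pct = mean(d) * 100,
                 sd_abs_diff_pct = sd(d) * 100,
                 n_ge_threshold = sum(d >= bias_threshold),
                 n = length(d))
}

#' Bland-Altman agreement analysis
#'
#' Bias is the mean of `test - reference`; the limits of agreement are
#' `bias +/- 1.96 * SD` of the differences (n-1 denominator). The per-image
#' plotting payload (pair means vs differences) is included for the
#' agreement plot.
#'
#' @param reference_ctrs,test_ctrs CTR vectors.
#' @return an object of class `bland_altman` with `bias`, `lower_loa`,
#'   `upper_loa` and a `points` tibble (`mean`, `diff`).
#' @export
bland_altman <- function(reference_ctrs, test_ctrs) {
  check_paired(reference_ctrs, test_ctrs, min_n = 2L)
  d <- test_ctrs - reference_ctrs
  bias <- mean(d)
  s <- sd(d)
  structure(list(bias = bias, lower_loa = bias - 1.96 * s,
                 upper_loa = bias + 1.96 * s,
                 points = tibble::tibble(mean = (test_ctrs + reference_ctrs) / 2,
                                         diff = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> bias %.4f, limits of agreement [%.4f, %.4f], n = %d\n",
              x$bias, x$lower_loa, x$upper_loa, nrow(x$points)))
  invisible(x)
}

#' @export
#' @rdname bland_altman
#' @param x a `bland_altman` object.
#' @param ... unused.
tidy.bland_altman <- function(x, ...) x$points

#' @export
#' @rdname bland_altman
glance.bland_altman <- function(x, ...) {
  tibble::tibble(bias = x$bias, lower_loa = x$lower_loa, upper_loa = x$upper_loa,
                 n = nrow(x$points))
}

#' ROC curve and AUC for cardiomegaly scores
#'
#' The ROC is traced by sweeping every distinct score threshold (prediction
#' positive when `score > t`); the AUC is the trapezoidal area under the
#' resulting curve, which for tied scores equals the pairwise probability
#' rule `P(score_pos > score_neg) + 0.5 * P(score_pos = score_neg)`.
#'
#' @param scores numeric scores (here: CTR values).
#' @param labels logical (or 0/1) class labels; both values must occur.
#' @return list with `roc_points` (tibble `threshold, fpr, tpr`, from (0,0)
#'   to (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) {
    stop_ctrseg("scores and labels must have equal length", "ctrseg_parameter_error")
  }
  if (!any(labels) || all(labels)) {
    stop_ctrseg("both classes must be present; AUC undefined", "ctrseg_degenerate_error")
  }
  np <- sum(labels); nn <- sum(!labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # collapse ties: cumulate per distinct threshold
  brk <- c(which(diff(s) != 0), length(s))
  tp <- cumsum(l)[brk]; fp <- cumsum(!l)[brk]
  roc <- tibble::tibble(threshold = c(Inf, s[brk]),
                        fpr = c(0, fp / nn), tpr = c(0, tp / np))
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  list(roc_points = roc, auc = auc)
}

#' Diagnostic performance of thresholded CTR calls
#'
#' Reference truth is cardiomegaly by the reference CTRs (strict
#' `> threshold`); the test method is evaluated both as thresholded calls
#' (accuracy, sensitivity, specificity) and as a continuous score (ROC/AUC).
#'
#' @param test_ctrs,reference_ctrs CTR vectors.
#' @param threshold cardiomegaly threshold (default 0.50).
#' @return an object of class `diagnostic_report`: accuracy, sensitivity,
#'   specificity, auc, roc_points, threshold, n.
#' @export
diagnostic_performance <- function(test_ctrs, reference_ctrs, threshold = 0.50) {
  check_paired(reference_ctrs, test_ctrs, min_n = 2L)
  truth <- classify_cardiomegaly(reference_ctrs, threshold)
  call <- classify_cardiomegaly(test_ctrs, threshold)
  roc <- roc_auc(test_ctrs, truth)
  structure(list(
    accuracy = mean(call == truth),
    sensitivity = if (any(truth)) mean(call[truth]) else NA_real_,
    specificity = if (any(!truth)) mean(!call[!truth]) else NA_real_,
    auc = roc$auc, roc_points = roc$roc_points,
    threshold = threshold, n = length(truth)
  ), class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat(sprintf("<diagnostic_report> accuracy %.3f, sensitivity %.3f, specificity %.3f, AUC %.3f (CTR > %.2f, n = %d)\n",
              x$accuracy, x$sensitivity, x$specificity, x$auc, x$threshold, x$n))
  invisible(x)
}

#' @export
#' @rdname diagnostic_performance
#' @param x a `diagnostic_report`.
#' @param ... unused.
tidy.diagnostic_report <- function(x, ...) x$roc_points

#' @export
#' @rdname diagnostic_performance
glance.diagnostic_report <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, sensitivity = x$sensitivity,
                 specificity = x$specificity, auc = x$auc,
                 threshold = x$threshold, n = x$n)
}

#' Paired two-sided t-test on per-image absolute CTR differences
#'
#' Compares two methods scored on the same images: a paired t-test on
#' `A_i - B_i` with `n - 1` degrees of freedom.
#'
#' @param abs_diffs_method_a,abs_diffs_method_b numeric vectors of per-image
#'   absolute differences, paired by image (`n >= 3`).
#' @return a tibble with `t_stat, df, p_value, mean_diff, n`.
#' @export
paired_t_test <- function(abs_diffs_method_a, abs_diffs_method_b) {
  check_paired(abs_diffs_method_a, abs_diffs_method_b, min_n = 3L)
  d <- abs_diffs_method_a - abs_diffs_method_b
  if (sd(d) == 0) {
    stop_ctrseg("pairwise differences have zero variance; t-test degenerate",
                "ctrseg_degenerate_error")
  }
  tt <- t.test(abs_diffs_method_a, abs_diffs_method_b, paired = TRUE)
  tibble::tibble(t_stat = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, mean_diff = mean(d), n = length(d))
}
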