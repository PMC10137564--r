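#' Evaluate a prediction run against reference masks and CTRs
#'
#' Produces the full report bundle for a dataset: (a) segmentation metrics
#' with per-image confusion counts summed before metric computation
#' (micro-average; per-image macro-average available), (b) the CTR agreement
#' report (R-squared, mean +/- SD absolute difference in percentage points,
#' count of images with absolute bias >= 2 percentage points, Bland-Altman
#' bias and limits, paired t-test of predicted vs reference CTRs), and
#' (c) the diagnostic report for cardiomegaly calls at CTR > 50%.
#'
#' @param manifest tibble or CSV path with columns `image_path`, `mask_path`
#'   (reference masks) and `true_ctr` (reference CTRs).
#' @param predictions a named or positional list of predicted label masks, a
#'   character vector of predicted mask paths (same order as the manifest),
#'   or a directory containing `pred_<image basename>` masks.
#' @param aggregate `"micro"` (sum pixel counts over images, default) or
#'   `"macro"` (average per-image metrics).
#' @param classes_to_average classes entering mIoU/ADC.
#' @param threshold cardiomegaly threshold.
#' @param bias_threshold absolute-difference threshold for the bias count.
#' @return an object of class `ctr_evaluation` bundling `seg`
#'   ([seg_metrics()]), `agreement`, `diagnostic`
#'   ([diagnostic_performance()]), the per-image `ctr` tibble and metadata.
#'   Images whose CTR extraction fails are excluded from the agreement and
#'   diagnostic statistics and listed in `excluded`.
#' @export
evaluate_run <- function(manifest, predictions, aggregate = c("micro", "macro"),
                         classes_to_average = c("lung", "heart"),
                         threshold = 0.50, bias_threshold = 0.02) {
  aggregate <- match.arg(aggregate)
  m <- if (is.character(manifest)) read_manifest(manifest) else tibble::as_tibble(manifest)
  if (!all(c("mask_path", "true_ctr") %in% names(m))) {
    stop_ctrseg("manifest needs mask_path and true_ctr columns", "ctrseg_format_error")
  }
  preds <- resolve_predictions(predictions, m)
  n <- nrow(m)

  conf_sum <- NULL
  per_image <- vector("list", n)
  ctr_rows <- vector("list", n)
  for (i in seq_len(n)) {
    ref <- read_mask(m$mask_path[i])
    pred <- if (is.character(preds)) read_mask(preds[i]) else preds[[i]]
    cf <- confusion(pred, ref)
    conf_sum <- if (is.null(conf_sum)) cf else
      dplyr::mutate(conf_sum, tp = .data$tp + cf$tp, fp = .data$fp + cf$fp,
                    fn = .data$fn + cf$fn, tn = .data$tn + cf$tn)
    per_image[[i]] <- cf
    res <- tryCatch(compute_ctr(pred), ctrseg_missing_structure = function(e) e)
    ctr_rows[[i]] <- if (inherits(res, "ctr_result")) {
      tibble::tibble(image_path = m$image_path[i], reference_ctr = m$true_ctr[i],
                     predicted_ctr = res$ctr, error_note = NA_character_)
    } else {
      tibble::tibble(image_path = m$image_path[i], reference_ctr = m$true_ctr[i],
                     predicted_ctr = NA_real_, error_note = conditionMessage(res))
    }
  }
  seg <- if (aggregate == "micro") {
    seg_metrics(conf_sum, classes_to_average)
  } else {
    per <- lapply(per_image, seg_metrics, classes_to_average = classes_to_average)
    macro <- seg_metrics(conf_sum, classes_to_average)  # per-class table from pooled counts
    macro$miou <- mean(vapply(per, `[[`, numeric(1), "miou"))
    macro$adc <- mean(vapply(per, `[[`, numeric(1), "adc"))
    macro
  }

  ctr_tab <- dplyr::bind_rows(ctr_rows)
  ok <- !is.na(ctr_tab$predicted_ctr)
  ref_ctr <- ctr_tab$reference_ctr[ok]
  prd_ctr <- ctr_tab$predicted_ctr[ok]
  diffs <- difference_stats(ref_ctr, prd_ctr, bias_threshold)
  ba <- bland_altman(ref_ctr, prd_ctr)
  tt <- tryCatch(
    {
      t0 <- t.test(prd_ctr, ref_ctr, paired = TRUE)
      tibble::tibble(t_stat = unname(t0$statistic), df = unname(t0$parameter),
                     p_value = t0$p.value)
    },
    error = function(e) tibble::tibble(t_stat = NA_real_, df = NA_real_,
                                       p_value = NA_real_))
  agreement <- list(
    r2 = regression_r2(ref_ctr, prd_ctr),
    mean_abs_diff_pct = diffs$mean_abs_diff_pct,
    sd_abs_diff_pct = diffs$sd_abs_diff_pct,
    n_bias_ge_threshold = diffs$n_ge_threshold,
    bias_threshold = bias_threshold,
    bland_altman = ba,
    t_stat = tt$t_stat, p_value = tt$p_value,
    n = sum(ok)
  )
  diag <- diagnostic_performance(prd_ctr, ref_ctr, threshold)

  structure(list(seg = seg, agreement = agreement, diagnostic = diag,
                 ctr = ctr_tab, excluded = ctr_tab$image_path[!ok],
                 meta = list(aggregate = aggregate,
                             classes_to_average = seg$class_set_averaged,
                             threshold = threshold, n_images = n)),
            class = "ctr_evaluation")
}

resolve_predictions <- function(predictions, m) {
  if (is.list(predictions)) {
    if (length(predictions) != nrow(m)) {
      stop_ctrseg("one predicted mask per manifest row is required", "ctrseg_parameter_error")
    }
    return(predictions)
  }
  if (is.character(predictions) && length(predictions) == 1 && dir.exists(predictions)) {
    paths <- file.path(predictions, paste0("pred_", basename(m$image_path)))
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0) {
      stop_ctrseg(paste0("missing prediction(s): ",
                         paste(head(missing, 5), collapse = ", ")),
                  "ctrseg_io_error")
    }
    return(paths)
  }
  if (is.character(predictions)) {
    if (length(predictions) != nrow(m) || !all(file.exists(predictions))) {
      stop_ctrseg("predictions must exist for every manifest row", "ctrseg_io_error")
    }
    return(predictions)
  }
  stop_ctrseg("predictions must be masks, paths or a directory", "ctrseg_parameter_error")
}

#' @export
print.ctr_evaluation <- function(x, ...) {
  cat(sprintf("<ctr_evaluation> %d images (%d with valid CTR)\n",
              x$meta$n_images, x$agreement$n))
  print(x$seg)
  cat(sprintf("CTR agreement: R^2 %.4f, mean |diff| %.2f +/- %.2f pp, >= %.0f pp bias: %d/%d\n",
              x$agreement$r2, x$agreement$mean_abs_diff_pct,
              x$agreement$sd_abs_diff_pct, x$agreement$bias_threshold * 100,
              x$agreement$n_bias_ge_threshold, x$agreement$n))
  print(x$diagnostic)
  invisible(x)
}

#' @export
#' @rdname evaluate_run
#' @param x a `ctr_evaluation`.
#' @param ... unused.
tidy.ctr_evaluation <- function(x, ...) {
  dplyr::bind_rows(
    x$seg$per_class |>
      tidyr::pivot_longer(c("iou", "dice", "ppv", "tpr"),
                          names_to = "metric", values_to = "value") |>
      dplyr::mutate(metric = paste(.data$metric, .data$class, sep = "_")) |>
      dplyr::select("metric", "value"),
    tibble::tibble(
      metric = c("miou", "adc", "r2", "mean_abs_diff_pct", "sd_abs_diff_pct",
                 "bland_altman_bias", "bland_altman_lower_loa",
                 "bland_altman_upper_loa", "accuracy", "sensitivity",
                 "specificity", "auc"),
      value = c(x$seg$miou, x$seg$adc, x$agreement$r2,
                x$agreement$mean_abs_diff_pct, x$agreement$sd_abs_diff_pct,
                x$agreement$bland_altman$bias, x$agreement$bland_altman$lower_loa,
                x$agreement$bland_altman$upper_loa, x$diagnostic$accuracy,
                x$diagnostic$sensitivity, x$diagnostic$specificity,
                x$diagnostic$auc)))
}

#' @export
#' @rdname evaluate_run
glance.ctr_evaluation <- function(x, ...) {
  tibble::tibble(miou = x$seg$miou, adc = x$seg$adc, r2 = x$agreement$r2,
                 mean_abs_diff_pct = x$agreement$mean_abs_diff_pct,
                 sd_abs_diff_pct = x$agreement$sd_abs_diff_pct,
                 n_bias_ge_threshold = x$agreement$n_bias_ge_threshold,
                 accuracy = x$diagnostic$accuracy,
                 sensitivity = x$diagnostic$sensitivity,
                 specificity = x$diagnostic$specificity,
                 auc = x$diagnostic$auc,
                 n = x$agreement$n, n_excluded = length(x$excluded))
}

#' Write an evaluation report bundle to disk
#'
#' Emits `report.json` (all scalar metrics + metadata), `metrics.csv` (tidy
#' metric table), `ctr.csv` (per-image CTRs), `roc.csv` (ROC points) and
#' `bland_altman.csv` (agreement plot payload).
#'
#' @param x a `ctr_evaluation`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(x, dir) {
  stopifnot(inherits(x, "ctr_evaluation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(tidy(x), file.path(dir, "metrics.csv"))
  readr::write_csv(x$ctr, file.path(dir, "ctr.csv"))
  readr::write_csv(x$diagnostic$roc_points, file.path(dir, "roc.csv"))
  readr::write_csv(x$agreement$bland_altman$points, file.path(dir, "bland_altman.csv"))
  js <- c(as.list(glance(x)),
          list(bland_altman = list(bias = x$agreement$bland_altman$bias,
                                   lower_loa = x$agreement$bland_altman$lower_loa,
                                   upper_loa = x$agreement$bland_altman$upper_loa),
               t_stat = x$agreement$t_stat, p_value = x$agreement$p_value,
               meta = x$meta, excluded = x$excluded))
  jsonlite::write_json(js, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
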