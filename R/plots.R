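#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_hline
#'   geom_abline labs theme_minimal coord_equal
#' @export
ggplot2::autoplot

#' ROC curve plot
#' @param object a `diagnostic_report`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.diagnostic_report <- function(object, ...) {
  ggplot(object$roc_points, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dotted", colour = "grey60") +
    geom_line(colour = "#2c7fb8") +
    geom_point(size = 0.8, colour = "#2c7fb8") +
    coord_equal() +
    labs(x = "False positive rate", y = "True positive rate",
         title = sprintf("Cardiomegaly ROC (AUC = %.3f)", object$auc)) +
    theme_minimal()
}

#' Bland-Altman agreement plot
#' @param object a `bland_altman` object.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot(object$points, aes(x = .data$mean, y = .data$diff)) +
    geom_point(alpha = 0.6) +
    geom_hline(yintercept = object$bias, colour = "#d95f02") +
    geom_hline(yintercept = c(object$lower_loa, object$upper_loa),
               linetype = "dashed", colour = "#d95f02") +
    labs(x = "Mean CTR of the two methods", y = "CTR difference (test - reference)",
         title = sprintf("Bland-Altman: bias %.4f, LoA [%.4f, %.4f]",
                         object$bias, object$lower_loa, object$upper_loa)) +
    theme_minimal()
}

#' Training history plot
#' @param object a `ctr_checkpoint`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ctr_checkpoint <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss", "val_miou"),
                           names_to = "series", values_to = "value")
  ggplot(h, aes(x = .data$epoch, y = .data$value, colour = .data$series)) +
    geom_line() +
    labs(x = "Epoch", y = NULL, colour = NULL, title = "Training history") +
    theme_minimal()
}

#' CTR scatter plot (predicted vs reference)
#' @param object a `ctr_evaluation`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ctr_evaluation <- function(object, ...) {
  ok <- !is.na(object$ctr$predicted_ctr)
  ggplot(object$ctr[ok, ], aes(x = .data$reference_ctr, y = .data$predicted_ctr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dotted", colour = "grey60") +
    geom_point(alpha = 0.6) +
    coord_equal() +
    labs(x = "Reference CTR", y = "Predicted CTR",
         title = sprintf("CTR agreement (R² = %.3f)", object$agreement$r2)) +
    theme_minimal()
}
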