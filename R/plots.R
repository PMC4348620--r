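#' Plot an ROC curve (smoothed line, empirical points)
#'
#' @param object An `ir_roc` from [roc_auc_smoothed()].
#' @param ... Unused.
#' @return A ggplot object: the binormal-smoothed curve as a line with the
#'   empirical (sensitivity, 1 - specificity) points overlaid.
#' @export
autoplot.ir_roc <- function(object, ...) {
  pts <- object$points
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_point(shape = 15, size = 1.8) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  subtitle = sprintf("AUC %.2f (empirical)%s",
                                     object$auc_empirical,
                                     if (!is.na(object$auc_smoothed))
                                       sprintf(", %.2f (smoothed)", object$auc_smoothed)
                                     else "")) +
    ggplot2::theme_minimal()
  if (!is.na(object$binormal_a)) {
    t <- seq(0.001, 0.999, length.out = 200)
    smooth <- tibble::tibble(
      fpr = t,
      sensitivity = pnorm(object$binormal_a + object$binormal_b * qnorm(t)))
    p <- p + ggplot2::geom_line(data = smooth, colour = "firebrick")
  }
  p
}

#' Score distributions of cases versus controls
#'
#' @param data Tibble of per-patient scores.
#' @param score,truth Column names of the score and the logical outcome.
#' @return A ggplot density plot by class.
#' @export
plot_score_distributions <- function(data, score = "ir_score",
                                     truth = "recurrence") {
  df <- tibble::tibble(score = data[[score]],
                       class = ifelse(as.logical(data[[truth]]),
                                      "recurrence", "non-recurrence"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, fill = .data$class,
                                   colour = .data$class)) +
    ggplot2::geom_density(alpha = 0.3) +
    ggplot2::scale_fill_manual(values = c(recurrence = "firebrick",
                                          `non-recurrence` = "grey30")) +
    ggplot2::scale_colour_manual(values = c(recurrence = "firebrick",
                                            `non-recurrence` = "grey30")) +
    ggplot2::labs(x = "Predicted probability of recurrence", y = "Density",
                  fill = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Cell-type map of one synthetic core
#'
#' @param object An `ir_cohort`.
#' @param core_id Core to display (default: the first).
#' @param ... Unused.
#' @return A ggplot tile map of the core's epithelium/stroma labels.
#' @export
autoplot.ir_cohort <- function(object, core_id = NULL, ...) {
  core_id <- core_id %||% object$pixels$core_id[1]
  px <- object$pixels[object$pixels$core_id == core_id, , drop = FALSE]
  ggplot2::ggplot(px, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$cell_type)) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = core_id, fill = NULL) +
    ggplot2::theme_minimal()
}
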