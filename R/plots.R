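# ggplot2 methods for the result types.

.curve_points <- function(y, s, type = c("roc", "pr")) {
  type <- match.arg(type)
  o <- order(s, decreasing = TRUE)
  ys <- y[o]; ss <- s[o]
  grp_end <- which(c(ss[-1] != ss[-length(ss)], TRUE))
  tp <- cumsum(ys)[grp_end]
  fp <- cumsum(1 - ys)[grp_end]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (type == "roc") {
    tibble::tibble(x = c(0, fp / n0), y = c(0, tp / n1))
  } else {
    tibble::tibble(x = tp / n1, y = tp / (tp + fp))
  }
}

#' Plot cross-validated ROC or precision-recall curves
#'
#' One pooled out-of-fold curve per localization label.
#'
#' @param object an `"mloc_cv"` result.
#' @param Y the label matrix the cross-validation was run on.
#' @param type `"roc"` or `"pr"`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mloc_cv <- function(object, Y, type = c("roc", "pr"), ...) {
  type <- match.arg(type)
  pts <- purrr::map_dfr(colnames(Y), function(lab) {
    if (length(unique(Y[, lab])) < 2) return(NULL)
    dplyr::mutate(.curve_points(Y[, lab], object$scores[, lab], type),
                  label = lab)
  })
  p <- ggplot2::ggplot(pts, ggplot2::aes(.data$x, .data$y,
                                         colour = .data$label)) +
    ggplot2::geom_path() +
    ggplot2::theme_minimal()
  if (type == "roc") {
    p + ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
      ggplot2::labs(x = "False positive rate", y = "True positive rate",
                    colour = "Localization")
  } else {
    p + ggplot2::labs(x = "Recall", y = "Precision",
                      colour = "Localization")
  }
}

#' Plot the ablation size trend
#'
#' Average AUC of all feature-subset models grouped by the number of blocks
#' used, with per-subset points.
#'
#' @param object an `"mloc_ablation"` tibble.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mloc_ablation <- function(object, ...) {
  summ <- ablation_size_summary(object)
  ggplot2::ggplot(object, ggplot2::aes(.data$n_blocks, .data$average_auc)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.5) +
    ggplot2::geom_line(data = summ, colour = "firebrick", linewidth = 1) +
    ggplot2::geom_point(data = summ, colour = "firebrick", size = 2) +
    ggplot2::scale_x_continuous(breaks = seq_len(max(object$n_blocks))) +
    ggplot2::labs(x = "Feature blocks used", y = "Average AUC") +
    ggplot2::theme_minimal()
}
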