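#' @method autoplot cross_map_result
#' @export
autoplot.cross_map_result <- function(object, ...) {
  ggplot2::ggplot(object$rho_by_delay,
                  ggplot2::aes(x = .data$delay, y = .data$rho)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best_delay, linetype = "dashed") +
    ggplot2::labs(x = "delay", y = expression(rho),
                  title = sprintf("Cross map %s -> %s", object$cause,
                                  object$effect)) +
    ggplot2::theme_minimal()
}

#' @method autoplot roc_curve
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC (AUROC = %.3f)", attr(object, "auroc"))) +
    ggplot2::theme_minimal()
}

#' @method autoplot pcm_network
#' @export
autoplot.pcm_network <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$target, y = .data$source,
                                    fill = .data$rho_D)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = substr(.data$decision, 1, 1))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1), name = expression(rho[D])) +
    ggplot2::labs(title = "PCM decision matrix (d = direct, i = indirect, n = none)") +
    ggplot2::theme_minimal()
}

#' Plot a threshold-robustness sweep
#'
#' Accuracy (with a ribbon of +/- one sd across trials) against the decision
#' threshold for the pairwise (`mcm`) and partial (`pcm`) rules; flatter
#' means more robust to the choice of `T`.
#'
#' @param sweep Output of [threshold_sweep()].
#' @return A ggplot object.
#' @export
plot_threshold_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$threshold, y = .data$accuracy,
                                      colour = .data$method,
                                      fill = .data$method)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$accuracy - .data$accuracy_sd,
                                      ymax = .data$accuracy + .data$accuracy_sd),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "threshold T", y = "accuracy") +
    ggplot2::theme_minimal()
}
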