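#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a permutation null distribution
#'
#' Histogram of the permuted group accuracies with the upper-percentile
#' significance boundary and chance level marked.
#'
#' @param object an `sd_null`.
#' @param bins histogram bins.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.sd_null <- function(object, bins = 30, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$accuracy)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70",
                            colour = "grey30") +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$boundary, colour = "red") +
    ggplot2::labs(
      title = sprintf("Permutation null: %s", object$contrast),
      subtitle = sprintf("upper %g%% boundary = %.2f%%", object$percentile,
                         100 * object$boundary),
      x = "group mean accuracy", y = "permutations") +
    ggplot2::theme_minimal()
}

#' Plot per-fold accuracies of a decoding result
#'
#' @param object an `sd_decoding`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.sd_decoding <- function(object, ...) {
  d <- tidy(object)
  d$run <- factor(d$run, levels = d$run)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$run, y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = object$mean_accuracy,
                        colour = "red") +
    ggplot2::labs(title = sprintf("Leave-one-run-out folds: %s",
                                  object$contrast),
                  x = "held-out run", y = "fold accuracy") +
    ggplot2::theme_minimal()
}

#' Group decoding accuracy by contrast
#'
#' Mean accuracy per contrast with per-participant points and, optionally,
#' the permutation-derived significance baseline as a dotted line.
#'
#' @param accuracies a tibble from [decode_study()] (columns `contrast`,
#'   `accuracy`, `participant_id`).
#' @param boundary optional significance baseline as a proportion (e.g. from
#'   [average_boundaries()]).
#' @return A ggplot object.
#' @export
plot_group_accuracy <- function(accuracies, boundary = NULL) {
  stopifnot(all(c("contrast", "accuracy") %in% names(accuracies)))
  means <- dplyr::summarise(dplyr::group_by(accuracies, .data$contrast),
                            accuracy = mean(.data$accuracy), .groups = "drop")
  p <- ggplot2::ggplot(accuracies,
                       ggplot2::aes(x = .data$contrast,
                                    y = .data$accuracy)) +
    ggplot2::geom_col(data = means, fill = "grey80", colour = "grey30") +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "decoding accuracy") +
    ggplot2::theme_minimal()
  if (!is.null(boundary))
    p <- p + ggplot2::geom_hline(yintercept = boundary, linetype = "dotted",
                                 colour = "red")
  p
}
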