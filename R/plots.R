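#' @export
autoplot.eps_spectrum <- function(object, ...) {
  df <- tibble(frequency_hz = object$freqs, power = object$power)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency_hz, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = "envelope spectrum power",
                  title = sprintf("one-sided envelope power spectrum (%d bins)",
                                  length(object$power)))
}

#' @export
autoplot.fisher_lda <- function(object, n_max = 30, ...) {
  df <- head(tidy(object), n_max)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$direction, y = .data$eigenvalue)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "discriminant direction", y = "eigenvalue",
                  title = "Fisher discriminant eigenvalue spectrum")
}

#' @export
autoplot.har_confusion <- function(object, ...) {
  df <- as_tibble(as.data.frame(as.table(unclass(object))))
  names(df) <- c("true", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(title = "confusion matrix (rows = true class)")
}

#' @export
autoplot.har_eval <- function(object, ...) {
  autoplot(object$confusion) +
    ggplot2::labs(subtitle = sprintf("accuracy %.2f%%, %s F1 %.2f%%",
                                     100 * object$accuracy,
                                     object$averaging, 100 * object$f1))
}

#' @export
autoplot.har_sweep <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), -"n_features",
                            names_to = "metric", values_to = "percent")
  df$n_features <- factor(df$n_features, levels = unique(object$n_features))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_features, y = .data$percent,
                                   colour = .data$metric,
                                   group = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "number of discriminant features", y = "percent",
                  title = "feature-count sweep")
}

#' Scatter plot of the two leading discriminant coordinates
#'
#' @param reduced a tibble from [lda_transform()] with at least `ld1`,
#'   `ld2` and a `label` column.
#' @return a ggplot object.
#' @export
plot_lda_features <- function(reduced) {
  if (!all(c("ld1", "ld2", "label") %in% names(reduced))) {
    abort("need columns ld1, ld2 and label")
  }
  ggplot2::ggplot(reduced, ggplot2::aes(x = .data$ld1, y = .data$ld2,
                                        colour = factor(.data$label))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(colour = "class",
                  title = "leading Fisher discriminant coordinates")
}
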