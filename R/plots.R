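# ggplot2 helpers for the main result types. Each takes the tidy output
# of the corresponding analysis function.

#' Plot divergence (unique-neuron fraction) profiles
#'
#' @param profiles A tibble with columns `dim`, `position`,
#'   `normalized` (see [unique_fraction_by_position()]).
#' @return A ggplot.
#' @export
plot_divergence <- function(profiles) {
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = .data$position, y = .data$normalized,
                               colour = factor(.data$dim),
                               group = .data$dim)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "simplex position (source → target)",
                  y = "unique fraction / source fraction",
                  colour = "dimension") +
    ggplot2::theme_minimal()
}

#' Plot inhibitory degree by simplex position
#'
#' @param profile Output of [inhibitory_degree_by_position()].
#' @return A ggplot.
#' @export
plot_position_profile <- function(profile) {
  long <- tidyr::pivot_longer(profile, c("in_degree", "out_degree"),
                              names_to = "direction")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$position, y = .data$value,
                               colour = .data$direction)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "simplex position", y = "mean inhibitory degree") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fitted_distance_model <- function(object, ...) {
  if (is.null(object$bins)) {
    abort("Fitted model carries no bin diagnostics to plot.")
  }
  p <- ggplot2::ggplot(object$bins,
                       ggplot2::aes(x = .data$mid, y = .data$p_hat)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_pairs), alpha = 0.6) +
    ggplot2::labs(x = "soma distance (µm)",
                  y = "connection probability",
                  title = paste0("Pathway ", object$pathway, ": a = ",
                                 signif(object$a, 3), ", b = ",
                                 signif(object$b, 3), " µm")) +
    ggplot2::theme_minimal()
  if (!is.null(object$bins$fitted)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$fitted),
                                colour = "red")
  }
  p
}

#' @export
autoplot.targeting_test <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d_ttl, y = .data$d_inh,
                                   colour = .data$flagged)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "total out-degree", y = "out-degree onto interneurons",
                  colour = "inhibitory\ntargeting") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.group_network <- function(object, ...) {
  to_long <- function(m, what) {
    tibble::tibble(source_group = rep(seq_len(nrow(m)) - 1L, ncol(m)),
                   target_group = rep(seq_len(ncol(m)) - 1L,
                                      each = nrow(m)),
                   value = as.vector(m), what = what)
  }
  df <- dplyr::bind_rows(to_long(object$excitation, "excitation"),
                         to_long(object$inhibition, "inhibition"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$target_group,
                                   y = .data$source_group,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~what) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "target group", y = "source group") +
    ggplot2::theme_minimal()
}
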