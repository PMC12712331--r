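#' Plot methods for model result objects
#'
#' `autoplot()` methods give quick ggplot2 views of each result type:
#' clade-size distributions on log-log axes, imbalance densities,
#' diversification curves, tempo trajectories and branch-length densities.
#'
#' @param object A result object from the package.
#' @param ... Unused.
#' @return A ggplot object.
#' @name cet-autoplot
NULL

#' @rdname cet-autoplot
#' @export
autoplot.cet_clade_dist <- function(object, ...) {
  df <- dplyr::filter(object, .data$n > 0, .data$p > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$p)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "clade size n", y = expression(P[n]),
                  title = sprintf("clade-size distribution (t = %g, x0 = %g)",
                                  attr(object, "t"), attr(object, "x0")))
}

#' @rdname cet-autoplot
#' @export
autoplot.cet_imbalance <- function(object, ...) {
  ggplot2::ggplot(object$density,
                  ggplot2::aes(x = .data$proportion, y = .data$density)) +
    ggplot2::geom_col(width = 1 / nrow(object$density)) +
    ggplot2::labs(x = "proportion of diversity in one sister group",
                  y = "density")
}

#' @rdname cet-autoplot
#' @export
autoplot.cet_curves <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$species,
                                       colour = factor(.data$x0))) +
    ggplot2::geom_line() +
    ggplot2::geom_line(ggplot2::aes(y = .data$lineages),
                       linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (myr)", y = "expected species (lineages dashed)",
                  colour = "x0")
}

#' @rdname cet-autoplot
#' @export
autoplot.cet_tempo_paths <- function(object, ...) {
  summ <- tidy(object)
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$t, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (myr)", y = "log-tempo")
}

#' @rdname cet-autoplot
#' @export
autoplot.cet_density <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "log-tempo x", y = "density")
}

#' @rdname cet-autoplot
#' @export
autoplot.cet_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$age, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "age (Ma)", y = "expected log-tempo",
                  title = sprintf("historical tempo (%s mode)",
                                  object$mode[1]))
}

#' @rdname cet-autoplot
#' @export
autoplot.cet_branch_density <- function(object, ...) {
  xvar <- if (attr(object, "kind") == "duration") "t" else "w"
  xlab <- if (attr(object, "kind") == "duration") {
    "branch duration (myr)"
  } else {
    "molecular change (myr-equivalents)"
  }
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[xvar]],
                                       y = .data$density,
                                       colour = factor(.data$x0))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = xlab, y = "density", colour = "x0")
}
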