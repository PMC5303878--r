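lattice_df <- function(g) {
  tibble(row = rep(seq_len(nrow(g)), ncol(g)),
         col = rep(seq_len(ncol(g)), each = nrow(g)),
         label = as.vector(g))
}

#' @export
autoplot.cell_lattice <- function(object, ...) {
  df <- lattice_df(object$grid)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = factor(.data$label))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(
      values = c(`-1` = "#3B6FB6", `0` = "grey90", `1` = "#C0392B"),
      labels = c(`-1` = "strain B", `0` = "empty", `1` = "strain A"),
      name = NULL) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("step %d", object$step)) +
    ggplot2::theme_void()
}

#' @export
autoplot.spin_lattice <- function(object, ...) {
  df <- lattice_df(object$spins)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = factor(.data$label))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`-1` = "black", `1` = "white"),
                               name = "spin") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Plot a structure-factor curve on log-log axes
#' @param object An `sf_curve`.
#' @param ... Unused.
#' @export
autoplot.sf_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$q, .data$S)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "wavenumber q (1/L)", y = "S(q)") +
    ggplot2::theme_minimal()
}

#' Plot the coarsening scaling relation S(q_m) versus q_m
#' @param object A `coarsening_fit`.
#' @param ... Unused.
#' @export
autoplot.coarsening_fit <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(.data$q_m, .data$s_qm)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "q_m", y = "S(q_m)",
                  subtitle = sprintf("slope %.2f (Model A predicts -2)",
                                     object$slope_sq_qm)) +
    ggplot2::theme_minimal()
}

#' Plot rescaled structure-factor curves (dynamic-scaling collapse)
#' @param object An `sf_collapse`.
#' @param ... Unused.
#' @export
autoplot.sf_collapse <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(.data$x, .data$y,
                               colour = factor(.data$time))) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "q / q_m", y = expression(S(q) * q[m]^2 * L^2),
                  colour = "time") +
    ggplot2::theme_minimal()
}

#' Plot an assortment profile r(h)
#' @param object Tibble from [assortment_profile()].
#' @param ... Unused.
#' @export
plot_assortment <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$h, .data$r_g)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "interaction radius h (cells)", y = "assortment r") +
    ggplot2::theme_minimal()
  if (all(c("ci_low", "ci_high") %in% names(object)))
    p <- p + ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                               ymax = .data$ci_high),
                                  alpha = 0.2)
  p
}

#' Plot cooperator frequency through time across scenarios
#' @param object Tibble from [run_cooperation_scenarios()].
#' @param ... Unused.
#' @export
plot_invasion <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$time, .data$coop_freq,
                               colour = factor(.data$init_freq))) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "time", y = "cooperator frequency",
                  colour = "initial\nfrequency") +
    ggplot2::theme_minimal()
}
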