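#' Plot a power spectrum
#'
#' Line plot of power against angular frequency, with the interior peak (when
#' present) marked.
#'
#' @param object A `circuit_spectrum` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.circuit_spectrum <- function(object, ...) {
  peak <- find_peak(object)
  gg <- ggplot2::ggplot(object, ggplot2::aes(x = .data$omega, y = .data$power)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(
      x = expression(omega ~ "(rad" ~ min^-1 * ")"),
      y = if (isTRUE(attr(object, "normalized"))) "normalized power" else "power",
      title = sprintf("%s spectrum", attr(object, "source"))
    )
  if (!is.na(peak)) {
    gg <- gg + ggplot2::geom_vline(xintercept = peak, linetype = "dashed",
                                   colour = "firebrick")
  }
  gg
}

#' Plot a stochastic trajectory
#'
#' Repressor copy number over time (step line), with promoter occupancy as a
#' secondary panel-free rug of fully-bound episodes omitted for clarity.
#'
#' @param object A `circuit_ssa` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.circuit_ssa <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$n)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::labs(x = "time (min)", y = "repressor molecules",
                  title = "stochastic trajectory")
}

#' Plot a deterministic trajectory
#'
#' Repressor copy number over time from the rate equations.
#'
#' @param object A `circuit_ode` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.circuit_ode <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$n)) +
    ggplot2::geom_line(colour = "firebrick", linewidth = 0.5) +
    ggplot2::labs(x = "time (min)", y = "repressor molecules",
                  title = "deterministic trajectory")
}

#' Plot a phase-diagram sweep
#'
#' Heatmap of the chosen quantity over the `(eps, lambda)` grid; cells with an
#' undefined value are left blank.
#'
#' @param object A `circuit_sweep` tibble.
#' @param value Column to map to fill: `"q90"` (default), `"omega_hat"` or
#'   `"period"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.circuit_sweep <- function(object, value = c("q90", "omega_hat", "period"),
                                   ...) {
  value <- match.arg(value)
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$eps), y = factor(.data$lam),
                               fill = .data[[value]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = expression(epsilon), y = expression(lambda),
                  fill = value)
}
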