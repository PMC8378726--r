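#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulation trace
#'
#' MAP, infusion rate and active-controller index against time; switch
#' events marked.
#'
#' @param object a `"map_trace"` from [simulate_closed_loop()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot map_trace
#' @export
autoplot.map_trace <- function(object, ...) {
  setpt <- attr(object, "setpoint")
  df <- tibble::tibble(
    time_s = rep(object$time_s, 3),
    value = c(object$map_mmHg, object$infusion_ml_hr,
              as.numeric(object$controller_index)),
    what = rep(c("MAP [mmHg]", "infusion [ml/hr]", "controller"),
               each = nrow(object)))
  df$what <- factor(df$what, levels = unique(df$what))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$what), scales = "free_y") +
    ggplot2::labs(x = "time [s]", y = NULL)
  sw <- attr(object, "switch_times")
  if (length(sw))
    p <- p + ggplot2::geom_vline(xintercept = sw, linetype = 3, colour = "grey50")
  if (!is.null(setpt)) {
    hl <- tibble::tibble(what = factor("MAP [mmHg]", levels = levels(df$what)),
                         y = setpt)
    p <- p + ggplot2::geom_hline(data = hl, ggplot2::aes(yintercept = .data$y),
                                 linetype = 2, colour = "grey40")
  }
  p
}

#' Plot a parameter trajectory
#' @param object a `"map_trajectory"`
#' @param ... unused.
#' @method autoplot map_trajectory
#' @export
autoplot.map_trajectory <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time_s, y = .data$theta)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time [s]", y = "drug sensitivity theta [mmHg/(ml/hr)]")
}

#' Frequency-domain view of a designed region
#'
#' Magnitudes of the weighted sensitivity and control sensitivity against
#' frequency for one synthesis result, with the achieved norm level.
#'
#' @param result a [design_controller()] result.
#' @param omega frequency grid (rad/s).
#' @return a ggplot object.
#' @export
plot_mixed_sensitivity <- function(result, omega = default_omega_grid(200)) {
  th <- result$theta_i; tau0 <- result$tau0; w <- result$weights
  vals <- vapply(omega, function(wq) {
    s <- 1i * wq
    g0 <- th / (tau0 * s + 1)
    k <- ss_eval(result$controller, s)[1, 1]
    S <- 1 / (1 + g0 * k)
    c(Mod(ss_eval(w$Ws, s)[1, 1] * S), Mod(w$Wk * k * S))
  }, numeric(2))
  n_om <- length(omega)
  df <- tibble::tibble(
    omega = rep(omega, 2),
    gain = c(vals[1, ], vals[2, ]),
    channel = rep(c("|Ws S|", "|Wk C S|"), each = n_om))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$omega, y = .data$gain,
                                   colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = result$gamma, linetype = 2) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency [rad/s]", y = "magnitude",
                  title = sprintf("region %s: achieved gamma = %.4f",
                                  result$region$index, result$gamma))
}
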