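#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a synthesis result
#'
#' @param x a [design_controller()] result.
#' @param ... unused.
#' @return one-row tibble with the region, weights and achieved norms.
#' @method tidy synthesis_result
#' @export
tidy.synthesis_result <- function(x, ...) {
  tibble::tibble(
    region = x$region$index, theta_lo = x$region$lo, theta_hi = x$region$hi,
    theta_nominal = x$theta_i, half_width = x$region$half_width,
    Wk = x$weights$Wk, gamma_opt = x$gamma_opt, gamma = x$gamma,
    gamma_design = x$gamma_design, controller_order = x$controller$n)
}

#' @rdname tidy.synthesis_result
#' @method glance synthesis_result
#' @export
glance.synthesis_result <- function(x, ...)
  tibble::tibble(gamma_opt = x$gamma_opt, gamma = x$gamma,
                 robust_pass = if (!is.null(x$robust)) x$robust$pass else NA)

#' Tidy a Lyapunov certificate
#' @param x a [certify_region()] result
#' @param ... unused.
#' @method tidy lyapunov_certificate
#' @export
tidy.lyapunov_certificate <- function(x, ...) {
  tibble::tibble(
    theta_lo = x$interval[1], theta_hi = x$interval[2],
    lambda = x$lambda, mu = x$mu, M = x$M,
    L_A = x$L_A, L_D = x$L_D, L_Q = x$L_Q,
    beta_i = x$beta, residual = x$residual, grid_size = x$grid_size)
}

#' Tidy a dwell-time certificate
#' @param x a [dwell_and_rate()] result
#' @param ... unused.
#' @method tidy dwell_certificate
#' @export
tidy.dwell_certificate <- function(x, ...) {
  tibble::tibble(region = seq_along(x$beta_i), beta_i = x$beta_i)
}

#' @rdname tidy.dwell_certificate
#' @method glance dwell_certificate
#' @export
glance.dwell_certificate <- function(x, ...)
  tibble::tibble(beta_max = x$beta_max, beta = x$beta, h_D = x$h_D,
                 rate_beta_max = x$rate_beta_max, rate_full = x$rate_full)

#' Glance at a simulation trace
#' @param x a `"map_trace"`
#' @param ... unused.
#' @method glance map_trace
#' @export
glance.map_trace <- function(x, ...) {
  tibble::tibble(
    duration_s = max(x$time_s), dt_s = attr(x, "dt"),
    n_switches = length(attr(x, "switch_times")),
    map_min = min(x$map_mmHg), map_max = max(x$map_mmHg),
    infusion_max = max(x$infusion_ml_hr),
    unstable = isTRUE(attr(x, "unstable")))
}
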