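#' Default toolkit configuration
#'
#' All defaults reproduce the standard MAP study setup: the five-region
#' partition, the printed weight template, hysteresis half-width 0.2, the
#' fig7-like full-range trajectory at sup-rate 0.0085, nominal patient
#' tau = 35 s / h = 40 s, 150 to 100 mmHg regulation, dt = 0.1 s over
#' 2000 s.  Keys carry explicit unit suffixes.
#'
#' @return nested list (serializable with [write_config()]).
#' @export
default_config <- function() {
  list(
    patient = list(theta_range = c(-9.5, -0.25),
                   tau_nominal_s = 35, tau_range_s = c(10, 60),
                   h_nominal_s = 40, h_range_s = c(20, 60),
                   M0_mmHg = 100),
    regions = list(auto = FALSE,
                   boundaries = c(-9.50, -5.80, -3.03, -1.42, -0.60, -0.25)),
    synthesis = list(bisection_tol = 1e-4, slack_split = 0.5),
    hysteresis = list(half_width = 0.2),
    certification = list(grid_size = 201, lambda_margin = "auto",
                         beta_fraction = 0.5, extend_by_hysteresis = TRUE),
    scenario = list(kind = "fig7_like", rate_per_s = 0.0085,
                    duration_s = 2000, setpoint_mmHg = 100,
                    start_mmHg = 150, dt_s = 0.1,
                    infusion_max_ml_hr = 180),
    seed = 1L)
}

#' Read / write a toolkit configuration
#' @param path YAML file path
#' @param config a configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  utils::modifyList(base, cfg)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the full design -- certify -- simulate -- report pipeline
#'
#' Executes, from a configuration list: (1) region partition and
#' mixed-sensitivity synthesis with the robust-stability check (refining if
#' a region fails); (2) hysteresis-logic construction; (3) Lyapunov
#' dwell-time certification of every region over its hysteresis-extended
#' interval; (4) admissible-rate verification of the scenario trajectory;
#' (5) closed-loop simulation of the nominal patient over the scenario; and
#' (6) performance scoring.  Fully deterministic given the configuration.
#'
#' @param config a [default_config()]-shaped list.
#' @param out_dir optional directory; when given, the controller bank
#'   (plain-text state-space), the design/certificate reports (JSON) and the
#'   trace (CSV) are written there.
#' @param quiet suppress stage messages.
#' @return list: `regions`, `bank` (synthesis results), `design_table`,
#'   `logic`, `certificates`, `dwell`, `rate_check`, `trajectory`, `trace`,
#'   `performance`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  pc <- config$patient; sc <- config$scenario
  tau0 <- pc$tau_nominal_s; h0 <- pc$h_nominal_s

  say("stage design: partition + mixed-sensitivity synthesis")
  regions <- if (isTRUE(config$regions$auto)) NULL else {
    b <- config$regions$boundaries
    lapply(seq_len(length(b) - 1), function(i) operating_region(b[i], b[i + 1], i))
  }
  des <- partition_and_design(pc$theta_range, regions = regions,
                              h = h0, tau0 = tau0,
                              tol = config$synthesis$bisection_tol,
                              slack_split = config$synthesis$slack_split)
  bank <- des$results; regions <- des$regions

  say("stage supervisor: hysteresis logic (half-width %.3g)",
      config$hysteresis$half_width)
  logic <- build_hysteresis(regions, config$hysteresis$half_width)

  say("stage certify: Lyapunov dwell-time certificates (%d regions)",
      length(regions))
  hw <- if (isTRUE(config$certification$extend_by_hysteresis))
    config$hysteresis$half_width else 0
  certs <- lapply(seq_along(regions), function(i) {
    ext <- c(if (i > 1) hw else 0, if (i < length(regions)) hw else 0)
    certify_region(regions[[i]], bank[[i]]$controller, tau0 = tau0,
                   grid_size = config$certification$grid_size,
                   lambda_margin = config$certification$lambda_margin,
                   extend = ext)
  })
  dwell <- dwell_and_rate(certs,
                          hysteresis_widths = 2 * config$hysteresis$half_width,
                          beta_fraction = config$certification$beta_fraction)

  say("stage scenario: %s trajectory at rate %.4g", sc$kind, sc$rate_per_s)
  traj <- make_trajectory(sc$kind, pc$theta_range, rate = sc$rate_per_s,
                          duration = sc$duration_s)
  rate_check <- verify_trajectory(traj, dwell)

  say("stage simulate: nominal patient, %g s at dt = %g s",
      sc$duration_s, sc$dt_s)
  patient <- list(tau_s = tau0, h_s = h0, M0_mmHg = pc$M0_mmHg,
                  trajectory = traj)
  trace <- simulate_closed_loop(patient, bank, logic,
                                setpoint = sc$setpoint_mmHg,
                                dt = sc$dt_s, T_end = sc$duration_s,
                                x0 = sc$start_mmHg - pc$M0_mmHg,
                                I_max = sc$infusion_max_ml_hr)
  perf <- performance_metrics(trace, setpoint = sc$setpoint_mmHg)

  out <- list(regions = regions, bank = bank,
              design_table = tidy_bank(bank), logic = logic,
              certificates = certs, dwell = dwell, rate_check = rate_check,
              trajectory = traj, trace = trace, performance = perf,
              config = config)
  if (!is.null(out_dir)) write_pipeline_artifacts(out, out_dir)
  out
}

tidy_bank <- function(bank) {
  dplyr::bind_rows(lapply(bank, function(d) tibble::tibble(
    region = d$region$index, theta_lo = d$region$lo, theta_hi = d$region$hi,
    theta_nominal = d$theta_i, Wk = d$weights$Wk,
    gamma_opt = d$gamma_opt, gamma = d$gamma,
    robust_norm = if (!is.null(d$robust)) d$robust$norm else NA_real_,
    robust_margin = if (!is.null(d$robust)) d$robust$margin else NA_real_,
    robust_pass = if (!is.null(d$robust)) d$robust$pass else NA)))
}

write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in res$bank)
    write_ss(d$controller,
             file.path(out_dir, sprintf("controller_%02d.ss", d$region$index)))
  jsonlite::write_json(list(
    design = res$design_table,
    certificates = tidy_certificates(res$certificates),
    dwell = res$dwell[c("beta_i", "beta_max", "beta", "h_D",
                        "rate_beta_max", "rate_full")],
    rate_check = res$rate_check,
    performance = res$performance),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_trace_csv(res$trace, file.path(out_dir, "trace.csv"))
  write_trajectory_csv(res$trajectory, file.path(out_dir, "trajectory.csv"))
  invisible(out_dir)
}

tidy_certificates <- function(certs) {
  dplyr::bind_rows(lapply(seq_along(certs), function(i) {
    ce <- certs[[i]]
    tibble::tibble(region = i, theta_lo = ce$interval[1],
                   theta_hi = ce$interval[2], lambda = ce$lambda,
                   mu = ce$mu, M = ce$M, L_A = ce$L_A, L_D = ce$L_D,
                   L_Q = ce$L_Q, beta_i = ce$beta,
                   residual = ce$residual)
  }))
}
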