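#' Hysteresis switching logic
#'
#' Builds the supervisor thresholds from adjacent region boundaries: between
#' regions i and i+1 (boundary `b`, region i the more-negative side) the
#' supervisor switches up (i to i+1) when theta rises past `b + half_width`
#' and back down when it falls past `b - half_width`.  With the five-region
#' MAP partition and `half_width = 0.2` this reproduces the standard
#' switching table (up at -5.60, -2.83, -1.22, -0.40; down at -6.00, -3.23,
#' -1.62, -0.80).
#'
#' @param regions ordered, adjacent [operating_region()]s.
#' @param half_width hysteresis half-width (same units as theta).
#' @return A `"hysteresis_logic"` list with `boundaries`, `up`, `down`,
#'   `half_width`, `n_regions`.
#' @export
build_hysteresis <- function(regions, half_width = 0.2) {
  stopifnot(length(regions) >= 1, half_width >= 0)
  lo <- vapply(regions, `[[`, numeric(1), "lo")
  hi <- vapply(regions, `[[`, numeric(1), "hi")
  if (length(regions) > 1 && any(abs(hi[-length(hi)] - lo[-1]) > 1e-9))
    stop("regions must be ordered and adjacent", call. = FALSE)
  widths <- hi - lo
  if (half_width >= min(widths))
    stop("invalid hysteresis: half_width must be smaller than every region width",
         call. = FALSE)
  if (half_width == 0)
    warning("degenerate hysteresis: half_width 0 gives coincident thresholds")
  b <- hi[-length(hi)]
  structure(list(boundaries = b, up = b + half_width, down = b - half_width,
                 half_width = half_width, n_regions = length(regions)),
            class = "hysteresis_logic")
}

#' One supervisor decision
#'
#' Deterministic hysteresis rule: from region `current`, switch up only when
#' theta exceeds the up-threshold of the current upper boundary, down only
#' below the down-threshold of the lower boundary; at most one step per
#' call.  Oscillations of amplitude below `half_width` around a boundary
#' never toggle the index (anti-chattering).
#'
#' @param theta current scheduling value.
#' @param current active region index.
#' @param logic a [build_hysteresis()] object.
#' @return new region index.
#' @export
supervisor_step <- function(theta, current, logic) {
  stopifnot(current >= 1, current <= logic$n_regions)
  if (current < logic$n_regions && theta > logic$up[current]) current + 1L
  else if (current > 1L && theta < logic$down[current - 1L]) current - 1L
  else as.integer(current)
}

# region index whose interval contains theta (first match)
region_of <- function(theta, regions) {
  for (i in seq_along(regions))
    if (theta >= regions[[i]]$lo - 1e-12 && theta <= regions[[i]]$hi + 1e-12)
      return(i)
  if (theta < regions[[1]]$lo) 1L else length(regions)
}

#' Closed-loop simulation of the switched delayed system
#'
#' Fixed-step simulation of the full architecture: LPV plant with input
#' delay (circular buffer of `round(h/dt)` samples), Smith-predictor
#' correction with the delayed branch realized as the FIR filter of
#' [fir_delay_branch()], the active controller integrated by exact
#' zero-order-hold discretization, hysteresis supervision on theta(t),
#' bumpless transfer on switches (incoming controller state chosen as the
#' minimum-norm state reproducing the outgoing command), actuator saturation
#' with back-calculation anti-windup, and a blow-up guard that flags (rather
#' than stops) an unstable run.
#'
#' @param patient list/row with `tau_s`, `h_s`, `M0_mmHg` and either a
#'   `trajectory` ("map_trajectory") or `theta_fun` (function of time); rows
#'   of [sample_patients()] work directly.
#' @param bank list of [design_controller()] results, one per region, in
#'   region order.
#' @param logic a [build_hysteresis()] for the same regions.
#' @param setpoint target MAP \[mmHg\].
#' @param dt step \[s\] (require `dt <= min(tau, h)/10`)
#' @param T_end total
#'   time \[s\].
#' @param x0 initial pressure deviation \[mmHg\] (150 mmHg start = 50).
#' @param I_max actuator bound \[ml/hr\]
#' @param clamp apply the saturation
#'   (disable to inspect the raw command).
#' @param bumpless logical; cold-start the incoming controller when `FALSE`.
#' @param single force a fixed controller index (no switching), for
#'   single-controller comparisons.
#' @param aw_gain anti-windup back-calculation gain \[1/s\].
#' @param blowup flag the trace as unstable if |deviation| exceeds this.
#' @return A `"map_trace"` tibble `(time_s, theta, map_mmHg, infusion_ml_hr,
#'   controller_index)` with attributes `switch_times`, `unstable`, `dt`,
#'   `setpoint`, `M0`.
#' @export
simulate_closed_loop <- function(patient, bank, logic, setpoint = 100,
                                 dt = 0.1, T_end = 2000, x0 = 50,
                                 I_max = 180, clamp = TRUE, bumpless = TRUE,
                                 single = NULL, aw_gain = 0.2, blowup = 1e4) {
  tau <- patient$tau_s[[1]]; h <- patient$h_s[[1]]; M0 <- patient$M0_mmHg[[1]]
  theta_fun <- if (!is.null(patient$theta_fun)) {
    f <- patient$theta_fun
    if (is.function(f)) f else f[[1]]
  } else {
    tr <- patient$trajectory
    if (inherits(tr, "map_trajectory")) trajectory_fun(tr)
    else trajectory_fun(tr[[1]])
  }
  stopifnot(dt > 0, dt <= min(tau, if (h > 0) h else tau) / 10)
  n_step <- round(T_end / dt)
  n_h <- round(h / dt)
  tau0 <- bank[[1]]$tau0
  firs <- lapply(bank, function(d) fir_delay_branch(d$theta_i, tau0, h, dt))
  n_fir <- length(firs[[1]]$kernel)
  disc <- lapply(bank, function(d) ss_discretize(d$controller, dt))
  # unit-gain delay-free predictor state recursion 1/(tau0 s + 1)
  a0 <- exp(-dt / tau0)
  ad <- exp(-dt / tau)
  regions <- lapply(bank, `[[`, "region")
  q <- if (is.null(single)) region_of(theta_fun(0), regions) else as.integer(single)
  x <- x0
  xk <- rep(0, bank[[q]]$controller$n)
  xp <- 0
  ubuf <- rep(0, max(n_fir, n_h, 1))
  r <- setpoint - M0
  out_t <- seq(0, n_step) * dt
  out_map <- out_I <- out_q <- out_th <- numeric(n_step + 1)
  out_map[1] <- x + M0; out_q[1] <- q; out_th[1] <- theta_fun(0)
  switches <- numeric(0)
  unstable <- FALSE
  for (k in seq_len(n_step)) {
    t <- (k - 1) * dt
    th <- theta_fun(t)
    if (is.null(single)) {
      qn <- supervisor_step(th, q, logic)
      if (qn != q) {
        switches <- c(switches, t)
        u_last <- c(bank[[q]]$controller$C %*% xk)
        q <- qn
        Cn <- bank[[q]]$controller$C
        xk <- if (bumpless)
          c(t(Cn) %*% solve(Cn %*% t(Cn), u_last)) else rep(0, ncol(Cn))
      }
    }
    des <- bank[[q]]; D <- disc[[q]]
    # Smith correction Pi u = theta_i * (delay-free branch) - FIR(delayed branch)
    pred <- des$theta_i * xp - sum(firs[[q]]$kernel * ubuf[seq_len(n_fir)])
    e <- r - (x + pred)
    xk <- c(D$Ad %*% xk + D$Bd * e)
    u_raw <- c(des$controller$C %*% xk) + c(des$controller$D) * e
    u <- if (clamp) min(max(u_raw, 0), I_max) else u_raw
    if (clamp && u != u_raw) {
      Cn <- des$controller$C
      xk <- xk + aw_gain * dt * c(t(Cn) %*% solve(Cn %*% t(Cn), u - u_raw))
    }
    u_del <- if (n_h >= 1) ubuf[n_h] else u
    x <- ad * x + (1 - ad) * th * u_del
    xp <- a0 * xp + (1 - a0) * u
    ubuf <- c(u, ubuf[-length(ubuf)])
    if (!is.finite(x) || abs(x) > blowup) { unstable <- TRUE
      x <- sign(x) * blowup }
    out_map[k + 1] <- x + M0; out_I[k + 1] <- u
    out_q[k + 1] <- q; out_th[k + 1] <- th
  }
  out_th[1] <- theta_fun(0); out_I[1] <- out_I[2]
  structure(
    tibble::tibble(time_s = out_t, theta = out_th, map_mmHg = out_map,
                   infusion_ml_hr = out_I, controller_index = as.integer(out_q)),
    switch_times = switches, unstable = unstable, dt = dt,
    setpoint = setpoint, M0 = M0,
    class = c("map_trace", "tbl_df", "tbl", "data.frame"))
}

#' Score a simulation trace against the clinical specifications
#'
#' Metric definitions (the specifications state targets, not definitions;
#' these are the package's):
#' * settling time: first time after which MAP stays within the `band` of
#'   the setpoint for the remainder of the run \[reported in minutes\];
#' * undershoot: `max(0, setpoint - min MAP)` after the first downward
#'   crossing of the setpoint;
#' * steady-state band: max |MAP - setpoint| over the final 20% of each
#'   constant-theta segment (identified from the trace's theta column);
#' * oscillation flag: sustained sign alternation of the error with
#'   amplitude > 1 mmHg over the final 20% of the run;
#' * infusion range over the whole trace.
#'
#' @param trace a [simulate_closed_loop()] trace.
#' @param setpoint target MAP (defaults to the trace attribute).
#' @param specs thresholds: settling \[min\], undershoot \[mmHg\], band
#'   \[mmHg\], infusion bounds \[ml/hr\].
#' @return A `"map_performance"` tibble with one row per specification item
#'   (`metric`, `value`, `threshold`, `pass`).
#' @export
performance_metrics <- function(trace, setpoint = attr(trace, "setpoint"),
                                specs = list(settling_min = 10, undershoot_mmHg = 10,
                                             band_mmHg = 5, infusion_min = 0,
                                             infusion_max = 180)) {
  m <- trace$map_mmHg; tt <- trace$time_s
  unstable <- isTRUE(attr(trace, "unstable"))
  err <- m - setpoint
  inband <- abs(err) <= specs$band_mmHg
  settle_s <- if (all(!inband)) Inf else {
    runs <- rev(cumprod(rev(inband)))     # 1 from the first index where in-band to the end
    j <- which(runs == 1)[1]
    tt[j]
  }
  cross <- which(err <= 0)[1]
  undershoot <- if (is.na(cross)) 0 else max(0, setpoint - min(m[cross:length(m)]))
  # constant-theta segments: runs of (numerically) zero slope longer than 60 s
  dth <- c(0, diff(trace$theta))
  flat <- abs(dth) <= 1e-12
  rle_f <- rle(flat)
  ends <- cumsum(rle_f$lengths); starts <- ends - rle_f$lengths + 1
  ss_band <- 0
  for (j in seq_along(rle_f$values)) {
    if (!rle_f$values[j]) next
    if (tt[ends[j]] - tt[starts[j]] < 60) next
    i0 <- starts[j] + floor(0.8 * (ends[j] - starts[j]))
    ss_band <- max(ss_band, max(abs(err[i0:ends[j]])))
  }
  tail_i <- seq(floor(0.8 * length(m)), length(m))
  sgn <- sign(err[tail_i]); sgn <- sgn[sgn != 0]
  oscillating <- length(sgn) > 2 && mean(diff(sgn) != 0) > 0.5 &&
    max(abs(err[tail_i])) > 1
  I <- trace$infusion_ml_hr
  res <- tibble::tibble(
    metric = c("settling_time_min", "undershoot_mmHg", "steady_state_band_mmHg",
               "oscillation", "infusion_min_ml_hr", "infusion_max_ml_hr"),
    value = c(settle_s / 60, undershoot, ss_band, as.numeric(oscillating),
              min(I), max(I)),
    threshold = c(specs$settling_min, specs$undershoot_mmHg, specs$band_mmHg,
                  0, specs$infusion_min, specs$infusion_max),
    pass = c(settle_s / 60 <= specs$settling_min,
             undershoot <= specs$undershoot_mmHg,
             ss_band <= specs$band_mmHg,
             !oscillating,
             min(I) >= specs$infusion_min,
             max(I) <= specs$infusion_max))
  if (unstable) res$pass <- FALSE
  class(res) <- c("map_performance", class(res))
  attr(res, "unstable") <- unstable
  res
}

#' Trace CSV exchange
#' @param trace a `"map_trace"`
#' @param path file path.
#' @export
write_trace_csv <- function(trace, path) {
  readr::write_csv(tibble::as_tibble(trace), path)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  structure(df, class = c("map_trace", class(df)))
}
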