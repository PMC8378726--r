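#' Patient model parameters
#'
#' Parameter record for the first-order delayed LPV model of the MAP response
#' to vasoactive drug infusion,
#' \deqn{G(s) = \frac{k}{\tau s + 1} e^{-h s},}
#' with drug sensitivity `k = theta(t)` treated as the measurable scheduling
#' parameter.  Defaults are the standard post-surgical hypertension setup:
#' theta in \[-9.5, -0.25\] mmHg/(ml/hr), tau nominal 35 s in \[10, 60\],
#' transport delay h nominal 40 s in \[20, 60\], baseline pressure 100 mmHg.
#'
#' @param theta_range numeric length-2; sensitivity range, strictly negative
#'   (the drug lowers pressure) \[mmHg per ml/hr\].
#' @param tau_nominal,tau_range distribution-lag nominal and range \[s\].
#' @param h_nominal,h_range transport-delay nominal and range \[s\].
#' @param M0 baseline mean arterial pressure \[mmHg\].
#' @return A `"patient_parameters"` list.
#' @examples
#' patient_parameters()
#' @export
patient_parameters <- function(theta_range = c(-9.5, -0.25),
                               tau_nominal = 35, tau_range = c(10, 60),
                               h_nominal = 40, h_range = c(20, 60),
                               M0 = 100) {
  theta_range <- sort(theta_range)
  tau_range <- sort(tau_range); h_range <- sort(h_range)
  if (any(theta_range >= 0))
    stop("theta_range must be strictly negative: the drug lowers pressure",
         call. = FALSE)
  if (tau_range[1] <= 0 || h_range[1] < 0)
    stop("tau_range must be strictly positive and h_range nonnegative",
         call. = FALSE)
  if (tau_nominal < tau_range[1] || tau_nominal > tau_range[2] ||
      h_nominal < h_range[1] || h_nominal > h_range[2])
    stop("nominal tau/h must lie inside their ranges", call. = FALSE)
  structure(list(theta_range = theta_range, tau_nominal = tau_nominal,
                 tau_range = tau_range, h_nominal = h_nominal,
                 h_range = h_range, M0 = M0),
            class = "patient_parameters")
}

#' Nominal frozen-parameter plant
#'
#' The plant at a frozen sensitivity `theta_i`: rational part
#' `theta_i/(tau s + 1)` returned as an [ss_model()], with the transport
#' delay `h` carried separately (never Pade-approximated).
#'
#' @param theta_i frozen drug sensitivity \[mmHg/(ml/hr)\].
#' @param tau distribution lag \[s\], positive.
#' @param h transport delay \[s\], nonnegative.
#' @return list with elements `rational` ([ss_model()]), `h`, `theta_i`, `tau`.
#' @examples
#' G <- nominal_plant(-7.65, 35, 40)
#' Re(freqresp(G$rational, 0))   # DC gain -7.65
#' @export
nominal_plant <- function(theta_i, tau, h = 0) {
  if (!is.finite(tau) || tau <= 0) stop("tau must be positive", call. = FALSE)
  if (h < 0) stop("h must be nonnegative", call. = FALSE)
  list(rational = first_order_ss(theta_i, tau), h = h,
       theta_i = theta_i, tau = tau)
}

#' One step of the LPV state equation
#'
#' The scalar LPV dynamics `x' = -x/tau + theta(t) u(t-h)/tau` with output
#' `M = x + M0`; the identity `M - M0 = x` (pressure deviation equals the
#' state) holds by construction.
#'
#' @param x state: pressure deviation from baseline \[mmHg\].
#' @param u_delayed delayed infusion rate `u(t-h)` \[ml/hr\].
#' @param theta current sensitivity
#' @param tau lag \[s\]
#' @param M0 baseline.
#' @return list with `dx` (state derivative) and `M` (output, mmHg).
#' @examples
#' lpv_step(50, 0, -7.65, 35, 100)   # M = 150, the starting pressure
#' @export
lpv_step <- function(x, u_delayed, theta, tau, M0 = 100) {
  if (!is.finite(tau) || tau <= 0) stop("tau must be positive", call. = FALSE)
  list(dx = -x / tau + theta * u_delayed / tau, M = x + M0)
}

# ---------------------------------------------------------------------------
# parameter trajectories

new_trajectory <- function(time, theta, kind) {
  stopifnot(length(time) == length(theta), !is.unsorted(time))
  seg <- diff(theta) / diff(time)
  structure(
    tibble::tibble(time_s = time, theta = theta),
    sup_rate = if (length(seg)) max(abs(seg)) else 0,
    kind = kind,
    class = c("map_trajectory", "tbl_df", "tbl", "data.frame"))
}

#' Generate a scheduling-parameter trajectory
#'
#' Piecewise-linear trajectories theta(t) of the drug sensitivity.  The
#' representation is deliberately piecewise linear so the supremum of
#' |theta'(t)| is exact (the maximum absolute segment slope), which is the
#' quantity the dwell-time certificate bounds.
#'
#' Kinds:
#' \describe{
#' \item{`constant`}{theta held at `from` (default: lower end of the range).}
#' \item{`ramp_hold`}{single ramp from the lower to the upper end of
#'   `theta_range` at `rate`, then hold.}
#' \item{`fig7_like`}{ramp--hold--ramp--hold covering the full range: rise on
#'   \[0, 400\] s, hold on \[400, 1100\] s, rise again from 1100 s until the
#'   range is exhausted, hold to `duration`.}
#' }
#'
#' @param kind one of `"constant"`, `"ramp_hold"`, `"fig7_like"`.
#' @param theta_range sensitivity range to cover \[mmHg/(ml/hr)\].
#' @param rate nonnegative ramp slope \[mmHg/(ml/hr) per s\].
#' @param duration total duration \[s\].
#' @param from starting value (defaults to `theta_range[1]`).
#' @return A `"map_trajectory"` tibble of breakpoints `(time_s, theta)` with
#'   attribute `sup_rate`; evaluate with [trajectory_fun()].
#' @examples
#' tr <- make_trajectory("fig7_like", rate = 0.0085, duration = 2000)
#' trajectory_sup_rate(tr)
#' @export
make_trajectory <- function(kind = c("constant", "ramp_hold", "fig7_like"),
                            theta_range = c(-9.5, -0.25), rate = 0.0085,
                            duration = 2000, from = NULL) {
  kind <- match.arg(kind)
  stopifnot(rate >= 0, duration > 0)
  theta_range <- sort(theta_range)
  lo <- theta_range[1]; hi <- theta_range[2]
  if (is.null(from)) from <- lo
  if (kind == "constant")
    return(new_trajectory(c(0, duration), c(from, from), kind))
  width <- hi - lo
  if (kind == "ramp_hold") {
    if (rate <= 0 || width / rate > duration)
      stop("infeasible trajectory: range not coverable at this rate within duration",
           call. = FALSE)
    t_ramp <- width / rate
    return(new_trajectory(c(0, t_ramp, duration), c(lo, hi, hi), kind))
  }
  # fig7_like: rise [0,400], hold [400,1100], rise from 1100, hold to end
  if (rate <= 0) stop("infeasible trajectory: fig7_like needs a positive rate",
                      call. = FALSE)
  d1 <- min(rate * 400, width)
  t2_end <- 1100 + (width - d1) / rate
  if (t2_end > duration)
    stop("infeasible trajectory: range not coverable at this rate within duration",
         call. = FALSE)
  tt <- c(0, 400, 1100, t2_end, duration)
  th <- c(lo, lo + d1, lo + d1, hi, hi)
  keep <- !duplicated(tt)
  new_trajectory(tt[keep], th[keep], kind)
}

#' Evaluate / interrogate a trajectory
#'
#' @param traj a `"map_trajectory"`.
#' @return `trajectory_fun()` returns a vectorized function of time (s);
#'   `trajectory_sup_rate()` the exact supremum of |theta'(t)|.
#' @export
trajectory_fun <- function(traj) {
  tt <- traj$time_s; th <- traj$theta
  function(t) stats::approx(tt, th, xout = pmin(pmax(t, tt[1]), tt[length(tt)]),
                            rule = 2)$y
}

#' @rdname trajectory_fun
#' @export
trajectory_sup_rate <- function(traj) attr(traj, "sup_rate")

#' Trajectory CSV exchange
#' @param traj a `"map_trajectory"`
#' @param path file path.
#' @export
write_trajectory_csv <- function(traj, path) {
  readr::write_csv(tibble::as_tibble(traj), path)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  new_trajectory(df$time_s, df$theta, "imported")
}

# ---------------------------------------------------------------------------

#' Sample virtual patients
#'
#' Draws `n` patient realizations with tau and h uniform over their
#' uncertainty ranges (the model literature gives ranges, not distributions;
#' uniform is the least-informative choice) and a shared sensitivity
#' trajectory.  Deterministic for a fixed seed.
#'
#' @param params a [patient_parameters()].
#' @param n number of virtual patients.
#' @param seed integer RNG seed.
#' @param trajectory optional shared `"map_trajectory"` (default: fig7-like).
#' @param nominal if `TRUE`, override sampling with the nominal tau and h.
#' @return tibble with columns `patient`, `tau_s`, `h_s`, `M0_mmHg`, `seed`
#'   and a list-column `trajectory`.
#' @export
sample_patients <- function(params = patient_parameters(), n = 1, seed = 1,
                            trajectory = NULL, nominal = FALSE) {
  stopifnot(inherits(params, "patient_parameters"))
  if (is.null(trajectory))
    trajectory <- make_trajectory("fig7_like", params$theta_range)
  rng <- local({ set.seed(seed)
    list(tau = stats::runif(n, params$tau_range[1], params$tau_range[2]),
         h = stats::runif(n, params$h_range[1], params$h_range[2])) })
  tibble::tibble(
    patient = seq_len(n),
    tau_s = if (nominal) rep(params$tau_nominal, n) else rng$tau,
    h_s = if (nominal) rep(params$h_nominal, n) else rng$h,
    M0_mmHg = params$M0,
    seed = seed,
    trajectory = rep(list(trajectory), n))
}
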