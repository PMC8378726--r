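#' Operating regions of the sensitivity range
#'
#' A compact sub-interval of the drug-sensitivity range with its nominal
#' (center) point and half-width, the unit over which one LTI robust
#' controller is designed.
#'
#' @param lo,hi interval endpoints (negative, `lo < hi`).
#' @param index optional integer label.
#' @return An `"operating_region"` list with `lo`, `hi`, `center` (the
#'   nominal design point), `half_width` and `index`.
#' @examples
#' operating_region(-9.5, -5.8)   # region 1 of the five-region partition
#' @export
operating_region <- function(lo, hi, index = NA_integer_) {
  if (!(lo < hi)) stop("invalid region: need lo < hi", call. = FALSE)
  structure(list(lo = lo, hi = hi, center = (lo + hi) / 2,
                 half_width = (hi - lo) / 2, index = index),
            class = "operating_region")
}

#' The five-region partition of the MAP problem
#'
#' The standard partition of theta in \[-9.5, -0.25\] into five regions with
#' controllers C1..C5: boundaries at -5.80, -3.03, -1.42, -0.60.
#'
#' @return list of five [operating_region()]s, in descending-|theta| order.
#' @export
map_regions <- function() {
  b <- c(-9.50, -5.80, -3.03, -1.42, -0.60, -0.25)
  lapply(1:5, function(i) operating_region(b[i], b[i + 1], i))
}

#' Region list as a tibble
#' @param regions list of [operating_region()]s.
#' @export
region_table <- function(regions) {
  tibble::tibble(
    region = vapply(regions, `[[`, integer(1) + 0, "index"),
    theta_lo = vapply(regions, `[[`, numeric(1), "lo"),
    theta_hi = vapply(regions, `[[`, numeric(1), "hi"),
    theta_nominal = vapply(regions, `[[`, numeric(1), "center"),
    half_width = vapply(regions, `[[`, numeric(1), "half_width"))
}

# ---------------------------------------------------------------------------
# partitioned plants and LFT separation

#' Partitioned (two-port) plant with input delay
#'
#' Container for the four transfer blocks of an uncertain plant in linear
#' fractional form.  Convention: the delay `exp(-h s)` multiplies the G12 and
#' G22 channels of the *raw* delayed plant; after Smith augmentation the
#' design blocks are delay-free and the residual carries the delay (see
#' [augment_and_decompose()]).
#'
#' @param G11,G12,G21,G22 [ss_model()]s (delay-free block dynamics).
#' @param h input delay \[s\].
#' @return A `"partitioned_plant"` list.
#' @export
partitioned_plant <- function(G11, G12, G21, G22, h = 0) {
  structure(list(G11 = G11, G12 = G12, G21 = G21, G22 = G22, h = h),
            class = "partitioned_plant")
}

#' LFT separation of the LPV plant over a region
#'
#' Writes the LPV delayed plant `theta/(tau0 s + 1) exp(-h s)` over a region
#' as an upper LFT of an LTI two-port with the normalized time-varying gain
#' `delta(t) = (theta(t) - theta_i)/Delta_i`, `|delta| <= 1`.  Closing the
#' uncertainty channel with a frozen `delta` recovers the frozen-theta plant
#' exactly:
#' blocks are `G11 = 0`, `G12 = exp(-hs)` (uncertainty output is the delayed
#' input), `G21 = Delta_i/(tau0 s + 1)`, `G22 = theta_i/(tau0 s + 1) e^{-hs}`.
#'
#' @param region an [operating_region()].
#' @param tau0 nominal lag \[s\]
#' @param h transport delay \[s\].
#' @return list with the `"partitioned_plant"` (`plant`) and the uncertainty
#'   description (`uncertainty`: half-width, normalization, induced norm
#'   bound 1).
#' @export
build_uncertainty_lft <- function(region, tau0 = 35, h = 40) {
  stopifnot(inherits(region, "operating_region"), tau0 > 0, h >= 0)
  if (region$half_width <= 0)
    stop("degenerate region: zero width", call. = FALSE)
  zero <- ss_model(matrix(0, 0, 0), matrix(0, 0, 1), matrix(0, 1, 0), 0)
  unit <- ss_model(matrix(0, 0, 0), matrix(0, 0, 1), matrix(0, 1, 0), 1)
  plant <- partitioned_plant(
    G11 = zero,
    G12 = unit,                                    # delayed by h in the raw plant
    G21 = first_order_ss(region$half_width, tau0),
    G22 = first_order_ss(region$center, tau0),     # delayed by h in the raw plant
    h = h)
  unc <- list(region = region, half_width = region$half_width,
              normalization = "delta = (theta - theta_i)/Delta_i",
              induced_norm_bound = 1)
  list(plant = plant, uncertainty = unc)
}

#' Additive-uncertainty LFT for the robust-stability check
#'
#' The design-loop robust-stability test covers, besides the gain variation
#' inside the region, the uncertain lag (Delta tau) and delay (Delta h)
#' through the additive bound of [additive_bound()].  The uncertainty channel
#' is additive at the plant output with the constant weight
#' `w = exp(-h0/tau0) (Delta_i + 2.715 |theta_i|)` (the control-sensitivity
#' weight), normalized so the small-gain threshold is 1.
#'
#' @inheritParams build_uncertainty_lft
#' @param h0 nominal delay used in the weight attenuation factor \[s\].
#' @return as [build_uncertainty_lft()].
#' @export
additive_uncertainty_lft <- function(region, tau0 = 35, h = 40, h0 = h) {
  stopifnot(inherits(region, "operating_region"), tau0 > 0)
  w <- exp(-h0 / tau0) * (region$half_width + 2.715 * abs(region$center))
  zero <- ss_model(matrix(0, 0, 0), matrix(0, 0, 1), matrix(0, 1, 0), 0)
  gain <- function(k) ss_model(matrix(0, 0, 0), matrix(0, 0, 1), matrix(0, 1, 0), k)
  plant <- partitioned_plant(
    G11 = zero,
    G12 = gain(1),                                 # z_r = (delayed) controller output
    G21 = gain(w),                                 # w_r enters the measured output
    G22 = first_order_ss(region$center, tau0),
    h = h)
  unc <- list(region = region, half_width = region$half_width,
              weight = w, normalization = "additive, |Delta| <= 1",
              induced_norm_bound = 1)
  list(plant = plant, uncertainty = unc)
}

#' Classical Smith predictor
#'
#' `Pi(s) = G22(s) - G22(s) e^{-sh}`: the parallel compensator that removes
#' the delay from the feedback design loop of a *stable* plant.  Returned as
#' a frequency-response closure plus its ingredients; `Pi(0) = 0` always.
#'
#' @param G22 stable [ss_model()] (the delay-free rational part).
#' @param h transport delay \[s\].
#' @return A `"smith_predictor"` list with `G22`, `h` and `fresp(omega)`.
#' @export
smith_predictor <- function(G22, h) {
  if (!is_stable(G22))
    stop("assumption violation: G22 must be stable (unified Smith predictor for unstable plants is not supported)",
         call. = FALSE)
  stopifnot(h >= 0)
  structure(list(
    G22 = G22, h = h,
    fresp = function(omega) freqresp(G22, omega) * (1 - exp(-1i * omega * h))),
    class = "smith_predictor")
}

#' Smith augmentation and decomposition
#'
#' Adding the Smith predictor in parallel from the control input to the
#' measurement turns the delayed two-port into the augmented plant
#' `[G11, G12 e^{-sh}; G21, G22]` with delay-free G22, and then decomposes it
#' as a delay-free design plant `G_tilde` plus a residual `Pi1` on the
#' uncertainty channel such that the closed-loop uncertainty transfer
#' satisfies
#' \deqn{M(s) = F_l(\tilde G(s), C(s)) e^{-sh} + \Pi_1(s)}
#' for every controller C (the identity, not a particular block transcription,
#' is the contract; it is verified on a frequency grid in the test-suite).
#' Here `G_tilde = [G11, G12; G21, G22]` with all blocks delay-free and
#' `Pi1 = G11 (1 - e^{-sh})`, a Smith-type residual on the w_r -> z_r channel
#' (identically zero when G11 = 0, as in the MAP problem).
#'
#' @param plant a [partitioned_plant()] (raw blocks; delay on channels 12, 22).
#' @return A `"smith_decomposition"` list: `G_tilde` (partitioned, delay-free),
#'   `Pi` (the [smith_predictor()]), `Pi1_fresp(omega)`, and `h`.
#' @export
augment_and_decompose <- function(plant) {
  stopifnot(inherits(plant, "partitioned_plant"))
  Pi <- smith_predictor(plant$G22, plant$h)
  G_tilde <- partitioned_plant(plant$G11, plant$G12, plant$G21, plant$G22, h = 0)
  h <- plant$h
  G11 <- plant$G11
  structure(list(
    G_tilde = G_tilde, Pi = Pi, h = h,
    Pi1_fresp = function(omega) freqresp(G11, omega) * (1 - exp(-1i * omega * h))),
    class = "smith_decomposition")
}

#' Frequency response of the closed uncertainty channel
#'
#' Evaluates, on a frequency grid, both sides of the decomposition identity:
#' `M_direct` closes the controller around the raw augmented plant
#' (`u = C y_tilde`, positive feedback as in the lower-LFT convention), and
#' `M_decomposed` uses `F_l(G_tilde, C) e^{-sh} + Pi1`.
#'
#' @param decomp a decomposition from [augment_and_decompose()].
#' @param C controller [ss_model()] (u = C y_tilde).
#' @param omega frequency grid \[rad/s\].
#' @return tibble with complex columns `direct` and `decomposed`.
#' @export
uncertainty_channel_fresp <- function(decomp, C, omega) {
  Gt <- decomp$G_tilde; h <- decomp$h
  g11 <- freqresp(Gt$G11, omega); g12 <- freqresp(Gt$G12, omega)
  g21 <- freqresp(Gt$G21, omega); g22 <- freqresp(Gt$G22, omega)
  cc <- freqresp(C, omega)
  # decomposed: F_l(G_tilde, C) e^{-sh} + Pi1
  fl <- g11 + g12 * cc * g21 / (1 - g22 * cc)
  dec <- fl * exp(-1i * omega * h) + decomp$Pi1_fresp(omega)
  # direct: close C around the augmented plant [G11, G12 e^{-sh}; G21, G22_df]
  u_per_w <- cc * g21 / (1 - g22 * cc)
  dir <- g11 + g12 * exp(-1i * omega * h) * u_per_w
  tibble::tibble(omega = omega, direct = dir, decomposed = dec)
}

#' Additive uncertainty bound for the uncertain lag and delay
#'
#' Bound on the additive perturbation of the frozen plant when theta ranges
#' over the region and tau, h over their uncertainty ranges:
#' `|G_Delta| <= Delta_i + |theta_i| * S` with
#' `S = sup_w (|e^{-j w dh} - 1| + |dtau * jw/(tau0 jw + 1)|)`.
#' The supremum is evaluated by frequency sweep and checked against the
#' analytic limits (first term sup 2, second term sup `dtau/tau0`).
#'
#' @param region an [operating_region()].
#' @param dh delay uncertainty half-range \[s\].
#' @param dtau lag uncertainty half-range \[s\].
#' @param tau0 nominal lag \[s\].
#' @return list with `bound`, the factor `S`, and its analytic value.
#' @examples
#' additive_bound(operating_region(-9.5, -5.8), dh = 20, dtau = 25)$S
#' @export
additive_bound <- function(region, dh = 20, dtau = 25, tau0 = 35) {
  stopifnot(tau0 > 0, dh >= 0, dtau >= 0)
  om <- default_omega_grid(2000, 1e-6, 1e4)
  sweep <- max(abs(exp(-1i * om * dh) - 1) + abs(dtau * 1i * om / (tau0 * 1i * om + 1)))
  S_analytic <- (if (dh > 0) 2 else 0) + dtau / tau0
  S <- max(sweep, S_analytic)   # sweep can only undershoot the supremum
  list(bound = region$half_width + abs(region$center) * S,
       S = S, S_sweep = sweep, S_analytic = S_analytic)
}

#' FIR realization of the delayed plant branch
#'
#' Discrete-time FIR approximation of `e^{-sh} G22(s)` at step `dt`: the
#' exact ZOH impulse response of the first-order rational part, shifted by
#' `round(h/dt)` samples and truncated at `trunc_tau` time constants.  This
#' is the realization the closed-loop simulator uses for the delayed branch
#' of the Smith predictor.
#'
#' @param theta_i,tau0 rational part `theta_i/(tau0 s + 1)`.
#' @param h delay \[s\]
#' @param dt sample step \[s\].
#' @param trunc_tau truncation horizon in units of tau0.
#' @return list with `kernel` (convolution weights, most-recent-first),
#'   `n_delay` (delay samples) and `fresp(omega)`.
#' @export
fir_delay_branch <- function(theta_i, tau0, h, dt, trunc_tau = 8) {
  stopifnot(tau0 > 0, dt > 0, h >= 0)
  nd <- round(h / dt)
  a <- exp(-dt / tau0)
  ntail <- ceiling(trunc_tau * tau0 / dt)
  kern <- c(rep(0, nd), theta_i * (1 - a) * a^(0:(ntail - 1)))
  list(kernel = kern, n_delay = nd, dt = dt,
       fresp = function(omega) vapply(omega, function(w)
         sum(kern * exp(-1i * w * dt * seq_along(kern))), complex(1)))
}
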