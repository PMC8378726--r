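#' Closed-loop system matrix of one region
#'
#' Assembles the parameter-dependent closed-loop matrix of the delay-free
#' switched loop,
#' \deqn{A_i(\theta) = \begin{bmatrix}
#'   A(\theta) + B_2(\theta) D_{C} C_2(\theta) & B_2(\theta) C_{C} \\
#'   B_{C} C_2(\theta) & A_{C} \end{bmatrix},}
#' for plant `(A, B2, C2)` and controller `(A_C, B_C, C_C, D_C)` in the
#' positive-feedback convention (`u = C y`).  A controller designed on the
#' tracking error (`u = K (r - y)`) enters with its input negated; use
#' `negate_input()` for that.
#'
#' @param theta frozen sensitivity value.
#' @param controller an [ss_model()] in the `u = C y` convention.
#' @param tau0 plant lag \[s\].
#' @return square matrix of dimension `1 + controller$n`.
#' @export
closed_loop_matrix <- function(theta, controller, tau0 = 35) {
  A <- -1 / tau0; B2 <- theta / tau0; C2 <- 1
  nk <- controller$n
  M <- matrix(0, 1 + nk, 1 + nk)
  M[1, 1] <- A + B2 * controller$D[1, 1] * C2
  if (nk > 0) {
    M[1, 2:(1 + nk)] <- B2 * controller$C
    M[2:(1 + nk), 1] <- controller$B * C2
    M[2:(1 + nk), 2:(1 + nk)] <- controller$A
  }
  M
}

#' @rdname closed_loop_matrix
#' @export
negate_input <- function(controller)
  ss_model(controller$A, -controller$B, controller$C, -controller$D)

#' Shifted Lyapunov equation
#'
#' Solves `A' Q + Q A = -2 lambda Q - I`, i.e. the standard Lyapunov equation
#' for the shifted matrix `A + lambda I`, and checks the substitution
#' residual.  Requires all eigenvalues of `A` strictly left of `-lambda`.
#'
#' @param A square Hurwitz matrix.
#' @param lambda nonnegative shift \[1/s\].
#' @return symmetric positive-definite `Q` with attribute `"residual"`.
#' @examples
#' solve_scaled_lyapunov(matrix(-1), 0.25)   # scalar: 1/(2 (1 - 0.25))
#' @export
solve_scaled_lyapunov <- function(A, lambda) {
  stopifnot(lambda >= 0)
  As <- A + lambda * diag(nrow(A))
  if (max(Re(eigen(As, only.values = TRUE)$values)) >= 0)
    stop("assumption violation: A + lambda I is not Hurwitz", call. = FALSE)
  Q <- lyap_solve(As, diag(nrow(A)))
  attr(Q, "residual") <- max(abs(t(As) %*% Q + Q %*% As + diag(nrow(A))))
  Q
}

# preconditioned certificate pass over a theta grid in coordinates xi = T z
cert_pass <- function(Acl, thetas, lambda, Tm) {
  Ti <- solve(Tm)
  Qs <- lapply(thetas, function(th) solve_scaled_lyapunov(Ti %*% Acl(th) %*% Tm, lambda))
  ev <- vapply(Qs, function(Q)
    range(eigen(Q, symmetric = TRUE, only.values = TRUE)$values), numeric(2))
  dth <- thetas[2] - thetas[1]
  dQ <- vapply(2:(length(thetas) - 1), function(j)
    norm((Qs[[j + 1]] - Qs[[j - 1]]) / (2 * dth), "2"), numeric(1))
  list(mu = min(ev[1, ]), M = max(ev[2, ]), L_Q = max(dQ),
       j_worst = which.max(dQ) + 1L, Qs = Qs,
       residual = max(vapply(Qs, attr, numeric(1), "residual")))
}

#' Lyapunov certificate of one region
#'
#' Grid-based estimation of the dwell-time constants of one closed-loop
#' region: decay margin `lambda_i`, norm bounds `L_Ai` and `L_Di`, the
#' eigenvalue sandwich `mu_i <= eig(Q_i(theta)) <= M_i` of the shifted
#' Lyapunov solutions, the parameter sensitivity `L_Qi = sup ||dQ/dtheta||`
#' (central differences; `||dQ/dt|| <= L_Qi |theta'|` by the chain rule), and
#' the per-region rate bound `beta_i = (1 + 2 lambda_i mu_i)/L_Qi`.
#'
#' For a scalar theta the dense grid (default 201 points) is exhaustive to
#' the stated tolerances.  The constants are realization-dependent: the grid
#' is evaluated in preconditioned coordinates `xi = T z` with
#' `T = Q(theta*)^{-1/2}` anchored where `||dQ/dtheta||` peaks (anchor chosen
#' over a coarse grid), which tightens `M/mu` by one to two orders of
#' magnitude versus raw coordinates; the certificate is valid in any fixed
#' coordinates, so the best-conditioned frame is reported.
#'
#' @param region an [operating_region()].
#' @param controller [ss_model()] on the tracking error (`u = K(r - y)`), as
#'   returned by [design_controller()].
#' @param tau0 plant lag \[s\].
#' @param grid_size points on the theta grid.
#' @param lambda_margin fraction in (0, 1) of the maximum admissible shift
#'   `lambda_max = d_min/2` (where `d_min` is the slowest grid decay, so the
#'   `-2 lambda` eigenvalue condition holds with margin).  The default 0.9
#'   equals `lambda = 0.45 d_min`, a 10% eigenvalue margin; `"auto"` picks
#'   the beta-maximizing fraction from `c(0.9, 0.4, 0.2, 0.1, 0.04, 0.02)`
#'   (smaller shifts give smaller, flatter `Q` families and usually a larger
#'   admissible rate).
#' @param extend widen the certified interval by this much on interior
#'   boundaries (the hysteresis keeps a controller active up to half a band
#'   beyond its region); pass 0 to certify the bare region.
#' @param n_anchor coarse anchor-search points for the preconditioner.
#' @return A `"lyapunov_certificate"` list with the constants
#'   `lambda`, `L_A`, `L_D`, `mu`, `M`, `L_Q`, `beta`, the grid, the
#'   residual maximum, and the preconditioner.
#' @export
certify_region <- function(region, controller, tau0 = 35, grid_size = 201,
                           lambda_margin = 0.9, extend = c(0, 0),
                           n_anchor = 9) {
  stopifnot(inherits(region, "operating_region"), grid_size >= 5)
  lo <- region$lo - extend[1]; hi <- region$hi + extend[2]
  Kn <- negate_input(controller)
  Acl <- function(th) closed_loop_matrix(th, Kn, tau0)
  thetas <- seq(lo, hi, length.out = grid_size)
  n <- 1 + controller$n
  eigs <- lapply(thetas, function(th) eigen(Acl(th), only.values = TRUE)$values)
  maxre <- vapply(eigs, function(e) max(Re(e)), numeric(1))
  if (any(maxre >= 0)) {
    bad <- thetas[which(maxre >= 0)[1]]
    stop(sprintf("certification failure: A(theta) not Hurwitz at theta = %.4g", bad),
         call. = FALSE)
  }
  d_min <- min(-maxre)
  lambda_max <- d_min / 2          # eigenvalue condition: Re <= -2 lambda
  fracs <- if (identical(lambda_margin, "auto"))
    c(0.9, 0.4, 0.2, 0.1, 0.04, 0.02) else lambda_margin
  stopifnot(all(fracs > 0 & fracs < 1))
  # norm bounds (coordinate-free quantities evaluated in the raw frame are
  # recomputed in the certified frame below)
  dth <- thetas[2] - thetas[1]
  best <- NULL
  for (fr in fracs) {
    lambda <- fr * lambda_max
    p0 <- cert_pass(Acl, thetas, lambda, diag(n))
    anchors <- thetas[unique(round(seq(1, grid_size, length.out = n_anchor)))]
    anchors <- unique(c(thetas[p0$j_worst], anchors))
    cand <- c(p0, list(Tm = diag(n)))
    for (a in anchors) {
      Qa <- solve_scaled_lyapunov(Acl(a), lambda)
      e <- eigen(Qa, symmetric = TRUE)
      Tm <- e$vectors %*% diag(1 / sqrt(e$values), length(e$values)) %*% t(e$vectors)
      pa <- cert_pass(Acl, thetas, lambda, Tm)
      beta_a <- (1 + 2 * lambda * pa$mu) / pa$L_Q
      if (beta_a > (1 + 2 * lambda * cand$mu) / cand$L_Q)
        cand <- c(pa, list(Tm = Tm))
    }
    cand$lambda <- lambda
    cand$beta <- (1 + 2 * lambda * cand$mu) / cand$L_Q
    if (is.null(best) || cand$beta > best$beta) best <- cand
  }
  Ti <- solve(best$Tm)
  Aframe <- function(th) Ti %*% Acl(th) %*% best$Tm
  L_A <- max(vapply(thetas, function(th) norm(Aframe(th), "2"), numeric(1)))
  L_D <- max(vapply(2:(grid_size - 1), function(j)
    norm((Aframe(thetas[j + 1]) - Aframe(thetas[j - 1])) / (2 * dth), "2"),
    numeric(1)))
  structure(list(
    region = region, interval = c(lo, hi), thetas = thetas,
    lambda = best$lambda, lambda_max = lambda_max,
    mu = best$mu, M = best$M, L_Q = best$L_Q, beta = best$beta,
    L_A = L_A, L_D = L_D, residual = best$residual,
    preconditioner = best$Tm, worst_decay = d_min,
    grid_size = grid_size), class = "lyapunov_certificate")
}

#' @export
print.lyapunov_certificate <- function(x, ...) {
  cat(sprintf(
    "<lyapunov_certificate> theta in [%.3g, %.3g]\n  lambda = %.3g, mu = %.3g, M = %.3g, L_Q = %.3g, beta_i = %.4g\n",
    x$interval[1], x$interval[2], x$lambda, x$mu, x$M, x$L_Q, x$beta))
  invisible(x)
}

#' Dwell time and admissible parameter rate
#'
#' Combines per-region certificates into the switched-system bounds:
#' `beta_max = min_i beta_i`, the dwell time
#' \deqn{h_D = \max_i \frac{2 M_i \ln(M_i/\mu_i)}{1 + 2\lambda_i \mu_i - L_{Qi} \beta}}
#' with `beta = beta_fraction * beta_max`, and the admissible rate
#' `min{ min_i { |d_i|/h_D, beta_i }, beta_max }` where `|d_i|` are the
#' hysteresis overlap widths.  Regions with `L_Q = 0` (theta-independent
#' loops) contribute an unbounded `beta_i` and drop out of the minimum.
#'
#' @param certs list of [certify_region()] outputs.
#' @param hysteresis_widths numeric vector of overlap widths `|d_{i,i+1}|`
#'   (recycled; default 0.4, twice the 0.2 hysteresis half-width).
#' @param beta_fraction `beta` in (0, 1) units of `beta_max`.
#' @return A `"dwell_certificate"` list: `beta_i`, `beta_max`, `beta`, `h_D`,
#'   `rate_beta_max` (the bound actually compared by the supervisor design,
#'   as in the source analysis) and `rate_full` (including the `|d|/h_D`
#'   term; see the vignette for why both are reported).
#' @export
dwell_and_rate <- function(certs, hysteresis_widths = 0.4, beta_fraction = 0.5) {
  stopifnot(beta_fraction > 0, beta_fraction < 1)
  beta_i <- vapply(certs, function(ce)
    if (ce$L_Q <= 0) Inf else ce$beta, numeric(1))
  beta_max <- min(beta_i)
  beta <- if (is.finite(beta_max)) beta_fraction * beta_max else 0
  denom <- vapply(certs, function(ce)
    1 + 2 * ce$lambda * ce$mu - if (ce$L_Q > 0) ce$L_Q * beta else 0,
    numeric(1))
  if (any(denom <= 0))
    stop("invalid beta_fraction: nonpositive dwell-time denominator", call. = FALSE)
  hD <- max(vapply(seq_along(certs), function(i) {
    ce <- certs[[i]]
    2 * ce$M * log(ce$M / ce$mu) / denom[i]
  }, numeric(1)))
  d <- rep_len(hysteresis_widths, max(1L, length(certs) - 1L))
  rate_full <- min(min(c(d / hD, beta_i)), beta_max)
  structure(list(beta_i = beta_i, beta_max = beta_max, beta = beta,
                 h_D = hD, hysteresis_widths = d,
                 rate_beta_max = beta_max, rate_full = rate_full),
            class = "dwell_certificate")
}

#' @export
print.dwell_certificate <- function(x, ...) {
  cat(sprintf(
    "<dwell_certificate> beta_max = %.4g, h_D = %.4g s\n  admissible rate: %.4g (beta_max bound), %.4g (full bound incl. |d|/h_D)\n",
    x$beta_max, x$h_D, x$rate_beta_max, x$rate_full))
  invisible(x)
}

#' Check a trajectory against a dwell certificate
#'
#' Passes iff the exact supremum rate of the piecewise-linear trajectory is
#' strictly below the certificate bound.  Both the `beta_max`-only bound and
#' the full bound (with the `|d|/h_D` term) are evaluated.
#'
#' @param traj a [make_trajectory()] trajectory.
#' @param cert a [dwell_and_rate()] certificate.
#' @param bound which bound to gate `pass` on.
#' @return list: `pass`, `sup_rate`, `bound_beta_max`, `bound_full`,
#'   `pass_full`.
#' @export
verify_trajectory <- function(traj, cert, bound = c("beta_max", "full")) {
  bound <- match.arg(bound)
  sr <- trajectory_sup_rate(traj)
  thr <- if (bound == "beta_max") cert$rate_beta_max else cert$rate_full
  list(pass = sr < thr, sup_rate = sr,
       bound_beta_max = cert$rate_beta_max, bound_full = cert$rate_full,
       pass_full = sr < cert$rate_full)
}
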