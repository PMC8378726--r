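test_that("closed-loop matrix assembles the block structure", {
  # zero controller: top-left is the plant A, couplings vanish
  K0 <- ss_model(matrix(0, 2, 2), matrix(0, 2, 1), matrix(0, 1, 2), 0)
  M <- closed_loop_matrix(-3, K0, tau0 = 35)
  expect_equal(M[1, 1], -1 / 35)
  expect_equal(M[1, 2:3], c(0, 0)); expect_equal(M[2:3, 1], c(0, 0))
  # scalar controller, hand-assembled 2x2
  K <- ss_model(-2, 0.5, 3, 0.25)
  th <- -4; tau0 <- 10
  Mh <- closed_loop_matrix(th, K, tau0)
  expect_equal(Mh, rbind(c(-1 / tau0 + (th / tau0) * 0.25, (th / tau0) * 3),
                         c(0.5, -2)))
  # designed controller at its nominal point: Hurwitz
  des <- get_design1()
  A1 <- closed_loop_matrix(-7.65, negate_input(des$controller))
  expect_lt(max(Re(eigen(A1, only.values = TRUE)$values)), 0)
})

test_that("shifted Lyapunov equation: closed forms and residuals", {
  # scalar A = -1, lambda = 0.25: Q = 1/(2 (1 - 0.25)) = 2/3
  Q <- solve_scaled_lyapunov(matrix(-1), 0.25)
  expect_equal(Q[1, 1], 2 / 3, tolerance = 1e-14)
  # lambda = 0 reduces to the standard equation A'Q + QA = -I
  A <- random_stable_siso(4, 61)$A
  Q0 <- solve_scaled_lyapunov(A, 0)
  expect_lt(max(abs(t(A) %*% Q0 + Q0 %*% A + diag(4))), 1e-10)
  # random stable 4x4 with a proportional shift: residual < 1e-10, Q > 0
  lam <- 0.1 * abs(max(Re(eigen(A, only.values = TRUE)$values)))
  Q1 <- solve_scaled_lyapunov(A, lam)
  expect_lt(attr(Q1, "residual"), 1e-10)
  expect_gt(min(eigen(Q1, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_error(solve_scaled_lyapunov(matrix(-1), 2), "Hurwitz")
})

test_that("scalar certification matches the closed-form Lyapunov family", {
  # closed loop A(theta) = -1/tau0 + theta/tau0 with tau0 = 1 and a static
  # unit controller gives the scalar family A = theta - 1 on [-1, -0.01];
  # Q(theta) = 1/(2(|A| - lambda)) with all quantities scalar
  # (error-convention controller u = K(r - y): D = -1 closes as +1 gain)
  Kstatic <- ss_model(matrix(0, 0, 0), matrix(0, 0, 1), matrix(0, 1, 0), -1)
  reg <- operating_region(-1, -0.01)
  d_min <- 1.01   # slowest decay at theta = -0.01
  lambda <- 0.45  # spec'd example shift
  ce <- certify_region(reg, Kstatic, tau0 = 1, grid_size = 101,
                       lambda_margin = lambda / (d_min / 2))
  qfun <- function(theta) 1 / (2 * (1 - theta - lambda))
  expect_equal(ce$lambda, lambda, tolerance = 1e-12)
  expect_equal(ce$mu, qfun(-1), tolerance = 1e-8)
  expect_equal(ce$M, qfun(-0.01), tolerance = 1e-8)
  # dQ/dtheta = 1/(2 (1 - theta - lambda)^2), maximal toward theta = -0.01;
  # the certificate reports the grid central-difference supremum of the same
  # closed-form family
  ths <- ce$thetas; dth <- ths[2] - ths[1]
  lq_exact <- max(vapply(2:(length(ths) - 1), function(j)
    abs(qfun(ths[j + 1]) - qfun(ths[j - 1])) / (2 * dth), numeric(1)))
  expect_equal(ce$L_Q, lq_exact, tolerance = 1e-8)
  expect_equal(ce$beta, (1 + 2 * lambda * ce$mu) / ce$L_Q, tolerance = 1e-12)
  expect_lt(ce$residual, 1e-10)
})

test_that("theta-independent loops certify with unbounded rate", {
  # zero-gain controller: closed loop is the plant pole alone, constant in theta
  K0 <- ss_model(matrix(0, 0, 0), matrix(0, 0, 1), matrix(0, 1, 0), 0)
  ce <- certify_region(operating_region(-5, -1), K0, tau0 = 35,
                       grid_size = 21, lambda_margin = 0.5)
  expect_equal(ce$L_Q, 0, tolerance = 1e-12)
  dw <- dwell_and_rate(list(ce), beta_fraction = 0.5)
  expect_identical(dw$beta_i, Inf)
})

test_that("certification fails loudly when the loop is not Hurwitz", {
  # a static gain of the wrong sign destabilizes the lag for theta < -1
  Kpos <- ss_model(matrix(0, 0, 0), matrix(0, 0, 1), matrix(0, 1, 0), 1)
  expect_error(certify_region(operating_region(-5, -2), Kpos, tau0 = 35,
                              grid_size = 11, lambda_margin = 0.5),
               "Hurwitz")
})

test_that("eigenvalue sandwich and residuals hold on a certified MAP region", {
  des <- get_design1()
  ce <- certify_region(des$region, des$controller, grid_size = 51,
                       lambda_margin = 0.2, n_anchor = 3)
  expect_lt(ce$residual, 1e-10)
  # mu I <= Q(theta) <= M I on the grid, in the certified frame
  Ti <- solve(ce$preconditioner)
  Kn <- negate_input(des$controller)
  for (th in ce$thetas[c(1, 13, 26, 39, 51)]) {
    Af <- Ti %*% closed_loop_matrix(th, Kn) %*% ce$preconditioner
    Q <- solve_scaled_lyapunov(Af, ce$lambda)
    ev <- eigen(Q, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), ce$mu - 1e-9)
    expect_lte(max(ev), ce$M + 1e-9)
  }
})

test_that("grid refinement leaves the certificate constants stable", {
  des <- get_design1()
  a <- certify_region(des$region, des$controller, grid_size = 101,
                      lambda_margin = 0.2, n_anchor = 3)
  b <- certify_region(des$region, des$controller, grid_size = 201,
                      lambda_margin = 0.2, n_anchor = 3)
  expect_equal(a$mu, b$mu, tolerance = 0.01)
  expect_equal(a$M, b$M, tolerance = 0.01)
  expect_equal(a$L_Q, b$L_Q, tolerance = 0.01)
})

test_that("Lyapunov solutions grow outward and the dwell formula is monotone", {
  des <- get_design1()
  Kn <- negate_input(des$controller)
  lam <- 0.001
  qs <- function(lo, hi) {
    ths <- seq(lo, hi, length.out = 41)
    ev <- vapply(ths, function(th) {
      Q <- solve_scaled_lyapunov(closed_loop_matrix(th, Kn), lam)
      range(eigen(Q, symmetric = TRUE, only.values = TRUE)$values)
    }, numeric(2))
    c(mu = min(ev[1, ]), M = max(ev[2, ]))
  }
  inner <- qs(-9.5, -5.8); outer <- qs(-9.7, -5.6)
  expect_lte(outer["mu"], inner["mu"] + 1e-12)   # enlarging cannot raise mu
  expect_gte(outer["M"], inner["M"] - 1e-12)     # nor lower M
  hD <- function(M, mu, lam, LQ, beta) 2 * M * log(M / mu) / (1 + 2 * lam * mu - LQ * beta)
  expect_gt(hD(30, 2, 0.01, 1, 0.1), hD(20, 2, 0.01, 1, 0.1))
  expect_lt(hD(30, 3, 0.01, 1, 0.1), hD(30, 2, 0.01, 1, 0.1))
})

test_that("dwell-time combination follows the closed-form bound", {
  fake <- function(mu, M, lam, LQ) structure(
    list(mu = mu, M = M, lambda = lam, L_Q = LQ,
         beta = (1 + 2 * lam * mu) / LQ), class = "lyapunov_certificate")
  # M = mu: log term vanishes, that region contributes dwell 0
  dw0 <- dwell_and_rate(list(fake(2, 2, 0.1, 1)), beta_fraction = 0.5)
  expect_equal(dw0$h_D, 0)
  # hand-evaluated case: M = 2, mu = 1, lambda = 0.5, L_Q = 1, beta = 1
  # beta_i = 2, dwell = 4 ln 2 / (1 + 1 - 1) = 2.7726
  dw <- dwell_and_rate(list(fake(1, 2, 0.5, 1)), beta_fraction = 0.5)
  expect_equal(dw$beta, 1)
  expect_equal(dw$h_D, 4 * log(2), tolerance = 1e-12)
  # the |d|/h_D term enters the full admissible rate
  expect_equal(dw$rate_full, min(0.4 / dw$h_D, dw$beta_max), tolerance = 1e-12)
  # a dwell time of 472.71 with |d| = 0.4 admits only 8.46e-4 through that term
  expect_equal(0.4 / 472.71, 8.46e-4, tolerance = 1e-3)
  expect_error(dwell_and_rate(list(fake(1, 2, 0.5, 1)), beta_fraction = 1.5),
               "beta_fraction")
})

test_that("trajectory verification gates on the strict rate inequality", {
  fake <- structure(list(mu = 1, M = 2, lambda = 0.5, L_Q = 1, beta = 3),
                    class = "lyapunov_certificate")
  dw <- dwell_and_rate(list(fake), beta_fraction = 0.5)
  const <- make_trajectory("constant", duration = 100)
  expect_true(verify_trajectory(const, dw)$pass)
  # ramp at exactly the bound fails the strict inequality
  atbound <- make_trajectory("ramp_hold", c(-9.5, -0.25),
                             rate = dw$rate_beta_max,
                             duration = 9.25 / dw$rate_beta_max + 10)
  expect_false(verify_trajectory(atbound, dw)$pass)
})
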