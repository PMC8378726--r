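om_grid <- 10^seq(-4, 1, length.out = 50)

test_that("uncertainty LFT closure recovers the LPV plant exactly", {
  r1 <- operating_region(-9.50, -5.80, 1)
  expect_equal(r1$center, -7.65)
  expect_equal(r1$half_width, 1.85)
  lft <- build_uncertainty_lft(r1, tau0 = 35, h = 40)
  expect_equal(lft$uncertainty$induced_norm_bound, 1)
  p <- lft$plant
  close_lft <- function(delta, omega) {
    g11 <- freqresp(p$G11, omega); g12 <- freqresp(p$G12, omega)
    g21 <- freqresp(p$G21, omega); g22 <- freqresp(p$G22, omega)
    # raw plant: delay on the 12 and 22 channels; upper closure w_r = delta z_r
    (g22 + g21 * delta * g12 / (1 - g11 * delta)) * exp(-1i * omega * 40)
  }
  for (theta in c(-7.65, -9.50, -5.80, -6.4)) {
    delta <- (theta - r1$center) / r1$half_width
    expect_lte(max(Mod(close_lft(delta, om_grid) -
                         theta / (35i * om_grid + 1) * exp(-40i * om_grid))),
               1e-10)
  }
  expect_error(build_uncertainty_lft(operating_region(-3, -3 + 1e-16)),
               "lo < hi|degenerate")
})

test_that("Smith predictor matches its defining frequency response", {
  G22 <- ss_model(-1 / 35, -7.65 / 35, 1, 0)
  Pi <- smith_predictor(G22, 40)
  expect_equal(Mod(Pi$fresp(0)), 0)                      # DC cancellation
  expect_equal(Mod(smith_predictor(G22, 0)$fresp(om_grid)),
               rep(0, length(om_grid)))
  # independent complex evaluation at omega = 0.05
  w <- 0.05
  direct <- (-7.65 / (35i * w + 1)) * (1 - exp(-1i * w * 40))
  expect_equal(Pi$fresp(w), direct, tolerance = 1e-12)
  unstable <- ss_model(0.1, 1, 1, 0)
  expect_error(smith_predictor(unstable, 40), "stable")
})

test_that("decomposition identity M = Fl(G_tilde, C) e^{-sh} + Pi1 holds for random stabilizing controllers", {
  r1 <- operating_region(-9.50, -5.80, 1)
  # generic plant with a nonzero G11 so the residual Pi1 is exercised too
  lft <- build_uncertainty_lft(r1, tau0 = 35, h = 40)
  plant <- lft$plant
  plant$G11 <- ss_model(-0.2, 0.1, 1, 0)
  decomp <- augment_and_decompose(plant)
  for (seed in 1:10) {
    # stabilizing by small gain: ||G22 C|| < 1 in the positive-feedback loop
    C <- random_stable_siso(3, 100 + seed,
                            norm_cap = 0.8 / hinf_norm(plant$G22)$norm)
    fr <- uncertainty_channel_fresp(decomp, C, om_grid)
    mismatch <- max(Mod(fr$direct - fr$decomposed)) /
      max(Mod(fr$direct), 1e-300)
    expect_lt(mismatch, 1e-8)
  }
})

test_that("decomposition degenerates correctly for h = 0 and C = 0", {
  r1 <- operating_region(-9.50, -5.80, 1)
  plant <- build_uncertainty_lft(r1, tau0 = 35, h = 0)$plant
  decomp <- augment_and_decompose(plant)
  expect_equal(Mod(decomp$Pi1_fresp(om_grid)), rep(0, length(om_grid)))
  # C = 0: M reduces to G11 e^{-sh} + Pi1 = G11 (here zero)
  plant40 <- build_uncertainty_lft(r1, tau0 = 35, h = 40)$plant
  plant40$G11 <- ss_model(-0.5, 1, 0.3, 0)
  d40 <- augment_and_decompose(plant40)
  C0 <- ss_model(matrix(0, 0, 0), matrix(0, 0, 1), matrix(0, 1, 0), 0)
  fr <- uncertainty_channel_fresp(d40, C0, om_grid)
  g11 <- freqresp(plant40$G11, om_grid)
  expect_equal(fr$decomposed, g11 * exp(-40i * om_grid) + d40$Pi1_fresp(om_grid),
               tolerance = 1e-12)
  expect_equal(fr$direct, fr$decomposed, tolerance = 1e-10)
})

test_that("classical Smith property: delayed loop = e^{-sh} times the delay-free loop", {
  # K = C (I - Pi C)^{-1}: reference-to-output of the delayed loop equals
  # the delay shift of the delay-free loop of C with G22
  g <- function(w) -7.65 / (35i * w + 1)
  h <- 40
  C <- random_stable_siso(3, 77, norm_cap = 0.5 / 7.65)
  for (w in c(0.001, 0.01, 0.03, 0.1, 1)) {
    cv <- ss_eval(C, 1i * w)[1, 1]
    piv <- g(w) * (1 - exp(-1i * w * h))
    kv <- cv / (1 - piv * cv)
    T_delayed <- g(w) * exp(-1i * w * h) * kv / (1 - g(w) * exp(-1i * w * h) * kv)
    T_free <- g(w) * cv / (1 - g(w) * cv)
    expect_equal(T_delayed, exp(-1i * w * h) * T_free, tolerance = 1e-9)
  }
})

test_that("additive uncertainty bound: analytic supremum and monotonicity", {
  r1 <- operating_region(-9.50, -5.80, 1)
  ab <- additive_bound(r1, dh = 20, dtau = 25, tau0 = 35)
  expect_equal(ab$S_analytic, 2 + 25 / 35, tolerance = 1e-12)   # 2.7143
  expect_lte(ab$S_analytic, 2.715)
  expect_equal(ab$S, ab$S_analytic, tolerance = 1e-4)           # sweep agrees
  expect_equal(additive_bound(r1, dh = 0, dtau = 0)$bound, r1$half_width)
  # monotone nondecreasing in dh, dtau, half-width and |theta_i|
  expect_lte(additive_bound(r1, dh = 10, dtau = 25)$bound, ab$bound)
  expect_lte(additive_bound(r1, dh = 20, dtau = 10)$bound, ab$bound)
  r_small <- operating_region(-8.5, -6.8)
  expect_lte(additive_bound(r_small, dh = 20, dtau = 25)$bound, ab$bound)
})

test_that("FIR realization tracks the delayed branch within 1% up to the loop bandwidth", {
  fir <- fir_delay_branch(-7.65, 35, 40, dt = 0.1)
  om <- 10^seq(-4, -1, length.out = 30)   # bandwidth 1/tau0 ~ 0.03 rad/s
  target <- -7.65 / (35i * om + 1) * exp(-40i * om)
  rel <- Mod(fir$fresp(om) - target) / Mod(target)
  expect_lt(max(rel), 0.01)
  expect_equal(fir$n_delay, 400)
})
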