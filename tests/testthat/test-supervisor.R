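test_that("hysteresis thresholds reproduce the switching table from the boundaries", {
  logic <- build_hysteresis(map_regions(), half_width = 0.2)
  expect_equal(logic$up, c(-5.60, -2.83, -1.22, -0.40))
  expect_equal(logic$down, c(-6.00, -3.23, -1.62, -0.80))
  expect_error(build_hysteresis(map_regions(), half_width = 0.35), "half_width")
  expect_warning(build_hysteresis(map_regions(), half_width = 0), "degenerate")
})

test_that("supervisor: monotone sweeps switch at the table values, oscillation never chatters", {
  logic <- build_hysteresis(map_regions(), half_width = 0.2)
  sweep <- function(thetas, start) {
    q <- start; events <- numeric(0); idx <- integer(0)
    for (th in thetas) {
      qn <- supervisor_step(th, q, logic)
      if (qn != q) { events <- c(events, th); idx <- c(idx, qn) }
      q <- qn
    }
    list(theta = events, index = idx)
  }
  up <- sweep(seq(-9.5, -0.25, by = 1e-3), 1)
  expect_equal(up$index, 2:5)
  expect_lt(max(abs(up$theta - c(-5.60, -2.83, -1.22, -0.40))), 2e-3)
  down <- sweep(seq(-0.25, -9.5, by = -1e-3), 5)
  expect_equal(down$index, 4:1)
  expect_lt(max(abs(down$theta - rev(c(-6.00, -3.23, -1.62, -0.80)))), 2e-3)
  # oscillation with amplitude below the half-width around a boundary
  osc <- -5.80 + 0.15 * sin(seq(0, 40, by = 0.05))
  q <- 1
  for (th in osc) q <- supervisor_step(th, q, logic)
  expect_equal(q, 1L)
  # at most one region step per call even for a huge jump
  expect_equal(supervisor_step(-0.3, 1, logic), 2L)
})

test_that("closed loop at equilibrium stays at equilibrium", {
  bank <- get_bank()$results
  logic <- build_hysteresis(get_bank()$regions, 0.2)
  patient <- list(tau_s = 35, h_s = 40, M0_mmHg = 100,
                  theta_fun = function(t) -7.65)
  tr <- simulate_closed_loop(patient, bank, logic, setpoint = 100,
                             x0 = 0, T_end = 300)
  expect_lt(max(abs(tr$map_mmHg - 100)), 1e-9)
  expect_lt(max(abs(tr$infusion_ml_hr)), 1e-9)
})

test_that("transport delay: no drug effect before h seconds", {
  bank <- get_bank()$results
  logic <- build_hysteresis(get_bank()$regions, 0.2)
  patient <- list(tau_s = 35, h_s = 40, M0_mmHg = 100,
                  theta_fun = function(t) -7.65)
  tr <- simulate_closed_loop(patient, bank, logic, T_end = 120, x0 = 50)
  early <- tr[tr$time_s <= 40 - 0.1, ]
  # pure open-loop decay of the initial deviation until the delay elapses
  expect_equal(early$map_mmHg, 100 + 50 * exp(-early$time_s / 35),
               tolerance = 1e-9)
  late <- tr[tr$time_s > 45, ]
  expect_gt(max(abs(late$map_mmHg - (100 + 50 * exp(-late$time_s / 35)))), 0.05)
})

test_that("integration step: halving dt changes the terminal pressure below 0.1 mmHg", {
  bank <- get_bank()$results
  logic <- build_hysteresis(get_bank()$regions, 0.2)
  patient <- list(tau_s = 35, h_s = 40, M0_mmHg = 100,
                  theta_fun = function(t) -7.65)
  t1 <- simulate_closed_loop(patient, bank, logic, dt = 0.1, T_end = 600)
  t2 <- simulate_closed_loop(patient, bank, logic, dt = 0.05, T_end = 600)
  expect_lt(abs(t1$map_mmHg[nrow(t1)] - t2$map_mmHg[nrow(t2)]), 0.1)
})

test_that("switching scenario: table-consistent switch locations and no chattering", {
  pipe <- get_pipeline()
  tr <- pipe$trace
  sw <- attr(tr, "switch_times")
  expect_length(sw, 4)
  fn <- trajectory_fun(pipe$trajectory)
  expect_equal(fn(sw), c(-5.60, -2.83, -1.22, -0.40), tolerance = 1e-2)
  # switch spacing bounded below by (2 half-width)/sup-rate
  rate <- trajectory_sup_rate(pipe$trajectory)
  expect_gte(min(diff(sw)), 2 * 0.2 / rate - 1)
})

test_that("performance metrics implement their definitions", {
  flat <- structure(
    tibble::tibble(time_s = seq(0, 1000, 0.5), theta = -7.65,
                   map_mmHg = 100, infusion_ml_hr = 5,
                   controller_index = 1L),
    dt = 0.5, setpoint = 100, M0 = 100,
    class = c("map_trace", "tbl_df", "tbl", "data.frame"))
  pm <- performance_metrics(flat)
  expect_equal(pm$value[pm$metric == "settling_time_min"], 0)
  expect_equal(pm$value[pm$metric == "undershoot_mmHg"], 0)
  expect_equal(pm$value[pm$metric == "steady_state_band_mmHg"], 0)
  expect_true(all(pm$pass))
  # dip to 88 mmHg against setpoint 100: undershoot 12, spec fails
  tt <- seq(0, 1000, 0.5)
  dip <- 100 + 50 * exp(-tt / 30) - 12 * exp(-((tt - 400) / 50)^2)
  dtr <- structure(
    tibble::tibble(time_s = tt, theta = -7.65, map_mmHg = dip,
                   infusion_ml_hr = 5, controller_index = 1L),
    dt = 0.5, setpoint = 100, M0 = 100,
    class = c("map_trace", "tbl_df", "tbl", "data.frame"))
  pmd <- performance_metrics(dtr)
  expect_equal(pmd$value[pmd$metric == "undershoot_mmHg"], 12, tolerance = 0.05)
  expect_false(pmd$pass[pmd$metric == "undershoot_mmHg"])
})

test_that("a single mid-range controller fails the full-range scenario that the bank passes", {
  pipe <- get_pipeline()
  expect_true(all(pipe$performance$pass))
  bank <- pipe$bank
  logic <- pipe$logic
  patient <- list(tau_s = 35, h_s = 40, M0_mmHg = 100,
                  trajectory = pipe$trajectory)
  single <- simulate_closed_loop(patient, bank, logic, single = 3,
                                 T_end = 2000)
  pm <- performance_metrics(single)
  expect_true(any(!pm$pass))
})

test_that("bumpless transfer keeps the command continuous across switches", {
  pipe <- get_pipeline()
  tr <- pipe$trace
  sw <- attr(tr, "switch_times")
  dt <- attr(tr, "dt")
  for (s in sw) {
    j <- which.min(abs(tr$time_s - s))
    jump <- abs(tr$infusion_ml_hr[j + 1] - tr$infusion_ml_hr[j])
    expect_lt(jump, 0.05)   # ml/hr across one step at a switch
  }
})

test_that("trace CSV round-trips", {
  pipe <- get_pipeline()
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(pipe$trace, path)
  back <- read_trace_csv(path)
  expect_equal(back$map_mmHg, pipe$trace$map_mmHg, tolerance = 1e-12)
  expect_equal(back$controller_index, pipe$trace$controller_index)
})
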