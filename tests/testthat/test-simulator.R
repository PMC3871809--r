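test_that("rk4 is exact on polynomial fields and fifth-order locally", {
  # constant derivative: exact
  y1 <- rk4_step(function(t, y) 3.5, 2, 0, 0.7)
  expect_identical(y1, 2 + 3.5 * 0.7)
  # zero field: identity
  expect_identical(rk4_step(function(t, y) 0 * y, c(1, 2), 5, 0.3), c(1, 2))
  # cubic-in-t field integrates exactly
  y <- rk4_step(function(t, y) t^3, 0, 0, 1)
  expect_equal(y, 0.25, tolerance = 1e-14)
  # exponential decay: local error O(dt^5), so halving shrinks it ~32x
  k <- 1.3
  err <- function(dt) abs(rk4_step(function(t, y) -k * y, 1, 0, dt) -
                            exp(-k * dt))
  ratio <- err(0.1) / err(0.05)
  expect_gt(ratio, 25); expect_lt(ratio, 40)
})

test_that("rk4 agrees with deSolve's classical fixed-step method", {
  library(deSolve)
  f <- function(t, y) c(y[2], -sin(y[1]) - 0.1 * y[2])   # damped pendulum
  fd <- function(t, y, parms) list(f(t, y))
  times <- seq(0, 10, by = 0.05)
  ref <- deSolve::ode(c(1, 0), times, fd, NULL, method = "rk4")
  y <- c(1, 0)
  for (i in seq_len(length(times) - 1)) {
    y <- rk4_step(f, y, times[i], diff(times)[1])
  }
  expect_equal(y, unname(ref[nrow(ref), 2:3]), tolerance = 1e-10)
})

test_that("trajectory book-keeping closes the water and dry-matter budgets", {
  ts <- toy_season()
  traj <- simulate_fruit(ts$params, ts$env, ts$config, quiet = TRUE)
  expect_true(all(diff(traj$t) > 0))
  n <- nrow(traj)
  dw <- traj$w[n] - traj$w[1]
  ds <- traj$s[n] - traj$s[1]
  expect_lt(abs(dw - (traj$cum_in_w[n] - traj$cum_out_w[n])) / abs(dw),
            1e-9)
  expect_lt(abs(ds - (traj$cum_in_s[n] - traj$cum_out_s[n])) / abs(ds),
            1e-9)
  expect_lte(attr(traj, "max_residual_mass"), 1e-9)
  expect_lte(attr(traj, "max_residual_sugar"), 1e-9)
  # output cadence equals the configured half-hour step here
  expect_equal(diff(traj$t)[1], 0.5 / 24, tolerance = 1e-12)
})

test_that("an isolated fruit keeps water and dry matter while starch turns over", {
  pz <- load_parameters(list(L_x = 0, L_p = 0, L1x = 0, L2x = 0,
                             Lp_inf = 0, q_m = 0))
  envf <- constant_test_environment(T = 20, H_a = pz$H_f)
  cfg <- simulation_config(t_start = 50, t_end = 55, cadence = 1,
                           initial = list(w = 30, s = 4, u = 1.5, P_f = 1))
  traj <- simulate_fruit(pz, envf, cfg, quiet = TRUE)
  n <- nrow(traj)
  expect_equal(traj$w[n], 30, tolerance = 1e-10)
  expect_equal(traj$s[n], 4, tolerance = 1e-10)
  expect_equal(traj$P_f[n], 1, tolerance = 1e-10)

  # starch follows its autonomous ODE; cross-check with an independent
  # stiff solver at tight tolerance
  library(deSolve)
  rate <- function(t, y, parms) {
    o <- other_dry_matter(4, 30, y, pz)
    s_s <- max(4 - o - y, 0)
    list(starch_synthesis_rate(t, pz) * s_s - pz$k_u * y)
  }
  ref <- deSolve::ode(1.5, c(50, 55), rate, NULL, rtol = 1e-10,
                      atol = 1e-12)
  expect_equal(traj$u[n], as.numeric(ref[2, 2]), tolerance = 1e-7)
})

test_that("identical configurations give identical trajectories", {
  ts <- toy_season(t_end = 52)
  a <- simulate_fruit(ts$params, ts$env, ts$config, quiet = TRUE)
  b <- simulate_fruit(ts$params, ts$env, ts$config, quiet = TRUE)
  expect_identical(as.matrix(a), as.matrix(b))

  runs <- run_scenarios(ts$params, ts$env, ts$config,
                        scenarios = list("low", 0, "high"))
  expect_identical(as.matrix(runs$low), as.matrix(runs[["0"]]))
  expect_false(isTRUE(all.equal(runs$low$FW, runs$high$FW)))
})

test_that("the stability guard keeps the stiff early season smooth", {
  cfg <- simulation_config(t_end = 2, cadence = 0.5)
  traj <- simulate_fruit(config = cfg, quiet = TRUE)
  expect_true(all(is.finite(traj$P_f)))
  expect_lt(max(abs(traj$P_f)), 10)
  expect_gt(max(traj$n_sub), 1)   # guard active where epsilon*phi is large
  # plain half-hour stepping stays bounded (the plastic-flow clipping
  # saturates the instability) but oscillates
  cfg2 <- simulation_config(t_end = 2, cadence = 0.5,
                            stability_guard = FALSE)
  traj2 <- simulate_fruit(config = cfg2, quiet = TRUE)
  expect_true(all(is.finite(traj2$P_f)))
  expect_gt(stats::sd(diff(traj2$P_f)), stats::sd(diff(traj$P_f)))
})

test_that("misconfigured simulations are rejected", {
  expect_error(simulation_config(step = 0), "step")
  expect_error(simulation_config(t_start = 10, t_end = 5), "t_start")
  expect_error(simulation_config(step = 0.5, cadence = 0.75), "multiple")
  ts <- toy_season()
  expect_error(simulate_fruit(ts$params, ts$env,
                              simulation_config(scenario = "drought",
                                                t_start = 50, t_end = 51,
                                                initial = ts$config$initial)),
               "unknown scenario")
})
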