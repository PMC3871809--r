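p <- default_parameters()

test_that("osmotic pressure is van 't Hoff plus a non-sugar baseline", {
  expect_identical(osmotic_pressure(0, 6.5, 20, p), 6.5)
  expect_equal(osmotic_pressure(0.1, 6.5, 20, p), 13.626459356725146,
               tolerance = 1e-12)
  # linear in concentration at fixed temperature
  d1 <- osmotic_pressure(0.05, 6.5, 20, p) - 6.5
  d2 <- osmotic_pressure(0.10, 6.5, 20, p) - 6.5
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
})

test_that("transpiration needs a vapour gradient and is linear in it", {
  expect_identical(transpiration_flux(100, 100, 20, 0.996, p), 0)
  expect_identical(transpiration_flux(100, 100, 20, 1, p), 0)  # clipped
  expect_equal(transpiration_flux(100, 100, 20, 0.6, p),
               0.06835636729328876, tolerance = 1e-10)
  t1 <- transpiration_flux(50, 200, 25, 0.796, p)
  t2 <- transpiration_flux(50, 200, 25, 0.596, p)
  expect_equal(t2 / t1, 2, tolerance = 1e-12)
  # Buck saturation pressure in bar at 20 C
  expect_equal(saturation_vapour_pressure(20), 0.02337282472851255,
               tolerance = 1e-12)
})

test_that("membrane water fluxes are linear in their driving forces", {
  expect_identical(xylem_uptake(-3, -3, 100, p), 0)
  expect_equal(xylem_uptake(-2, -3, 100, p), 0.04752, tolerance = 1e-12)
  expect_equal(xylem_uptake(-2, -3, 200, p), 2 * 0.04752, tolerance = 1e-12)

  # sigma = 1 reduces the driving force to the water-potential difference
  p1 <- load_parameters(list(sigma_p = 1))
  expect_equal(phloem_water_uptake(8, 20, 4, 12, 100, p1),
               p1$a_p * 100 * p1$L_p * ((8 - 20) - (4 - 12)),
               tolerance = 1e-12)
  # balanced pressure and osmotic terms give zero flow
  expect_equal(phloem_water_uptake(4 + 0.9 * 8, 20, 4, 12, 100, p), 0,
               tolerance = 1e-12)
  expect_equal(phloem_water_uptake(8, 20, 4, 12, 100, p), -0.152064,
               tolerance = 1e-12)
})

test_that("sugar uptake combines carrier, advective and diffusive paths", {
  z <- sugar_uptake(0, 0, 0.5, 0.05, 100, p)
  expect_identical(unlist(z), c(U_a = 0, U_m = 0, U_d = 0))
  half <- sugar_uptake(p$K_m, 0, 0, 0.05, 100, p)
  expect_equal(half$U_a, 0.025, tolerance = 1e-12)
  ex <- sugar_uptake(0.15, 0.05, 0.1, 0.05, 100, p)
  expect_equal(ex$U_a, 0.03260869565217391, tolerance = 1e-12)
  expect_equal(ex$U_m, 0.001, tolerance = 1e-12)
  expect_equal(ex$U_d, 0.00198, tolerance = 1e-12)
})

test_that("respiration has Q10 maintenance and implicit growth closure", {
  expect_identical(respiration_flux(0, 20, 0, p), 0)
  expect_equal(respiration_flux(10, 20, 0, p), 10 * p$q_m, tolerance = 1e-14)
  expect_equal(respiration_flux(5, 30, 0, p) / respiration_flux(5, 20, 0, p),
               p$Q10_r, tolerance = 1e-12)

  # implicit closure inside the derivative assembly: the reported R_f is
  # exactly maintenance + q_g * growth, and ds closes the budget
  st <- list(t = 80, w = 50, s = 8, u = 4, P_f = 4)
  env <- constant_test_environment()(80)
  d <- state_derivatives(st, env, 80, p)
  U <- d$U_a + d$U_m + d$U_d
  maint <- p$q_m * p$Q10_r^((env$T - 20) / 10) * st$s
  expect_equal(d$ds, U - d$R_f, tolerance = 1e-12)
  expect_equal(d$R_f, maint + p$q_g * max(d$ds, 0), tolerance = 1e-12)
})

test_that("derived quantities partition dry matter and size the fruit", {
  st <- fruit_state(3.2, 0.5, 0.01, 2, 0)
  d <- derive_quantities(st, p, 20)
  expect_equal(d$o, 0.27467528087793824, tolerance = 1e-12)
  expect_equal(d$s_s, 0.21532471912206175, tolerance = 1e-12)
  expect_equal(d$Z, 0.4306494382441235, tolerance = 1e-12)
  expect_equal(d$o + d$s_s + st$u, st$s, tolerance = 1e-9)
  expect_equal(d$C_f, d$s_s / (st$w + d$s_s), tolerance = 1e-14)
  expect_equal(d$V, 3.7, tolerance = 1e-12)
  expect_equal(d$A_f, 12.068419721327457, tolerance = 1e-10)
  expect_equal(d$psi_f, st$P_f - d$pi_f, tolerance = 1e-12)

  q <- quality_outputs(st, d)
  expect_identical(q$FW, 3.7)
  expect_equal(q$DM_pct, 13.513513513513512, tolerance = 1e-12)
  expect_equal(q$diameter_rel, 3.7^(1/3), tolerance = 1e-14)
  st0 <- fruit_state(3.2, 0.5, 0, 2, 0)
  expect_identical(quality_outputs(st0, derive_quantities(st0, p, 20))$ST_pct, 0)
  # cube law: doubled FW at same composition
  st2 <- fruit_state(6.4, 1.0, 0.02, 2, 0)
  q2 <- quality_outputs(st2, derive_quantities(st2, p, 20))
  expect_equal(q2$diameter_rel / q$diameter_rel, 2^(1/3), tolerance = 1e-12)
})

test_that("quality percentages stay in range over random valid states", {
  st <- random_fruit_states(1000, seed = 31)
  for (i in seq(1, 1000, by = 7)) {
    s1 <- fruit_state(st$w[i], st$s[i], st$u[i], st$P_f[i], st$t[i])
    d <- derive_quantities(s1, p, 17, warn = FALSE)
    q <- quality_outputs(s1, d)
    expect_gt(q$DM_pct, 0); expect_lt(q$DM_pct, 100)
    expect_gte(q$SS_pct, 0); expect_lte(q$SS_pct, 100)
    expect_lte(q$ST_pct, 100)
  }
})

test_that("isolated fruit has zero derivatives except starch turnover", {
  # no membrane or pedicel conductance, no maintenance respiration, no
  # vapour gradient, past the synthesis cutoff: pure starch breakdown
  pz <- load_parameters(list(L_x = 0, L_p = 0, L1x = 0, L2x = 0,
                             Lp_inf = 0, q_m = 0))
  st <- list(t = 166, w = 60, s = 12, u = 6, P_f = 1.5)   # below yield
  env <- constant_test_environment(H_a = pz$H_f)(166)
  d <- state_derivatives(st, env, 166, pz)
  expect_identical(d$dw, 0)
  expect_identical(d$ds, 0)
  expect_identical(d$dP, 0)
  expect_equal(d$du, -pz$k_u * st$u / 24, tolerance = 1e-12)
})

test_that("turgor law wiring matches the elastic Lockhart form", {
  st <- list(t = 90, w = 60, s = 10, u = 5, P_f = 5)
  env <- constant_test_environment()(90)
  d <- state_derivatives(st, env, 90, p)
  V <- (st$w + st$s) / p$rho_sol
  lhs <- d$dP / p$epsilon
  rhs <- (d$dw + d$ds) / p$rho_sol / V -
    wall_extensibility(90, p) * max(st$P_f - p$Y, 0)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})
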