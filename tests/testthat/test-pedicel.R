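p <- default_parameters()

test_that("pedicel flow primitives are linear and antisymmetric", {
  expect_identical(pedicel_phloem_flow(5, 5, 0.016), 0)
  expect_equal(pedicel_phloem_flow(7, 5, 0.016), 0.032, tolerance = 1e-12)
  expect_equal(pedicel_phloem_flow(5, 7, 0.016),
               -pedicel_phloem_flow(7, 5, 0.016), tolerance = 1e-14)
  expect_error(pedicel_phloem_flow(1, 0, -0.1), ">= 0")

  expect_identical(pedicel_xylem_flow(-2, -2, 0.09), 0)
  expect_equal(pedicel_xylem_flow(-2, -7, 0.09), 0.45, tolerance = 1e-12)
  expect_equal(pedicel_xylem_flow(-7, -2, 0.09), -0.45, tolerance = 1e-12)

  expect_identical(pedicel_sugar_flux(0, 0.12), 0)
  expect_identical(pedicel_sugar_flux(0.032, 0), 0)
  expect_equal(pedicel_sugar_flux(0.032, 0.12), 0.00384, tolerance = 1e-12)
})

test_that("accepted solutions satisfy both conservation laws to 1e-9", {
  st <- fruit_state(50, 8, 2, 4, 80)
  env <- list(t = 80, T = 20, H_a = 0.7, Tr = 0.001, psi_x = -2, C_p = 0.13)
  der <- derive_quantities(st, p, env$T)
  for (closure in c("pathway", "equilibrium")) {
    pc <- load_parameters(options = list(pedicel_closure = closure))
    ped <- solve_fruit_end(st, der, env, 80, pc)
    expect_lte(abs(ped$residual_mass), 1e-9)
    expect_lte(abs(ped$residual_sugar), 1e-9)
    expect_lt(ped$iterations, 200)
    # component identities
    expect_equal(ped$F_p,
                 pedicel_phloem_flow(stem_state(env, pc)$P_p,
                                     ped$P_p_fruit_end,
                                     pedicel_phloem_conductance(80, pc)),
                 tolerance = 1e-12)
    expect_equal(ped$F_x,
                 pedicel_xylem_flow(env$psi_x, ped$psi_fruit_end,
                                    pedicel_xylem_conductance(80, pc)),
                 tolerance = 1e-12)
  }
})

test_that("solver matches the brute-force grid oracle", {
  st <- random_fruit_states(30, seed = 77)
  cfg <- environment_config()
  for (closure in c("pathway", "equilibrium")) {
    pc <- load_parameters(options = list(pedicel_closure = closure))
    for (i in seq(1, 30, by = 3)) {
      s1 <- list(t = st$t[i], w = st$w[i], s = st$s[i], u = st$u[i],
                 P_f = st$P_f[i])
      env <- sample_environment(st$t[i], cfg)
      der <- derive_quantities(s1, pc, env$T, warn = FALSE)
      ped <- solve_fruit_end(s1, der, env, st$t[i], pc)
      ora <- pedicel_grid_oracle(s1, env, st$t[i], pc)
      expect_lt(abs(ped$C_p_fruit_end - ora$C_p_fruit_end), 1e-4)
      expect_lt(abs(ped$P_p_fruit_end - ora$P_p_fruit_end), 1e-3)
      expect_lt(abs(ped$psi_fruit_end - ora$psi_fruit_end), 1e-3)
    }
  }
})

test_that("solution responds continuously to small stem perturbations", {
  st <- random_fruit_states(20, seed = 5)
  cfg <- environment_config()
  for (i in seq(1, 20, by = 4)) {
    s1 <- list(t = st$t[i], w = st$w[i], s = st$s[i], u = st$u[i],
               P_f = st$P_f[i])
    env <- sample_environment(st$t[i], cfg)
    der <- derive_quantities(s1, p, env$T, warn = FALSE)
    a <- solve_fruit_end(s1, der, env, st$t[i], p)
    env2 <- env; env2$psi_x <- env$psi_x + 1e-6
    b <- solve_fruit_end(s1, der, env2, st$t[i], p)
    expect_lt(abs(b$psi_fruit_end - a$psi_fruit_end), 1e-4)
    expect_lt(abs(b$C_p_fruit_end - a$C_p_fruit_end), 1e-4)
  }
})

test_that("raising stem concentration does not decrease sucrose delivery", {
  st <- fruit_state(60, 10, 5, 5, 90)
  env <- list(t = 90, T = 18, H_a = 0.7, Tr = 0.001, psi_x = -2, C_p = 0.10)
  der <- derive_quantities(st, p, env$T)
  s0 <- solve_fruit_end(st, der, env, 90, p)$S_ped
  for (cp in c(0.12, 0.14, 0.16)) {
    env$C_p <- cp
    s1 <- solve_fruit_end(st, der, env, 90, p)$S_ped
    expect_gte(s1, s0 - 1e-12)
    s0 <- s1
  }
})

test_that("a fruit with no uptake surface exchanges nothing", {
  st <- fruit_state(50, 8, 2, 4, 80)
  env <- list(t = 80, T = 20, H_a = 0.7, Tr = 0.001, psi_x = -2, C_p = 0.13)
  der <- derive_quantities(st, p, env$T)
  der$A_f <- 0
  ped <- solve_fruit_end(st, der, env, 80, p)
  expect_identical(ped$F_p + ped$F_x + ped$U_x + ped$U_p + ped$U_a, 0)
  expect_identical(ped$C_p_fruit_end, env$C_p)
})

test_that("zero-resistance pedicel recovers the pedicel-free formulation", {
  st <- fruit_state(50, 8, 2, 4, 80)
  env <- list(t = 80, T = 20, H_a = 0.7, Tr = 0.001, psi_x = -2, C_p = 0.13)
  peq <- load_parameters(options = list(pedicel_closure = "equilibrium"))
  der <- derive_quantities(st, peq, env$T)
  ped <- solve_fruit_end(st, der, env, 80, peq, conductance_scale = 1e6)
  expect_lt(abs(ped$psi_fruit_end - env$psi_x), 1e-4)
  expect_lt(abs(ped$C_p_fruit_end - env$C_p), 1e-4)
  free <- pedicel_free_fluxes(st, der, env, 80, peq)
  for (fl in c("U_x", "U_p", "U_a", "U_m", "U_d")) {
    expect_lt(abs(ped[[fl]] - free[[fl]]) / max(abs(free[[fl]]), 1e-3), 1e-4)
  }
  # default (per-pathway) closure: the xylem side recovers exactly
  der2 <- derive_quantities(st, p, env$T)
  ped2 <- solve_fruit_end(st, der2, env, 80, p, conductance_scale = 1e6)
  expect_lt(abs(ped2$psi_fruit_end - env$psi_x), 1e-4)
  expect_lt(abs(ped2$U_x - free$U_x) / max(abs(free$U_x), 1e-3), 1e-4)
  expect_lt(abs(ped2$P_p_fruit_end - stem_state(env, p)$P_p), 1e-4)
})
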