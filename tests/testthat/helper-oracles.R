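# Shared test helpers: an infinitely-differentiable driving environment
# for integrator-order measurements, and a brute-force 2-D grid-refinement
# oracle for the fruit-end vasculature solve. The oracle re-derives every
# flux from the primitive formulas and minimizes the squared conservation
# residuals by nested grid search; it shares no code path with the
# package's closed-form + root-finding solver.

smooth_test_environment <- function() {
  function(t) {
    ph <- 2 * pi * t
    list(t = t, T = 15 + 5 * sin(ph), H_a = 0.75 - 0.15 * sin(ph),
         Tr = 0.001 * (1 + sin(ph)) / 2, psi_x = -2 + 1 * sin(ph),
         C_p = 0.13 + 0.04 * sin(ph))
  }
}

# constant environment (no diurnal variation); handy for fixed points
constant_test_environment <- function(T = 20, H_a = 0.996, psi_x = -2,
                                      C_p = 0.13) {
  function(t) list(t = t, T = T, H_a = H_a, Tr = 0, psi_x = psi_x,
                   C_p = C_p)
}

# brute-force 2-D minimizer of r1^2 + r2^2 over
# (x = pressure/potential, y = concentration): a coarse global grid
# search locates the basin, then derivative-free Nelder-Mead polishes
# the minimum to high precision. Entirely independent of the package
# solver's closed-form elimination and bracketed root-finding.
.grid_refine <- function(r1fun, r2fun, x_range, y_range, y_floor = 0,
                         n = 61L) {
  xs <- seq(x_range[1], x_range[2], length.out = n)
  ys <- seq(y_range[1], y_range[2], length.out = n)
  score <- outer(xs, ys, r1fun)^2 + outer(xs, ys, r2fun)^2
  ij <- which(score == min(score), arr.ind = TRUE)[1, ]
  fn <- function(par) {
    y <- max(par[2], y_floor)
    r1fun(par[1], y)^2 + r2fun(par[1], y)^2
  }
  opt <- stats::optim(c(xs[ij[1]], ys[ij[2]]), fn, method = "Nelder-Mead",
                      control = list(reltol = 1e-16, maxit = 20000,
                                     parscale = c(1, 0.01)))
  list(x = opt$par[1], y = max(opt$par[2], y_floor))
}

pedicel_grid_oracle <- function(state, env, t, params, n = 61L) {
  Tc <- env$T
  kT <- params$R_g * (Tc + 273.15) * params$rho_sol / params$M_s
  pi_p <- kT * env$C_p + params$pi_pO
  P_p <- env$psi_x + pi_p
  der <- derive_quantities(state, params, Tc, warn = FALSE)
  A <- der$A_f
  Gx <- params$a_x * A * params$L_x
  Gp <- params$a_p * A * params$L_p
  Lpp <- pedicel_phloem_conductance(t, params)
  Lxp <- pedicel_xylem_conductance(t, params)
  nu_m <- max_active_uptake(state$s, Tc, params)
  sp <- params$sigma_p
  sugar_conc <- function(F_p, C) {
    switch(params$options$pedicel_sugar_conc,
           stem = ifelse(F_p >= 0, env$C_p, C),
           mean = (env$C_p + C) / 2,
           fruit_end = C)
  }

  if (identical(params$options$pedicel_closure, "pathway")) {
    # unknowns (P_p', C'); the xylem side is independent and linear
    parts <- function(P_pf, C) {
      pi_pf <- kT * C + params$pi_pO
      b <- state$P_f + sp * (pi_pf - der$pi_f)
      U_p <- Gp * (P_pf - b)
      U_a <- nu_m * C / (params$K_m + C)
      U_d <- params$p_s * params$a_p * A * (C - der$C_f)
      U_m <- (1 - sp) * (C + der$C_f) / 2 * U_p
      F_p <- Lpp * (P_p - P_pf)
      list(F_p = F_p, upt = U_a + U_m + U_d, U_p = U_p, C = C)
    }
    r1 <- function(P_pf, C) { z <- parts(P_pf, C); z$F_p - (z$U_p + z$upt) }
    r2 <- function(P_pf, C) { z <- parts(P_pf, C)
      z$F_p * sugar_conc(z$F_p, C) - z$upt }
    sol <- .grid_refine(r1, r2, c(P_p - 40, P_p + 10), c(0, 0.45), n = n)
    psi <- (Lxp * env$psi_x + Gx * der$psi_f) / (Lxp + Gx)
    list(psi_fruit_end = psi, P_p_fruit_end = sol$x, C_p_fruit_end = sol$y)
  } else {
    # unknowns (psi', C') with P_p' = psi' + pi_p'(C')
    parts <- function(psi, C) {
      pi_pf <- kT * C + params$pi_pO
      P_pf <- psi + pi_pf
      U_x <- Gx * (psi - der$psi_f)
      U_p <- Gp * (P_pf - state$P_f - sp * (pi_pf - der$pi_f))
      F_p <- Lpp * (P_p - P_pf)
      F_x <- Lxp * (env$psi_x - psi)
      U_a <- nu_m * C / (params$K_m + C)
      U_m <- (1 - sp) * (C + der$C_f) / 2 * U_p
      U_d <- params$p_s * params$a_p * A * (C - der$C_f)
      list(F_p = F_p, F_x = F_x, U_x = U_x, U_p = U_p,
           upt = U_a + U_m + U_d)
    }
    r1 <- function(psi, C) { z <- parts(psi, C)
      (z$F_p + z$F_x) - (z$U_x + z$U_p) }
    r2 <- function(psi, C) { z <- parts(psi, C)
      z$F_p * sugar_conc(z$F_p, C) - z$upt }
    sol <- .grid_refine(r1, r2, c(env$psi_x - 30, env$psi_x + 30),
                        c(0, 0.45), n = n)
    list(psi_fruit_end = sol$x, C_p_fruit_end = sol$y,
         P_p_fruit_end = sol$x + kT * sol$y + params$pi_pO)
  }
}
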