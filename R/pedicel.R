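#' Stem-end vasculature state
#'
#' Builds the stem-end phloem state from an environment sample: osmotic
#' pressure from the stem phloem sugar concentration plus the non-sugar
#' baseline, and turgor from the local-equilibrium construction
#' `P_p = psi_x + pi_p` (stem phloem in water-potential equilibrium with
#' the stem xylem).
#'
#' @param env environment sample (list with `T`, `psi_x`, `C_p`)
#' @param params a `kiwi_params` list
#' @return list with `psi_x`, `C_p`, `pi_p`, `P_p`
#' @export
stem_state <- function(env, params) {
  pi_p <- osmotic_pressure(env$C_p, params$pi_pO, env$T, params)
  list(psi_x = env$psi_x, C_p = env$C_p, pi_p = pi_p,
       P_p = env$psi_x + pi_p)
}

#' Pedicel phloem mass flow
#'
#' `F_p = L_p_ped * (P_p - P_p')`: pressure-driven solution flow along
#' the pedicel phloem.
#'
#' @param P_p stem-end phloem turgor (bar)
#' @param P_pf fruit-end phloem turgor (bar)
#' @param L_p_ped pedicel phloem axial conductance (g h^-1 bar^-1)
#' @return `F_p` (g h^-1)
#' @export
pedicel_phloem_flow <- function(P_p, P_pf, L_p_ped) {
  if (any(L_p_ped < 0)) stop("conductance must be >= 0", call. = FALSE)
  L_p_ped * (P_p - P_pf)
}

#' Pedicel xylem mass flow
#'
#' `F_x = L_x_ped * (psi_x - psi')`: flow driven by the hydrostatic
#' pressure difference between stem xylem and fruit apoplasm.
#'
#' @param psi_x stem xylem water potential (bar)
#' @param psi_f_end fruit-end xylem/apoplast water potential (bar)
#' @param L_x_ped pedicel xylem axial conductance (g h^-1 bar^-1)
#' @return `F_x` (g h^-1)
#' @export
pedicel_xylem_flow <- function(psi_x, psi_f_end, L_x_ped) {
  if (any(L_x_ped < 0)) stop("conductance must be >= 0", call. = FALSE)
  L_x_ped * (psi_x - psi_f_end)
}

#' Pedicel sucrose flux
#'
#' Advective approximation `S_ped = F_p * C_p'` with the fruit-end
#' concentration (the `mean` convention `(C_p + C_p')/2` is selectable
#' through the parameter options).
#'
#' @param F_p pedicel phloem mass flow (g h^-1)
#' @param C_pf fruit-end phloem sugar concentration (g/g)
#' @return `S_ped` (g h^-1)
#' @export
pedicel_sugar_flux <- function(F_p, C_pf) {
  F_p * C_pf
}

# Illinois (regula falsi with stagnation fix) on f over [a, b] with a
# guaranteed sign change; tol is on |f|, per the pedicel contract.
.illinois <- function(f, a, b, fa, fb, tol = 1e-10, maxit = 200L) {
  side <- 0L
  for (i in seq_len(maxit)) {
    x <- (fa * b - fb * a) / (fa - fb)
    if (!is.finite(x) || x <= min(a, b) || x >= max(a, b)) x <- (a + b) / 2
    fx <- f(x)
    if (abs(fx) <= tol || abs(b - a) < 1e-15) {
      return(list(root = x, f = fx, iter = i))
    }
    if (sign(fx) == sign(fa)) {
      a <- x; fa <- fx
      if (side == -1L) fb <- fb / 2
      side <- -1L
    } else {
      b <- x; fb <- fx
      if (side == 1L) fa <- fa / 2
      side <- 1L
    }
  }
  stop(sprintf("pedicel sugar balance did not converge in %d iterations (residual %.3e)",
               maxit, fx), call. = FALSE)
}

#' Solve the fruit-end vasculature state
#'
#' At each instant the fruit-end phloem concentration `C_p'`, the
#' fruit-end phloem pressure `P_p'`, and the fruit-end xylem/apoplast
#' water potential `psi'` are unknown; the pedicel has no storage, so
#' they are fixed by conservation between pedicel flows and fruit
#' uptake, closed in one of two selectable ways
#' (`params$options$pedicel_closure`):
#'
#' * `"pathway"` (default): the xylem and phloem conduits conserve mass
#'   separately at the fruit end. The xylem balance
#'   `F_x = U_x` gives `psi'` in closed form; the phloem balance
#'   `F_p = U_p + U_a + U_m + U_d` (arriving sap leaves through the
#'   membrane as water plus sugar) gives `P_p'` in closed form for any
#'   `C_p'`. This is the Muench configuration: sap flow is driven by the
#'   pressure drop sustained by membrane unloading, and the model fruit
#'   imports sugar at realistic seasonal rates.
#' * `"equilibrium"`: a single total mass balance
#'   `F_p + F_x = U_x + U_p` with the fruit-end phloem in local
#'   water-potential equilibrium with the fruit-end xylem
#'   (`P_p' = psi' + pi_p'(C_p')`, mirroring the stem-end
#'   construction); `psi'` is then linear and closed-form given `C_p'`.
#'   This variant recovers the pedicel-free model exactly in the
#'   zero-resistance limit, but couples the phloem pressure drop to the
#'   xylem potential drop, which throttles sap flow.
#'
#' In both closures the remaining sucrose balance
#' `S_ped = U_a + U_m + U_d` is a scalar root-finding problem in
#' `C_p'`, solved with a bracketed Illinois (regula-falsi hybrid)
#' iteration to an absolute residual tolerance of 1e-10 g h^-1.
#'
#' @param state a `kiwi_state`
#' @param derived matching [derive_quantities()] output
#' @param env environment sample (list with `T`, `psi_x`, `C_p`)
#' @param t time (DAFB)
#' @param params a `kiwi_params` list
#' @param conductance_scale multiplier on both pedicel conductances
#'   (used for zero-resistance limit studies)
#' @return a list of class `kiwi_pedicel`: `psi_fruit_end`,
#'   `C_p_fruit_end`, `P_p_fruit_end`, `pi_p_fruit_end`, pedicel flows
#'   `F_p`, `F_x`, `S_ped`, fruit uptakes `U_x`, `U_p`, `U_a`, `U_m`,
#'   `U_d`, conservation residuals and iteration count.
#' @export
solve_fruit_end <- function(state, derived, env, t, params,
                            conductance_scale = 1) {
  T_c <- env$T
  stem <- stem_state(env, params)
  Lpp <- pedicel_phloem_conductance(t, params) * conductance_scale
  Lxp <- pedicel_xylem_conductance(t, params) * conductance_scale
  A_f <- derived$A_f
  Gx <- params$a_x * A_f * params$L_x
  Gp <- params$a_p * A_f * params$L_p
  nu_m <- max_active_uptake(state$s, T_c, params)
  kT <- params$R_g * (T_c + 273.15) * params$rho_sol / params$M_s
  psi_f <- derived$psi_f; pi_f <- derived$pi_f; C_f <- derived$C_f
  P_f <- state$P_f; sp <- params$sigma_p
  # advected concentration in the pedicel sucrose flux. "stem" is the
  # upwind plug-flow convention: sap flowing toward the fruit carries the
  # stem concentration, backflow carries the fruit-end concentration.
  sconc <- switch(params$options$pedicel_sugar_conc,
                  fruit_end = function(Cp, Fp) Cp,
                  mean = function(Cp, Fp) (stem$C_p + Cp) / 2,
                  stem = function(Cp, Fp) if (Fp >= 0) stem$C_p else Cp)
  pathway <- identical(params$options$pedicel_closure, "pathway")

  # degenerate fruit: no uptake surface -> no fluxes; stem values carry over
  if (A_f <= 0 || (Gx + Gp) == 0) {
    out <- list(psi_fruit_end = stem$psi_x, C_p_fruit_end = stem$C_p,
                P_p_fruit_end = stem$P_p, pi_p_fruit_end = stem$pi_p,
                F_p = 0, F_x = 0, S_ped = 0, U_x = 0, U_p = 0,
                U_a = 0, U_m = 0, U_d = 0,
                residual_mass = 0, residual_sugar = 0, iterations = 0L)
    class(out) <- "kiwi_pedicel"
    return(out)
  }

  if (pathway) {
    # xylem branch is independent of C_p'
    psi <- if (Lxp + Gx > 0) {
      (Lxp * stem$psi_x + Gx * psi_f) / (Lxp + Gx)
    } else stem$psi_x
    U_x0 <- Gx * (psi - psi_f)
    F_x0 <- Lxp * (stem$psi_x - psi)
    eval_at <- function(Cp) {
      pi_pf <- kT * Cp + params$pi_pO
      U_a <- nu_m * Cp / (params$K_m + Cp)
      U_d <- params$p_s * params$a_p * A_f * (Cp - C_f)
      m <- (1 - sp) * (Cp + C_f) / 2           # U_m = m * U_p
      b <- P_f + sp * (pi_pf - pi_f)           # U_p = Gp * (P_pf - b)
      P_pf <- if (Lpp + (1 + m) * Gp > 0) {
        (Lpp * stem$P_p + (1 + m) * Gp * b - U_a - U_d) /
          (Lpp + (1 + m) * Gp)
      } else stem$P_p
      U_p <- Gp * (P_pf - b)
      F_p <- Lpp * (stem$P_p - P_pf)
      U_m <- m * U_p
      S_ped <- F_p * sconc(Cp, F_p)
      list(psi = psi, P_pf = P_pf, pi_pf = pi_pf, U_x = U_x0, U_p = U_p,
           F_p = F_p, F_x = F_x0, U_a = U_a, U_m = U_m, U_d = U_d,
           S_ped = S_ped,
           rmass = (F_p + F_x0) - (U_x0 + U_p + U_a + U_m + U_d),
           g = S_ped - (U_a + U_m + U_d))
    }
  } else {
    denom <- Lpp + Lxp + Gx + Gp
    eval_at <- function(Cp) {
      pi_pf <- kT * Cp + params$pi_pO
      psi <- (Lpp * (stem$P_p - pi_pf) + Lxp * stem$psi_x + Gx * psi_f +
                Gp * (P_f - (1 - sp) * pi_pf - sp * pi_f)) / denom
      P_pf <- psi + pi_pf
      U_x <- Gx * (psi - psi_f)
      U_p <- Gp * (P_pf - P_f - sp * (pi_pf - pi_f))
      F_p <- Lpp * (stem$P_p - P_pf)
      F_x <- Lxp * (stem$psi_x - psi)
      U_a <- nu_m * Cp / (params$K_m + Cp)
      U_m <- (1 - sp) * (Cp + C_f) / 2 * U_p
      U_d <- params$p_s * params$a_p * A_f * (Cp - C_f)
      S_ped <- F_p * sconc(Cp, F_p)
      list(psi = psi, P_pf = P_pf, pi_pf = pi_pf, U_x = U_x, U_p = U_p,
           F_p = F_p, F_x = F_x, U_a = U_a, U_m = U_m, U_d = U_d,
           S_ped = S_ped,
           rmass = (F_p + F_x) - (U_x + U_p),
           g = S_ped - (U_a + U_m + U_d))
    }
  }
  g <- function(Cp) eval_at(Cp)$g

  hi <- 1.5 * max(stem$C_p, C_f, 0.01)
  lo <- 0
  flo <- g(lo); fhi <- g(hi)
  if (sign(flo) == sign(fhi) && flo != 0 && fhi != 0) {
    # scan for an interior bracket (active uptake makes g non-monotone)
    grid <- seq(lo, hi, length.out = 33L)
    gv <- vapply(grid, g, numeric(1))
    idx <- which(diff(sign(gv)) != 0)
    if (!length(idx)) {
      hi2 <- max(3 * hi, 0.95)
      grid <- seq(lo, hi2, length.out = 97L)
      gv <- vapply(grid, g, numeric(1))
      idx <- which(diff(sign(gv)) != 0)
      if (!length(idx)) {
        stop(sprintf(paste0("no bracket for pedicel sugar balance at t=%.3f: ",
                            "g(0)=%.3e, g(%.3f)=%.3e"),
                     t, gv[1L], hi2, gv[length(gv)]), call. = FALSE)
      }
    }
    lo <- grid[idx[1L]]; hi <- grid[idx[1L] + 1L]
    flo <- gv[idx[1L]]; fhi <- gv[idx[1L] + 1L]
  }

  sol <- if (flo == 0) list(root = lo, f = 0, iter = 0L)
         else if (fhi == 0) list(root = hi, f = 0, iter = 0L)
         else .illinois(g, lo, hi, flo, fhi)

  at <- eval_at(sol$root)
  out <- list(psi_fruit_end = at$psi, C_p_fruit_end = sol$root,
              P_p_fruit_end = at$P_pf, pi_p_fruit_end = at$pi_pf,
              F_p = at$F_p, F_x = at$F_x, S_ped = at$S_ped,
              U_x = at$U_x, U_p = at$U_p,
              U_a = at$U_a, U_m = at$U_m, U_d = at$U_d,
              residual_mass = at$rmass,
              residual_sugar = at$g, iterations = sol$iter)
  class(out) <- "kiwi_pedicel"
  out
}

#' Fruit fluxes without a pedicel
#'
#' Evaluates the membrane fluxes with the fruit bathed directly in the
#' stem vasculature (`psi' = psi_x`, `C_p' = C_p`,
#' `P_p' = psi_x + pi_p`): the zero-resistance limit of the pedicel
#' model, i.e. the original single-compartment formulation with uptake
#' straight from the stem.
#'
#' @inheritParams solve_fruit_end
#' @return list with `U_x`, `U_p`, `U_a`, `U_m`, `U_d`
#' @export
pedicel_free_fluxes <- function(state, derived, env, t, params) {
  stem <- stem_state(env, params)
  A_f <- derived$A_f
  U_x <- xylem_uptake(stem$psi_x, derived$psi_f, A_f, params)
  U_p <- phloem_water_uptake(stem$P_p, stem$pi_p, state$P_f, derived$pi_f,
                             A_f, params)
  nu_m <- max_active_uptake(state$s, env$T, params)
  su <- sugar_uptake(stem$C_p, derived$C_f, U_p, nu_m, A_f, params)
  c(list(U_x = U_x, U_p = U_p), su)
}
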