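#' Construct and validate a fruit state
#'
#' The instantaneous state of the berry: water mass `w`, total dry matter
#' `s`, starch mass `u`, and turgor `P_f`, at time `t` (DAFB). Turgor may
#' transiently be non-positive (observed in the model very early in the
#' season) but must be finite.
#'
#' @param w water mass (g), > 0
#' @param s dry matter (g), > 0
#' @param u starch mass (g), in \[0, s\]
#' @param P_f turgor (bar), finite
#' @param t time (DAFB)
#' @return a `kiwi_state` list
#' @export
fruit_state <- function(w, s, u, P_f, t = 0) {
  stopifnot(is.numeric(w), is.numeric(s), is.numeric(u), is.numeric(P_f))
  if (!(w > 0)) stop("water mass w must be > 0", call. = FALSE)
  if (!(s > 0)) stop("dry matter s must be > 0", call. = FALSE)
  if (u < 0 || u > s) stop("starch u must lie in [0, s]", call. = FALSE)
  if (!is.finite(P_f)) stop("turgor P_f must be finite", call. = FALSE)
  structure(list(t = t, w = w, s = s, u = u, P_f = P_f),
            class = "kiwi_state")
}

#' Osmotic pressure of a sugar solution (van 't Hoff)
#'
#' `pi = R_g * (T + 273.15) * C * rho_sol / M_s + pi_other`: the sugar
#' concentration `C` is a mass fraction (g solute per g solution),
#' converted to molarity with the solution-density convention
#' `rho_sol` = 1 g cm^-3 and sucrose-equivalent molar mass, plus a
#' constant baseline `pi_other` from non-sugar solutes.
#'
#' @param C sugar concentration (g per g solution), in \[0, 1)
#' @param pi_other baseline osmotic pressure from other solutes (bar)
#' @param T_c temperature (deg C)
#' @param params a `kiwi_params` list
#' @return osmotic pressure (bar)
#' @export
osmotic_pressure <- function(C, pi_other, T_c, params) {
  params$R_g * (T_c + 273.15) * C * params$rho_sol / params$M_s + pi_other
}

#' Saturation vapour pressure of water (Buck equation)
#'
#' `P_sat = 6.1121 * exp(17.502 * T / (240.97 + T))` hPa, returned in bar.
#' Any standard saturation formula agreeing to under 1% on 0-40 C would
#' serve; this one is pinned as the package's convention.
#'
#' @param T_c temperature (deg C); vectorized
#' @return saturation vapour pressure (bar)
#' @export
saturation_vapour_pressure <- function(T_c) {
  6.1121 * exp(17.502 * T_c / (240.97 + T_c)) * 1e-3
}

#' Fruit transpiration flux
#'
#' Vapour diffusion across the skin:
#' `T_f = A_f * rho * (M_w * P_sat(T) / (R_g * (T + 273.15))) * (H_f - H_a)`,
#' clipped at zero (no condensation uptake). `H_f` is the near-saturated
#' humidity of the internal air spaces.
#'
#' @param A_f fruit surface area (cm^2)
#' @param rho skin permeance (cm h^-1)
#' @param T_c temperature (deg C)
#' @param H_a ambient relative humidity (fraction)
#' @param params a `kiwi_params` list
#' @return transpiration (g h^-1)
#' @export
transpiration_flux <- function(A_f, rho, T_c, H_a, params) {
  conc <- params$M_w * saturation_vapour_pressure(T_c) /
    (params$R_g * (T_c + 273.15))        # g cm^-3 saturated vapour
  pmax(A_f * rho * conc * (params$H_f - H_a), 0)
}

#' Water uptake from the fruit-end xylem
#'
#' Proportional to the water-potential difference across the composite
#' membrane: `U_x = a_x * A_f * L_x * (psi_xf - psi_f)`. The sign carries
#' direction; backflow out of the fruit is permitted.
#'
#' @param psi_xf fruit-end xylem water potential (bar)
#' @param psi_f fruit water potential `P_f - pi_f` (bar)
#' @param A_f fruit surface area (cm^2)
#' @param params a `kiwi_params` list
#' @return `U_x` (g h^-1)
#' @export
xylem_uptake <- function(psi_xf, psi_f, A_f, params) {
  params$a_x * A_f * params$L_x * (psi_xf - psi_f)
}

#' Water uptake from the fruit-end phloem
#'
#' Osmotically assisted mass flow with a reflection coefficient
#' representing the partially symplastic pathway:
#' `U_p = a_p * A_f * L_p * (P_p' - P_f - sigma_p * (pi_p' - pi_f))`.
#'
#' @param P_pf fruit-end phloem turgor (bar)
#' @param pi_pf fruit-end phloem osmotic pressure (bar)
#' @param P_f fruit turgor (bar)
#' @param pi_f fruit osmotic pressure (bar)
#' @param A_f fruit surface area (cm^2)
#' @param params a `kiwi_params` list
#' @return `U_p` (g h^-1)
#' @export
phloem_water_uptake <- function(P_pf, pi_pf, P_f, pi_f, A_f, params) {
  params$a_p * A_f * params$L_p *
    (P_pf - P_f - params$sigma_p * (pi_pf - pi_f))
}

#' Sugar uptake across the composite membrane
#'
#' Parallel combination of Michaelis-Menten active transport on the
#' fruit-end phloem concentration, advection with the phloem water flow
#' (mean-concentration convention), and diffusion:
#' `U_a = nu_m * C_p'/(K_m + C_p')`;
#' `U_m = (1 - sigma_p) * (C_p' + C_f)/2 * U_p`;
#' `U_d = p_s * a_p * A_f * (C_p' - C_f)`.
#'
#' @param C_pf fruit-end phloem sugar concentration (g/g)
#' @param C_f fruit sugar concentration (g/g)
#' @param U_p phloem water uptake (g h^-1)
#' @param nu_m maximal active uptake (g h^-1), see [max_active_uptake()]
#' @param A_f fruit surface area (cm^2)
#' @param params a `kiwi_params` list
#' @return list with `U_a`, `U_m`, `U_d` (g h^-1)
#' @export
sugar_uptake <- function(C_pf, C_f, U_p, nu_m, A_f, params) {
  list(U_a = nu_m * C_pf / (params$K_m + C_pf),
       U_m = (1 - params$sigma_p) * (C_pf + C_f) / 2 * U_p,
       U_d = params$p_s * params$a_p * A_f * (C_pf - C_f))
}

#' Respiratory dry-matter loss
#'
#' Maintenance plus growth respiration:
#' `R_f = q_m * Q10_r^((T-20)/10) * s + q_g * max(ds_dt_gross, 0)`.
#' Inside the simulator the growth component is resolved implicitly (see
#' [state_derivatives()]); this function evaluates the explicit form for
#' a given gross growth rate.
#'
#' @param s dry matter (g)
#' @param T_c temperature (deg C)
#' @param ds_dt_gross gross dry-matter growth rate (g h^-1)
#' @param params a `kiwi_params` list
#' @return `R_f` (g h^-1)
#' @export
respiration_flux <- function(s, T_c, ds_dt_gross, params) {
  params$q_m * params$Q10_r^((T_c - 20) / 10) * s +
    params$q_g * pmax(ds_dt_gross, 0)
}

#' Derived quantities of a fruit state
#'
#' Computes, from `(w, s, u, P_f)` and temperature: the dry-matter
#' partition (`o`, `s_s`, `Z`), fruit sugar concentration
#' `C_f = s_s/(w + s_s)`, osmotic pressure `pi_f`, water potential
#' `psi_f = P_f - pi_f`, volume `V = (w + s)/rho_sol`, and surface area
#' `A_f = gamma * FW^eta`.
#'
#' @param state a `kiwi_state` (or any list with `w`, `s`, `u`, `P_f`)
#' @param params a `kiwi_params` list
#' @param T_c temperature (deg C)
#' @param warn warn if the soluble-solids floor engages
#' @return a list of class `kiwi_derived`
#' @export
derive_quantities <- function(state, params, T_c, warn = TRUE) {
  o <- other_dry_matter(state$s, state$w, state$u, params)
  s_s <- soluble_solids_mass(state$s, o, state$u, warn = warn)
  Z <- soluble_fraction(s_s, state$s)
  C_f <- s_s / (state$w + s_s)
  pi_f <- osmotic_pressure(C_f, params$pi_fO, T_c, params)
  FW <- state$w + state$s
  structure(list(o = o, s_s = s_s, Z = Z, C_f = C_f, pi_f = pi_f,
                 psi_f = state$P_f - pi_f, V = FW / params$rho_sol,
                 A_f = fruit_surface_area(FW, params)),
            class = "kiwi_derived")
}

#' Quality outputs of a fruit state
#'
#' The observable quality attributes: fresh weight `FW = w + s`, dry
#' weight `DW = s`, dry-matter percentage `DM% = 100 s/FW`, soluble
#' solids percentage of juice `SS% = 100 s_s/(w + s_s)`, starch as a
#' percentage of dry matter `ST% = 100 u/s`, and a relative diameter
#' `FW^(1/3)` (fresh weight scales with the diameter cubed).
#'
#' @param state a `kiwi_state`
#' @param derived the matching `kiwi_derived` from [derive_quantities()]
#' @return a named list with `FW`, `DW`, `DM_pct`, `SS_pct`, `ST_pct`,
#'   `diameter_rel`
#' @export
quality_outputs <- function(state, derived) {
  FW <- state$w + state$s
  list(FW = FW, DW = state$s,
       DM_pct = 100 * state$s / FW,
       SS_pct = 100 * derived$s_s / (state$w + derived$s_s),
       ST_pct = 100 * state$u / state$s,
       diameter_rel = FW^(1/3))
}

# ---------------------------------------------------------------------
# Flux assembly: everything needed for one derivative evaluation at one
# instant, given the fruit state, the solved fruit-end vasculature, and
# the environment sample. Internal hot path -- returns a plain list.
# ---------------------------------------------------------------------
.assemble_fluxes <- function(state, derived, ped, env, t, params) {
  rho <- skin_permeance(t, params)
  T_f <- transpiration_flux(derived$A_f, rho, env$T, env$H_a, params)

  U_x <- ped$U_x; U_p <- ped$U_p
  U_sugar <- ped$U_a + ped$U_m + ped$U_d

  maint <- params$q_m * params$Q10_r^((env$T - 20) / 10) * state$s
  net <- U_sugar - maint
  # growth respiration proportional to net growth, resolved implicitly:
  # ds = (U - maint)/(1 + q_g) when growing, else ds = U - maint
  ds <- if (net > 0) net / (1 + params$q_g) else net
  R_f <- U_sugar - ds

  dw <- U_x + U_p - T_f
  du <- starch_rate(derived$s_s, state$u, t, params) / 24   # d^-1 -> h^-1
  phi <- wall_extensibility(t, params)
  dV <- (dw + ds) / params$rho_sol
  dP <- params$epsilon *
    (dV / derived$V - phi * max(state$P_f - params$Y, 0))

  list(dw = dw, ds = ds, du = du, dP = dP,
       T_f = T_f, R_f = R_f, phi = phi, rho = rho,
       U_x = U_x, U_p = U_p, U_a = ped$U_a, U_m = ped$U_m, U_d = ped$U_d)
}

#' State derivatives of the fruit ODE
#'
#' Assembles the four derivatives at one instant:
#' `dw/dt = U_x + U_p - T_f` (water balance),
#' `ds/dt = U_a + U_m + U_d - R_f` (dry-matter balance, with growth
#' respiration resolved implicitly as `(U - maintenance)/(1 + q_g)`),
#' `du/dt` from the starch sub-model (per-day rates divided by 24 at this
#' boundary and nowhere else), and the elastic Lockhart/Ortega turgor law
#' `dP_f/dt = epsilon * ((1/V) dV/dt - phi(t) * max(P_f - Y, 0))` with
#' `dV/dt = (dw/dt + ds/dt)/rho_sol`. Plastic growth is never negative;
#' shrinkage is carried by the elastic term.
#'
#' @param state a `kiwi_state`
#' @param env an environment sample (list with `T`, `H_a`, `psi_x`, `C_p`)
#' @param t time (DAFB)
#' @param params a `kiwi_params` list
#' @param ped optional pre-computed pedicel solution from
#'   [solve_fruit_end()]; solved here if missing
#' @param derived optional pre-computed [derive_quantities()] result
#' @return list with derivatives (per hour) and the flux set
#' @export
state_derivatives <- function(state, env, t, params, ped = NULL,
                              derived = NULL) {
  if (is.null(derived)) derived <- derive_quantities(state, params, env$T,
                                                     warn = FALSE)
  if (is.null(ped)) ped <- solve_fruit_end(state, derived, env, t, params)
  fl <- .assemble_fluxes(state, derived, ped, env, t, params)
  if (!all(is.finite(c(fl$dw, fl$ds, fl$du, fl$dP)))) {
    stop(sprintf(paste0("non-finite derivative at t = %.4f ",
                        "(w=%.4g s=%.4g u=%.4g P_f=%.4g)"),
                 t, state$w, state$s, state$u, state$P_f), call. = FALSE)
  }
  c(fl, list(pedicel = ped, derived = derived))
}
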