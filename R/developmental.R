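#' Cell-wall extensibility schedule
#'
#' `log(phi)` is piecewise linear in fruit age: a plateau at `phi_1`
#' during cell division (`t <= d_1`), a log-linear transition down to
#' `phi_2` between `d_1` and `d_2`, and a slow log-linear decline at rate
#' `phi_k` thereafter. Continuous everywhere; spans the orders of
#' magnitude separating the cell-division and cell-expansion phases.
#'
#' @param t time (DAFB); vectorized
#' @param params a `kiwi_params` list
#' @return extensibility `phi` (bar^-1 h^-1)
#' @export
wall_extensibility <- function(t, params) {
  l1 <- log(params$phi_1); l2 <- log(params$phi_2)
  lp <- ifelse(t <= params$d_1, l1,
        ifelse(t <= params$d_2,
               l1 + (l2 - l1) * (t - params$d_1) / (params$d_2 - params$d_1),
               l2 - params$phi_k * (t - params$d_2)))
  exp(lp)
}

#' Maximal active sugar uptake rate
#'
#' Proportional to dry weight and temperature-scaled with a Q10 around a
#' 20 C reference: `nu_m = nu_1 * s * Q10_nu^((T - 20)/10)`.
#'
#' @param s fruit dry matter (g)
#' @param T_c temperature (deg C)
#' @param params a `kiwi_params` list
#' @return `nu_m` (g h^-1)
#' @export
max_active_uptake <- function(s, T_c, params) {
  params$nu_1 * s * params$Q10_nu^((T_c - 20) / 10)
}

#' Pedicel xylem axial conductance
#'
#' Double-logistic in fruit age: conductance rises early (midpoint `t_1`,
#' rate `k1x`, amplitude `L1x - L2x`) as the pedicel develops, then
#' declines (midpoint `t_2`, rate `k2x`) to a late-season plateau `L2x`,
#' matching the observed fall and recovery of whole-fruit hydraulic
#' resistance.
#'
#' @param t time (DAFB); vectorized
#' @param params a `kiwi_params` list
#' @return conductance (g h^-1 bar^-1)
#' @export
pedicel_xylem_conductance <- function(t, params) {
  params$L2x + (params$L1x - params$L2x) *
    stats::plogis(params$k1x * (t - params$t_1)) *
    (1 - stats::plogis(params$k2x * (t - params$t_2)))
}

#' Pedicel phloem axial conductance
#'
#' Single logistic rising to the asymptote `Lp_inf` with midpoint `t_1`
#' and rate `k1p`: phloem conductance grows in proportion to xylem
#' conductance while the pedicel develops, then stays constant (no
#' evidence of late-season phloem breakdown).
#'
#' @inheritParams pedicel_xylem_conductance
#' @return conductance (g h^-1 bar^-1)
#' @export
pedicel_phloem_conductance <- function(t, params) {
  params$Lp_inf * stats::plogis(params$k1p * (t - params$t_1))
}

#' Skin permeance to water vapour
#'
#' Exponential decline with fruit age from `rho_0` at `t_rho` (the first
#' day covered by the underlying permeance data) toward the asymptote
#' `rho_inf`; held at `rho_0` before `t_rho`.
#'
#' @inheritParams pedicel_xylem_conductance
#' @return permeance `rho` (cm h^-1)
#' @export
skin_permeance <- function(t, params) {
  ifelse(t < params$t_rho, params$rho_0,
         params$rho_inf + (params$rho_0 - params$rho_inf) *
           exp(-params$k_rho * (t - params$t_rho)))
}

#' Fruit surface area from fresh weight
#'
#' Allometric relation `A_f = gamma * FW^eta`.
#'
#' @param FW fresh weight (g); vectorized
#' @param params a `kiwi_params` list
#' @return surface area (cm^2)
#' @export
fruit_surface_area <- function(FW, params) {
  if (any(FW < 0)) stop("fresh weight must be non-negative", call. = FALSE)
  params$gamma * FW^params$eta
}
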