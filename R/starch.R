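#' Structural ("other") dry matter
#'
#' Partitions fruit dry matter: the structural fraction (cell walls,
#' membranes, etc.) is an exponentially declining proportion of dry
#' weight, capped so that structural matter plus a basal soluble-solids
#' requirement never exceeds the dry matter not already locked in starch.
#'
#' With the default `proportional` form,
#' `o = min(A_o * s * exp(-k_o * s), s - u - (s_b/100) * base)`,
#' floored at zero, where `base` is fresh weight `w + s` (default) or
#' juice mass, per `params$options$s_b_base`. The alternative
#' `saturating` form `A_o * (1 - exp(-k_o * s))` (suggested by the gram
#' unit sometimes attached to `A_o`) is selectable but yields implausibly
#' small structural mass and is not the default.
#'
#' @param s dry matter (g)
#' @param w water mass (g)
#' @param u starch mass (g)
#' @param params a `kiwi_params` list.
#' @return structural dry matter `o` (g)
#' @export
other_dry_matter <- function(s, w, u, params) {
  uncapped <- switch(params$options$starch_o_form,
    proportional = params$A_o * s * exp(-params$k_o * s),
    saturating   = params$A_o * (1 - exp(-params$k_o * s)))
  base <- switch(params$options$s_b_base,
    fresh = w + s,
    # juice = water + soluble solids; at this point s_s is unknown, so the
    # juice base uses the non-starch dry matter bound s - u as its soluble
    # part, the tightest consistent cap
    juice = w + pmax(s - u, 0))
  cap <- s - u - (params$s_b / 100) * base
  pmax(pmin(uncapped, cap), 0)
}

#' Soluble solids mass
#'
#' `s_s = s - o - u`, floored at zero. A negative value before flooring
#' signals an inconsistent partition (possible very early in the season,
#' where the starch sub-model is known to be rough) and raises a warning
#' rather than an error.
#'
#' @param s dry matter (g)
#' @param o structural dry matter (g)
#' @param u starch mass (g)
#' @param warn warn when the floor engages (default `TRUE`)
#' @return soluble solids mass (g)
#' @export
soluble_solids_mass <- function(s, o, u, warn = TRUE) {
  s_s <- s - o - u
  if (any(s_s < 0)) {
    if (warn) {
      warning("soluble solids mass negative before flooring (",
              paste(signif(s_s[s_s < 0], 4), collapse = ", "),
              " g); floored at 0", call. = FALSE)
    }
    s_s <- pmax(s_s, 0)
  }
  s_s
}

#' Starch synthesis rate coefficient
#'
#' The synthesis coefficient declines with fruit age, slowly at first and
#' then more rapidly, reaching zero at the cutoff time `t_r`:
#' `k_s(t) = k_s1 * (1 - exp(-(t_r - t)/t_h))` for `t < t_r`, else 0.
#' `t_h` is the lead time before `t_r` at which `k_s` has dropped to
#' `1 - exp(-1)` (about 63%) of its maximum.
#'
#' @param t time (days after full bloom, DAFB)
#' @param params a `kiwi_params` list
#' @return `k_s` (d^-1); vectorized over `t`
#' @export
starch_synthesis_rate <- function(t, params) {
  ks <- params$k_s1 * (1 - exp(-(params$t_r - t) / params$t_h))
  ks[t >= params$t_r] <- 0
  pmax(ks, 0)
}

#' Net starch accumulation rate
#'
#' `du/dt = k_s(t) * s_s - k_u * u` in g per day: first-order synthesis
#' from the soluble pool and first-order hydrolysis of the starch pool.
#'
#' @param s_s soluble solids mass (g)
#' @param u starch mass (g)
#' @param t time (DAFB)
#' @param params a `kiwi_params` list
#' @return `du/dt` (g d^-1)
#' @export
starch_rate <- function(s_s, u, t, params) {
  starch_synthesis_rate(t, params) * s_s - params$k_u * u
}

#' Soluble fraction of dry matter
#'
#' @param s_s soluble solids mass (g)
#' @param s dry matter (g), must be positive
#' @return `Z = s_s / s` in \[0, 1\]
#' @export
soluble_fraction <- function(s_s, s) {
  if (any(s <= 0)) stop("dry matter must be positive", call. = FALSE)
  s_s / s
}
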