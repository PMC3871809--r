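---
title: "A biophysical simulator of kiwifruit berry development: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A biophysical simulator of kiwifruit berry development}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`kiwisim` simulates a single kiwifruit (*Actinidia deliciosa*) berry from
shortly after full bloom (DAFB 0) to around harvest (DAFB 170). The fruit
is one well-mixed compartment with four state variables:

* `w` — water mass (g),
* `s` — total dry matter (g),
* `u` — starch mass (g, a sub-pool of `s`),
* `P_f` — cell turgor (bar).

The fruit exchanges water and sucrose with the stem vasculature across a
composite membrane whose area grows in proportion to fruit surface area
(`A_f = gamma * FW^eta`), and loses water by transpiration through a skin
whose permeance declines with age. Water import from the xylem is
proportional to the water-potential difference; phloem import is
osmotically assisted mass flow with reflection coefficient `sigma_p`.
Sugar import is a parallel combination of Michaelis–Menten active
transport, advection with the phloem water flow, and diffusion. Dry
matter is lost to maintenance respiration (`Q10`-scaled) and growth
respiration proportional to net growth; the growth component is resolved
implicitly as `ds/dt = (uptake - maintenance)/(1 + q_g)`, the closed form
of "growth respiration proportional to net growth".

Volume change follows the Lockhart/Ortega law extended with elasticity:

```
dP_f/dt = epsilon * ( (1/V) dV/dt - phi(t) * max(P_f - Y, 0) )
```

with `dV/dt = (dw/dt + ds/dt) / rho_sol` (density convention
1 g cm^-3, so fresh weight, volume, and the cube of diameter are used
interchangeably). Plastic (irreversible) expansion happens only above
the yield threshold `Y`; shrinkage is carried entirely by the elastic
term. Osmotic pressures are sucrose-equivalent van 't Hoff terms on mass
fractions (g solute per g solution) plus constant non-sugar baselines
(`pi_fO`, `pi_pO`).

## The pedicel

The berry's stalk contributes most of its hydraulic resistance, so the
stem and the fruit-end of the vasculature are distinct. The pedicel is a
resistive conduit with no storage: axial phloem flow
`F_p = L_p_ped(t) * (P_p - P_p')` and axial xylem flow
`F_x = L_x_ped(t) * (psi_x - psi')`, with seasonally varying
conductances. At every evaluation instant the fruit-end unknowns — the
apoplast potential `psi'`, the phloem pressure `P_p'` and the phloem
sugar concentration `C_p'` — are determined by conservation.

Because the published description leaves the closure of this small
algebraic system open, the package implements two and makes the choice a
parameter option (`options$pedicel_closure`):

* **`"pathway"` (default).** Xylem and phloem conserve mass separately
  at the fruit end: `F_x = U_x` fixes `psi'` in closed form, and
  `F_p = U_p + U_a + U_m + U_d` fixes `P_p'` in closed form for any
  trial `C_p'`. This is the Münch configuration — sap flows because
  membrane unloading keeps the fruit-end pressure below the stem-end
  pressure. It reproduces the reported seasonal dry-weight accumulation
  (~20 g by day 170), the strong sensitivity of dry weight to the
  pedicel phloem conductance, and the absence of xylem backflow.
* **`"equilibrium"`.** One total mass balance `F_p + F_x = U_x + U_p`
  with the fruit-end phloem in local water-potential equilibrium with
  the fruit-end xylem (`P_p' = psi' + pi_p'(C_p')`), mirroring the
  stem-end construction `P_p = psi_x + pi_p`. This variant recovers the
  pedicel-free single-compartment model *exactly* in the
  zero-resistance limit (that equivalence is asserted in the test
  suite), but it ties the phloem pressure drop to the xylem potential
  drop, which throttles sap flow to a few hundredths of a gram per hour
  and starves the fruit of carbon. It is retained as the reference
  formulation for the limit checks, not for production runs.

The remaining sucrose balance `S_ped = U_a + U_m + U_d` is solved for
`C_p'` by a bracketed Illinois (regula-falsi) iteration to an absolute
residual of 1e-10 g h^-1, with a grid fallback for bracketing. The
advected concentration in `S_ped` is also an option
(`options$pedicel_sugar_conc`): the default `"stem"` is upwind plug
flow — sap flowing toward the fruit carries the stem concentration,
backflow carries the fruit-end concentration. This convention is
mass-conservative and makes the sugar balance monotone with a unique
root. The `"fruit_end"` and `"mean"` conventions are selectable; with
`"fruit_end"` the balance can develop multiple roots, and the solver may
land on a starved branch where the fruit-end concentration collapses to
a few thousandths — one reason that convention is not the default.

## The starch sub-model

Dry matter is partitioned diagnostically into structural matter
(`o = A_o * s * exp(-k_o * s)`, capped so that structural matter plus a
basal soluble requirement of `s_b` = 3.8% of fresh weight never exceeds
the non-starch dry matter), starch `u`, and soluble solids
`s_s = s - o - u` (floored at zero with a warning). Starch dynamics are
first order:

```
du/dt = k_s(t) * s_s - k_u * u
k_s(t) = k_s1 * (1 - exp(-(t_r - t)/t_h)),  zero from t_r onward
```

`k_s` declines slowly at first and then rapidly, reaching exactly
`1 - exp(-1)` (63%) of its maximum at `t_r - t_h` = 140 DAFB and zero at
`t_r` = 165 DAFB; the rise of soluble solids near harvest is pure
hydrolysis at rate `k_u`.

A structural limitation worth stating plainly: with the published
constants the synthesis/breakdown ratio `k_s1/k_u` is about 9, so
whenever import is slower than synthesis the sub-model converges to a
degenerate equilibrium in which starch holds ~88% of dry matter and the
structural pool is squeezed to zero by the cap. The simulated early and
mid-season starch share is therefore higher, and soluble solids lower,
than field observations — the same early-season bias the model's source
description acknowledges — and the starch *share* of dry matter is
nearly crop-load-invariant (only the absolute pools respond to crop
load). The seasonal *shape* (rise, plateau, steep pre-harvest fall) is
reproduced.

## Developmental functions

Several coefficients follow prescribed developmental schedules:

* `wall_extensibility`: `log(phi)` piecewise linear — a plateau at
  `phi_1` = 0.2 bar^-1 h^-1 through `d_1` = 15 DAFB (cell division), a
  log-linear fall to `phi_2` by `d_2` = 60 DAFB, then a slow decline at
  rate `phi_k`.
* `pedicel_xylem_conductance`: a double logistic (rise with midpoint
  `t_1` = 30 d, decline with midpoint `t_2` = 70 d to the plateau
  `L2x`), matching the observed fall-then-recovery of whole-fruit
  hydraulic resistance. The printed closed form of this fit was not
  recoverable, so the shape is reconstructed from its six fitted
  constants and the stated qualitative constraints; it is isolated in
  one function so a corrected form is a drop-in.
* `pedicel_phloem_conductance`: a single logistic rising to `Lp_inf`,
  proportional to the xylem curve early (`k1p = k1x` = 0.1 d^-1) and
  constant late (no phloem breakdown). Also a reconstruction.
* `skin_permeance`: exponential decline from `rho_0` = 800 cm h^-1 at
  `t_rho` = 18 DAFB toward `rho_inf` = 25 cm h^-1; held at `rho_0`
  before the first datum at 18 DAFB.
* `max_active_uptake`: `nu_1 * s`, Q10-scaled around a 20 °C reference.

## Conflicting printed parameter values

Three cell-expansion constants are printed in two mutually inconsistent
forms in the model's source description (running text vs parameter
table): `Y` (2 vs 0.08 bar), `phi_2` (0.00135 vs 0.000135 bar^-1 h^-1)
and `phi_k` (0.0028 vs 0.028 d^-1). The package default takes `Y` = 2
bar (the value argued from turgor measurements) and the *tabulated*
`phi_2`/`phi_k`. The reason is dynamical: in quasi-steady growth the
relative volumetric growth rate equals `phi * (P_f - Y)`. With the
text values, late-season `phi` (~1e-3 bar^-1 h^-1) pins turgor at
~2.1 bar all season, water uptake never brakes, and the simulated berry
reaches several hundred grams at sub-1% dry matter. Only with the
tabulated values does `phi` fall low enough (~1e-5 by day 150) for
turgor to climb toward the reported ~15 bar while fresh weight slows
onto its observed two-phase trajectory (~100 g, ~20% dry matter at day
170). Both pure-text and pure-table combinations remain selectable via
`load_parameters(variant = "text" | "table")`.

The maintenance/growth respiration constants (`q_m`, `q_g`, `Q10_r`)
are carried over from the peach-model lineage this model extends; they
live only in the parameter registry and the shipped parameter file,
never in code.

# The synthetic environment

The model is driven by four inputs — air temperature, relative
humidity, stem water potential and stem phloem sucrose concentration —
generated hourly by `make_environment()`:

* Daily temperature and humidity extrema follow second-order Fourier
  seasonal envelopes in calendar day-of-year; within a day the
  sine-exponential diurnal model is used (sunrise minimum, sine arc
  with an afternoon lag, exponential night decay), with day length from
  latitude and date. Humidity is phase-inverted against temperature.
* Vine transpiration is a smooth `sin^2` daytime curve whose daily
  integral equals a seasonal Fourier envelope of daily totals; stem
  water potential is `P_soil - Tr / L_soil_stem` (−1 bar soil, 0.001
  L s^-1 bar^-1).
* Phloem sucrose varies between fixed daily extrema (9% and 17% by
  mass) in proportion to the temperature pattern; a crop-load scenario
  subtracts a constant offset (0.01 g/g for the high-crop scenario).

The actual Fourier coefficients behind the original model's weather are
unpublished, so the shipped envelopes are **illustrative**: they are set
once to the stated qualitative conditions — May about 7 °C cooler than
January, summer transpiration several times the autumn rate, Southern
Hemisphere seasonality with bloom in mid-November — and all quantitative
testing avoids depending on their particular values. Consequently the
package's seasonal curves should match the published ones in shape and
scale, not point by point. Real weather can be supplied as an hourly
CSV (`read_environment_csv()` / `environment_from_series()`).

The generator is deterministic given its configuration. Its envelopes
are constant within each day, which makes the driving functions
piecewise-smooth with small midnight seams — a property to remember
when measuring integrator convergence (below).

# Numerics

* **Integrator.** Classical fixed-step RK4 on the four states plus four
  book-keeping states that accumulate the water and dry-matter flux
  integrals with the same quadrature (so conservation checks test
  derivative assembly, not quadrature differences). The default step is
  half an hour; output cadence defaults to one hour.
* **Semi-explicit DAE.** The pedicel system is algebraic; it is
  re-solved at every RK4 stage (not once per step), because turgor can
  move substantially within half an hour.
* **Stability guard.** The turgor equation has fast modes of order
  `epsilon * (phi(t) + S/V)` (plastic relaxation plus elastic flux
  feedback through the series vascular conductance `S`), reaching
  ~31 h^-1 during the cell-division phase — far outside RK4's stability
  interval at a half-hour step. Each macro step is therefore divided
  into `ceiling(step * lambda / guard_z)` equal substeps, a
  deterministic function of the macro-step state and time (no error
  estimators, no step rejection). With the guard disabled the half-hour
  method remains bounded — the `max(P_f - Y, 0)` clipping saturates the
  instability — but shows artificial turgor oscillation early in the
  season, which is the behaviour the fixed half-hour reference method
  is on record as exhibiting.
* **Root-finding.** The pedicel sugar balance is solved by a bracketed
  Illinois iteration, tolerance 1e-10 g h^-1 on the residual, at most
  200 iterations, with a 97-point grid scan as bracketing fallback; an
  unbracketable balance aborts the step with diagnostics. Accepted
  solutions carry conservation residuals at or below 1e-9 g h^-1.
* **No-elasticity variant.** `simulation_config(elastic = FALSE)`
  replaces the turgor state by the algebraic pure-Lockhart balance
  (plastic growth equals net inflow; below yield, volume is constant),
  solved by a warm-started bracketed root at every stage evaluation.
  The elastic model converges to this variant as
  `epsilon` grows; the test suite checks 1% agreement of the turgor
  trajectory at `epsilon` = 1e5 bar.
* **Degenerate inputs.** Non-finite states or masses at the 1e-6 g
  floor abort with the offending time and state; a fruit with zero
  uptake surface exchanges nothing by convention; the soluble-solids
  floor warns rather than aborts (early-season states can transiently
  violate the partition).

## Measuring convergence

Step-halving the full default season changes harvest fresh weight by
well under 0.1%. A formal convergence-order measurement, however, needs
a smooth right-hand side, and two features of the operational model cap
the observable order: the piecewise-daily weather envelopes (midnight
seams) and the day/night kinks of the diurnal shape. The test suite
therefore measures order on a ten-day mid-season window (days 35–45,
past the stiff phase) driven by an infinitely differentiable synthetic
environment, observing order ≥ 3 (close to the nominal 4; the residual
gap comes from the `max()` switches in the growth law and partition).

## Problem sizes used by the tests

The test suite runs three full seasons (half-hour and quarter-hour
steps, two crop loads), six additional seasons inside the
one-at-a-time sensitivity checks, a 12-day elasticity-ablation window
with its compensating membrane-area refit, 100 random-state pedicel
oracle comparisons, and assorted 2–10-day windows — sizes chosen to
exercise every regime of the model (stiff early season, smooth
mid-season, post-cutoff hydrolysis) while keeping a complete run of the
suite within a few minutes on one core.

# What the synthetic tests do and do not show

The synthetic generator emulates the *structure* of the driving data —
diurnal shapes, seasonal envelopes, crop-load contrast — not any actual
weather record; the LVDT (dendrometer) fixtures are cube-law images of
the model's own trajectories with multiplicative noise. Passing tests
therefore demonstrate internal correctness (conservation, oracle
equivalence, limiting cases, stated anchors) and qualitative fidelity
(curve shapes, sensitivity signs, diurnal shrink-swell behaviour and
its dependence on elasticity). They do not validate the model against
field data, and the shipped environment coefficients should not be
mistaken for a fitted local climate.

# Known limitations

* The starch sub-model's degenerate equilibrium (above) overstates
  early/mid-season starch share and flattens the crop-load response of
  the starch *percentage*; improving it is explicitly future work in
  the model's lineage.
* Late-season turgor climbs to ~13–15 bar, an order of magnitude above
  direct measurements on ripening kiwifruit — a known artefact of the
  single-compartment formulation (no separate apoplast, no membrane
  leakage); a two-compartment revision is out of scope here.
* The pedicel closure and the advected-concentration convention are
  reconstructions; both are isolated behind options so a corrected
  supplementary formulation is a drop-in.
* One fruit, not a vine: stem water potential and phloem concentration
  are inputs, not outputs of a whole-plant balance.
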