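#' One-at-a-time sensitivity run
#'
#' Perturbs a single model parameter or input-pattern extremum up and
#' down, re-simulates, and reports the change in the quality outputs
#' (FW, DW, DM%, SS%, ST%) on the evaluation day. Parameters are
#' perturbed relatively (`delta` = 0.2 means +/-20%); input extrema
#' (`T_min`, `T_max`, `H_min`, `H_max`, `Cp_min`, `Cp_max`, `Psi_min`,
#' `Psi_max`) are shifted by the absolute `delta` in their own units,
#' moving the daily extrema of the named input while preserving the
#' diurnal shape.
#'
#' The default summary is the signed half-difference
#' `(X(+d) - X(-d))/2`; `method = "abs_mean"` instead reports the mean
#' of the two absolute changes from the base run, signed by the upward
#' perturbation.
#'
#' @param target a parameter name from [parameter_registry()] or one of
#'   the input extrema names above
#' @param delta perturbation size (relative for parameters, absolute for
#'   inputs)
#' @param params base `kiwi_params`
#' @param env base `kiwi_env_config`
#' @param config a `kiwi_sim_config`; its `t_end` is the evaluation day
#' @param method `"half_difference"` (default) or `"abs_mean"`
#' @return one-row data.frame: `target`, `base`, `delta`, `dFW`, `dDW`,
#'   `dDM_pct`, `dSS_pct`, `dST_pct`
#' @export
sensitivity_run <- function(target, delta, params = default_parameters(),
                            env = environment_config(),
                            config = simulation_config(),
                            method = c("half_difference", "abs_mean")) {
  method <- match.arg(method)
  if (delta == 0) stop("delta must be non-zero", call. = FALSE)
  input_names <- c("T_min", "T_max", "H_min", "H_max",
                   "Cp_min", "Cp_max", "Psi_min", "Psi_max")
  is_input <- target %in% input_names
  if (!is_input && !target %in% parameter_registry()$name) {
    stop("unknown sensitivity target '", target, "'", call. = FALSE)
  }

  run_with <- function(sgn) {
    if (is_input) {
      e <- env
      e$input_shifts[[target]] <- e$input_shifts[[target]] + sgn * delta
      simulate_fruit(params, e, config, quiet = TRUE)
    } else {
      p <- params
      p[[target]] <- p[[target]] * (1 + sgn * delta)
      validate_parameters(p)
      simulate_fruit(p, env, config, quiet = TRUE)
    }
  }
  outputs <- function(traj) {
    last <- traj[nrow(traj), ]
    c(FW = last$FW, DW = last$DW, DM_pct = last$DM_pct,
      SS_pct = last$SS_pct, ST_pct = last$ST_pct)
  }

  up <- outputs(run_with(1)); dn <- outputs(run_with(-1))
  ch <- if (method == "half_difference") {
    (up - dn) / 2
  } else {
    base <- outputs(run_with(0))
    sign(up - base) * (abs(up - base) + abs(dn - base)) / 2
  }
  data.frame(target = target,
             base = if (is_input) NA_real_ else params[[target]],
             delta = delta,
             dFW = ch[["FW"]], dDW = ch[["DW"]], dDM_pct = ch[["DM_pct"]],
             dSS_pct = ch[["SS_pct"]], dST_pct = ch[["ST_pct"]],
             stringsAsFactors = FALSE)
}

#' Batch sensitivity table
#'
#' Runs [sensitivity_run()] for each row of `specs` and binds the
#' results into one table in the same layout as the model's published
#' sensitivity summaries (one row per target, change in each quality
#' output on the evaluation day).
#'
#' @param specs data.frame with columns `target` and `delta`
#' @inheritParams sensitivity_run
#' @return data.frame, one row per spec
#' @export
sensitivity_table <- function(specs, params = default_parameters(),
                              env = environment_config(),
                              config = simulation_config(),
                              method = "half_difference") {
  stopifnot(all(c("target", "delta") %in% names(specs)))
  do.call(rbind, lapply(seq_len(nrow(specs)), function(i) {
    sensitivity_run(specs$target[i], specs$delta[i], params, env, config,
                    method = method)
  }))
}

#' Default sensitivity specification
#'
#' The standard one-at-a-time design: the four driving inputs perturbed
#' at their daily extrema by location/season-scale amounts, and the
#' model parameters perturbed by 20% (less where a value sits near a
#' natural limit, more where it is essentially unknown).
#'
#' @return data.frame with columns `target`, `delta`
#' @export
default_sensitivity_specs <- function() {
  rbind(
    data.frame(target = c("Cp_min", "Cp_max", "T_min", "T_max",
                          "Psi_min", "Psi_max", "H_min", "H_max"),
               delta = c(0.02, 0.02, 2, 2, 2, 0.5, 0.1, 0.03)),
    data.frame(target = c("w_0", "s_0", "P_f0", "pi_pO", "pi_fO",
                          "Y", "d_1", "d_2", "phi_1", "phi_2", "phi_k",
                          "epsilon", "K_m", "nu_1", "Q10_nu",
                          "sigma_p", "a_x", "a_p", "p_s",
                          "rho_0", "k_rho", "t_rho", "rho_inf",
                          "t_1", "t_2", "L1x", "k1x", "k2x", "L2x",
                          "Lp_inf", "k1p",
                          "u_0", "A_o", "k_o", "s_b", "k_s1", "t_r",
                          "t_h", "k_u"),
               delta = c(0.2, 0.2, 1, 0.2, 0.2,
                         0.25, 0.2, 0.2, 0.2, 0.2, 0.2,
                         0.2, 0.2, 0.2, 0.5,
                         0.05, 0.2, 0.2, 0.5,
                         0.2, 0.2, 0.22, 0.2,
                         0.2, 0.2, 0.2, 0.2, 0.2, 0.2,
                         0.2, 0.2,
                         0.2, 0.2, 0.2, 0.2, 0.2, 0.06,
                         0.2, 0.2)))
}

#' Fractional fresh weight from a diameter series
#'
#' Converts dendrometer (LVDT) diameter records to fractional fresh
#' weight via the cube law: `f(t) = (d(t)/d(t0))^3`.
#'
#' @param d data.frame with columns `t` (decimal DAFB, strictly
#'   increasing) and `diameter_mm` (> 0)
#' @return data.frame with `t` and `fw_frac`
#' @export
lvdt_fractional_weight <- function(d) {
  stopifnot(all(c("t", "diameter_mm") %in% names(d)))
  if (any(diff(d$t) <= 0)) stop("time must be strictly increasing",
                                call. = FALSE)
  if (any(d$diameter_mm <= 0)) stop("diameters must be positive",
                                    call. = FALSE)
  data.frame(t = d$t, fw_frac = (d$diameter_mm / d$diameter_mm[1])^3)
}

# per-day diurnal amplitude (max - min) of a trajectory column
#' Diurnal amplitude of a trajectory variable
#'
#' For each whole day in `[from, to)`, the difference between the daily
#' maximum and minimum of column `col`.
#'
#' @param traj a `kiwi_trajectory` (or data.frame with `t` and `col`)
#' @param from,to day window (DAFB)
#' @param col column name (default `"FW"`)
#' @return data.frame with `day` and `amplitude`
#' @export
diurnal_amplitude <- function(traj, from, to, col = "FW") {
  days <- seq(floor(from), ceiling(to) - 1)
  amp <- vapply(days, function(d) {
    sel <- traj$t >= d & traj$t < d + 1
    if (!any(sel)) return(NA_real_)
    diff(range(traj[[col]][sel]))
  }, numeric(1))
  data.frame(day = days, amplitude = amp)
}

#' Diurnal drawdown of a trajectory variable
#'
#' For each whole day in `[from, to)`, the largest intraday drop of
#' column `col` below its running maximum. Growth makes the plain daily
#' range (max - min) trend-dominated; the drawdown isolates actual
#' shrinkage, which is the signature of reversible (elastic) volume
#' change -- a model without an elastic component cannot shrink.
#'
#' @inheritParams diurnal_amplitude
#' @return data.frame with `day` and `drawdown`
#' @export
diurnal_drawdown <- function(traj, from, to, col = "FW") {
  days <- seq(floor(from), ceiling(to) - 1)
  dd <- vapply(days, function(d) {
    sel <- traj$t >= d & traj$t < d + 1
    if (!any(sel)) return(NA_real_)
    x <- traj[[col]][sel]
    max(cummax(x) - x)
  }, numeric(1))
  data.frame(day = days, drawdown = dd)
}

#' Compare simulated growth with an LVDT diameter series
#'
#' Converts the diameter series to fractional fresh weight, scales it to
#' the model's fresh weight at the anchor day (the two series are then
#' exactly equal there), and summarizes per-day diurnal amplitudes of
#' both over the comparison window.
#'
#' @param traj a `kiwi_trajectory` covering the window
#' @param d LVDT data.frame (`t`, `diameter_mm`) covering the window
#' @param anchor_day scaling anchor (DAFB)
#' @param window comparison window `c(from, to)` (DAFB)
#' @return list with `series` (aligned data.frame: `t`, `FW_model`,
#'   `FW_lvdt`), `amplitudes` (per day, both series), and
#'   `amplitude_ratio` (mean LVDT/model amplitude)
#' @export
compare_window <- function(traj, d, anchor_day = 55, window = c(55, 60)) {
  if (min(traj$t) > window[1] || max(traj$t) < window[2] ||
      min(d$t) > window[1] || max(d$t) < window[2]) {
    stop("both series must cover the comparison window", call. = FALSE)
  }
  fr <- lvdt_fractional_weight(d)
  f_model <- stats::approxfun(traj$t, traj$FW)
  f_lvdt <- stats::approxfun(fr$t, fr$fw_frac)
  scale <- f_model(anchor_day) / f_lvdt(anchor_day)
  ts <- fr$t[fr$t >= window[1] & fr$t <= window[2]]
  series <- data.frame(t = ts, FW_model = f_model(ts),
                       FW_lvdt = f_lvdt(ts) * scale)
  amp_m <- diurnal_amplitude(series, window[1], window[2], "FW_model")
  amp_l <- diurnal_amplitude(series, window[1], window[2], "FW_lvdt")
  amps <- data.frame(day = amp_m$day, model = amp_m$amplitude,
                     lvdt = amp_l$amplitude)
  list(series = series, amplitudes = amps,
       amplitude_ratio = mean(amps$lvdt / amps$model, na.rm = TRUE))
}

#' Elasticity ablation comparison
#'
#' Compares diurnal fresh-weight oscillations with and without the
#' elastic component over a mid-season window. Both runs start from the
#' same state (taken from `base_traj` at the window start). The
#' no-elasticity (pure Lockhart) run uses a compensating rescale of the
#' membrane-area fractions `a_x`, `a_p` -- a scalar multiplier fitted by
#' secant iteration so that its fresh weight at the window end matches
#' the elastic run -- mirroring how the no-elasticity model variant must
#' be refitted before its diurnal behaviour can be compared.
#'
#' @param base_traj a default-run `kiwi_trajectory` covering the window
#' @param params a `kiwi_params`
#' @param env a `kiwi_env_config`
#' @param window simulation window `c(from, to)` (DAFB)
#' @param amp_window amplitude comparison window (DAFB)
#' @param step integration step (h)
#' @param refit_iter secant iterations for the area multiplier
#' @return list with `elastic`, `rigid` (trajectories), `kappa` (fitted
#'   area multiplier), and `amplitudes` (per-day FW amplitudes)
#' @export
elasticity_ablation <- function(base_traj, params = default_parameters(),
                                env = environment_config(),
                                window = c(52, 60.5),
                                amp_window = c(55, 60), step = 0.5,
                                refit_iter = 3L) {
  i0 <- which.min(abs(base_traj$t - window[1]))
  init <- list(w = base_traj$w[i0], s = base_traj$s[i0],
               u = base_traj$u[i0], P_f = base_traj$P_f[i0])
  cfg_e <- simulation_config(t_start = base_traj$t[i0], t_end = window[2],
                             step = step, cadence = step, initial = init)
  elastic <- simulate_fruit(params, env, cfg_e, quiet = TRUE)
  target <- elastic$FW[nrow(elastic)]

  run_rigid <- function(kappa) {
    p <- params
    p$a_x <- params$a_x * kappa
    p$a_p <- params$a_p * kappa
    cfg <- cfg_e
    cfg$elastic <- FALSE
    simulate_fruit(p, env, cfg, quiet = TRUE)
  }
  # secant on log(kappa) for FW(window end) = elastic target
  k1 <- 1; r1 <- run_rigid(k1); f1 <- r1$FW[nrow(r1)] - target
  k2 <- if (f1 > 0) 0.7 else 1.4
  rigid <- r2 <- run_rigid(k2); f2 <- r2$FW[nrow(r2)] - target
  for (it in seq_len(refit_iter)) {
    if (abs(f2) < 1e-3 * target || f2 == f1) break
    k3 <- exp(log(k2) - f2 * (log(k2) - log(k1)) / (f2 - f1))
    k3 <- min(max(k3, 0.2), 5)
    k1 <- k2; f1 <- f2
    k2 <- k3; rigid <- run_rigid(k2); f2 <- rigid$FW[nrow(rigid)] - target
  }
  amp_e <- diurnal_amplitude(elastic, amp_window[1], amp_window[2])
  amp_r <- diurnal_amplitude(rigid, amp_window[1], amp_window[2])
  dd_e <- diurnal_drawdown(elastic, amp_window[1], amp_window[2])
  dd_r <- diurnal_drawdown(rigid, amp_window[1], amp_window[2])
  list(elastic = elastic, rigid = rigid, kappa = k2,
       amplitudes = data.frame(day = amp_e$day, elastic = amp_e$amplitude,
                               rigid = amp_r$amplitude),
       drawdowns = data.frame(day = dd_e$day, elastic = dd_e$drawdown,
                              rigid = dd_r$drawdown))
}
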