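#' Deterministic synthetic weather fixture
#'
#' Writes an hourly environment CSV from the synthetic generator. The
#' generator is fully deterministic given its configuration; the header
#' comment records the configuration hash inputs so identical calls give
#' byte-identical files.
#'
#' @param path output CSV path
#' @param from,to DAFB range
#' @param step_h step (hours)
#' @param cfg a `kiwi_env_config`
#' @param scenario crop-load scenario
#' @return `path`, invisibly
#' @export
generate_weather_fixture <- function(path, from = 50, to = 55, step_h = 1,
                                     cfg = environment_config(),
                                     scenario = "low") {
  df <- write_environment_csv(path, from, to, step_h, cfg, scenario)
  lines <- readLines(path)
  writeLines(c(sprintf("# kiwisim weather fixture; DAFB %g..%g step %gh scenario %s",
                       from, to, step_h, scenario), lines), path)
  invisible(path)
}

#' Synthetic LVDT diameter series from a trajectory
#'
#' Emulates a dendrometer record: diameters proportional to the cube
#' root of the simulated fresh weight, with multiplicative white noise.
#' Seeded and reproducible; the seed is restored on exit.
#'
#' @param traj a `kiwi_trajectory`
#' @param from,to window (DAFB); defaults to the trajectory's range
#' @param noise_sd multiplicative noise standard deviation on diameter
#' @param seed mandatory RNG seed
#' @param diameter_scale mm per g^(1/3)
#' @param path optional CSV output path (columns `t`, `diameter_mm`)
#' @return data.frame with `t`, `diameter_mm`
#' @export
generate_lvdt_fixture <- function(traj, from = min(traj$t),
                                  to = max(traj$t), noise_sd = 0.0005,
                                  seed, diameter_scale = 10, path = NULL) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  sel <- traj$t >= from & traj$t <= to
  t <- traj$t[sel]
  d0 <- diameter_scale * traj$FW[sel]^(1/3)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  d <- data.frame(t = t, diameter_mm = d0 * (1 + stats::rnorm(length(d0),
                                                              0, noise_sd)))
  if (!is.null(path)) {
    utils::write.csv(d, path, row.names = FALSE)
  }
  d
}

#' Random valid fruit states
#'
#' Seeded generator of physiologically plausible states for
#' property-style tests: fresh weight log-uniform over the seasonal
#' range, dry-matter fraction, starch share of dry matter, and turgor
#' drawn uniformly within observed-scale bounds. Every state satisfies
#' the fruit-state invariants (`w > 0`, `s > 0`, `0 <= u <= s`, finite
#' turgor).
#'
#' @param n number of states
#' @param seed mandatory RNG seed
#' @param t_range DAFB range to attach to the states
#' @return data.frame with `t`, `w`, `s`, `u`, `P_f`
#' @export
random_fruit_states <- function(n, seed, t_range = c(10, 170)) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  FW <- exp(stats::runif(n, log(3), log(160)))
  dm <- stats::runif(n, 0.08, 0.22)
  s <- FW * dm
  w <- FW - s
  u <- s * stats::runif(n, 0, 0.6)
  P_f <- stats::runif(n, -1, 8)
  t <- stats::runif(n, t_range[1], t_range[2])
  data.frame(t = t, w = w, s = s, u = u, P_f = P_f)
}

#' Toy mid-season configuration for fast checks
#'
#' A five-day window in the smooth cell-expansion phase with a plausible
#' mid-season initial state: the standard quick-run setup used across
#' the test-suite.
#'
#' @param t_start,t_end window (DAFB)
#' @param step integration step (h)
#' @param cadence output cadence (h)
#' @return list with `params`, `env`, `config`
#' @export
toy_season <- function(t_start = 50, t_end = 55, step = 0.5,
                       cadence = 0.5) {
  list(params = default_parameters(),
       env = environment_config(),
       config = simulation_config(t_start = t_start, t_end = t_end,
                                  step = step, cadence = cadence,
                                  initial = list(w = 30, s = 4, u = 1.5,
                                                 P_f = 3)))
}
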