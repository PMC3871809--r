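#' Environment generator configuration
#'
#' Settings for the synthetic driving inputs: hourly temperature and
#' relative humidity (a diurnal sine-exponential shape between daily
#' extrema, with day length from latitude and calendar date), vine
#' transpiration (a smooth daytime curve integrating to a seasonal daily
#' total), stem water potential (soil potential minus transpiration over
#' the soil-stem conductance), and stem phloem sucrose concentration
#' (varying between fixed daily extrema in proportion to the temperature
#' pattern, minus a crop-load offset).
#'
#' Seasonal envelopes are second-order Fourier series in calendar
#' day-of-year. The coefficients shipped here are illustrative: they are
#' hand-set to reproduce the qualitative seasonal pattern of a Bay of
#' Plenty (Southern Hemisphere) kiwifruit site -- May about 7 C cooler
#' than January, summer transpiration several times the autumn rate --
#' not fitted to any weather record.
#'
#' @param latitude site latitude (degrees; negative = Southern Hemisphere)
#' @param bloom_doy calendar day-of-year of full bloom (DAFB = 0)
#' @param T_max,T_min,H_max,H_min,Tr_daily Fourier coefficient vectors
#'   `c(a0, a1, b1, a2, b2)` for the seasonal envelopes (temperatures in
#'   C, humidities as fractions, transpiration as L/day totals)
#' @param lag_a time lag (h) by which the diurnal temperature peak
#'   follows mid-morning scaling of the sine arc
#' @param night_b dimensionless night decay constant of the
#'   sine-exponential model
#' @param P_soil soil water potential (bar)
#' @param L_soil_stem soil-to-stem water conductance (L s^-1 bar^-1)
#' @param C_min,C_max daily phloem sucrose concentration extrema (g/g)
#' @param crop_offsets named list of phloem-concentration offsets (g/g)
#'   per crop-load scenario
#' @param input_shifts named numeric vector of additive shifts applied to
#'   the daily extrema of the inputs (`T_min`, `T_max`, `H_min`, `H_max`,
#'   `Cp_min`, `Cp_max`, `Psi_min`, `Psi_max`); used by the sensitivity
#'   analysis
#' @return a list of class `kiwi_env_config`
#' @export
environment_config <- function(latitude = -37.8,
                               bloom_doy = 319,
                               T_max = .fourier_peak(19.5, 4.9, 0.5, 28),
                               T_min = .fourier_peak(9.5, 4.9, 0.5, 28),
                               H_max = .fourier_peak(0.95, 0.01, 0, 208),
                               H_min = .fourier_peak(0.62, 0.07, 0, 208),
                               Tr_daily = .fourier_peak(38, 32, 6, 28),
                               lag_a = 1.8, night_b = 2.5,
                               P_soil = -1, L_soil_stem = 0.001,
                               C_min = 0.09, C_max = 0.17,
                               crop_offsets = list(low = 0, high = 0.01),
                               input_shifts = c(T_min = 0, T_max = 0,
                                                H_min = 0, H_max = 0,
                                                Cp_min = 0, Cp_max = 0,
                                                Psi_min = 0, Psi_max = 0)) {
  if (!(C_min < C_max)) stop("C_min must be < C_max", call. = FALSE)
  if (!(L_soil_stem > 0)) stop("L_soil_stem must be > 0", call. = FALSE)
  full <- c(T_min = 0, T_max = 0, H_min = 0, H_max = 0,
            Cp_min = 0, Cp_max = 0, Psi_min = 0, Psi_max = 0)
  bad <- setdiff(names(input_shifts), names(full))
  if (length(bad)) stop("unknown input shift(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  full[names(input_shifts)] <- input_shifts
  structure(list(latitude = latitude, bloom_doy = bloom_doy,
                 T_max = T_max, T_min = T_min, H_max = H_max,
                 H_min = H_min, Tr_daily = Tr_daily,
                 lag_a = lag_a, night_b = night_b,
                 P_soil = P_soil, L_soil_stem = L_soil_stem,
                 C_min = C_min, C_max = C_max,
                 crop_offsets = crop_offsets, input_shifts = full),
            class = "kiwi_env_config")
}

# Fourier coefficients c(a0, a1, b1, a2, b2) for
# mean + amp1*cos(w(d-peak)) + amp2*cos(2w(d-peak)), w = 2*pi/365
.fourier_peak <- function(mean, amp1, amp2, peak_doy) {
  w <- 2 * pi / 365
  c(a0 = mean,
    a1 = amp1 * cos(w * peak_doy), b1 = amp1 * sin(w * peak_doy),
    a2 = amp2 * cos(2 * w * peak_doy), b2 = amp2 * sin(2 * w * peak_doy))
}

#' Evaluate a seasonal Fourier envelope
#'
#' @param doy calendar day-of-year (vectorized)
#' @param coef coefficients `c(a0, a1, b1, a2, b2)`
#' @return envelope value(s)
#' @export
seasonal_envelope <- function(doy, coef) {
  w <- 2 * pi / 365
  coef[[1]] + coef[[2]] * cos(w * doy) + coef[[3]] * sin(w * doy) +
    coef[[4]] * cos(2 * w * doy) + coef[[5]] * sin(2 * w * doy)
}

#' Day length and sun times from latitude and calendar day
#'
#' Standard solar-declination day-length formula; solar time, with noon
#' at hour 12.
#'
#' @param doy calendar day-of-year
#' @param latitude degrees (negative south)
#' @return list with `daylength`, `sunrise`, `sunset` (hours)
#' @export
day_length <- function(doy, latitude) {
  decl <- -23.44 * cos(2 * pi * (doy + 10) / 365) * pi / 180
  lat <- latitude * pi / 180
  cosH <- pmin(pmax(-tan(lat) * tan(decl), -1), 1)
  dl <- acos(cosH) * 24 / pi
  list(daylength = dl, sunrise = 12 - dl / 2, sunset = 12 + dl / 2)
}

# day-of-year for a given DAFB day
.doy_of <- function(day, cfg) (cfg$bloom_doy + day - 1) %% 365 + 1

# daily extrema after input shifts
.day_envelopes <- function(day, cfg) {
  doy <- .doy_of(day, cfg)
  sh <- cfg$input_shifts
  Tmax <- seasonal_envelope(doy, cfg$T_max) + sh[["T_max"]]
  Tmin <- seasonal_envelope(doy, cfg$T_min) + sh[["T_min"]]
  Hmax <- min(max(seasonal_envelope(doy, cfg$H_max) + sh[["H_max"]], 0), 1)
  Hmin <- min(max(seasonal_envelope(doy, cfg$H_min) + sh[["H_min"]], 0), Hmax)
  list(doy = doy, Tmax = Tmax, Tmin = Tmin, Hmax = Hmax, Hmin = Hmin,
       TrD = max(seasonal_envelope(doy, cfg$Tr_daily), 0),
       sun = day_length(doy, cfg$latitude))
}

# normalized diurnal temperature shape in [0, 1]:
# sine arc from sunrise (0) peaking after noon, exponential decay at night
.diurnal_shape <- function(hour, sun, lag_a, night_b) {
  sr <- sun$sunrise; ss <- sun$sunset
  dl <- sun$daylength; nl <- 24 - dl
  f_sunset <- sin(pi * dl / (dl + 2 * lag_a))
  if (hour >= sr && hour <= ss) {
    sin(pi * (hour - sr) / (dl + 2 * lag_a))
  } else {
    n <- if (hour > ss) hour - ss else hour + 24 - ss
    f_sunset * (exp(-night_b * n / nl) - exp(-night_b)) /
      (1 - exp(-night_b))
  }
}

#' Diurnal air temperature
#'
#' Sine-exponential diurnal model: temperature rises from the daily
#' minimum at sunrise along a sine arc whose half-period exceeds the day
#' length (so the maximum falls `lag_a` hours after mid-day), then decays
#' exponentially through the night back to the minimum at the next
#' sunrise. Daily extrema come from the seasonal envelopes.
#'
#' @param day integer DAFB day (selects the seasonal envelope)
#' @param hour decimal hour of day (0-24, solar time)
#' @param cfg a `kiwi_env_config`
#' @return temperature (deg C)
#' @export
diurnal_temperature <- function(day, hour, cfg) {
  e <- .day_envelopes(day, cfg)
  e$Tmin + (e$Tmax - e$Tmin) *
    .diurnal_shape(hour, e$sun, cfg$lag_a, cfg$night_b)
}

#' Diurnal relative humidity
#'
#' Mirror image of the temperature pattern between the daily humidity
#' extrema: humidity is at its maximum when temperature is at its
#' minimum and vice versa.
#'
#' @inheritParams diurnal_temperature
#' @return relative humidity (fraction in \[0, 1\])
#' @export
diurnal_humidity <- function(day, hour, cfg) {
  e <- .day_envelopes(day, cfg)
  f <- .diurnal_shape(hour, e$sun, cfg$lag_a, cfg$night_b)
  min(max(e$Hmax - (e$Hmax - e$Hmin) * f, 0), 1)
}

#' Diurnal vine transpiration
#'
#' A smooth non-negative daytime curve, zero at night, proportional to
#' `sin^2` over the daylight arc and scaled so its 24 h integral equals
#' the seasonal envelope's daily total.
#'
#' @inheritParams diurnal_temperature
#' @return vine transpiration (L s^-1)
#' @export
vine_transpiration <- function(day, hour, cfg) {
  e <- .day_envelopes(day, cfg)
  sr <- e$sun$sunrise; ss <- e$sun$sunset
  if (hour <= sr || hour >= ss) return(0)
  peak <- 2 * e$TrD / (e$sun$daylength * 3600)   # L/s at solar noon
  peak * sin(pi * (hour - sr) / e$sun$daylength)^2
}

#' Stem water potential from vine transpiration
#'
#' `psi_x = P_soil - Tr / L_soil_stem`: the stem is drawn below the soil
#' potential in proportion to the transpiration stream.
#'
#' @param Tr vine transpiration (L s^-1)
#' @param cfg a `kiwi_env_config`
#' @return stem water potential (bar)
#' @export
stem_water_potential <- function(Tr, cfg) {
  if (any(Tr < 0)) stop("transpiration must be >= 0", call. = FALSE)
  cfg$P_soil - Tr / cfg$L_soil_stem
}

# stem water potential at (day, hour) with extrema shifts applied:
# base daily extrema are P_soil (night) and P_soil - peak/L (solar noon);
# shifted extrema remap the base curve affinely, preserving its shape
.psi_x_at <- function(day, hour, cfg) {
  Tr <- vine_transpiration(day, hour, cfg)
  psi <- stem_water_potential(Tr, cfg)
  sh <- cfg$input_shifts
  if (sh[["Psi_min"]] == 0 && sh[["Psi_max"]] == 0) return(psi)
  e <- .day_envelopes(day, cfg)
  peak <- 2 * e$TrD / (e$sun$daylength * 3600)
  max0 <- cfg$P_soil
  min0 <- cfg$P_soil - peak / cfg$L_soil_stem
  if (min0 == max0) return(psi + sh[["Psi_max"]])
  new_max <- max0 + sh[["Psi_max"]]
  new_min <- min0 + sh[["Psi_min"]]
  new_max + (psi - max0) * (new_min - new_max) / (min0 - max0)
}

#' Stem phloem sucrose concentration
#'
#' Varies between the configured daily extrema in proportion to the
#' diurnal temperature pattern (so day length shapes the daily mean),
#' minus a crop-load offset, floored at zero. A heavier crop dilutes the
#' phloem: its offset lowers the concentration throughout the season.
#'
#' @inheritParams diurnal_temperature
#' @param crop_offset concentration offset (g/g), e.g. 0.01 for the
#'   high-crop scenario
#' @return phloem sucrose concentration (g per g solution)
#' @export
phloem_concentration <- function(day, hour, cfg, crop_offset = 0) {
  e <- .day_envelopes(day, cfg)
  f <- .diurnal_shape(hour, e$sun, cfg$lag_a, cfg$night_b)
  sh <- cfg$input_shifts
  cmin <- cfg$C_min + sh[["Cp_min"]]
  cmax <- cfg$C_max + sh[["Cp_max"]]
  max(cmin + (cmax - cmin) * f - crop_offset, 0)
}

#' Sample the environment at one time point
#'
#' Composes temperature, humidity, transpiration, stem water potential,
#' and phloem concentration at a decimal DAFB time.
#'
#' @param t decimal DAFB
#' @param cfg a `kiwi_env_config`
#' @param scenario crop-load scenario name (a key of
#'   `cfg$crop_offsets`) or a numeric offset (g/g)
#' @return list with `t`, `T`, `H_a`, `Tr`, `psi_x`, `C_p`
#' @export
sample_environment <- function(t, cfg, scenario = "low") {
  offset <- if (is.numeric(scenario)) scenario else {
    if (!scenario %in% names(cfg$crop_offsets)) {
      stop("unknown scenario '", scenario, "'", call. = FALSE)
    }
    cfg$crop_offsets[[scenario]]
  }
  day <- floor(t); hour <- 24 * (t - day)
  list(t = t,
       T = diurnal_temperature(day, hour, cfg),
       H_a = diurnal_humidity(day, hour, cfg),
       Tr = vine_transpiration(day, hour, cfg),
       psi_x = .psi_x_at(day, hour, cfg),
       C_p = phloem_concentration(day, hour, cfg, offset))
}

#' Build an environment sampling function
#'
#' Returns `function(t)` yielding the environment sample at decimal DAFB
#' `t`; the form consumed by the simulator. Deterministic given the
#' configuration.
#'
#' @inheritParams sample_environment
#' @return a function of one argument
#' @export
make_environment <- function(cfg, scenario = "low") {
  force(cfg)
  offset <- if (is.numeric(scenario)) scenario else {
    if (!scenario %in% names(cfg$crop_offsets)) {
      stop("unknown scenario '", scenario, "'", call. = FALSE)
    }
    cfg$crop_offsets[[scenario]]
  }
  sh <- cfg$input_shifts
  shifted_psi <- sh[["Psi_min"]] != 0 || sh[["Psi_max"]] != 0
  cmin <- cfg$C_min + sh[["Cp_min"]]
  cmax <- cfg$C_max + sh[["Cp_max"]]
  cache <- new.env(parent = emptyenv())

  # identical numbers to sample_environment(); the per-day envelope and
  # the shared diurnal shape are computed once instead of five times
  function(t) {
    day <- floor(t); hour <- 24 * (t - day)
    key <- as.character(day)
    e <- cache[[key]]
    if (is.null(e)) {
      e <- .day_envelopes(day, cfg)
      cache[[key]] <- e
    }
    f <- .diurnal_shape(hour, e$sun, cfg$lag_a, cfg$night_b)
    sr <- e$sun$sunrise; ss <- e$sun$sunset
    Tr <- if (hour <= sr || hour >= ss) 0 else {
      2 * e$TrD / (e$sun$daylength * 3600) *
        sin(pi * (hour - sr) / e$sun$daylength)^2
    }
    psi <- cfg$P_soil - Tr / cfg$L_soil_stem
    if (shifted_psi) {
      peak <- 2 * e$TrD / (e$sun$daylength * 3600)
      max0 <- cfg$P_soil
      min0 <- cfg$P_soil - peak / cfg$L_soil_stem
      psi <- if (min0 == max0) psi + sh[["Psi_max"]] else {
        (max0 + sh[["Psi_max"]]) +
          (psi - max0) * ((min0 + sh[["Psi_min"]]) -
                          (max0 + sh[["Psi_max"]])) / (min0 - max0)
      }
    }
    list(t = t,
         T = e$Tmin + (e$Tmax - e$Tmin) * f,
         H_a = min(max(e$Hmax - (e$Hmax - e$Hmin) * f, 0), 1),
         Tr = Tr,
         psi_x = psi,
         C_p = max(cmin + (cmax - cmin) * f - offset, 0))
  }
}

#' Write an hourly environment series to CSV
#'
#' Columns: `t` (decimal DAFB), `T` (C), `H_a` (fraction), `Tr` (L/s),
#' `psi_x` (bar), `C_p` (g/g).
#'
#' @param path output path
#' @param from,to DAFB range
#' @param step_h time step in hours
#' @inheritParams sample_environment
#' @return the data.frame written, invisibly
#' @export
write_environment_csv <- function(path, from = 0, to = 170, step_h = 1,
                                  cfg = environment_config(),
                                  scenario = "low") {
  ts <- seq(from, to, by = step_h / 24)
  rows <- lapply(ts, sample_environment, cfg = cfg, scenario = scenario)
  df <- do.call(rbind, lapply(rows, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Read and validate an hourly environment series
#'
#' Requires columns `t`, `T`, `H_a`, `C_p` and at least one of `Tr`,
#' `psi_x` (the missing one is derived through the soil-stem relation).
#' Rejects non-monotone time, humidity outside \[0, 1\], and
#' non-numeric entries, reporting the offending CSV line.
#'
#' @param path CSV path
#' @param cfg a `kiwi_env_config` (supplies `P_soil`, `L_soil_stem` when
#'   deriving the missing column)
#' @return a validated data.frame
#' @export
read_environment_csv <- function(path, cfg = environment_config()) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("t", "T", "H_a", "C_p")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("environment CSV missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!("Tr" %in% names(df)) && !("psi_x" %in% names(df))) {
    stop("environment CSV needs at least one of 'Tr', 'psi_x'",
         call. = FALSE)
  }
  for (cl in intersect(c(need, "Tr", "psi_x"), names(df))) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[cl]]))))
    if (length(bad)) {
      stop(sprintf("environment CSV line %d: non-numeric '%s'",
                   bad[1] + 1L, cl), call. = FALSE)
    }
    df[[cl]] <- as.numeric(df[[cl]])
  }
  if (any(diff(df$t) <= 0)) {
    stop(sprintf("environment CSV line %d: time not strictly increasing",
                 which(diff(df$t) <= 0)[1] + 2L), call. = FALSE)
  }
  if (any(df$H_a < 0 | df$H_a > 1)) {
    stop(sprintf("environment CSV line %d: humidity outside [0, 1]",
                 which(df$H_a < 0 | df$H_a > 1)[1] + 1L), call. = FALSE)
  }
  if (!("psi_x" %in% names(df))) {
    df$psi_x <- stem_water_potential(df$Tr, cfg)
  }
  if (!("Tr" %in% names(df))) {
    df$Tr <- pmax((cfg$P_soil - df$psi_x) * cfg$L_soil_stem, 0)
  }
  df
}

#' Environment sampling function from a measured series
#'
#' Linear interpolation of a validated hourly series (as returned by
#' [read_environment_csv()]); the same interface as
#' [make_environment()].
#'
#' @param df data.frame with columns `t`, `T`, `H_a`, `Tr`, `psi_x`, `C_p`
#' @return a function of one argument
#' @export
environment_from_series <- function(df) {
  fns <- lapply(c(T = "T", H_a = "H_a", Tr = "Tr", psi_x = "psi_x",
                  C_p = "C_p"),
                function(cl) stats::approxfun(df$t, df[[cl]], rule = 2))
  function(t) {
    list(t = t, T = fns$T(t), H_a = fns$H_a(t), Tr = fns$Tr(t),
         psi_x = fns$psi_x(t), C_p = fns$C_p(t))
  }
}
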