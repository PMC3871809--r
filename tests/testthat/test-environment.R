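cfg <- environment_config()

test_that("diurnal temperature hits its envelope anchors continuously", {
  for (day in c(20, 80, 150)) {
    e <- kiwisim:::.day_envelopes(day, cfg)
    sr <- e$sun$sunrise; ss <- e$sun$sunset
    expect_equal(diurnal_temperature(day, sr, cfg), e$Tmin,
                 tolerance = 1e-10)
    hours <- seq(0, 24, by = 0.01)
    Tmax_obs <- max(vapply(hours, function(h)
      diurnal_temperature(day, h, cfg), numeric(1)))
    expect_equal(Tmax_obs, e$Tmax, tolerance = 0.01)
    # continuity across the sunset joint
    expect_lt(abs(diurnal_temperature(day, ss - 1e-7, cfg) -
                  diurnal_temperature(day, ss + 1e-7, cfg)), 1e-4)
    # humidity is phase-inverted: maximum at the temperature minimum
    expect_equal(diurnal_humidity(day, sr, cfg), e$Hmax, tolerance = 1e-10)
    h_at_Tmax <- diurnal_humidity(day, hours[which.max(vapply(hours,
      function(h) diurnal_temperature(day, h, cfg), numeric(1)))], cfg)
    expect_equal(h_at_Tmax, e$Hmin, tolerance = 1e-3)
  }
})

test_that("transpiration is zero at night and integrates to the envelope", {
  expect_identical(vine_transpiration(60, 0, cfg), 0)
  expect_identical(vine_transpiration(60, 23.9, cfg), 0)
  e <- kiwisim:::.day_envelopes(60, cfg)
  total <- stats::integrate(Vectorize(function(h)
    vine_transpiration(60, h, cfg)), 0, 24,
    subdivisions = 2000L, rel.tol = 1e-8)$value * 3600
  expect_equal(total, e$TrD, tolerance = 1e-3 * e$TrD)
  # summer daily total is several times the autumn total
  summer <- kiwisim:::.day_envelopes(60, cfg)$TrD    # January
  autumn <- kiwisim:::.day_envelopes(180, cfg)$TrD   # May (harvest)
  expect_gt(summer / autumn, 2.5)
})

test_that("stem water potential is linear in transpiration", {
  expect_identical(stem_water_potential(0, cfg), -1)
  expect_equal(stem_water_potential(0.001, cfg), -2, tolerance = 1e-12)
  tr <- c(0, 5e-4, 1e-3, 2e-3)
  psi <- stem_water_potential(tr, cfg)
  expect_equal(diff(psi) / diff(tr), rep(-1 / cfg$L_soil_stem, 3),
               tolerance = 1e-12)
  expect_error(stem_water_potential(-0.1, cfg), ">= 0")
})

test_that("phloem concentration spans its extrema and crop offset shifts it", {
  day <- 60
  e <- kiwisim:::.day_envelopes(day, cfg)
  sr <- e$sun$sunrise
  h_peak <- sr + (e$sun$daylength + 2 * cfg$lag_a) / 2
  expect_equal(phloem_concentration(day, sr, cfg, 0), 0.09,
               tolerance = 1e-10)
  expect_equal(phloem_concentration(day, h_peak, cfg, 0), 0.17,
               tolerance = 1e-10)
  expect_equal(phloem_concentration(day, h_peak, cfg, 0.01), 0.16,
               tolerance = 1e-10)
  expect_identical(phloem_concentration(day, sr, cfg, 0.2), 0)  # floored
})

test_that("the default season reproduces the stated seasonal contrasts", {
  # mean temperature in May about 7 C below January (bloom mid-November)
  mean_T <- function(d0, d1) {
    ts <- seq(d0, d1, by = 1 / 12)
    mean(vapply(ts, function(t) sample_environment(t, cfg)$T, numeric(1)))
  }
  jan <- mean_T(48, 78); may <- mean_T(168, 198)
  expect_gt(jan - may, 6); expect_lt(jan - may, 8)

  ts <- seq(0, 170, by = 1 / 6)
  H <- vapply(ts, function(t) sample_environment(t, cfg)$H_a, numeric(1))
  P <- vapply(ts, function(t) sample_environment(t, cfg)$psi_x, numeric(1))
  expect_true(all(H >= 0 & H <= 1))
  expect_true(all(P <= -1 + 1e-12))
})

test_that("the cached sampler matches the reference composition exactly", {
  shifted <- environment_config(input_shifts = c(T_max = 1.5, Psi_min = -2,
                                                 Cp_max = 0.01))
  set.seed(9)
  ts <- runif(200, 0, 170)
  for (cc in list(cfg, shifted)) {
    f <- make_environment(cc, "high")
    for (t in ts[1:50]) {
      a <- f(t); b <- sample_environment(t, cc, "high")
      expect_identical(a, b)
    }
  }
})

test_that("input shifts move exactly the named daily extrema", {
  sh <- environment_config(input_shifts = c(T_max = 2))
  d <- 70
  e0 <- kiwisim:::.day_envelopes(d, cfg); e1 <- kiwisim:::.day_envelopes(d, sh)
  expect_equal(e1$Tmax - e0$Tmax, 2, tolerance = 1e-12)
  expect_identical(e1$Tmin, e0$Tmin)

  shp <- environment_config(input_shifts = c(Psi_min = -2, Psi_max = -0.5))
  ts <- seq(d, d + 1, by = 1 / 48)
  p0 <- vapply(ts, function(t) sample_environment(t, cfg)$psi_x, numeric(1))
  p1 <- vapply(ts, function(t) sample_environment(t, shp)$psi_x, numeric(1))
  expect_equal(max(p1) - max(p0), -0.5, tolerance = 1e-6)
  expect_equal(min(p1) - min(p0), -2, tolerance = 1e-3)
})

test_that("environment CSV round-trips and rejects malformed input", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "env.csv")
  df0 <- write_environment_csv(path, 50, 52, 1, cfg, "low")
  df1 <- read_environment_csv(path, cfg)
  expect_equal(df1$T, df0$T, tolerance = 1e-8)
  expect_equal(df1$C_p, df0$C_p, tolerance = 1e-8)

  f <- environment_from_series(df1)
  s <- f(50.5)
  ref <- sample_environment(50.5, cfg)
  expect_equal(s$T, ref$T, tolerance = 1e-6)

  bad <- df0; bad$t[3] <- bad$t[2]
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(read_environment_csv(path, cfg), "line 4.*increasing")
  bad <- df0; bad$H_a[5] <- 1.7
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(read_environment_csv(path, cfg), "line 6.*humidity|humidity")
  bad <- df0; bad$T <- NULL; bad$H_a <- NULL
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(read_environment_csv(path, cfg), "missing column")
})

test_that("day length tracks latitude and season", {
  dl_summer <- day_length(15, -37.8)$daylength   # mid-January
  dl_winter <- day_length(196, -37.8)$daylength  # mid-July
  expect_gt(dl_summer, 13.5); expect_lt(dl_summer, 15.5)
  expect_gt(dl_winter, 8.5); expect_lt(dl_winter, 10.5)
  expect_equal(day_length(80, 0)$daylength, 12, tolerance = 0.2)
})
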