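test_that("diurnal downscaling respects its anchor points and damping", {
  p <- micro_params()
  day <- list(tmin = 2, tmax = 12)
  # zero-amplitude identity
  expect_equal(hourly_air_temperature(list(tmin = 5, tmax = 5), 0:23), rep(5, 24))
  # open site hits tmax exactly at 15:00 and tmin at 05:00
  expect_equal(hourly_air_temperature(day, 15, canopy_cover = 0), 12)
  expect_equal(hourly_air_temperature(day, 5, canopy_cover = 0), 2)
  # output bounded by [tmin, tmax]
  t_all <- hourly_air_temperature(day, 0:23)
  expect_true(all(t_all >= 2 - 1e-12 & t_all <= 12 + 1e-12))
  # canopy 0.9 with damping 0.5 leaves 55% of the open-site diurnal range
  open <- hourly_air_temperature(day, 0:23, canopy_cover = 0, params = p)
  shaded <- hourly_air_temperature(day, 0:23, canopy_cover = 0.9, params = p)
  expect_equal(diff(range(shaded)), 0.55 * diff(range(open)))
  expect_error(hourly_air_temperature(day, 24), "hour")
})

test_that("precipitation partitions on the daily-mean threshold with multiplier", {
  p <- micro_params()
  expect_equal(partition_precipitation(-3, 10, p), list(rain = 0, snowfall = 10))
  expect_equal(partition_precipitation(4, 10, p), list(rain = 10, snowfall = 0))
  p15 <- micro_params(snowfall_multiplier = 1.5)
  expect_equal(partition_precipitation(-3, 10, p15)$snowfall, 15)
  expect_error(partition_precipitation(0, -1, p), "precip")
})

test_that("snowpack accumulation, interception, and degree-day melt are exact", {
  p <- micro_params(interception_coeff = 1)
  s <- snow_state(0, p)
  for (d in 1:10) s <- step_snowpack(s, 10, -5, canopy_cover = 0.3, params = p)
  expect_equal(s$swe, 70)  # 30% of every 10 mm intercepted, no melt

  p0 <- micro_params(degree_day_factor = 3)
  s2 <- step_snowpack(snow_state(20, p0), 0, 2, canopy_cover = 0, params = p0)
  expect_equal(s2$melt, 6)
  expect_equal(s2$swe, 14)
  # melt capped at available SWE, never negative
  s3 <- step_snowpack(snow_state(2, p0), 0, 10, canopy_cover = 0, params = p0)
  expect_equal(s3$swe, 0)
  expect_equal(s3$melt, 2)
  # swe and depth vanish together
  expect_identical(snow_state(0)$depth, 0)
})

test_that("snow mass balance holds exactly over randomized forcing", {
  p <- micro_params()
  for (s in 1:25) {
    withr::with_seed(s, {
      snowfall <- rgamma(365, 0.4, scale = 12) * rbinom(365, 1, 0.4)
      temp <- rnorm(365, 0, 6)
      canopy <- runif(1, 0, 0.9)
    })
    st <- snow_state(0, p)
    tot_in <- tot_out <- 0
    for (d in 1:365) {
      st <- step_snowpack(st, snowfall[d], temp[d], canopy, p)
      tot_in <- tot_in + st$snowfall_effective
      tot_out <- tot_out + st$melt
    }
    expect_lt(abs(st$swe - (tot_in - tot_out)), 1e-9)
    expect_gte(st$swe, 0)
  }
})

test_that("a single soil step preserves steady states and obeys the snow limit", {
  p <- micro_params()
  prof <- rep(4, length(p$soil_depth_nodes))
  expect_equal(step_soil_temperature(prof, 4, snow_depth = 0, params = p), prof)
  # very deep snow pins the surface boundary to 0 C regardless of air
  stepped <- step_soil_temperature(prof, -20, snow_depth = 1e6, params = p)
  expect_equal(stepped[1], 0)
  expect_error(step_soil_temperature(prof[-1], 4, params = p), "length")
  expect_error(step_soil_temperature(prof, 4, dt = -1, params = p), "dt")
  expect_error(micro_params(soil_depth_nodes = c(0, 5, 2)), "increasing")
})

test_that("the batched soil march equals repeated single steps", {
  p <- micro_params()
  tb_raw <- 5 + 8 * sin(2 * pi * (1:72) / 24)
  series <- soil_temperature_series(tb_raw, p, dt = 3600, initial = 2)
  prof <- rep(2, length(p$soil_depth_nodes))
  for (i in seq_along(tb_raw)) {
    prof <- step_soil_temperature(prof, tb_raw[i], snow_depth = 0,
                                  dt = 3600, params = p)
    expect_equal(unname(series[i, ]), prof, tolerance = 1e-10)
  }
})

test_that("interior soil temperatures obey the discrete maximum principle", {
  p <- micro_params()
  for (s in 1:10) {
    tb <- withr::with_seed(s, rnorm(500, 2, 8))
    init <- withr::with_seed(s + 100, runif(1, -5, 10))
    series <- soil_temperature_series(tb, p, initial = init)
    hi <- cummax(pmax(tb, init))
    lo <- cummin(pmin(tb, init))
    interior <- series[, -1, drop = FALSE]
    expect_true(all(interior <= hi + 1e-9))
    expect_true(all(interior >= lo - 1e-9))
  }
})

test_that("elevation enters as a pure -6.5 C/km lapse shift", {
  w <- generate_daily_weather(weather_config(precip_prob = 0, seed = 4), 2, 2000)
  m_lo <- run_microclimate(ref_site(0, elevation = 236), w)
  m_hi <- run_microclimate(ref_site(0, elevation = 1236), w)
  expect_equal(m_hi$air_temp, m_lo$air_temp - 6.5)
})

test_that("constant dry forcing drives the soil to the forcing temperature", {
  w <- data.frame(site_id = "s", year = rep(2000:2001, each = 365),
                  doy = rep(1:365, 2), tmin = 6, tmax = 6, precip = 0)
  m <- run_microclimate(ref_site(0), w)
  expect_true(all(m$swe == 0))
  last <- m[m$year == 2001 & m$doy == 365, ]
  expect_equal(max(abs(last$soil_temp_50 - 6)), 0, tolerance = 1e-6)
})

test_that("microclimate runs are deterministic and reject gappy weather", {
  w <- generate_daily_weather(weather_config(seed = 10), 2, 2000)
  m1 <- run_microclimate(ref_site(0.4), w)
  m2 <- run_microclimate(ref_site(0.4), w)
  expect_identical(m1, m2)
  w_gap <- w[-200, ]
  expect_error(run_microclimate(ref_site(0.4), w_gap), "gap-free")
})

test_that("canopy lowers peak SWE and extends snow persistence (two-run check)", {
  w <- generate_daily_weather(weather_config(seed = 6), 3, 2000)
  open <- snow_season_summary(run_microclimate(ref_site(0), w))
  shaded <- snow_season_summary(run_microclimate(ref_site(0.9), w))
  expect_true(all(open$peak_swe >= shaded$peak_swe))
  expect_true(all(shaded$last_snow_doy >= open$last_snow_doy))
  # the contrast is real, not degenerate: snow actually fell
  expect_gt(max(open$peak_swe), 0)
})

test_that("microclimate CSV round-trips through the fixed dialect", {
  w <- generate_daily_weather(weather_config(seed = 12), 2, 2000)
  m <- run_microclimate(ref_site(0.3), w)
  path <- withr::local_tempfile(fileext = ".csv")
  write_microclimate_csv(m, path)
  back <- read_microclimate_csv(path)
  expect_equal(attr(back, "depths"), attr(m, "depths"))
  expect_equal(back$air_temp, m$air_temp, tolerance = 1e-6)
  expect_equal(back$soil_temp_2.5, m$soil_temp_2.5, tolerance = 1e-6)
})
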