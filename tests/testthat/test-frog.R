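test_that("body temperature equilibrates instantly or relaxes exponentially", {
  tr0 <- frog_traits(thermal_time_constant = 0)
  expect_equal(body_temperature(1.2, tr0, previous_body_temp = -5), 1.2)

  # step 0 -> 10 C with tau = 2 h at the reference mass: after 2 h the
  # closed-form response is 10 * (1 - exp(-1))
  tr2 <- frog_traits(thermal_time_constant = 2, mass = 11.6)
  b <- 0
  for (i in 1:2) b <- body_temperature(10, tr2, previous_body_temp = b)
  expect_equal(b, 10 * (1 - exp(-1)), tolerance = 1e-10)

  # any time constant converges to a constant environment
  tr5 <- frog_traits(thermal_time_constant = 5)
  b <- -10
  for (i in 1:500) b <- body_temperature(3, tr5, previous_body_temp = b)
  expect_equal(b, 3, tolerance = 1e-8)

  # the series form matches the stepwise form
  soil <- c(0, 0, 5, 5, 5, 2, 2)
  series <- frogphen:::body_temperature_series(soil, tr2)
  b <- soil[1]
  stepwise <- vapply(soil, function(s) {
    b <<- body_temperature(s, tr2, previous_body_temp = b); b
  }, numeric(1))
  expect_equal(series, stepwise, tolerance = 1e-12)
})

test_that("gating clauses follow the trailing-window, current-day-inclusive rule", {
  tr <- frog_traits()  # gates: DOY > 65, 3 d thaw, 5 d snow-free
  warm <- rep(1, 10); bare <- rep(0, 10)
  # calendar gate alone blocks
  expect_false(check_gating_conditions(warm, bare, doy = 64, tr))
  expect_false(check_gating_conditions(warm, bare, doy = 65, tr))
  expect_true(check_gating_conditions(warm, bare, doy = 66, tr))
  # 0.0 C on days 78-80 passes a -0.16 C threshold (strict >)
  expect_true(check_gating_conditions(c(-1, -1, 0, 0, 0), bare[1:5], 80, tr))
  # boundary equality fails: body must exceed the threshold
  expect_false(check_gating_conditions(rep(-0.16, 5), bare[1:5], 80, tr))
  # snow on day 79 blocks until five clear days have accrued
  snow_hist <- c(0, 0, 0, 1, 0)           # days 76..80, snow on 79
  expect_false(check_gating_conditions(warm[1:5], snow_hist, 80, tr))
  snow_ok <- c(1, 0, 0, 0, 0, 0)          # days 79..84: clear 80..84
  expect_true(check_gating_conditions(warm[1:6], snow_ok, 84, tr))
  # histories shorter than the windows are insufficient evidence
  expect_false(check_gating_conditions(warm[1:2], bare, 80, tr))
  expect_false(check_gating_conditions(warm, bare[1:4], 80, tr))
})

test_that("favorable hours are boundary-inclusive, strictly counted, and ct_max-guarded", {
  tr1 <- frog_traits(favorable_consecutive_hours = 1, emergence_air_temp = 5)
  expect_true(favorable_for_activity(5, tr1, hours_above_count = 1))
  tr24 <- frog_traits(favorable_consecutive_hours = 24)
  expect_false(favorable_for_activity(10, tr24, hours_above_count = 23))
  expect_true(favorable_for_activity(10, tr24, hours_above_count = 24))
  hot <- frog_traits(favorable_consecutive_hours = 1, ct_max = 31)
  expect_false(favorable_for_activity(32, hot, hours_above_count = 10))
})

test_that("a frozen year yields no emergence and engineered years hit exact hours", {
  tr <- frog_traits(emergence_air_temp = 5, favorable_consecutive_hours = 3)
  frozen <- make_micro_year(air_day = rep(-5, 365), soil_day = rep(-3, 365))
  out <- simulate_frog_year(frozen, tr)
  expect_true(is.na(out$emergence_doy))

  # air warms above 5 C at 08:00 on DOY 80 only; soil thawed from DOY 70,
  # snow-free all along: with a 3-h requirement the first valid hour is 10:00
  air <- matrix(0, nrow = 24, ncol = 365)
  air[9:20, 80:365] <- 10  # hours 08..19 warm from DOY 80
  soil <- ifelse(seq_len(365) >= 70, 2, -2)
  eng <- make_micro_year(soil_day = soil, air_hourly = air)
  out2 <- simulate_frog_year(eng, tr)
  expect_identical(out2$emergence_doy, 80L)
  expect_identical(out2$emergence_hour, 10L)

  # snow persisting through DOY 150 delays emergence to DOY 155 under the
  # 5-snow-free-day trailing window (current day included)
  snow <- ifelse(seq_len(365) <= 150, 20, 0)
  warm_all <- matrix(10, nrow = 24, ncol = 365)
  eng2 <- make_micro_year(soil_day = rep(2, 365), snow_day = snow,
                          air_hourly = warm_all)
  tr1 <- frog_traits(emergence_air_temp = 5, favorable_consecutive_hours = 1)
  out3 <- simulate_frog_year(eng2, tr1)
  expect_identical(out3$emergence_doy, 155L)

  expect_error(simulate_frog_year(eng[1:100, ], tr), "complete")
})

test_that("simulate_frog_year matches the literal exhaustive-scan oracle", {
  for (s in 1:40) {
    py <- random_pond_year(s)
    fast <- simulate_frog_year(py$micro, py$traits)
    slow <- emergence_oracle(py$micro, py$traits)
    expect_identical(fast$emergence_doy, as.integer(slow["doy"]))
    expect_identical(fast$emergence_hour, as.integer(slow["hour"]))
  }
})

test_that("stricter thresholds never advance emergence and the calendar gate binds", {
  for (s in 1:12) {
    py <- random_pond_year(s + 500)
    base <- simulate_frog_year(py$micro, py$traits)$emergence_doy
    expect_true(is.na(base) || base > py$traits$earliest_doy)

    bump <- function(field, delta) {
      tr <- py$traits
      tr[[field]] <- tr[[field]] + delta
      simulate_frog_year(py$micro, tr)$emergence_doy
    }
    later_thaw <- bump("thaw_threshold_temp", 0.5)
    later_hours <- bump("favorable_consecutive_hours",
                        min(5L, 24L - py$traits$favorable_consecutive_hours))
    later_snow <- bump("snowfree_consecutive_days", 3L)
    for (later in list(later_thaw, later_hours, later_snow)) {
      if (is.na(base)) expect_true(is.na(later))
      else expect_true(is.na(later) || later >= base)
    }
  }
})
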