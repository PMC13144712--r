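# Independent exhaustive-scan oracle for the emergence rules.  Applies the
# rule definitions literally, hour by hour, with explicit loops and no shared
# code with simulate_frog_year().
emergence_oracle <- function(micro, traits) {
  micro <- micro[order(micro$doy, micro$hour), , drop = FALSE]
  depths <- attr(micro, "depths")
  soil_cols <- grep("^soil_temp_", names(micro), value = TRUE)
  if (is.null(depths)) depths <- as.numeric(sub("^soil_temp_", "", soil_cols))
  node <- which.min(abs(depths - traits$burrow_depth))
  soil <- micro[[soil_cols[node]]]
  air <- micro$air_temp
  snow <- micro$snow_depth

  # body temperature: explicit hour-by-hour relaxation
  tau <- traits$thermal_time_constant * (traits$mass / 11.6)^(1 / 3)
  n <- length(soil)
  body <- numeric(n)
  prev <- soil[1]
  for (i in seq_len(n)) {
    body[i] <- if (tau <= 0) soil[i] else
      soil[i] + (prev - soil[i]) * exp(-1 / tau)
    prev <- body[i]
  }

  daily_min_body <- vapply(1:365, function(d)
    min(body[((d - 1) * 24 + 1):(d * 24)]), numeric(1))
  daily_snow <- vapply(1:365, function(d) snow[(d - 1) * 24 + 1], numeric(1))

  count <- 0L
  for (d in 1:365) {
    gate <- d > traits$earliest_doy &&
      d >= traits$thaw_consecutive_days &&
      all(daily_min_body[(d - traits$thaw_consecutive_days + 1):d] >
            traits$thaw_threshold_temp) &&
      d >= traits$snowfree_consecutive_days &&
      all(daily_snow[(d - traits$snowfree_consecutive_days + 1):d] == 0)
    for (h in 0:23) {
      i <- (d - 1) * 24 + h + 1
      count <- if (air[i] >= traits$emergence_air_temp) count + 1L else 0L
      if (gate && count >= traits$favorable_consecutive_hours &&
          air[i] <= traits$ct_max)
        return(c(doy = d, hour = h))
    }
  }
  c(doy = NA_integer_, hour = NA_integer_)
}

# A randomized pond-year under randomized traits, for oracle-equivalence and
# monotonicity checks.  Returns the sliced analysis year plus the traits.
random_pond_year <- function(seed) {
  withr::with_seed(seed, {
    cfg <- weather_config(
      mean_annual_temp = runif(1, 6, 11),
      seasonal_amplitude = runif(1, 9, 15),
      anomaly_sd = runif(1, 1, 4),
      ar1_coeff = runif(1, 0.3, 0.85),
      precip_prob = runif(1, 0.2, 0.5),
      seed = sample.int(1e6, 1)
    )
    traits <- frog_traits(
      mass = runif(1, 7.6, 15.6),
      burrow_depth = runif(1, 2, 5),
      thaw_threshold_temp = runif(1, -0.7, 0.4),
      thaw_consecutive_days = sample(1:5, 1),
      snowfree_consecutive_days = sample(1:7, 1),
      emergence_air_temp = runif(1, 1, 10),
      favorable_consecutive_hours = sample(1:24, 1),
      thermal_time_constant = sample(c(0, runif(1, 0.5, 3)), 1)
    )
    canopy <- runif(1, 0, 0.9)
    weather <- generate_daily_weather(cfg, 2, 2000)
    micro <- run_microclimate(ref_site(canopy), weather)
    yr <- micro[micro$year == 2001, , drop = FALSE]
    attr(yr, "depths") <- attr(micro, "depths")
    list(micro = yr, traits = traits)
  })
}
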