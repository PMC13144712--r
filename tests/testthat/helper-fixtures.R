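# Fixtures are built in code: hand-constructed hourly microclimate years for
# the emergence rules, and small synthetic study set-ups for pipeline tests.

# A hand-constructed one-pond-year microclimate series.  air_temp/soil/snow
# are day-level vectors (length 365) recycled over hours unless hourly
# matrices (24 x 365) are supplied.
make_micro_year <- function(air_day = rep(10, 365), soil_day = rep(5, 365),
                            snow_day = rep(0, 365), year = 2001,
                            pond_id = "T1", air_hourly = NULL) {
  air <- if (is.null(air_hourly)) rep(air_day, each = 24) else as.numeric(air_hourly)
  out <- data.frame(
    pond_id = pond_id, year = year,
    doy = rep(1:365, each = 24), hour = rep(0:23, times = 365),
    air_temp = air,
    soil_temp_0 = air,
    soil_temp_2.5 = rep(soil_day, each = 24),
    soil_temp_5 = rep(soil_day, each = 24),
    swe = rep(snow_day, each = 24),
    snow_depth = rep(snow_day, each = 24),
    stringsAsFactors = FALSE
  )
  attr(out, "depths") <- c(0, 2.5, 5)
  out
}

# Reference pond site used when only canopy (or nothing) varies.
ref_site <- function(canopy = 0, elevation = 236, pond_id = "REF") {
  list(pond_id = pond_id, canopy_cover = canopy, elevation = elevation,
       latitude = 41.95, area = 400, leaf_area_index = 5 * canopy)
}

# Small complete study: weather, ponds, dynamic emergence.
small_study <- function(n_ponds = 4, n_years = 6, seed = 101,
                        start_year = 2000) {
  cfg <- weather_config(seed = seed)
  weather <- generate_daily_weather(cfg, n_years, start_year)
  ponds <- generate_pond_network(n_ponds, seed = seed + 1)
  config <- run_config(start_year, start_year + n_years - 1, ponds)
  list(weather = weather, ponds = ponds, config = config,
       emergence = run_simulation(config, weather))
}
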