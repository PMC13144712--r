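## Below-canopy microclimate: diurnal downscaling of daily forcing, canopy
## interception of snowfall, degree-day snowmelt, and 1-D soil heat conduction
## with snow insulation.  This is a deliberately simplified analogue of a full
## radiative microclimate model: radiation is never computed explicitly;
## canopy acts through three scalar pathways (diurnal amplitude damping,
## snowfall interception, melt damping).

#' Microclimate model parameters
#'
#' @param snow_threshold_temp Daily-mean temperature (degrees C) below which
#'   precipitation falls as snow.
#' @param snowfall_multiplier Dimensionless factor (>= 0) applied to snowfall;
#'   values above 1 emulate microsites that accumulate windthrown snow.
#' @param interception_coeff Fraction of snowfall intercepted per unit canopy
#'   cover, in `[0, 1]`.
#' @param degree_day_factor Snowmelt rate (mm SWE per degree C per day).
#' @param canopy_melt_damping Fractional reduction of the melt rate per unit
#'   canopy cover, in `[0, 1]`; shading slows spring melt.
#' @param snow_density Bulk snow density (kg m^-3) converting SWE to depth.
#' @param soil_diffusivity Soil thermal diffusivity (m^2 s^-1).
#' @param soil_depth_nodes Strictly increasing depths (cm) starting at 0 (the
#'   surface).  The defaults bracket the 2-5 cm burrow depths typical of wood
#'   frog hibernacula.
#' @param snow_insulation_scale e-folding snow depth (cm) of the air-soil
#'   decoupling: with snow depth `d` the upper boundary temperature is
#'   `w * air + (1 - w) * 0` with `w = exp(-d / scale)`, pinning the interface
#'   toward 0 degrees C under deep snow (the subnivium).
#' @param canopy_amplitude_damping Fractional reduction of the diurnal air
#'   temperature amplitude per unit canopy cover, in `[0, 1]`.
#' @param rain_absorption Fraction (in `[0, 1]`) of rain entering the soil;
#'   absorbed rain nudges the surface boundary toward the (non-freezing) rain
#'   temperature.
#' @param reference_elevation Elevation (m ASL) at which the driving weather
#'   series is valid; pond temperatures are lapse-adjusted relative to it.
#'
#' @return An object of class `micro_params` (a validated list).
#' @export
micro_params <- function(snow_threshold_temp = 0,
                         snowfall_multiplier = 1,
                         interception_coeff = 0.3,
                         degree_day_factor = 3,
                         canopy_melt_damping = 0.5,
                         snow_density = 100,
                         soil_diffusivity = 4e-7,
                         soil_depth_nodes = c(0, 2.5, 5, 10, 20, 50),
                         snow_insulation_scale = 10,
                         canopy_amplitude_damping = 0.5,
                         rain_absorption = 0.5,
                         reference_elevation = 236) {
  p <- list(
    snow_threshold_temp = snow_threshold_temp,
    snowfall_multiplier = snowfall_multiplier,
    interception_coeff = interception_coeff,
    degree_day_factor = degree_day_factor,
    canopy_melt_damping = canopy_melt_damping,
    snow_density = snow_density,
    soil_diffusivity = soil_diffusivity,
    soil_depth_nodes = soil_depth_nodes,
    snow_insulation_scale = snow_insulation_scale,
    canopy_amplitude_damping = canopy_amplitude_damping,
    rain_absorption = rain_absorption,
    reference_elevation = reference_elevation
  )
  if (p$snowfall_multiplier < 0) stop("snowfall_multiplier must be >= 0")
  if (p$interception_coeff < 0 || p$interception_coeff > 1)
    stop("interception_coeff must lie in [0, 1]")
  if (p$degree_day_factor < 0) stop("degree_day_factor must be >= 0")
  if (p$canopy_melt_damping < 0 || p$canopy_melt_damping > 1)
    stop("canopy_melt_damping must lie in [0, 1]")
  if (p$snow_density <= 0) stop("snow_density must be > 0")
  if (p$soil_diffusivity <= 0) stop("soil_diffusivity must be > 0")
  if (p$snow_insulation_scale <= 0) stop("snow_insulation_scale must be > 0")
  if (p$canopy_amplitude_damping < 0 || p$canopy_amplitude_damping > 1)
    stop("canopy_amplitude_damping must lie in [0, 1]")
  if (p$rain_absorption < 0 || p$rain_absorption > 1)
    stop("rain_absorption must lie in [0, 1]")
  z <- p$soil_depth_nodes
  if (length(z) < 2L || z[1] != 0 || any(diff(z) <= 0))
    stop("soil_depth_nodes must be strictly increasing from 0")
  structure(p, class = "micro_params")
}

#' @export
print.micro_params <- function(x, ...) {
  cat("<micro_params>\n")
  cat(sprintf("  snow   : threshold %.1f C, multiplier %.2f, interception %.2f, DDF %.1f mm/C/d, melt damping %.2f, density %.0f kg/m3\n",
              x$snow_threshold_temp, x$snowfall_multiplier, x$interception_coeff,
              x$degree_day_factor, x$canopy_melt_damping, x$snow_density))
  cat(sprintf("  soil   : kappa %.2e m2/s, nodes [%s] cm, snow insulation scale %.1f cm\n",
              x$soil_diffusivity, paste(x$soil_depth_nodes, collapse = ", "),
              x$snow_insulation_scale))
  cat(sprintf("  canopy : amplitude damping %.2f; rain absorption %.2f; reference elevation %.0f m\n",
              x$canopy_amplitude_damping, x$rain_absorption, x$reference_elevation))
  invisible(x)
}

## Diurnal shape in [-1, 1]: minimum at 05:00, maximum at 15:00.  Piecewise
## cosine because the two extremes are 10 h (rising) and 14 h (falling) apart.
diurnal_shape <- function(hour) {
  rising <- hour >= 5 & hour <= 15
  s <- numeric(length(hour))
  s[rising] <- -cos(pi * (hour[rising] - 5) / 10)
  fall <- !rising
  since_peak <- (hour[fall] - 15) %% 24
  s[fall] <- cos(pi * since_peak / 14)
  s
}

#' Hourly below-canopy air temperature from daily extremes
#'
#' Downscales one day's `tmin`/`tmax` to hours by a piecewise-sinusoidal cycle
#' with the minimum at 05:00 and the maximum at 15:00 local time.  Canopy
#' damps the departure from the daily mean by the factor
#' `1 - canopy_amplitude_damping * canopy_cover`, so the output always lies
#' within `[tmin, tmax]` and equals `tmax` at 15:00 for an open site.
#'
#' @param day A one-row data frame (or list) with `tmin` and `tmax`.
#' @param hour Integer hour(s) in 0..23.
#' @param canopy_cover Canopy cover fraction in `[0, 1]`.
#' @param params A [micro_params()].
#' @return Air temperature(s) in degrees C.
#' @export
hourly_air_temperature <- function(day, hour, canopy_cover = 0,
                                   params = micro_params()) {
  if (any(hour < 0 | hour > 23)) stop("hour must lie in 0..23")
  tmin <- day$tmin; tmax <- day$tmax
  if (any(tmax < tmin)) stop("tmax must be >= tmin")
  damp <- 1 - params$canopy_amplitude_damping * canopy_cover
  mid <- (tmin + tmax) / 2
  mid + diurnal_shape(hour) * (tmax - tmin) / 2 * damp
}

#' Partition daily precipitation into rain and snowfall
#'
#' Single-threshold partition on the daily mean temperature: below
#' `snow_threshold_temp` all precipitation falls as snow and is scaled by
#' `snowfall_multiplier`; otherwise it falls as rain.  Mass is conserved when
#' the multiplier is 1.
#'
#' @param daily_mean_temp Daily mean air temperature (degrees C).
#' @param precip Daily precipitation (mm water equivalent, >= 0).
#' @param params A [micro_params()].
#' @return A list with elements `rain` and `snowfall` (both mm SWE).
#' @export
partition_precipitation <- function(daily_mean_temp, precip,
                                    params = micro_params()) {
  if (any(precip < 0)) stop("precip must be >= 0")
  snow_day <- daily_mean_temp < params$snow_threshold_temp
  list(rain = ifelse(snow_day, 0, precip),
       snowfall = ifelse(snow_day, precip * params$snowfall_multiplier, 0))
}

#' Snowpack state
#'
#' @param swe Snow water equivalent (mm, >= 0).
#' @param params A [micro_params()] supplying `snow_density` for the
#'   SWE-to-depth conversion.
#' @return A list of class `snow_state` with `swe` (mm) and `depth` (cm);
#'   `depth = swe * 100 / snow_density`, so `swe == 0` iff `depth == 0`.
#' @export
snow_state <- function(swe = 0, params = micro_params()) {
  if (swe < 0) stop("swe must be >= 0")
  structure(list(swe = swe, depth = swe * 100 / params$snow_density),
            class = "snow_state")
}

#' Advance the snowpack by one day
#'
#' Effective snowfall is `snowfall * (1 - interception_coeff * canopy_cover)`;
#' potential melt is `degree_day_factor * max(daily_mean_temp, 0) *
#' (1 - canopy_melt_damping * canopy_cover)`, capped at the SWE available
#' after accumulation.  Mass balance is exact: the returned state carries the
#' realized `snowfall_effective` and `melt` so callers can audit
#' `sum(effective snowfall) - sum(melt) == final SWE`.
#'
#' @param state A [snow_state()].
#' @param snowfall Daily snowfall (mm SWE, before interception).
#' @param daily_mean_temp Daily mean air temperature (degrees C).
#' @param canopy_cover Canopy cover fraction in `[0, 1]`.
#' @param params A [micro_params()].
#' @return A `snow_state` with additional elements `snowfall_effective` and
#'   `melt` (both mm SWE) for the day.
#' @export
step_snowpack <- function(state, snowfall, daily_mean_temp, canopy_cover = 0,
                          params = micro_params()) {
  stopifnot(inherits(state, "snow_state"))
  if (snowfall < 0) stop("snowfall must be >= 0")
  eff <- snowfall * (1 - params$interception_coeff * canopy_cover)
  melt_pot <- params$degree_day_factor * max(daily_mean_temp, 0) *
    (1 - params$canopy_melt_damping * canopy_cover)
  available <- state$swe + eff
  melt <- min(melt_pot, available)
  new <- snow_state(available - melt, params)
  new$snowfall_effective <- eff
  new$melt <- melt
  new
}

## Vectorized daily snow season: eff and melt_pot are per-day vectors; returns
## swe, melt realized.  Same arithmetic as step_snowpack, looped.
snow_series <- function(eff, melt_pot, swe0 = 0) {
  n <- length(eff)
  swe <- numeric(n)
  melt <- numeric(n)
  s <- swe0
  for (i in seq_len(n)) {
    avail <- s + eff[i]
    m <- if (melt_pot[i] < avail) melt_pot[i] else avail
    s <- avail - m
    swe[i] <- s
    melt[i] <- m
  }
  list(swe = swe, melt = melt)
}

## Interior-node implicit operator for the 1-D heat equation on the (possibly
## non-uniform) depth grid.  Returns A = M^{-1} and avec = M^{-1} c where
## M x_new = x_old + c * Tb_new, surface node Dirichlet, bottom zero-flux.
soil_operator <- function(params, dt) {
  z <- params$soil_depth_nodes / 100  # cm -> m
  kappa <- params$soil_diffusivity
  m <- length(z) - 1L                 # interior nodes (below the surface)
  L <- matrix(0, m, m)
  cvec <- numeric(m)
  for (i in seq_len(m)) {
    j <- i + 1L  # index into full profile
    hm <- z[j] - z[j - 1L]
    if (i < m) {
      hp <- z[j + 1L] - z[j]
      a <- 2 * kappa / ((hm + hp) * hm)   # coupling upward
      cc <- 2 * kappa / ((hm + hp) * hp)  # coupling downward
      if (i > 1L) L[i, i - 1L] <- a else cvec[i] <- a
      L[i, i + 1L] <- cc
      L[i, i] <- -(a + cc)
    } else {
      a <- kappa / hm^2                   # zero-flux bottom (mirror node)
      if (i > 1L) L[i, i - 1L] <- a else cvec[i] <- a
      L[i, i] <- -a
    }
  }
  M <- diag(m) - dt * L
  A <- solve(M)
  list(A = A, avec = as.numeric(A %*% (dt * cvec)))
}

#' One implicit time step of soil heat conduction
#'
#' Advances the soil temperature profile by one backward-Euler step of the 1-D
#' heat equation `dT/dt = kappa d2T/dz2`.  The surface node is held at the
#' snow-blended boundary temperature `w * surface_air_temp + (1 - w) * 0` with
#' `w = exp(-snow_depth / snow_insulation_scale)`; the bottom boundary is
#' zero-flux.  The scheme is unconditionally stable and satisfies a discrete
#' maximum principle.
#'
#' @param profile Soil temperatures (degrees C) at `params$soil_depth_nodes`,
#'   surface first.
#' @param surface_air_temp Air temperature at the surface (degrees C).
#' @param snow_depth Snow depth (cm, >= 0).
#' @param dt Time step (s, > 0).
#' @param params A [micro_params()].
#' @return The updated profile (same length as `profile`).
#' @export
step_soil_temperature <- function(profile, surface_air_temp, snow_depth = 0,
                                  dt = 3600, params = micro_params()) {
  z <- params$soil_depth_nodes
  if (length(profile) != length(z)) stop("profile length must match soil_depth_nodes")
  if (!all(is.finite(profile))) stop("profile must be finite")
  if (dt <= 0) stop("dt must be > 0")
  if (snow_depth < 0) stop("snow_depth must be >= 0")
  w <- exp(-snow_depth / params$snow_insulation_scale)
  tb <- w * surface_air_temp
  op <- soil_operator(params, dt)
  interior <- as.numeric(op$A %*% profile[-1L] + op$avec * tb)
  c(tb, interior)
}

#' March the soil profile through an hourly boundary-temperature series
#'
#' Applies [step_soil_temperature()]'s implicit scheme over a whole series of
#' prescribed surface boundary temperatures in one pass (the operator is
#' factorized once and the recursion runs in compiled code).  Equivalent to
#' repeated single steps up to floating-point noise.
#'
#' @param boundary_temp Surface boundary temperatures (degrees C), one per
#'   time step.
#' @param params A [micro_params()].
#' @param dt Time step (s).
#' @param initial Initial temperature (degrees C) of all subsurface nodes.
#' @return A matrix with one row per time step and one `soil_temp_<depth>`
#'   column per node (the surface column repeats `boundary_temp`).
#' @export
soil_temperature_series <- function(boundary_temp, params = micro_params(),
                                    dt = 3600, initial = 0) {
  if (dt <= 0) stop("dt must be > 0")
  op <- soil_operator(params, dt)
  m <- length(params$soil_depth_nodes) - 1L
  interior <- soil_march_cpp(op$A, op$avec, boundary_temp, rep(initial, m))
  out <- cbind(boundary_temp, interior)
  colnames(out) <- paste0("soil_temp_", params$soil_depth_nodes)
  out
}

#' Run the microclimate model for one pond
#'
#' Transforms a gap-free daily weather series plus pond site descriptors into
#' an hourly series of below-canopy air temperature, snowpack state, and soil
#' temperatures.  Temperatures are first lapse-adjusted by -6.5 degrees C per
#' km of elevation relative to `params$reference_elevation`; precipitation is
#' partitioned into rain and snow, the snowpack is stepped daily, air
#' temperature is downscaled to hours with canopy amplitude damping, and the
#' soil profile is marched hourly under the snow-blended surface boundary (on
#' rain days the boundary is additionally nudged toward the non-freezing rain
#' temperature in proportion to `rain_absorption` and the rain amount).
#' Deterministic: identical inputs give identical output.
#'
#' @param site A one-row data frame or list with at least `pond_id`,
#'   `canopy_cover`, `elevation` (see [generate_pond_network()]).
#' @param weather Daily weather data frame (`year`, `doy`, `tmin`, `tmax`,
#'   `precip`), sorted and gap-free on the 365-day calendar.
#' @param params A [micro_params()].
#' @param initial_soil_temp Initial soil temperature (degrees C) for all
#'   nodes; the first simulated year is normally discarded as burn-in.
#' @return A data frame of class `microclimate_series` with columns `pond_id`,
#'   `year`, `doy`, `hour`, `air_temp`, one `soil_temp_<depth>` column per
#'   node, `swe` (mm) and `snow_depth` (cm).  A per-day forcing table is
#'   attached as attribute `"daily"` (used by the null model and for snow
#'   mass-balance audits), the node depths as attribute `"depths"`.
#' @export
run_microclimate <- function(site, weather, params = micro_params(),
                             initial_soil_temp = 0) {
  need <- c("year", "doy", "tmin", "tmax", "precip")
  if (!all(need %in% names(weather))) stop("weather lacks required columns")
  ord <- order(weather$year, weather$doy)
  weather <- weather[ord, , drop = FALSE]
  years <- unique(weather$year)
  for (y in years) {
    d <- weather$doy[weather$year == y]
    if (!identical(as.integer(d), 1:365)) {
      miss <- setdiff(1:365, d)
      stop(sprintf("weather for year %s is not gap-free (e.g. missing doy %s)",
                   y, if (length(miss)) miss[1] else "duplicated days"))
    }
  }
  canopy <- site$canopy_cover
  lapse <- -6.5 * (site$elevation - params$reference_elevation) / 1000
  tmin <- weather$tmin + lapse
  tmax <- weather$tmax + lapse
  dm <- (tmin + tmax) / 2
  n_days <- nrow(weather)

  part <- partition_precipitation(dm, weather$precip, params)
  eff <- part$snowfall * (1 - params$interception_coeff * canopy)
  melt_pot <- params$degree_day_factor * pmax(dm, 0) *
    (1 - params$canopy_melt_damping * canopy)
  sn <- snow_series(eff, melt_pot)
  swe <- sn$swe
  depth <- swe * 100 / params$snow_density

  ## hourly air temperature (24 x n_days), canopy-damped diurnal cycle
  damp <- 1 - params$canopy_amplitude_damping * canopy
  shape <- diurnal_shape(0:23)
  air <- rep(dm, each = 24L) +
    rep(shape, times = n_days) * rep((tmax - tmin) / 2 * damp, each = 24L)

  ## surface boundary: snow insulation blend toward 0 C, then rain nudge
  w <- exp(-rep(depth, each = 24L) / params$snow_insulation_scale)
  tb <- w * air
  rain <- part$rain
  wr <- params$rain_absorption * rain / (rain + 20)
  wrh <- rep(wr, each = 24L)
  train <- rep(pmax(dm, 0), each = 24L)
  tb <- (1 - wrh) * tb + wrh * train

  op <- soil_operator(params, 3600)
  n_int <- length(params$soil_depth_nodes) - 1L
  interior <- soil_march_cpp(op$A, op$avec,
                             tb, rep(initial_soil_temp, n_int))
  soil <- cbind(tb, interior)
  colnames(soil) <- paste0("soil_temp_", params$soil_depth_nodes)

  out <- data.frame(
    pond_id = site$pond_id,
    year = rep(weather$year, each = 24L),
    doy = rep(weather$doy, each = 24L),
    hour = rep(0:23, times = n_days),
    air_temp = air,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(soil))
  out$swe <- rep(swe, each = 24L)
  out$snow_depth <- rep(depth, each = 24L)

  daily <- data.frame(
    year = weather$year, doy = weather$doy,
    daily_mean_temp = dm, rain = rain,
    snowfall_effective = eff, melt = sn$melt,
    swe = swe, snow_depth = depth,
    stringsAsFactors = FALSE
  )
  attr(out, "daily") <- daily
  attr(out, "depths") <- params$soil_depth_nodes
  attr(out, "site") <- as.list(site)
  attr(out, "params") <- params
  attr(out, "initial_soil_temp") <- initial_soil_temp
  class(out) <- c("microclimate_series", "data.frame")
  out
}

#' Last snow day and peak snowpack per year
#'
#' Convenience summary used when examining the canopy-interception pathway:
#' per simulated year, the peak SWE and the last day-of-year (within spring,
#' DOY <= `spring_end`) on which snow was present (0 if the spring is
#' snow-free).
#'
#' @param micro A `microclimate_series`.
#' @param spring_end Last DOY considered part of the melt season.
#' @return A data frame with `year`, `peak_swe`, `last_snow_doy`.
#' @export
snow_season_summary <- function(micro, spring_end = 200L) {
  daily <- attr(micro, "daily")
  if (is.null(daily)) stop("microclimate series lacks the daily forcing attribute")
  res <- lapply(split(daily, daily$year), function(d) {
    spring <- d[d$doy <= spring_end, , drop = FALSE]
    with_snow <- spring$doy[spring$swe > 0]
    data.frame(year = d$year[1], peak_swe = max(d$swe),
               last_snow_doy = if (length(with_snow)) max(with_snow) else 0L)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
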