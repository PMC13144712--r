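## Synthetic daily meteorology, pond networks, and oviposition surveys.
##
## All phenology in the package runs on a 365-day calendar (DOY 1..365, leap
## days dropped): emergence dates are day-of-year quantities and a fixed-length
## year keeps multi-year series rectangular.

#' Configuration for the synthetic daily weather generator
#'
#' Describes a single-site daily temperature and precipitation climate: a
#' sinusoidal seasonal cycle in the daily mean temperature, an AR(1) anomaly
#' process superimposed on it, an optional linear warming trend, a seasonally
#' modulated diurnal range (wider in summer, as under clear summer skies), and
#' occurrence/amount precipitation drawn as Bernoulli-Gamma.
#'
#' Defaults emulate a cool temperate forest climate of southern New England:
#' annual mean near 9 degrees C, seasonal half-amplitude 12.5 degrees C with
#' the coldest day in late January, and roughly 900 mm of annual precipitation.
#'
#' @param mean_annual_temp Mean annual daily-mean temperature (degrees C).
#' @param seasonal_amplitude Half-amplitude of the seasonal cycle (degrees C,
#'   >= 0); the noise-free daily mean on the coldest day equals
#'   `mean_annual_temp - seasonal_amplitude`.
#' @param coldest_doy Day-of-year (1-based) of the seasonal minimum.
#' @param diurnal_range Annual-mean difference `tmax - tmin` (degrees C, >= 0).
#' @param diurnal_range_amplitude Seasonal modulation of the diurnal range
#'   (degrees C, in `[0, diurnal_range]`): the range is
#'   `diurnal_range - diurnal_range_amplitude` on the coldest day and
#'   `diurnal_range + diurnal_range_amplitude` half a year later.
#' @param ar1_coeff Lag-1 autocorrelation of daily temperature anomalies, in
#'   `[0, 1)`.
#' @param anomaly_sd Stationary standard deviation of the anomalies (degrees C).
#' @param warming_trend Linear trend added to the daily mean (degrees C per
#'   year relative to the first simulated year).
#' @param precip_prob Probability that any given day is wet, in `[0, 1]`.
#' @param precip_shape,precip_scale Gamma shape and scale for wet-day totals
#'   (mm water equivalent); both must be positive.
#' @param seed Integer seed making the generated series reproducible.
#'
#' @return An object of class `weather_config` (a validated list).
#' @seealso [generate_daily_weather()]
#' @export
weather_config <- function(mean_annual_temp = 9,
                           seasonal_amplitude = 12.5,
                           coldest_doy = 25,
                           diurnal_range = 10,
                           diurnal_range_amplitude = 3,
                           ar1_coeff = 0.7,
                           anomaly_sd = 3.5,
                           warming_trend = 0,
                           precip_prob = 0.35,
                           precip_shape = 0.6,
                           precip_scale = 12,
                           seed = 1L) {
  cfg <- list(
    mean_annual_temp = mean_annual_temp,
    seasonal_amplitude = seasonal_amplitude,
    coldest_doy = coldest_doy,
    diurnal_range = diurnal_range,
    diurnal_range_amplitude = diurnal_range_amplitude,
    ar1_coeff = ar1_coeff,
    anomaly_sd = anomaly_sd,
    warming_trend = warming_trend,
    precip_prob = precip_prob,
    precip_shape = precip_shape,
    precip_scale = precip_scale,
    seed = as.integer(seed)
  )
  num <- cfg[setdiff(names(cfg), "seed")]
  if (!all(vapply(num, function(x) is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))))
    stop("all weather_config values must be finite scalars")
  if (cfg$seasonal_amplitude < 0) stop("seasonal_amplitude must be >= 0")
  if (cfg$diurnal_range < 0) stop("diurnal_range must be >= 0")
  if (cfg$diurnal_range_amplitude < 0 || cfg$diurnal_range_amplitude > cfg$diurnal_range)
    stop("diurnal_range_amplitude must lie in [0, diurnal_range]")
  if (cfg$ar1_coeff < 0 || cfg$ar1_coeff >= 1) stop("ar1_coeff must lie in [0, 1)")
  if (cfg$anomaly_sd < 0) stop("anomaly_sd must be >= 0")
  if (cfg$precip_prob < 0 || cfg$precip_prob > 1) stop("precip_prob must lie in [0, 1]")
  if (cfg$precip_shape <= 0 || cfg$precip_scale <= 0)
    stop("precip_shape and precip_scale must be > 0")
  if (cfg$coldest_doy < 1 || cfg$coldest_doy > 365) stop("coldest_doy must lie in [1, 365]")
  structure(cfg, class = "weather_config")
}

#' @export
print.weather_config <- function(x, ...) {
  cat("<weather_config>\n")
  cat(sprintf("  mean annual temp : %.2f C (seasonal amplitude %.2f C, coldest DOY %d)\n",
              x$mean_annual_temp, x$seasonal_amplitude, as.integer(x$coldest_doy)))
  cat(sprintf("  anomalies        : AR(1) phi = %.2f, sd = %.2f C; trend %.3f C/yr\n",
              x$ar1_coeff, x$anomaly_sd, x$warming_trend))
  cat(sprintf("  diurnal range    : %.1f +/- %.1f C\n",
              x$diurnal_range, x$diurnal_range_amplitude))
  cat(sprintf("  precipitation    : P(wet) = %.2f, Gamma(shape %.2f, scale %.2f) mm\n",
              x$precip_prob, x$precip_shape, x$precip_scale))
  invisible(x)
}

## deterministic part of the daily mean temperature
seasonal_mean_temp <- function(cfg, year_index, doy) {
  cfg$mean_annual_temp + cfg$warming_trend * year_index -
    cfg$seasonal_amplitude * cos(2 * pi * (doy - cfg$coldest_doy) / 365.25)
}

seasonal_diurnal_range <- function(cfg, doy) {
  cfg$diurnal_range - cfg$diurnal_range_amplitude *
    cos(2 * pi * (doy - cfg$coldest_doy) / 365.25)
}

#' Generate synthetic daily weather
#'
#' Draws a gap-free multi-year daily series of minimum/maximum air temperature
#' and precipitation at one site.  The daily mean follows
#' `mean + trend * (year - start_year) - amplitude * cos(2*pi*(doy - coldest_doy)/365.25)`
#' plus a stationary AR(1) anomaly; `tmin`/`tmax` are the mean offset
#' symmetrically by half the (seasonally modulated) diurnal range, so
#' `tmax >= tmin` holds by construction.  Precipitation is
#' Bernoulli(`precip_prob`) times Gamma(`precip_shape`, `precip_scale`).
#'
#' Years are 365 days long (DOY 1..365).  The series is bit-reproducible for a
#' given `config$seed` and leaves the caller's RNG state untouched.
#'
#' @param config A [weather_config()].
#' @param n_years Number of years to generate (>= 2: one burn-in year plus at
#'   least one analysis year).
#' @param start_year First calendar year label.
#' @param site_id Site identifier stored in the output.
#'
#' @return A data frame with columns `site_id`, `year`, `doy`, `tmin`, `tmax`,
#'   `precip` (mm water equivalent).
#' @export
generate_daily_weather <- function(config, n_years, start_year = 2000L,
                                   site_id = "site1") {
  stopifnot(inherits(config, "weather_config"))
  if (!is.numeric(n_years) || length(n_years) != 1L || !is.finite(n_years) || n_years < 2)
    stop("n_years must be >= 2 (one burn-in year plus at least one analysis year)")
  n_years <- as.integer(n_years)
  n <- 365L * n_years
  year_index <- rep(seq_len(n_years) - 1L, each = 365L)
  doy <- rep(seq_len(365L), times = n_years)

  base <- seasonal_mean_temp(config, year_index, doy)
  rng <- seasonal_diurnal_range(config, doy)

  out <- withr::with_seed(config$seed, {
    if (config$anomaly_sd > 0) {
      innov_sd <- config$anomaly_sd * sqrt(1 - config$ar1_coeff^2)
      a0 <- rnorm(1L, 0, config$anomaly_sd)
      innov <- rnorm(n, 0, innov_sd)
      anom <- as.numeric(stats::filter(innov, config$ar1_coeff,
                                       method = "recursive", init = a0))
    } else {
      anom <- numeric(n)
    }
    wet <- if (config$precip_prob > 0) rbinom(n, 1L, config$precip_prob) else integer(n)
    amount <- ifelse(wet == 1L, rgamma(n, shape = config$precip_shape,
                                       scale = config$precip_scale), 0)
    list(anom = anom, precip = amount)
  })

  dm <- base + out$anom
  data.frame(
    site_id = site_id,
    year = start_year + year_index,
    doy = doy,
    tmin = dm - rng / 2,
    tmax = dm + rng / 2,
    precip = out$precip,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic pond network
#'
#' Creates `n_ponds` pond sites whose canopy covers are evenly spaced across
#' `canopy_range` (endpoints included whenever `n_ponds >= 2`), with elevations
#' scattered around `elevation_mean`, latitudes near 41.95 N, log-normal pond
#' areas, and leaf area index scaled from canopy cover.  All ponds in a
#' network share one weather series; they differ only in these site
#' descriptors.
#'
#' @param n_ponds Number of ponds (>= 1).
#' @param canopy_range Length-2 numeric `c(lo, hi)` with `0 <= lo <= hi <= 1`.
#' @param elevation_mean Mean pond elevation (m above sea level).
#' @param elevation_sd Standard deviation of elevations (m).
#' @param seed Integer seed.
#'
#' @return A data frame with columns `pond_id`, `canopy_cover`, `elevation`,
#'   `latitude`, `area`, `leaf_area_index`.
#' @export
generate_pond_network <- function(n_ponds, canopy_range = c(0, 0.9),
                                  elevation_mean = 236, elevation_sd = 15,
                                  seed = 1L) {
  if (!is.numeric(n_ponds) || length(n_ponds) != 1L || n_ponds < 1)
    stop("n_ponds must be >= 1")
  n_ponds <- as.integer(n_ponds)
  lo <- canopy_range[1]; hi <- canopy_range[2]
  if (!(is.finite(lo) && is.finite(hi) && lo >= 0 && lo <= hi && hi <= 1))
    stop("canopy_range must satisfy 0 <= lo <= hi <= 1")
  canopy <- if (n_ponds == 1L) mean(c(lo, hi)) else seq(lo, hi, length.out = n_ponds)
  withr::with_seed(as.integer(seed), {
    data.frame(
      pond_id = sprintf("P%02d", seq_len(n_ponds)),
      canopy_cover = canopy,
      elevation = rnorm(n_ponds, elevation_mean, elevation_sd),
      latitude = rnorm(n_ponds, 41.95, 0.01),
      area = rlnorm(n_ponds, meanlog = log(400), sdlog = 0.5),
      leaf_area_index = 5 * canopy,
      stringsAsFactors = FALSE
    )
  })
}

#' Generate synthetic oviposition survey records
#'
#' Turns predicted emergence dates into plausible egg-mass survey records:
#' oviposition trails emergence by a stochastic lag
#' `max(0, round(rnorm(lag_mean, lag_sd)))` days, the first survey falls on the
#' oviposition day, and subsequent surveys follow on a weekly cadence (the
#' field protocol of at-least-weekly searches after early March) with
#' geometrically declining counts of new egg masses.  Pond-years with missing
#' emergence yield no surveys.
#'
#' @param emergence Data frame with columns `pond_id`, `year`,
#'   `emergence_doy` (may be `NA`).
#' @param lag_mean,lag_sd Mean (>= 0) and standard deviation (>= 0, days) of
#'   the emergence-to-oviposition lag.
#' @param surveys_per_year Number of surveys per pond-year (>= 1).
#' @param mean_total_masses Poisson mean for the first-survey egg-mass count.
#' @param seed Integer seed.
#'
#' @return A data frame with columns `pond_id`, `year`, `survey_doy`,
#'   `new_egg_masses`; empty (zero rows) when `emergence` is empty.
#' @export
generate_observations <- function(emergence, lag_mean = 5, lag_sd = 2,
                                  surveys_per_year = 3L,
                                  mean_total_masses = 35, seed = 1L) {
  if (!is.data.frame(emergence) ||
      !all(c("pond_id", "year", "emergence_doy") %in% names(emergence)))
    stop("emergence must have columns pond_id, year, emergence_doy")
  if (lag_mean < 0) stop("lag_mean must be >= 0")
  if (lag_sd < 0) stop("lag_sd must be >= 0")
  surveys_per_year <- as.integer(surveys_per_year)
  if (surveys_per_year < 1L) stop("surveys_per_year must be >= 1")
  empty <- data.frame(pond_id = character(), year = integer(),
                      survey_doy = integer(), new_egg_masses = integer(),
                      stringsAsFactors = FALSE)
  keep <- !is.na(emergence$emergence_doy)
  em <- emergence[keep, , drop = FALSE]
  if (nrow(em) == 0L) return(empty)

  withr::with_seed(as.integer(seed), {
    rows <- lapply(seq_len(nrow(em)), function(i) {
      lag <- max(0, round(rnorm(1L, lag_mean, lag_sd)))
      first_doy <- em$emergence_doy[i] + lag
      doys <- first_doy + 7L * (seq_len(surveys_per_year) - 1L)
      doys <- doys[doys <= 365L]
      n0 <- rpois(1L, mean_total_masses) + 1L
      counts <- pmax(round(n0 * 0.5^(seq_along(doys) - 1L)), 0L)
      counts[1L] <- max(counts[1L], 1L)
      data.frame(pond_id = em$pond_id[i], year = em$year[i],
                 survey_doy = as.integer(doys),
                 new_egg_masses = as.integer(counts),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
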