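## Multi-pond, multi-year orchestration, the climatological-normals null
## model, and all validation / trend statistics.

#' Simulation run configuration
#'
#' @param start_year,end_year First and last simulated calendar years; the
#'   span must exceed `burn_in_years`.
#' @param ponds Pond network data frame (see [generate_pond_network()]).
#' @param traits A [frog_traits()].
#' @param params A [micro_params()].
#' @param burn_in_years Number of leading years discarded while state
#'   variables (soil profile, snowpack) equilibrate (default 1).
#' @param elevation_override Optional elevation (m ASL) applied to every pond,
#'   removing elevation differences (used in validation, where all ponds are
#'   set to the mean pond elevation).
#' @return An object of class `run_config`.
#' @export
run_config <- function(start_year, end_year, ponds,
                       traits = frog_traits(), params = micro_params(),
                       burn_in_years = 1L, elevation_override = NULL) {
  burn_in_years <- as.integer(burn_in_years)
  if (end_year - start_year + 1L <= burn_in_years)
    stop("simulated span must exceed burn_in_years")
  if (!is.data.frame(ponds) || nrow(ponds) < 1L)
    stop("ponds must be a non-empty data frame")
  if (!is.null(elevation_override) &&
      (!is.numeric(elevation_override) || length(elevation_override) != 1L))
    stop("elevation_override must be a single elevation in m")
  structure(list(start_year = as.integer(start_year),
                 end_year = as.integer(end_year),
                 ponds = ponds, traits = traits, params = params,
                 burn_in_years = burn_in_years,
                 elevation_override = elevation_override),
            class = "run_config")
}

## slice one year out of a microclimate series, preserving the attributes
## simulate_frog_year needs
slice_year <- function(micro, y) {
  out <- micro[micro$year == y, , drop = FALSE]
  attr(out, "depths") <- attr(micro, "depths")
  out
}

analysis_years <- function(config) {
  seq(config$start_year + config$burn_in_years, config$end_year)
}

#' Run the coupled microclimate-frog simulation for a pond network
#'
#' For each pond, runs the microclimate model over the full weather span and
#' simulates one frog per year, discarding the first `burn_in_years` years.
#' All ponds share the single weather series; they differ only in site
#' descriptors.  Deterministic: repeated calls give identical output.
#'
#' @param config A [run_config()].
#' @param weather Daily weather data frame covering
#'   `config$start_year..config$end_year`, gap-free.
#' @return A data frame of emergence records: `pond_id`, `year`,
#'   `emergence_doy`, `emergence_hour` (one row per pond per non-burn-in
#'   year; `NA` day when the frog never emerged).
#' @export
run_simulation <- function(config, weather) {
  stopifnot(inherits(config, "run_config"))
  yrs <- config$start_year:config$end_year
  if (!all(yrs %in% weather$year))
    stop("weather does not cover the configured year span")
  weather <- weather[weather$year %in% yrs, , drop = FALSE]
  keep_years <- analysis_years(config)
  rows <- lapply(seq_len(nrow(config$ponds)), function(i) {
    site <- as.list(config$ponds[i, , drop = FALSE])
    if (!is.null(config$elevation_override))
      site$elevation <- config$elevation_override
    micro <- run_microclimate(site, weather, config$params)
    do.call(rbind, lapply(keep_years, function(y)
      simulate_frog_year(slice_year(micro, y), config$traits)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Climatological-normals microclimate (null model)
#'
#' Averages the hourly air temperature of a multi-year microclimate series
#' across years at fixed (day-of-year, hour), averages the daily snow- and
#' rain-driving forcing at fixed day-of-year, then *recomputes* snowpack and
#' soil temperature on the averaged year and concatenates `n_replicates`
#' copies.  Snow is re-run rather than averaged directly because averaging
#' snow depth across years produces physically inconsistent series (e.g.
#' perpetual trace snow); this is the one place the two constructions differ.
#'
#' Snowpack and soil state are first spun up over a few repetitions of the
#' averaged year and the periodic steady-state year is extracted, so every
#' emitted replicate is bit-identical: any statistic of interannual variation
#' in downstream predictions is exactly zero.  The replicate years carry
#' consecutive labels starting at the first input year, so null predictions
#' join against observations year-by-year.
#'
#' @param micro A `microclimate_series` from [run_microclimate()] covering one
#'   or more complete years.
#' @param n_replicates Number of identical replicate years to emit.
#' @return A `microclimate_series` of `n_replicates` years.
#' @export
climatological_null <- function(micro, n_replicates) {
  daily <- attr(micro, "daily")
  params <- attr(micro, "params")
  site <- attr(micro, "site")
  init <- attr(micro, "initial_soil_temp")
  if (is.null(daily) || is.null(params) || is.null(site))
    stop("micro must be a microclimate_series produced by run_microclimate()")
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  years <- unique(micro$year)
  n_years <- length(years)
  if (nrow(micro) != n_years * 365L * 24L)
    stop("all input years must be complete (365 x 24 records)")

  ## hourly normals of air temperature at fixed (doy, hour)
  air <- matrix(micro$air_temp, nrow = 365L * 24L, ncol = n_years)
  air_bar <- rowMeans(air)

  ## daily normals of the forcing that drives snow and the soil boundary
  dm_bar <- rowMeans(matrix(daily$daily_mean_temp, nrow = 365L))
  eff_bar <- rowMeans(matrix(daily$snowfall_effective, nrow = 365L))
  rain_bar <- rowMeans(matrix(daily$rain, nrow = 365L))

  canopy <- site$canopy_cover
  melt_pot <- params$degree_day_factor * pmax(dm_bar, 0) *
    (1 - params$canopy_melt_damping * canopy)

  ## recompute snow and soil on the averaged year: spin up over a few
  ## repetitions and keep the periodic steady-state year, so that every
  ## emitted replicate is identical
  spin <- 3L
  sn <- snow_series(rep(eff_bar, spin + 1L), rep(melt_pot, spin + 1L))
  keep_d <- spin * 365L + seq_len(365L)
  swe_year <- sn$swe[keep_d]
  melt_year <- sn$melt[keep_d]
  depth_year <- swe_year * 100 / params$snow_density

  w <- exp(-rep(rep(depth_year, each = 24L), spin + 1L) /
             params$snow_insulation_scale)
  tb <- w * rep(air_bar, spin + 1L)
  wr <- params$rain_absorption * rain_bar / (rain_bar + 20)
  wrh <- rep(rep(wr, each = 24L), spin + 1L)
  train <- rep(rep(pmax(dm_bar, 0), each = 24L), spin + 1L)
  tb <- (1 - wrh) * tb + wrh * train

  op <- soil_operator(params, 3600)
  n_int <- length(params$soil_depth_nodes) - 1L
  if (is.null(init)) init <- 0
  interior_all <- soil_march_cpp(op$A, op$avec, tb, rep(init, n_int))
  keep_h <- spin * 365L * 24L + seq_len(365L * 24L)
  soil_year <- cbind(tb[keep_h], interior_all[keep_h, , drop = FALSE])

  swe <- rep(swe_year, n_replicates)
  depth <- rep(depth_year, n_replicates)
  air_all <- rep(air_bar, n_replicates)
  soil <- soil_year[rep(seq_len(365L * 24L), n_replicates), , drop = FALSE]
  colnames(soil) <- paste0("soil_temp_", params$soil_depth_nodes)

  year_labels <- min(years) + seq_len(n_replicates) - 1L
  n_days <- 365L * n_replicates
  out <- data.frame(
    pond_id = site$pond_id,
    year = rep(year_labels, each = 365L * 24L),
    doy = rep(rep(1:365, each = 24L), times = n_replicates),
    hour = rep(0:23, times = n_days),
    air_temp = air_all,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(soil))
  out$swe <- rep(swe, each = 24L)
  out$snow_depth <- rep(depth, each = 24L)

  daily_out <- data.frame(
    year = rep(year_labels, each = 365L),
    doy = rep(1:365, times = n_replicates),
    daily_mean_temp = rep(dm_bar, n_replicates),
    rain = rep(rain_bar, n_replicates),
    snowfall_effective = rep(eff_bar, n_replicates),
    melt = rep(melt_year, n_replicates),
    swe = swe, snow_depth = depth,
    stringsAsFactors = FALSE
  )
  attr(out, "daily") <- daily_out
  attr(out, "depths") <- params$soil_depth_nodes
  attr(out, "site") <- site
  attr(out, "params") <- params
  attr(out, "initial_soil_temp") <- init
  class(out) <- c("microclimate_series", "data.frame")
  out
}

#' Run the null-model simulation for a pond network
#'
#' Builds each pond's climatological-normals series from its dynamic
#' microclimate ([climatological_null()]) and simulates frog emergence on it,
#' so null predictions are identical in every non-burn-in year.
#'
#' @inheritParams run_simulation
#' @return Emergence records in the same layout as [run_simulation()].
#' @export
run_null_simulation <- function(config, weather) {
  stopifnot(inherits(config, "run_config"))
  yrs <- config$start_year:config$end_year
  if (!all(yrs %in% weather$year))
    stop("weather does not cover the configured year span")
  weather <- weather[weather$year %in% yrs, , drop = FALSE]
  keep_years <- analysis_years(config)
  rows <- lapply(seq_len(nrow(config$ponds)), function(i) {
    site <- as.list(config$ponds[i, , drop = FALSE])
    if (!is.null(config$elevation_override))
      site$elevation <- config$elevation_override
    micro <- run_microclimate(site, weather, config$params)
    null <- climatological_null(micro, n_replicates = length(yrs))
    do.call(rbind, lapply(keep_years, function(y)
      simulate_frog_year(slice_year(null, y), config$traits)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Egg-mass-weighted observation day for one pond-year
#'
#' Survey dates averaged with the number of new egg masses as weights:
#' `sum(doy * count) / sum(count)`.  When every count is zero the unweighted
#' mean of the survey days is returned (with a message), since the weighted
#' mean is undefined.
#'
#' @param surveys Data frame of surveys for a single pond-year with columns
#'   `survey_doy` and `new_egg_masses`.
#' @return The weighted mean day-of-year (numeric).
#' @export
weighted_observation_doy <- function(surveys) {
  if (nrow(surveys) < 1L) stop("at least one survey is required")
  doy <- surveys$survey_doy
  w <- surveys$new_egg_masses
  if (any(w < 0)) stop("new_egg_masses must be >= 0")
  if (sum(w) == 0) {
    message("all egg-mass counts are zero; falling back to the unweighted mean survey day")
    return(mean(doy))
  }
  sum(doy * w) / sum(w)
}

#' Collapse survey records to one observed day per pond-year
#'
#' @param observations Survey data frame (`pond_id`, `year`, `survey_doy`,
#'   `new_egg_masses`).
#' @return Data frame with `pond_id`, `year`, `observed_doy`.
#' @export
observed_emergence_doy <- function(observations) {
  if (nrow(observations) == 0L)
    return(data.frame(pond_id = character(), year = integer(),
                      observed_doy = numeric(), stringsAsFactors = FALSE))
  parts <- split(observations,
                 interaction(observations$pond_id, observations$year, drop = TRUE))
  out <- do.call(rbind, lapply(parts, function(d) {
    data.frame(pond_id = d$pond_id[1], year = d$year[1],
               observed_doy = weighted_observation_doy(d),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$pond_id, out$year), , drop = FALSE]
}

#' Validate predicted emergence against observed oviposition
#'
#' Inner-joins predictions and observations on pond-year (unmatched records
#' are counted and reported, never imputed) and computes the root mean square
#' error and mean absolute error of `predicted - observed` (days), a per-pond
#' error table, and the SD of network-mean predictions and observations
#' across trailing moving windows of years.
#'
#' @param predictions Emergence records (`pond_id`, `year`, `emergence_doy`).
#' @param observations Either survey records (with `survey_doy`,
#'   `new_egg_masses`; collapsed via [observed_emergence_doy()]) or an
#'   already-collapsed table with `observed_doy`.
#' @param window Moving-window width in years (default 5).
#' @return An object of class `validation_report`: a list with `rmse`, `mae`,
#'   `n_pairs`, `n_dropped`, `errors` (the joined pond-year table),
#'   `per_pond`, `prediction_sd` and `observation_sd` (moving-window SDs, or
#'   `NULL` when the matched years are not consecutive).
#' @export
validate_emergence <- function(predictions, observations, window = 5L) {
  obs <- if ("observed_doy" %in% names(observations)) observations
         else observed_emergence_doy(observations)
  pred <- predictions[!is.na(predictions$emergence_doy),
                      c("pond_id", "year", "emergence_doy")]
  joined <- merge(pred, obs[, c("pond_id", "year", "observed_doy")],
                  by = c("pond_id", "year"))
  n_dropped <- (nrow(pred) - nrow(joined)) + (nrow(obs) - nrow(joined))
  if (nrow(joined) == 0L) stop("no matched pond-year pairs between predictions and observations")
  joined$error <- joined$emergence_doy - joined$observed_doy
  rmse <- sqrt(mean(joined$error^2))
  mae <- mean(abs(joined$error))

  per_pond <- do.call(rbind, lapply(split(joined, joined$pond_id), function(d) {
    data.frame(pond_id = d$pond_id[1], n = nrow(d),
               mae = mean(abs(d$error)), rmse = sqrt(mean(d$error^2)),
               bias = mean(d$error), stringsAsFactors = FALSE)
  }))
  rownames(per_pond) <- NULL

  annual <- function(v) {
    means <- tapply(v, joined$year, mean)
    yrs <- as.integer(names(means))
    list(years = yrs, means = as.numeric(means),
         consecutive = length(yrs) >= 2 && all(diff(yrs) == 1L))
  }
  ap <- annual(joined$emergence_doy)
  ao <- annual(joined$observed_doy)
  pred_sd <- if (ap$consecutive && length(ap$means) >= window)
    moving_window_sd(ap$means, window) else NULL
  obs_sd <- if (ao$consecutive && length(ao$means) >= window)
    moving_window_sd(ao$means, window) else NULL

  structure(list(rmse = rmse, mae = mae, n_pairs = nrow(joined),
                 n_dropped = n_dropped, errors = joined, per_pond = per_pond,
                 prediction_sd = pred_sd, observation_sd = obs_sd,
                 window = as.integer(window)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat(sprintf("  %d matched pond-years (%d unmatched records dropped)\n",
              x$n_pairs, x$n_dropped))
  cat(sprintf("  RMSE %.2f days, MAE %.2f days\n", x$rmse, x$mae))
  if (!is.null(x$prediction_sd))
    cat(sprintf("  mean %d-yr moving-window SD: predictions %.2f, observations %.2f days\n",
                x$window, mean(x$prediction_sd), mean(x$observation_sd)))
  invisible(x)
}

#' Moving-window standard deviation of an annual series
#'
#' Sample SD within each complete trailing window of `window` consecutive
#' years; incomplete windows are omitted, so a series shorter than the window
#' yields an empty result.
#'
#' @param annual_series Numeric vector on consecutive years.
#' @param window Window width (>= 2).
#' @return Numeric vector of length `max(0, length(annual_series) - window + 1)`.
#' @export
moving_window_sd <- function(annual_series, window = 5L) {
  window <- as.integer(window)
  if (window < 2L) stop("window must be >= 2")
  n <- length(annual_series)
  if (n < window) return(numeric(0))
  vapply(window:n, function(i) sd(annual_series[(i - window + 1L):i]), numeric(1))
}

#' Regression of prediction error on scaled covariates
#'
#' Ordinary least squares of the prediction errors (days) on covariates
#' min-max scaled to `[0, 1]` (so coefficient magnitudes are comparable),
#' with percentile bootstrap confidence intervals over case resampling.
#' Constant covariates, whose scaling is undefined, are dropped with a
#' warning.  Coefficients are always reported on the scaled-covariate scale.
#'
#' @param errors Numeric response (prediction error in days), >= 10 values.
#' @param covariates Data frame of numeric covariates (e.g. drought index,
#'   egg count, canopy cover, pond area), same number of rows.
#' @param n_boot Bootstrap iterations (default 1000).
#' @param seed Integer seed for the resampling.
#' @param conf_level Confidence level (default 0.95).
#' @return A data frame with `term`, `estimate`, `ci_lower`, `ci_upper`.
#' @export
error_regression <- function(errors, covariates, n_boot = 1000L, seed = 1L,
                             conf_level = 0.95) {
  if (length(errors) < 10L) stop("at least 10 rows are required")
  if (!is.data.frame(covariates) || nrow(covariates) != length(errors))
    stop("covariates must be a data frame with one row per error")
  if (!all(vapply(covariates, is.numeric, logical(1))) ||
      !all(vapply(covariates, function(x) all(is.finite(x)), logical(1))))
    stop("covariates must be finite and numeric")

  rng <- vapply(covariates, function(x) diff(range(x)), numeric(1))
  if (any(rng == 0)) {
    warning(sprintf("dropping constant covariate(s): %s",
                    paste(names(covariates)[rng == 0], collapse = ", ")))
    covariates <- covariates[, rng > 0, drop = FALSE]
  }
  if (ncol(covariates) == 0L) stop("no non-constant covariates remain")
  scaled <- as.data.frame(lapply(covariates, function(x)
    (x - min(x)) / diff(range(x))))
  X <- cbind(`(Intercept)` = 1, as.matrix(scaled))
  fit <- lm.fit(X, errors)
  est <- fit$coefficients

  n <- length(errors)
  alpha <- (1 - conf_level) / 2
  boot <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      lm.fit(X[idx, , drop = FALSE], errors[idx])$coefficients
    }, numeric(ncol(X)))
  })
  ci <- apply(boot, 1L, quantile, probs = c(alpha, 1 - alpha), na.rm = TRUE)
  data.frame(term = names(est), estimate = unname(est),
             ci_lower = ci[1L, ], ci_upper = ci[2L, ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter records by drought severity
#'
#' Drops pond-year records from years whose Palmer Drought Severity Index
#' falls below the threshold (severe drought), since drought delays
#' oviposition relative to emergence and inflates apparent prediction error.
#'
#' @param records Data frame with a `year` column.
#' @param pdsi_by_year Named numeric vector (names are years) or data frame
#'   with `year` and `pdsi`.
#' @param threshold Minimum PDSI retained (default -2.5).
#' @return `records` restricted to years with `pdsi >= threshold`.
#' @export
drought_filter <- function(records, pdsi_by_year, threshold = -2.5) {
  if (is.data.frame(pdsi_by_year))
    pdsi_by_year <- setNames(pdsi_by_year$pdsi, pdsi_by_year$year)
  missing_years <- setdiff(unique(records$year), names(pdsi_by_year))
  if (length(missing_years))
    stop(sprintf("no PDSI value for year(s): %s",
                 paste(missing_years, collapse = ", ")))
  keep <- pdsi_by_year[as.character(records$year)] >= threshold
  records[keep, , drop = FALSE]
}

#' Decadal trend in phenology with fixed pond intercepts
#'
#' Pooled OLS of day-of-year on year with a fixed intercept per pond (the
#' estimand — the mean within-pond slope — coincides with a random-intercept,
#' common-slope mixed model), with a percentile case bootstrap for the 95%
#' confidence interval.  The slope is reported per year and per decade.
#'
#' @param observations Data frame with `pond_id`, `year`, and `doy` (observed
#'   or predicted day-of-year).
#' @param n_boot Bootstrap iterations (default 1000).
#' @param seed Integer seed for resampling.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `decadal_trend`: list with `slope_per_year`,
#'   `slope_per_decade`, `ci_per_decade`, `n`, `n_boot`.
#' @export
decadal_trend <- function(observations, n_boot = 1000L, seed = 1L,
                          conf_level = 0.95) {
  need <- c("pond_id", "year", "doy")
  if (!all(need %in% names(observations)))
    stop("observations must have columns pond_id, year, doy")
  obs <- observations[is.finite(observations$doy), need]
  if (length(unique(obs$year)) < 2L) stop("at least 2 distinct years are required")
  pond <- factor(obs$pond_id)
  X <- if (nlevels(pond) > 1L)
    stats::model.matrix(~ year + pond, data.frame(year = obs$year, pond = pond))
  else cbind(`(Intercept)` = 1, year = obs$year)
  fit <- lm.fit(X, obs$doy)
  slope <- unname(fit$coefficients["year"])

  n <- nrow(obs)
  alpha <- (1 - conf_level) / 2
  boot <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      unname(lm.fit(X[idx, , drop = FALSE], obs$doy[idx])$coefficients["year"])
    }, numeric(1))
  })
  ci <- quantile(boot, probs = c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  structure(list(slope_per_year = slope, slope_per_decade = 10 * slope,
                 ci_per_decade = 10 * ci, n = n, n_boot = as.integer(n_boot)),
            class = "decadal_trend")
}

#' @export
print.decadal_trend <- function(x, ...) {
  cat("<decadal_trend>\n")
  cat(sprintf("  %.3f days/decade (95%% CI %.3f to %.3f; %d pond-years, %d bootstraps)\n",
              x$slope_per_decade, x$ci_per_decade[1], x$ci_per_decade[2],
              x$n, x$n_boot))
  invisible(x)
}
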