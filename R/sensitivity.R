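## One-at-a-time (OAT) sensitivity analysis: each parameter takes its minimum,
## mean, and maximum while all others sit at their means; a parameter's
## importance is the range (max - min) of the three interannual-mean emergence
## dates, which captures non-monotone responses; categories attribute that
## importance to exogenous (meteorology, geography) versus endogenous
## (behavior, morphology, physiology) drivers.

PARAM_CATEGORIES <- c("meteorology", "geography", "behavior", "morphology",
                      "physiology")

#' Default OAT parameter table
#'
#' One row per parameter: its category along the exogenous-endogenous
#' gradient, the three OAT values (`min`, `mean`, `max`, with
#' `mean = (min + max) / 2`), the model field it binds to (`applies_to`,
#' `"weather."`, `"site."`, `"micro."` or `"traits."` prefixed), and whether
#' the range may be inflated (endogenous trait parameters only).
#'
#' Ranges follow published wood frog values where available — mass spans
#' 7.6-15.6 g, the favorable-hours requirement spans 1-24 h, canopy cover
#' spans the 0-0.9 of the pond network — and plausible study-region spans
#' otherwise (e.g. +/- 2 degrees C ambient temperature, +/- 100 m elevation
#' about the 236 m mean pond elevation).
#'
#' @return A data frame with columns `name`, `category`, `min`, `mean`,
#'   `max`, `applies_to`, `inflatable`.
#' @export
default_parameter_table <- function() {
  tab <- rbind(
    data.frame(name = "temp_offset", category = "meteorology",
               min = -2, max = 2, applies_to = "weather.temp_offset",
               inflatable = FALSE),
    data.frame(name = "precip_multiplier", category = "meteorology",
               min = 0.5, max = 1.5, applies_to = "weather.precip_multiplier",
               inflatable = FALSE),
    data.frame(name = "snowfall_multiplier", category = "meteorology",
               min = 0.5, max = 1.5, applies_to = "micro.snowfall_multiplier",
               inflatable = FALSE),
    data.frame(name = "canopy_cover", category = "geography",
               min = 0, max = 0.9, applies_to = "site.canopy_cover",
               inflatable = FALSE),
    data.frame(name = "elevation", category = "geography",
               min = 136, max = 336, applies_to = "site.elevation",
               inflatable = FALSE),
    data.frame(name = "leaf_area_index", category = "geography",
               min = 0, max = 5, applies_to = "site.leaf_area_index",
               inflatable = FALSE),
    data.frame(name = "emergence_air_temp", category = "behavior",
               min = 1, max = 10, applies_to = "traits.emergence_air_temp",
               inflatable = TRUE),
    data.frame(name = "favorable_consecutive_hours", category = "behavior",
               min = 1, max = 24,
               applies_to = "traits.favorable_consecutive_hours",
               inflatable = TRUE),
    data.frame(name = "burrow_depth", category = "behavior",
               min = 2, max = 5, applies_to = "traits.burrow_depth",
               inflatable = TRUE),
    data.frame(name = "mass", category = "morphology",
               min = 7.6, max = 15.6, applies_to = "traits.mass",
               inflatable = TRUE),
    data.frame(name = "thaw_threshold_temp", category = "physiology",
               min = -0.66, max = 0.34,
               applies_to = "traits.thaw_threshold_temp", inflatable = TRUE),
    data.frame(name = "thermal_time_constant", category = "physiology",
               min = 0, max = 2, applies_to = "traits.thermal_time_constant",
               inflatable = TRUE)
  )
  tab$mean <- (tab$min + tab$max) / 2
  tab <- tab[, c("name", "category", "min", "mean", "max", "applies_to",
                 "inflatable")]
  validate_parameter_table(tab)
  tab
}

validate_parameter_table <- function(params) {
  need <- c("name", "category", "min", "mean", "max", "applies_to", "inflatable")
  if (!is.data.frame(params) || !all(need %in% names(params)))
    stop("parameter table must have columns name, category, min, mean, max, applies_to, inflatable")
  if (anyDuplicated(params$name)) stop("duplicate parameter names")
  if (!all(params$category %in% PARAM_CATEGORIES))
    stop(sprintf("category must be one of: %s",
                 paste(PARAM_CATEGORIES, collapse = ", ")))
  bad <- params$min > params$mean | params$mean > params$max
  if (any(bad))
    stop(sprintf("min <= mean <= max violated for: %s",
                 paste(params$name[bad], collapse = ", ")))
  invisible(params)
}

#' Build the OAT run plan
#'
#' One shared baseline run with every parameter at its mean, plus a low and a
#' high run per parameter with nonzero span: `2P + 1` distinct simulations
#' for `P` such parameters.  Parameters with `min == max` contribute no runs
#' beyond the baseline.  The plan is an explicit table and round-trips
#' through CSV serialization unchanged.
#'
#' @param params A parameter table (see [default_parameter_table()]).
#' @return A data frame with columns `run_id`, `parameter`, `level`
#'   (`"baseline"`, `"low"`, `"high"`), `value`; attribute `"params"` holds
#'   the validated table.
#' @export
oat_design <- function(params) {
  validate_parameter_table(params)
  if (nrow(params) < 1L) stop("at least one parameter is required")
  rows <- list(data.frame(run_id = "baseline", parameter = NA_character_,
                          level = "baseline", value = NA_real_,
                          stringsAsFactors = FALSE))
  for (i in seq_len(nrow(params))) {
    if (params$min[i] == params$max[i]) next
    nm <- params$name[i]
    rows[[length(rows) + 1L]] <-
      data.frame(run_id = paste0(nm, "_low"), parameter = nm, level = "low",
                 value = params$min[i], stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <-
      data.frame(run_id = paste0(nm, "_high"), parameter = nm, level = "high",
                 value = params$max[i], stringsAsFactors = FALSE)
  }
  plan <- do.call(rbind, rows)
  attr(plan, "params") <- params
  plan
}

## named vector of parameter values for one run: all means, with the run's
## parameter overridden
run_values <- function(params, parameter = NA, value = NA) {
  v <- setNames(params$mean, params$name)
  if (!is.na(parameter)) v[parameter] <- value
  v
}

#' Build an emergence simulator over the OAT parameter space
#'
#' Returns a deterministic closure mapping a full named vector of parameter
#' values (one per row of `params`) to the simulation response.  The weather
#' series is generated once from `weather_config`; runs use a single
#' reference pond whose site descriptors are governed by the parameter table.
#' Values bind by the `applies_to` prefix: `weather.temp_offset` is added to
#' `tmin`/`tmax`, `weather.precip_multiplier` scales precipitation,
#' `micro.*`, `site.*` and `traits.*` replace the corresponding fields.
#'
#' @param params Parameter table; its `applies_to` column drives the binding.
#' @param weather_config A [weather_config()] for the shared forcing.
#' @param n_years Simulated years including `burn_in_years`.
#' @param start_year First simulated year.
#' @param burn_in_years Discarded leading years (default 1).
#' @param base_site Reference pond (defaults to a mid-canopy pond at the
#'   236 m reference elevation).
#' @param base_traits,base_params Baseline [frog_traits()] / [micro_params()]
#'   for fields the table does not govern.
#' @param response `"emergence"` for annual emergence DOYs (one per
#'   non-burn-in year), `"microclimate"` for the named vector of interannual
#'   means of annual minimum/maximum hourly below-canopy air and topsoil
#'   temperature (`air_min`, `air_max`, `soil_min`, `soil_max`).
#' @return A function `f(values)` where `values` is a full named parameter
#'   vector.
#' @export
oat_simulator <- function(params, weather_config, n_years = 10L,
                          start_year = 2000L, burn_in_years = 1L,
                          base_site = NULL, base_traits = frog_traits(),
                          base_params = micro_params(),
                          response = c("emergence", "microclimate")) {
  validate_parameter_table(params)
  response <- match.arg(response)
  weather0 <- generate_daily_weather(weather_config, n_years, start_year)
  if (is.null(base_site))
    base_site <- list(pond_id = "REF", canopy_cover = 0.45,
                      elevation = base_params$reference_elevation,
                      latitude = 41.95, area = 400, leaf_area_index = 2.25)
  binding <- strsplit(params$applies_to, ".", fixed = TRUE)
  names(binding) <- params$name
  keep_years <- seq(start_year + burn_in_years, start_year + n_years - 1L)

  function(values) {
    if (!all(params$name %in% names(values)))
      stop("values must name every parameter in the table")
    weather <- weather0
    site <- base_site
    traits <- base_traits
    mp <- base_params
    for (nm in params$name) {
      b <- binding[[nm]]
      v <- unname(values[[nm]])
      switch(b[1],
        weather = {
          if (b[2] == "temp_offset") {
            weather$tmin <- weather$tmin + v
            weather$tmax <- weather$tmax + v
          } else if (b[2] == "precip_multiplier") {
            weather$precip <- weather$precip * v
          } else stop(sprintf("unknown weather binding: %s", b[2]))
        },
        site = site[[b[2]]] <- v,
        micro = mp[[b[2]]] <- v,
        traits = {
          v2 <- if (b[2] %in% c("favorable_consecutive_hours",
                                "thaw_consecutive_days",
                                "snowfree_consecutive_days",
                                "earliest_doy")) as.integer(round(v)) else v
          traits[[b[2]]] <- v2
        },
        stop(sprintf("unknown binding prefix: %s", b[1]))
      )
    }
    micro <- run_microclimate(site, weather, mp)
    if (response == "microclimate") {
      topsoil_col <- paste0("soil_temp_", mp$soil_depth_nodes[2])
      per_year <- lapply(split(seq_len(nrow(micro)), micro$year), function(idx) {
        c(air_min = min(micro$air_temp[idx]),
          air_max = max(micro$air_temp[idx]),
          soil_min = min(micro[[topsoil_col]][idx]),
          soil_max = max(micro[[topsoil_col]][idx]))
      })
      keep <- as.character(keep_years)
      return(rowMeans(do.call(cbind, per_year[keep])))
    }
    vapply(keep_years, function(y)
      as.numeric(simulate_frog_year(slice_year(micro, y), traits)$emergence_doy),
      numeric(1))
  }
}

#' Execute an OAT plan
#'
#' Runs the simulator once for the shared baseline and once per low/high run,
#' summarizes each run's annual emergence dates to their interannual mean
#' (pond-years with missing emergence are excluded from the mean and
#' counted), and reports each parameter's importance as the range between the
#' lowest and highest of its three means — capturing non-monotone responses.
#' A parameter whose three runs all fail to emerge has undefined importance
#' and is flagged, never silently zeroed.  Relative importance (`share_pct`)
#' is each parameter's importance as a percentage of the summed importance.
#'
#' @param plan An [oat_design()] plan.
#' @param simulator A function mapping a full named parameter vector to a
#'   numeric vector of annual responses (see [oat_simulator()]).
#' @return A data frame with one row per parameter: `parameter`, `category`,
#'   `mean_low`, `mean_mid`, `mean_high`, `n_missing` (non-emerging years
#'   across the three runs), `importance` (days), `share_pct`, `flagged`.
#' @export
run_oat <- function(plan, simulator) {
  params <- attr(plan, "params")
  if (is.null(params)) stop("plan must carry its parameter table (use oat_design())")

  summarize_run <- function(x) {
    list(mean = if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE),
         n_missing = sum(is.na(x)))
  }
  ## the all-means baseline is executed exactly once and shared
  base <- summarize_run(simulator(run_values(params)))

  res <- lapply(seq_len(nrow(params)), function(i) {
    nm <- params$name[i]
    if (params$min[i] == params$max[i]) {
      lo <- hi <- base
    } else {
      lo <- summarize_run(simulator(run_values(params, nm, params$min[i])))
      hi <- summarize_run(simulator(run_values(params, nm, params$max[i])))
    }
    means <- c(lo$mean, base$mean, hi$mean)
    flagged <- all(is.na(means))
    importance <- if (flagged) NA_real_ else
      max(means, na.rm = TRUE) - min(means, na.rm = TRUE)
    data.frame(parameter = nm, category = params$category[i],
               mean_low = lo$mean, mean_mid = base$mean, mean_high = hi$mean,
               n_missing = lo$n_missing + base$n_missing + hi$n_missing,
               importance = importance, flagged = flagged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  total <- sum(out$importance, na.rm = TRUE)
  out$share_pct <- if (total > 0) 100 * out$importance / total else NA_real_
  rownames(out) <- NULL
  out
}

#' Attribute importance to exogenous/endogenous categories
#'
#' Sums per-parameter importance within each category and expresses it as a
#' percentage of the total importance across all parameters, so the shares
#' sum to 100.  With zero total importance the shares are undefined and
#' reported as `NA` (with a warning).
#'
#' @param results Output of [run_oat()] (rows with `NA` importance are
#'   excluded).
#' @return A data frame with `category`, `importance` (days), `share_pct`.
#' @export
category_attribution <- function(results) {
  ok <- results[!is.na(results$importance), , drop = FALSE]
  if (nrow(ok) == 0L) stop("no parameter has finite importance")
  imp <- tapply(ok$importance, factor(ok$category, levels = PARAM_CATEGORIES), sum)
  imp[is.na(imp)] <- 0
  total <- sum(imp)
  share <- if (total > 0) 100 * imp / total else {
    warning("total importance is zero; category shares are undefined")
    rep(NA_real_, length(imp))
  }
  data.frame(category = names(imp), importance = as.numeric(imp),
             share_pct = as.numeric(share), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Inflate trait ranges about their means
#'
#' Widens the `min`/`max` of inflatable (endogenous trait) parameters to
#' represent broader phenotypes or plasticity than the empirical ranges.
#' `inflation` is either a scalar factor applied about the mean
#' (`min' = mean - f * (mean - min)`, `max' = mean + f * (max - mean)`) or a
#' named list of explicit `c(min, max)` overrides (e.g. widening the
#' favorable-hours requirement from 1-24 h to 1-96 h).  Means are unchanged;
#' widened minima of non-negative parameters are clipped at `lower_bound`.
#'
#' @param params Parameter table.
#' @param inflation Scalar factor (>= 0) or named list of `c(min, max)`.
#' @param lower_bound Physical floor applied when clipping widened minima of
#'   parameters whose original minimum is non-negative (default 0).
#' @return The table with widened ranges.
#' @export
inflate_trait_ranges <- function(params, inflation, lower_bound = 0) {
  validate_parameter_table(params)
  out <- params
  if (is.list(inflation)) {
    for (nm in names(inflation)) {
      i <- match(nm, out$name)
      if (is.na(i)) stop(sprintf("unknown parameter: %s", nm))
      if (!out$inflatable[i])
        stop(sprintf("parameter %s is not inflatable", nm))
      rng <- inflation[[nm]]
      if (length(rng) != 2L || rng[1] > rng[2])
        stop(sprintf("override for %s must be c(min, max) with min <= max", nm))
      out$min[i] <- rng[1]
      out$max[i] <- rng[2]
      # the mean stays put; widen it into range only if the override excludes it
      out$mean[i] <- min(max(out$mean[i], rng[1]), rng[2])
    }
  } else {
    f <- inflation
    if (!is.numeric(f) || length(f) != 1L || f < 0)
      stop("inflation must be a non-negative scalar factor or a named list")
    idx <- which(out$inflatable)
    for (i in idx) {
      new_min <- out$mean[i] - f * (out$mean[i] - out$min[i])
      new_max <- out$mean[i] + f * (out$max[i] - out$mean[i])
      if (out$min[i] >= lower_bound) new_min <- max(new_min, lower_bound)
      if (new_min > new_max) stop("inflation produced min > max")
      out$min[i] <- new_min
      out$max[i] <- new_max
    }
  }
  validate_parameter_table(out)
  out
}

#' Microclimate-temperature sensitivity to exogenous parameters
#'
#' Runs the OAT machinery with the microclimate itself as the response: per
#' parameter, the importance (range over the three runs) of the interannual
#' mean annual minimum and maximum of hourly below-canopy air temperature and
#' topsoil temperature — four importance values per parameter.  Only
#' meteorological and geographical parameters are admitted; endogenous frog
#' parameters are irrelevant to the microclimate and are rejected.
#'
#' @param params Parameter table restricted to categories `meteorology` and
#'   `geography`.
#' @param simulator A multi-response simulator from
#'   `oat_simulator(..., response = "microclimate")`.
#' @return A data frame with one row per parameter: `parameter`, `category`,
#'   and importance columns `air_min`, `air_max`, `soil_min`, `soil_max`.
#' @export
microclimate_sensitivity <- function(params, simulator) {
  validate_parameter_table(params)
  if (!all(params$category %in% c("meteorology", "geography")))
    stop("only meteorological and geographical parameters are admitted")
  base <- simulator(run_values(params))
  vars <- c("air_min", "air_max", "soil_min", "soil_max")
  res <- lapply(seq_len(nrow(params)), function(i) {
    nm <- params$name[i]
    if (params$min[i] == params$max[i]) {
      lo <- hi <- base
    } else {
      lo <- simulator(run_values(params, nm, params$min[i]))
      hi <- simulator(run_values(params, nm, params$max[i]))
    }
    imp <- vapply(vars, function(v) {
      vals <- c(lo[[v]], base[[v]], hi[[v]])
      max(vals) - min(vals)
    }, numeric(1))
    cbind(data.frame(parameter = nm, category = params$category[i],
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(imp)))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
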