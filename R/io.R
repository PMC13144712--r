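## Tidy CSV writers/readers with fixed headers, and a YAML configuration
## dialect for the generator and model settings.

write_checked <- function(x, path, cols) {
  if (!all(cols %in% names(x))) stop(sprintf("missing columns: %s",
                                             paste(setdiff(cols, names(x)), collapse = ", ")))
  write.csv(x[, cols, drop = FALSE], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_checked <- function(path, cols) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(cols %in% names(x))) stop(sprintf("%s lacks columns: %s", path,
                                             paste(setdiff(cols, names(x)), collapse = ", ")))
  x
}

#' Read and write the package's tidy CSV formats
#'
#' Fixed-header CSV serialization for the main tabular objects: daily weather
#' (`site_id, year, doy, tmin, tmax, precip`), pond networks
#' (`pond_id, canopy_cover, elevation, latitude, area, leaf_area_index`),
#' survey observations (`pond_id, year, survey_doy, new_egg_masses`),
#' emergence records (`pond_id, year, emergence_doy, emergence_hour`), and
#' hourly microclimate series (`pond_id, year, doy, hour, air_temp,
#' soil_temp_<depth>..., swe, snow_depth`).
#'
#' @param x The object to write.
#' @param path File path.
#' @return Writers return `path` invisibly; readers return a data frame.
#' @name frogphen_io
NULL

#' @rdname frogphen_io
#' @export
write_weather_csv <- function(x, path)
  write_checked(x, path, c("site_id", "year", "doy", "tmin", "tmax", "precip"))

#' @rdname frogphen_io
#' @export
read_weather_csv <- function(path)
  read_checked(path, c("site_id", "year", "doy", "tmin", "tmax", "precip"))

#' @rdname frogphen_io
#' @export
write_ponds_csv <- function(x, path)
  write_checked(x, path, c("pond_id", "canopy_cover", "elevation", "latitude",
                           "area", "leaf_area_index"))

#' @rdname frogphen_io
#' @export
read_ponds_csv <- function(path)
  read_checked(path, c("pond_id", "canopy_cover", "elevation", "latitude",
                       "area", "leaf_area_index"))

#' @rdname frogphen_io
#' @export
write_observations_csv <- function(x, path)
  write_checked(x, path, c("pond_id", "year", "survey_doy", "new_egg_masses"))

#' @rdname frogphen_io
#' @export
read_observations_csv <- function(path)
  read_checked(path, c("pond_id", "year", "survey_doy", "new_egg_masses"))

#' @rdname frogphen_io
#' @export
write_emergence_csv <- function(x, path)
  write_checked(x, path, c("pond_id", "year", "emergence_doy", "emergence_hour"))

#' @rdname frogphen_io
#' @export
read_emergence_csv <- function(path)
  read_checked(path, c("pond_id", "year", "emergence_doy", "emergence_hour"))

#' @rdname frogphen_io
#' @export
write_microclimate_csv <- function(x, path) {
  cols <- c("pond_id", "year", "doy", "hour", "air_temp",
            grep("^soil_temp_", names(x), value = TRUE), "swe", "snow_depth")
  write_checked(as.data.frame(x), path, cols)
}

#' @rdname frogphen_io
#' @export
read_microclimate_csv <- function(path) {
  x <- read_checked(path, c("pond_id", "year", "doy", "hour", "air_temp",
                            "swe", "snow_depth"))
  soil_cols <- grep("^soil_temp_", names(x), value = TRUE)
  if (length(soil_cols) == 0L) stop("no soil_temp_<depth> columns found")
  attr(x, "depths") <- as.numeric(sub("^soil_temp_", "", soil_cols))
  class(x) <- c("microclimate_series", "data.frame")
  x
}

#' @rdname frogphen_io
#' @export
write_parameter_table_csv <- function(x, path) {
  validate_parameter_table(x)
  write_checked(x, path, c("name", "category", "min", "mean", "max",
                           "applies_to", "inflatable"))
}

#' @rdname frogphen_io
#' @export
read_parameter_table_csv <- function(path) {
  x <- read_checked(path, c("name", "category", "min", "mean", "max",
                            "applies_to", "inflatable"))
  x$inflatable <- as.logical(x$inflatable)
  validate_parameter_table(x)
  x
}

#' @rdname frogphen_io
#' @export
write_oat_plan_csv <- function(x, path) {
  p <- attr(x, "params")
  write_checked(x, path, c("run_id", "parameter", "level", "value"))
  if (!is.null(p))
    write_parameter_table_csv(p, sub("(\\.csv)?$", "_params.csv", path))
  invisible(path)
}

#' @rdname frogphen_io
#' @export
read_oat_plan_csv <- function(path) {
  x <- read_checked(path, c("run_id", "parameter", "level", "value"))
  ppath <- sub("(\\.csv)?$", "_params.csv", path)
  if (file.exists(ppath)) attr(x, "params") <- read_parameter_table_csv(ppath)
  x
}

#' Write and read a study configuration file
#'
#' Serializes the generator, microclimate, and trait settings to one YAML
#' file so a whole synthetic study is reproducible from a single structured
#' text document.
#'
#' @param weather A [weather_config()].
#' @param params A [micro_params()].
#' @param traits A [frog_traits()].
#' @param network List of pond-network settings (`n_ponds`, `canopy_range`,
#'   `elevation_mean`, `seed`, ...).
#' @param run List of run settings (`start_year`, `end_year`,
#'   `burn_in_years`, ...).
#' @param path File path.
#' @return `write_study_config()` returns `path` invisibly;
#'   `read_study_config()` returns a list with elements `weather`, `params`,
#'   `traits`, `network`, `run` (the first three reconstructed through their
#'   validating constructors).
#' @export
write_study_config <- function(path, weather = weather_config(),
                               params = micro_params(),
                               traits = frog_traits(),
                               network = list(n_ponds = 64, canopy_range = c(0, 0.9),
                                              elevation_mean = 236, seed = 1),
                               run = list(start_year = 2000, end_year = 2010,
                                          burn_in_years = 1)) {
  yaml::write_yaml(list(weather = unclass(weather), micro = unclass(params),
                        traits = unclass(traits), network = network, run = run),
                   path)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  list(weather = do.call(weather_config, cfg$weather),
       params = do.call(micro_params, cfg$micro),
       traits = do.call(frog_traits, cfg$traits),
       network = cfg$network,
       run = cfg$run)
}
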