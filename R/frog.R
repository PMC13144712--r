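## Rule-based wood frog emergence: a single buried frog per pond, tracked
## hourly through winter, released when calendar, thaw, snow, and aboveground
## activity conditions are all met.

#' Wood frog trait set
#'
#' Endogenous parameters of the emergence model.  Defaults follow published
#' wood frog values where they exist: thaw begins at -0.16 degrees C (the
#' inflection temperature of frog thawing), emergence requires three
#' consecutive days of thawed body temperature and five consecutive snow-free
#' days, and never occurs on or before day-of-year 65.
#'
#' @param mass Body mass (g, > 0); enters only through the optional thermal
#'   lag, scaled as `(mass / 11.6)^(1/3)`.
#' @param burrow_depth Hibernaculum depth (cm); mapped to the nearest soil
#'   node.  Wood frogs overwinter in the topsoil, typically 2-5 cm deep.
#' @param thaw_threshold_temp Body temperature (degrees C) that must be
#'   exceeded for thaw.
#' @param thaw_consecutive_days Required consecutive days (current day
#'   included) with daily minimum body temperature above
#'   `thaw_threshold_temp`.
#' @param snowfree_consecutive_days Required consecutive snow-free days
#'   (current day included).
#' @param earliest_doy Emergence never occurs on or before this day-of-year.
#' @param emergence_air_temp Chosen air temperature of emergence (degrees C):
#'   aboveground hours count as favorable only at or above it.
#' @param favorable_consecutive_hours Consecutive favorable hours required
#'   before the frog emerges (>= 1).
#' @param ct_min,ct_max Critical thermal limits (degrees C, `ct_min < ct_max`);
#'   air above `ct_max` blocks activity regardless of the warm-hour count.
#' @param thermal_time_constant Body thermal time constant (hours) at the
#'   11.6 g reference mass; 0 means instantaneous equilibrium with the burrow
#'   node, appropriate for a small buried ectotherm.
#'
#' @return An object of class `frog_traits` (a validated list).
#' @export
frog_traits <- function(mass = 11.6,
                        burrow_depth = 3.5,
                        thaw_threshold_temp = -0.16,
                        thaw_consecutive_days = 3L,
                        snowfree_consecutive_days = 5L,
                        earliest_doy = 65L,
                        emergence_air_temp = 5,
                        favorable_consecutive_hours = 12L,
                        ct_min = -2,
                        ct_max = 31,
                        thermal_time_constant = 0) {
  tr <- list(
    mass = mass,
    burrow_depth = burrow_depth,
    thaw_threshold_temp = thaw_threshold_temp,
    thaw_consecutive_days = as.integer(thaw_consecutive_days),
    snowfree_consecutive_days = as.integer(snowfree_consecutive_days),
    earliest_doy = as.integer(earliest_doy),
    emergence_air_temp = emergence_air_temp,
    favorable_consecutive_hours = as.integer(favorable_consecutive_hours),
    ct_min = ct_min,
    ct_max = ct_max,
    thermal_time_constant = thermal_time_constant
  )
  if (tr$mass <= 0) stop("mass must be > 0")
  if (tr$ct_min >= tr$ct_max) stop("ct_min must be < ct_max")
  if (tr$thaw_consecutive_days < 1L || tr$snowfree_consecutive_days < 1L ||
      tr$favorable_consecutive_hours < 1L)
    stop("consecutive-day/hour requirements must be >= 1")
  if (tr$thermal_time_constant < 0) stop("thermal_time_constant must be >= 0")
  if (tr$burrow_depth < 0) stop("burrow_depth must be >= 0")
  structure(tr, class = "frog_traits")
}

#' @export
print.frog_traits <- function(x, ...) {
  cat("<frog_traits>\n")
  cat(sprintf("  mass %.1f g, burrow depth %.1f cm, thermal time constant %.1f h\n",
              x$mass, x$burrow_depth, x$thermal_time_constant))
  cat(sprintf("  gates: DOY > %d; body > %.2f C for %d d; snow-free %d d\n",
              x$earliest_doy, x$thaw_threshold_temp,
              x$thaw_consecutive_days, x$snowfree_consecutive_days))
  cat(sprintf("  activity: air >= %.1f C for %d consecutive h, air <= ct_max %.1f C\n",
              x$emergence_air_temp, x$favorable_consecutive_hours, x$ct_max))
  invisible(x)
}

## nearest soil node to the burrow depth (first match wins on ties, i.e. the
## shallower node)
burrow_node <- function(depths, burrow_depth) {
  which.min(abs(depths - burrow_depth))
}

#' Frog body temperature from the burrow-node soil temperature
#'
#' With `thermal_time_constant = 0` the frog is in instantaneous equilibrium
#' with the soil at its burrow node.  Otherwise body temperature relaxes
#' toward the soil temperature with first-order dynamics whose time constant
#' scales with `(mass / 11.6)^(1/3)`, the linear-dimension scaling of a
#' geometrically similar body.
#'
#' @param soil_temp Soil temperature at the burrow node (degrees C).
#' @param traits A [frog_traits()].
#' @param previous_body_temp Body temperature at the previous step (degrees C).
#' @param dt Time step (s).
#' @return Body temperature (degrees C).
#' @export
body_temperature <- function(soil_temp, traits, previous_body_temp = soil_temp,
                             dt = 3600) {
  tau <- traits$thermal_time_constant * (traits$mass / 11.6)^(1 / 3)
  if (tau <= 0) return(soil_temp)
  alpha <- exp(-dt / (tau * 3600))
  soil_temp + (previous_body_temp - soil_temp) * alpha
}

## body temperature over a whole hourly series (recursive filter form of
## body_temperature)
body_temperature_series <- function(soil_temp, traits, dt = 3600) {
  tau <- traits$thermal_time_constant * (traits$mass / 11.6)^(1 / 3)
  if (tau <= 0) return(soil_temp)
  alpha <- exp(-dt / (tau * 3600))
  as.numeric(stats::filter((1 - alpha) * soil_temp, alpha,
                           method = "recursive", init = soil_temp[1]))
}

#' Daily gating conditions for emergence
#'
#' Evaluates, for the current day, the three conditions that keep the frog
#' belowground: the calendar must have advanced beyond `earliest_doy`; the
#' daily minimum body temperature must have exceeded `thaw_threshold_temp` on
#' each of the trailing `thaw_consecutive_days` (current day included); and
#' the pond must have been snow-free on each of the trailing
#' `snowfree_consecutive_days` (current day included).  Histories shorter than
#' the required windows count as insufficient evidence and return `FALSE`.
#'
#' @param body_temp_history Daily minimum body temperatures (degrees C), last
#'   element = current day.
#' @param snow_history Daily snow depths (cm), last element = current day.
#' @param doy Current day-of-year.
#' @param traits A [frog_traits()].
#' @return `TRUE` iff all three gates pass.
#' @export
check_gating_conditions <- function(body_temp_history, snow_history, doy,
                                    traits = frog_traits()) {
  if (doy <= traits$earliest_doy) return(FALSE)
  k <- traits$thaw_consecutive_days
  m <- traits$snowfree_consecutive_days
  if (length(body_temp_history) < k || length(snow_history) < m) return(FALSE)
  thaw_ok <- all(utils::tail(body_temp_history, k) > traits$thaw_threshold_temp)
  snow_ok <- all(utils::tail(snow_history, m) == 0)
  thaw_ok && snow_ok
}

#' Is the current hour favorable for aboveground activity?
#'
#' The caller tracks `hours_above_count`, the running count of consecutive
#' hours with air temperature at or above `emergence_air_temp` (boundary
#' inclusive).  The hour is favorable when that count has reached
#' `favorable_consecutive_hours` and the air temperature does not exceed
#' `ct_max`.
#'
#' @param air_temp Air temperature at frog height this hour (degrees C).
#' @param traits A [frog_traits()].
#' @param hours_above_count Running count of consecutive warm hours, current
#'   hour included.
#' @return `TRUE` iff the hour is favorable.
#' @export
favorable_for_activity <- function(air_temp, traits = frog_traits(),
                                   hours_above_count = 0L) {
  hours_above_count >= traits$favorable_consecutive_hours &&
    air_temp <= traits$ct_max
}

## consecutive run length of TRUE ending at each position
consecutive_true <- function(x) {
  r <- rle(x)
  unlist(lapply(seq_along(r$lengths), function(i) {
    if (r$values[i]) seq_len(r$lengths[i]) else rep(0L, r$lengths[i])
  }), use.names = FALSE)
}

#' Simulate one frog for one pond-year
#'
#' Scans a complete hourly microclimate year and returns the first hour at
#' which the daily gating conditions ([check_gating_conditions()]) hold for
#' that day and the hour itself is favorable for activity
#' ([favorable_for_activity()], with the consecutive warm-hour counter run
#' across the whole year).  The trailing thaw window is evaluated on daily
#' minima of hourly body temperature, the strictest reading that prevents
#' emergence after nights that refreeze.
#'
#' @param micro A `microclimate_series` (or plain data frame with its
#'   columns) covering exactly one pond-year: 365 days x 24 hours.
#' @param traits A [frog_traits()].
#' @return A one-row data frame (`pond_id`, `year`, `emergence_doy`,
#'   `emergence_hour`), with `NA`s when the frog never emerges.
#' @export
simulate_frog_year <- function(micro, traits = frog_traits()) {
  if (nrow(micro) != 365L * 24L)
    stop("micro must cover one complete year (365 x 24 hourly records)")
  if (length(unique(micro$year)) != 1L) stop("micro must span a single year")
  ord <- order(micro$doy, micro$hour)
  micro <- micro[ord, , drop = FALSE]
  depths <- attr(micro, "depths")
  soil_cols <- grep("^soil_temp_", names(micro), value = TRUE)
  if (is.null(depths))
    depths <- as.numeric(sub("^soil_temp_", "", soil_cols))
  node <- burrow_node(depths, traits$burrow_depth)
  soil <- micro[[soil_cols[node]]]

  body <- body_temperature_series(soil, traits)
  body_daily_min <- apply(matrix(body, nrow = 24L), 2L, min)
  snow_daily <- matrix(micro$snow_depth, nrow = 24L)[1L, ]

  k <- traits$thaw_consecutive_days
  m <- traits$snowfree_consecutive_days
  thaw_day <- body_daily_min > traits$thaw_threshold_temp
  snow_free <- snow_daily == 0
  trailing_all <- function(x, w) {
    cs <- cumsum(x)
    n <- length(x)
    ok <- logical(n)
    idx <- w:n
    ok[idx] <- (cs[idx] - c(0, cs)[idx - w + 1L]) == w
    ok
  }
  eligible_day <- (1:365 > traits$earliest_doy) &
    trailing_all(thaw_day, k) & trailing_all(snow_free, m)

  warm <- micro$air_temp >= traits$emergence_air_temp
  count <- consecutive_true(warm)
  favorable <- count >= traits$favorable_consecutive_hours &
    micro$air_temp <= traits$ct_max

  hit <- which(favorable & eligible_day[(seq_len(nrow(micro)) - 1L) %/% 24L + 1L])
  if (length(hit) == 0L) {
    return(data.frame(pond_id = micro$pond_id[1], year = micro$year[1],
                      emergence_doy = NA_integer_, emergence_hour = NA_integer_,
                      stringsAsFactors = FALSE))
  }
  h <- hit[1L]
  data.frame(pond_id = micro$pond_id[1], year = micro$year[1],
             emergence_doy = as.integer(micro$doy[h]),
             emergence_hour = as.integer(micro$hour[h]),
             stringsAsFactors = FALSE)
}
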