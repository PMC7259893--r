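# Microclimate scenario definitions: six bounding palaeoclimates
# (hot/moderate/cold x arid/humid) at 12 degrees N, 150 m elevation.

.scenario_temps <- list(
  hot      = c(26, 40),
  moderate = c(20, 34),
  cold     = c(16, 30)
)
.scenario_rh <- list(
  arid  = c(13, 65),
  humid = c(48, 96)
)

#' Default soil properties
#'
#' A generic dry loam: conductivity 0.9 W/m/K, volumetric heat capacity
#' 1.5 MJ/m^3/K, solar reflectivity 0.3, IR emissivity 0.95, ten log-spaced
#' nodes from the surface to a 2 m deep boundary.
#'
#' @param n_nodes Number of soil nodes.
#' @param max_depth Depth of the fixed-temperature boundary, m.
#' @return A `SoilProperties` list.
#' @export
default_soil <- function(n_nodes = 10, max_depth = 2) {
  depths <- c(0, max_depth * (exp(seq_len(n_nodes - 1) / (n_nodes - 1) * log(41)) - 1) / 40)
  structure(list(
    thermal_conductivity = 0.9,        # W/m/K
    volumetric_heat_capacity = 1.5e6,  # J/m^3/K
    solar_reflectivity = 0.3,
    ir_emissivity = 0.95,
    node_depths = depths
  ), class = "SoilProperties")
}

#' Build one of the six microclimate scenarios
#'
#' Scenario names combine a thermal regime (`hot`, `moderate`, `cold`) with a
#' humidity regime (`arid`, `humid`), e.g. `"hot_arid"`. Annual air temperature
#' envelopes are hot 26-40, moderate 20-34, cold 16-30 degC; relative humidity
#' arid 13-65 %, humid 48-96 %; winds 1-4 m/s; cloud 50-90 %; latitude 12 N,
#' elevation 150 m; atmosphere 18 % O2, 0.13 % CO2.
#'
#' @param name Scenario label, one of the six combinations above.
#' @param soil Optional `SoilProperties` override.
#' @param shade_max Percent of solar blocked in the deepest shade site.
#' @return A `MicroclimateScenario` object.
#' @examples
#' sc <- build_scenario("hot_arid")
#' sc$air_temp_max
#' @export
build_scenario <- function(name, soil = default_soil(), shade_max = 90) {
  valid <- as.vector(outer(names(.scenario_temps), names(.scenario_rh), paste, sep = "_"))
  if (!is.character(name) || length(name) != 1 || !(name %in% valid)) {
    stop_config("unknown scenario '%s'; valid scenarios: %s",
                as.character(name)[1], paste(sort(valid), collapse = ", "))
  }
  parts <- strsplit(name, "_", fixed = TRUE)[[1]]
  tt <- .scenario_temps[[parts[1]]]
  rr <- .scenario_rh[[parts[2]]]
  sc <- structure(list(
    name = name,
    latitude = 12,
    elevation = 150,
    air_temp_min = tt[1], air_temp_max = tt[2],
    wind_min = 1, wind_max = 4,
    rh_min = rr[1], rh_max = rr[2],
    cloud_min = 50, cloud_max = 90,
    substrate = soil,
    o2_fraction = 18,
    co2_fraction = 0.13,
    shade_max = shade_max
  ), class = "MicroclimateScenario")
  validate_scenario(sc)
  sc
}

#' Validate a microclimate scenario
#'
#' Checks ranged pairs (min <= max), humidity/cloud within 0-100, positive O2
#' and a latitude within -90..90.
#'
#' @param sc A `MicroclimateScenario`.
#' @return The scenario, invisibly; errors on violation.
#' @export
validate_scenario <- function(sc) {
  chk <- function(lo, hi, what) {
    if (lo > hi) stop_config("%s: min (%g) exceeds max (%g)", what, lo, hi)
  }
  chk(sc$air_temp_min, sc$air_temp_max, "air temperature")
  chk(sc$wind_min, sc$wind_max, "wind")
  chk(sc$rh_min, sc$rh_max, "relative humidity")
  chk(sc$cloud_min, sc$cloud_max, "cloud")
  if (sc$rh_min < 0 || sc$rh_max > 100) stop_config("relative humidity outside 0-100")
  if (sc$cloud_min < 0 || sc$cloud_max > 100) stop_config("cloud outside 0-100")
  if (sc$o2_fraction <= 0) stop_config("o2_fraction must be positive")
  if (abs(sc$latitude) > 90) stop_config("latitude outside -90..90")
  d <- sc$substrate$node_depths
  if (d[1] != 0 || any(diff(d) <= 0)) stop_config("soil node_depths must increase from 0")
  invisible(sc)
}

#' Monthly air-temperature envelope for a scenario
#'
#' The scenario's annual min/max bound a smooth seasonal cycle: each model
#' month's daily minimum and maximum track a cosine of day-of-year with the
#' warmest month in July (northern low latitude). The annual extremes equal
#' the scenario envelope; the seasonal half-amplitude is a fixed fraction of
#' the annual range (default 0.5: July spans the top half of the envelope,
#' January the bottom half).
#'
#' @param sc A `MicroclimateScenario`.
#' @param month Month number 1-12.
#' @param seasonal_fraction Fraction of the annual range swept seasonally.
#' @return List with `t_min`, `t_max` (degC) for the mid-month model day,
#'   plus `rh_min`, `rh_max`, `wind_min`, `wind_max`, `cloud_min`,
#'   `cloud_max` (held constant across the year) and `day_of_year`.
#' @export
month_envelope <- function(sc, month, seasonal_fraction = 0.5) {
  stopifnot(month %in% 1:12)
  doy <- mid_month_doy(month)
  # warm peak at July 15 (doy 196)
  season <- cos(2 * pi * (doy - 196) / 365.25)   # 1 in July, -1 in January
  range_t <- sc$air_temp_max - sc$air_temp_min
  half <- seasonal_fraction * range_t / 2
  centre_mid <- (sc$air_temp_min + sc$air_temp_max) / 2
  # centre of the diurnal cycle moves seasonally; diurnal amplitude constant
  centre <- centre_mid + half * season
  diurnal_half <- (1 - seasonal_fraction) * range_t / 2
  list(
    t_min = centre - diurnal_half, t_max = centre + diurnal_half,
    rh_min = sc$rh_min, rh_max = sc$rh_max,
    wind_min = sc$wind_min, wind_max = sc$wind_max,
    cloud_min = sc$cloud_min, cloud_max = sc$cloud_max,
    day_of_year = doy, month = month
  )
}

#' Mid-month model days
#'
#' @param month Month 1-12.
#' @return Day of year of the 15th of that month (non-leap calendar).
#' @export
mid_month_doy <- function(month) {
  cumdays <- c(0, cumsum(c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30)))
  cumdays[month] + 15
}

#' Days per month (non-leap year)
#' @return Integer vector of length 12.
#' @export
month_lengths <- function() c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
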