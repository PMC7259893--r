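# Hourly microclimate generation: diurnal sinusoids anchored to sunrise and
# solar noon + 1 h, clear-sky solar geometry with cloud attenuation, longwave
# sky radiant temperature, and logarithmic profiles to animal height.

#' Diurnal sinusoidal interpolation between a daily minimum and maximum
#'
#' A continuous, 24-h periodic piecewise cosine that attains `v_min` exactly
#' at sunrise and `v_max` exactly one hour after solar noon (phase
#' `min_at_sunrise_max_at_noon_plus1`, used for air temperature and wind), or
#' the reverse (`inverted`, used for relative humidity and cloud, which peak
#' at sunrise).
#'
#' @param v_min,v_max Daily extreme values (`v_min <= v_max`).
#' @param sunrise_hour Local solar hour of sunrise.
#' @param solar_noon Local solar hour of solar noon (the maximum is anchored
#'   at `solar_noon + 1`).
#' @param hour Hour (may be fractional, vectorised), local solar time 0-24.
#' @param phase `"min_at_sunrise_max_at_noon_plus1"` or `"inverted"`.
#' @return Interpolated value(s).
#' @examples
#' diurnal_curve(26, 40, 6, 12, c(6, 13, 9.5))
#' @export
diurnal_curve <- function(v_min, v_max, sunrise_hour, solar_noon, hour,
                          phase = c("min_at_sunrise_max_at_noon_plus1", "inverted")) {
  phase <- match.arg(phase)
  if (v_min > v_max) stop_config("v_min exceeds v_max")
  peak <- solar_noon + 1
  rise_len <- (peak - sunrise_hour) %% 24
  fall_len <- 24 - rise_len
  dh <- (hour - sunrise_hour) %% 24
  frac <- ifelse(dh <= rise_len,
                 (1 - cos(pi * dh / rise_len)) / 2,
                 (1 + cos(pi * (dh - rise_len) / fall_len)) / 2)
  v <- v_min + (v_max - v_min) * frac
  if (phase == "inverted") v <- v_max + v_min - v
  v
}

#' Solar geometry for a given day and latitude
#'
#' Standard declination/hour-angle geometry in local solar time (no longitude
#' or equation-of-time correction).
#'
#' @param latitude Degrees N.
#' @param day_of_year 1-365.
#' @return List with `declination` (deg), `sunrise`, `sunset`, `solar_noon`
#'   (solar hours) and `cos_zenith(hour)` a function of hour.
#' @export
solar_geometry <- function(latitude, day_of_year) {
  decl <- 23.45 * sin(2 * pi * (284 + day_of_year) / 365)
  phi <- latitude * pi / 180
  del <- decl * pi / 180
  x <- -tan(phi) * tan(del)
  ws <- acos(pmin(1, pmax(-1, x)))         # sunrise hour angle, rad
  list(
    declination = decl,
    sunrise = 12 - ws * 12 / pi,
    sunset = 12 + ws * 12 / pi,
    solar_noon = 12,
    cos_zenith = function(hour) {
      h <- (hour - 12) * pi / 12
      sin(phi) * sin(del) + cos(phi) * cos(del) * cos(h)
    }
  )
}

#' Solar flux on a horizontal surface
#'
#' Clear-sky total from a single-transmittance formulation
#' (S0 * cos(zenith) * tau^airmass with tau = 0.70 per optical air mass,
#' pressure-corrected for elevation), split 85 % direct / 15 % diffuse under
#' clear sky, and attenuated by cloud as a factor (1 - 0.65 * cloud/100).
#' Zero when the sun is below the horizon.
#'
#' @param latitude Degrees N.
#' @param day_of_year 1-365.
#' @param hour Local solar hour (vectorised).
#' @param cloud Cloud cover, percent.
#' @param elevation Site elevation, m.
#' @return List with `direct` and `diffuse` (W/m^2, horizontal) and
#'   `cos_zenith`.
#' @export
solar_flux <- function(latitude, day_of_year, hour, cloud = 0, elevation = 0) {
  cst <- dt_constants()
  geo <- solar_geometry(latitude, day_of_year)
  cz <- pmax(0, geo$cos_zenith(hour))
  m <- ifelse(cz > 0, pmin(1 / pmax(cz, 1e-6), 38), 0) *
    air_pressure(elevation) / 101325
  total <- ifelse(cz > 0, cst$solar_constant * cz * cst$tau_atm^m, 0)
  total <- total * (1 - cst$cloud_solar_atten * cloud / 100)
  list(direct = (1 - cst$diffuse_fraction) * total,
       diffuse = cst$diffuse_fraction * total,
       cos_zenith = cz)
}

#' Longwave radiant sky temperature
#'
#' Clear-sky effective emissivity from the Swinbank air-temperature
#' correlation (eps = 9.365e-6 * T_air^2, T in Kelvin), blended toward 1
#' with cloud fraction; the sky radiant temperature is `eps^(1/4) * T_air`
#' in Kelvin. Humidity is accepted for interface symmetry but does not
#' enter the clear-sky emissivity (the correlation is temperature-only).
#'
#' @param t_air Air temperature, degC.
#' @param rh Relative humidity, percent (unused by the correlation).
#' @param cloud Cloud cover, percent.
#' @return Sky radiant temperature, degC.
#' @export
longwave_sky <- function(t_air, rh = 50, cloud = 0) {
  eps_clear <- pmin(1, 9.365e-6 * C2K(t_air)^2)
  eps <- eps_clear + (cloud / 100) * (1 - eps_clear)
  eps^0.25 * C2K(t_air) - 273.15
}

#' Air temperature and wind at a given height
#'
#' Logarithmic boundary-layer profile between the ground surface and the
#' reference height: wind goes to zero at the roughness height and air
#' temperature interpolates between the ground-surface temperature and the
#' reference air temperature on the same log coordinate.
#'
#' @param t_ref,wind_ref Air temperature (degC) and wind (m/s) at
#'   `ref_height`.
#' @param t_surface Ground surface temperature, degC.
#' @param z Height, m (`0 < z <= ref_height`).
#' @param roughness Roughness height, m.
#' @param ref_height Reference measurement height, m.
#' @return List with `t_air` (degC) and `wind` (m/s) at `z`.
#' @export
env_at_height <- function(t_ref, wind_ref, t_surface, z, roughness = 0.01,
                          ref_height = 2) {
  if (z > ref_height) z <- ref_height
  if (z <= roughness) {
    warning("height at or below roughness height; clamping to surface values")
    return(list(t_air = t_surface, wind = 0))
  }
  w <- log(z / roughness) / log(ref_height / roughness)
  list(t_air = t_surface + (t_ref - t_surface) * w, wind = wind_ref * w)
}

# Convective transfer coefficient at the ground surface (McAdams flat plate).
.ground_h <- function(wind) 5.7 + 3.8 * wind

#' Solve the one-dimensional transient soil heat balance for one model day
#'
#' Backward-Euler finite differences on the scenario's soil node grid with the
#' surface node driven by absorbed solar, net longwave exchange with the sky
#' and convection with the air (surface radiation linearised and re-iterated
#' each step). The deep boundary is held at the daily mean air temperature.
#' The forcing day is repeated for spin-up days until the profile is 24-h
#' periodic (max |T(h) - T(h-24)| < 0.05 degC), then the converged day is
#' returned.
#'
#' @param soil A `SoilProperties` list.
#' @param forcing Data frame with 24 rows: `t_air`, `wind`, `t_sky`,
#'   `solar` (total horizontal, W/m^2).
#' @param spinup_days Minimum spin-up days (3 by default).
#' @param max_days Abort with an error after this many days without
#'   periodicity.
#' @param substeps Sub-steps per hour for the implicit march.
#' @return A `SoilGrid` list: `node_depths`, `temperatures` (24 x n matrix),
#'   `surface_flux` data frame (solar_abs, ir_net, conv, cond, residual W/m^2).
#' @export
solve_soil <- function(soil, forcing, spinup_days = 3, max_days = 30,
                       substeps = 6) {
  cst <- dt_constants()
  z <- soil$node_depths
  n <- length(z)
  k <- soil$thermal_conductivity
  C <- soil$volumetric_heat_capacity
  dz <- diff(z)
  # control-volume widths
  w <- c(dz[1] / 2, (dz[-length(dz)] + dz[-1]) / 2, dz[length(dz)] / 2)
  t_deep <- mean(forcing$t_air)
  temps <- rep(t_deep, n)
  dt <- 3600 / substeps
  alpha <- 1 - soil$solar_reflectivity
  eps <- soil$ir_emissivity
  hist <- matrix(NA_real_, 24, n)
  day <- 0
  repeat {
    day <- day + 1
    prev <- hist
    for (hr in 1:24) {
      f <- forcing[hr, ]
      for (s in seq_len(substeps)) {
        told <- temps
        ts0 <- told[1]
        h <- .ground_h(f$wind)
        # linearise surface radiation about ts0, iterate the linearisation
        for (it in 1:2) {
          hr_lin <- 4 * eps * cst$sigma * C2K(ts0)^3
          a <- b <- cc <- d <- numeric(n)
          g1 <- k / dz[1]
          b[1] <- C * w[1] / dt + h + hr_lin + g1
          cc[1] <- -g1
          d[1] <- C * w[1] / dt * told[1] + alpha * f$solar +
            h * f$t_air + hr_lin * ts0 +
            eps * cst$sigma * (C2K(f$t_sky)^4 - C2K(ts0)^4)
          for (i in 2:(n - 1)) {
            gm <- k / dz[i - 1]; gp <- k / dz[i]
            a[i] <- -gm; cc[i] <- -gp
            b[i] <- C * w[i] / dt + gm + gp
            d[i] <- C * w[i] / dt * told[i]
          }
          b[n] <- 1; a[n] <- 0; d[n] <- t_deep
          # Thomas algorithm
          for (i in 2:n) {
            mfac <- a[i] / b[i - 1]
            b[i] <- b[i] - mfac * cc[i - 1]
            d[i] <- d[i] - mfac * d[i - 1]
          }
          new <- numeric(n)
          new[n] <- d[n] / b[n]
          for (i in (n - 1):1) new[i] <- (d[i] - cc[i] * new[i + 1]) / b[i]
          ts0 <- new[1]
        }
        temps <- new
      }
      hist[hr, ] <- temps
    }
    if (day > spinup_days && all(abs(hist - prev) < 0.05, na.rm = TRUE)) break
    if (day >= max_days) {
      stop_config("soil solver not periodic after %d days (max residual %.3f degC)",
                  day, max(abs(hist - prev), na.rm = TRUE))
    }
  }
  # diagnostic surface flux decomposition: replay one converged day and
  # evaluate the surface balance at the solver's own sub-steps (the implicit
  # march satisfies it up to the radiation linearisation error)
  sf <- data.frame(hour = 0:23, solar_abs = NA_real_, ir_net = NA_real_,
                   conv = NA_real_, cond = NA_real_, residual = NA_real_)
  for (hr in 1:24) {
    f <- forcing[hr, ]
    res_max <- 0
    for (s in seq_len(substeps)) {
      told1 <- temps[1]
      prev_col <- temps
      # one implicit sub-step (same scheme as the march)
      ts0 <- told1
      h <- .ground_h(f$wind)
      for (it in 1:2) {
        hr_lin <- 4 * eps * cst$sigma * C2K(ts0)^3
        a <- b <- cc <- d <- numeric(n)
        g1 <- k / dz[1]
        b[1] <- C * w[1] / dt + h + hr_lin + g1
        cc[1] <- -g1
        d[1] <- C * w[1] / dt * told1 + alpha * f$solar + h * f$t_air +
          hr_lin * ts0 + eps * cst$sigma * (C2K(f$t_sky)^4 - C2K(ts0)^4)
        for (i in 2:(n - 1)) {
          gm <- k / dz[i - 1]; gp <- k / dz[i]
          a[i] <- -gm; cc[i] <- -gp
          b[i] <- C * w[i] / dt + gm + gp
          d[i] <- C * w[i] / dt * prev_col[i]
        }
        b[n] <- 1; a[n] <- 0; d[n] <- t_deep
        for (i in 2:n) {
          mfac <- a[i] / b[i - 1]
          b[i] <- b[i] - mfac * cc[i - 1]
          d[i] <- d[i] - mfac * d[i - 1]
        }
        new <- numeric(n)
        new[n] <- d[n] / b[n]
        for (i in (n - 1):1) new[i] <- (d[i] - cc[i] * new[i + 1]) / b[i]
        ts0 <- new[1]
      }
      temps <- new
      ts <- temps[1]
      fl_sol <- alpha * f$solar
      fl_ir <- eps * cst$sigma * (C2K(f$t_sky)^4 - C2K(ts)^4)
      fl_cv <- h * (f$t_air - ts)
      fl_cd <- -k * (ts - temps[2]) / dz[1]
      res_max <- max(res_max, abs(fl_sol + fl_ir + fl_cv + fl_cd -
                                    C * w[1] * (ts - told1) / dt))
    }
    sf$solar_abs[hr] <- fl_sol
    sf$ir_net[hr] <- fl_ir
    sf$conv[hr] <- fl_cv
    sf$cond[hr] <- fl_cd
    sf$residual[hr] <- res_max
    hist[hr, ] <- temps
  }
  structure(list(node_depths = z, temperatures = hist, surface_flux = sf,
                 spinup_days_used = day),
            class = "SoilGrid")
}

#' Hourly environments for one model day of a scenario
#'
#' Generates the full 24-hour operative environment at the open (sun) and
#' deep-shade sites: diurnal air temperature, wind, humidity and cloud
#' curves, solar fluxes, longwave sky temperature, the solved soil column and
#' the air temperature/wind at mean animal height. Shade blocks
#' `shade_max` % of solar and replaces the sky radiant temperature with air
#' temperature (overhead canopy); at night only the radiant substitution
#' applies.
#'
#' @param scenario A `MicroclimateScenario`.
#' @param month Model month 1-12 (mid-month day).
#' @param animal_height Mean animal height, m.
#' @param roughness Surface roughness height, m.
#' @param ref_height Reference height of the scenario wind/air values, m.
#' @param latitude_override Optional latitude replacing the scenario's.
#' @return A `DayEnvironment` list with elements `sun` and `shade`, each a
#'   data frame of 24 `HourlyEnvironment` rows, plus `soil_sun`, `soil_shade`
#'   and metadata.
#' @export
microclimate_day <- function(scenario, month, animal_height = 1,
                             roughness = 0.01, ref_height = 2,
                             latitude_override = NULL) {
  env <- month_envelope(scenario, month)
  lat <- latitude_override %||% scenario$latitude
  geo <- solar_geometry(lat, env$day_of_year)
  hours <- 0:23
  t_air <- diurnal_curve(env$t_min, env$t_max, geo$sunrise, geo$solar_noon, hours)
  wind <- diurnal_curve(env$wind_min, env$wind_max, geo$sunrise, geo$solar_noon, hours)
  rh <- diurnal_curve(env$rh_min, env$rh_max, geo$sunrise, geo$solar_noon, hours,
                      phase = "inverted")
  cloud <- diurnal_curve(env$cloud_min, env$cloud_max, geo$sunrise, geo$solar_noon,
                         hours, phase = "inverted")
  sol <- solar_flux(lat, env$day_of_year, hours, cloud, scenario$elevation)
  t_sky <- longwave_sky(t_air, rh, cloud)
  shade_f <- 1 - scenario$shade_max / 100

  make_site <- function(site) {
    if (site == "open-sun") {
      s_dir <- sol$direct; s_dif <- sol$diffuse; tsky <- t_sky
    } else {
      s_dir <- sol$direct * shade_f; s_dif <- sol$diffuse * shade_f
      tsky <- t_air   # canopy radiates near air temperature
    }
    soil <- solve_soil(scenario$substrate,
                       data.frame(t_air = t_air, wind = wind, t_sky = tsky,
                                  solar = s_dir + s_dif))
    t_surf <- soil$temperatures[, 1]
    prof <- mapply(function(tr, wr, ts) {
      p <- env_at_height(tr, wr, ts, animal_height, roughness, ref_height)
      c(p$t_air, p$wind)
    }, t_air, wind, t_surf)
    list(env = data.frame(
      hour = hours, site = site,
      t_air_ref = t_air, t_air_animal = prof[1, ], wind_animal = pmax(prof[2, ], 0.1),
      rh = rh, cloud = cloud,
      solar_direct = s_dir, solar_diffuse = s_dif, cos_zenith = sol$cos_zenith,
      t_sky = tsky, t_ground_surface = t_surf,
      elevation = scenario$elevation, o2_fraction = scenario$o2_fraction
    ), soil = soil)
  }
  sun <- make_site("open-sun")
  shade <- make_site("deep-shade")
  structure(list(sun = sun$env, shade = shade$env,
                 soil_sun = sun$soil, soil_shade = shade$soil,
                 month = month, day_of_year = env$day_of_year,
                 sunrise = geo$sunrise, sunset = geo$sunset,
                 scenario = scenario$name),
            class = "DayEnvironment")
}

#' A spatially uniform chamber environment
#'
#' Metabolic-chamber conditions: ground, sky and air temperatures equal, no
#' solar input, constant wind and humidity.
#'
#' @param t_air Chamber temperature, degC.
#' @param wind Wind speed, m/s (0.1 by default).
#' @param rh Relative humidity, percent (5 by default).
#' @param elevation Elevation, m.
#' @param o2_fraction Atmospheric O2, percent.
#' @return A one-row environment data frame (`HourlyEnvironment` fields).
#' @export
chamber_environment <- function(t_air, wind = 0.1, rh = 5, elevation = 150,
                                o2_fraction = 18) {
  data.frame(hour = 12, site = "chamber",
             t_air_ref = t_air, t_air_animal = t_air, wind_animal = wind,
             rh = rh, cloud = 0, solar_direct = 0, solar_diffuse = 0,
             cos_zenith = 0, t_sky = t_air, t_ground_surface = t_air,
             elevation = elevation, o2_fraction = o2_fraction)
}
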