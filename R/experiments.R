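# Experiment drivers: metabolic-chamber thermoneutral-zone sweeps, viability
# matrices over scenario x RMR grade x CTR, parameter sweeps, and two-level
# full-factorial (Yates) climate sensitivity analysis.

#' Metabolic-chamber thermoneutral-zone sweep
#'
#' Chamber conditions: ground, sky and air temperatures equal, no solar,
#' 0.1 m/s wind, 5 % relative humidity, behaviours disabled, standing
#' posture. `mode = "resting"` uses no activity multiplier (target = RMR);
#' `mode = "active"` uses the physiology's multiplier (the active
#' thermoneutral zone). Critical temperatures are scanned at `step`
#' resolution and refined by bisection to 0.1 degC.
#'
#' @param animal An `AnimalSpec`.
#' @param phys A `PhysiologySpec`.
#' @param t_min,t_max Sweep bounds, degC (0-51 by default).
#' @param step Scan step, degC.
#' @param mode `"resting"` or `"active"`.
#' @param tolerance Relative tolerance defining thermoneutrality.
#' @return A `TNZResult` list: `grid` (data frame t_air_C, q_met_W, t_core_C,
#'   stress), `lower_critical`, `upper_critical`, `width` (degC; `NA` when no
#'   thermoneutral interval exists, with a `diagnostic` message).
#' @export
metabolic_chamber <- function(animal, phys, t_min = 0, t_max = 51, step = 0.5,
                              mode = c("active", "resting"), tolerance = 0.01) {
  mode <- match.arg(mode)
  if (t_min >= t_max) stop_config("t_min must be below t_max")
  mult <- if (mode == "resting") 1 else phys$activity_multiplier
  run1 <- function(tt) {
    env <- chamber_environment(tt)
    solve_hour(animal, phys, env, env, behaviors_enabled = character(0),
               activity_multiplier = mult, tolerance = tolerance)
  }
  temps <- seq(t_min, t_max, by = step)
  res <- lapply(temps, run1)
  grid <- data.frame(
    t_air_C = temps,
    q_met_W = vapply(res, `[[`, 0, "achieved_met"),
    t_core_C = vapply(res, `[[`, 0, "t_core"),
    stress = vapply(res, `[[`, "", "stress")
  )
  neutral <- grid$stress == "none"
  if (!any(neutral)) {
    return(structure(list(grid = grid, lower_critical = NA_real_,
                          upper_critical = NA_real_, width = NA_real_,
                          mode = mode,
                          diagnostic = "no thermoneutral interval in sweep range"),
                     class = "TNZResult"))
  }
  refine <- function(t_out, t_in) {
    # bisect between a stressed and a neutral temperature to 0.1 degC
    for (i in 1:12) {
      if (abs(t_in - t_out) <= 0.1) break
      mid <- (t_out + t_in) / 2
      if (run1(mid)$stress == "none") t_in <- mid else t_out <- mid
    }
    t_in
  }
  i_lo <- which(neutral)[1]
  i_hi <- tail(which(neutral), 1)
  lower <- if (i_lo > 1) refine(temps[i_lo - 1], temps[i_lo]) else temps[i_lo]
  upper <- if (i_hi < length(temps)) refine(temps[i_hi + 1], temps[i_hi]) else temps[i_hi]
  structure(list(grid = grid, lower_critical = lower, upper_critical = upper,
                 width = upper - lower, mode = mode, diagnostic = NULL),
            class = "TNZResult")
}

#' Compare two thermoneutral zones
#'
#' Reports the change in width and in each bound between a reference and a
#' comparison TNZ (comparison minus reference).
#'
#' @param ref,cmp `TNZResult` objects or `c(lower, upper)` bound pairs.
#' @return List: `width_change`, `lower_shift`, `upper_shift` (degC).
#' @examples
#' tnz_compare(c(32, 45), c(15, 36))  # width +8, upper bound -9
#' @export
tnz_compare <- function(ref, cmp) {
  bounds <- function(x) {
    if (inherits(x, "TNZResult")) c(x$lower_critical, x$upper_critical) else x
  }
  r <- bounds(ref); c_ <- bounds(cmp)
  list(width_change = (c_[2] - c_[1]) - (r[2] - r[1]),
       lower_shift = c_[1] - r[1],
       upper_shift = c_[2] - r[2])
}

#' Classify annual viability from the metabolic-energy ratio
#'
#' Ratio r = annual / target:
#' r > 1.10 far_above (cold-stressed); 1.05 < r <= 1.10 above;
#' 0.95 <= r <= 1.05 target; 0.90 <= r < 0.95 below; r < 0.90 far_below
#' (heat-stressed). Boundary ratios are assigned to the milder class.
#'
#' @param annual_me Annual metabolic energy, MJ.
#' @param annual_target Annual target ME, MJ (> 0).
#' @return One of `"far_above"`, `"above"`, `"target"`, `"below"`,
#'   `"far_below"`.
#' @export
classify_viability <- function(annual_me, annual_target) {
  if (annual_target <= 0) stop_config("annual_target must be positive")
  r <- annual_me / annual_target
  if (r > 1.10) "far_above"
  else if (r > 1.05) "above"
  else if (r >= 0.95) "target"
  else if (r >= 0.90) "below"
  else "far_below"
}

#' Run the scenario x RMR grade x CTR viability matrix
#'
#' One annual simulation per combination of thermal scenario, RMR grade and
#' CTR label (27 cells for the default 3 x 3 x 3 design), classified by
#' [classify_viability()]. Heatmap-ready hourly layers (core temperature, ME
#' as multiple of RMR, shade occupancy) are retained per cell.
#'
#' @param animal An `AnimalSpec` (insulation already attached).
#' @param scenarios Thermal regimes (combined with the humidity regime).
#' @param grades RMR grades.
#' @param ctrs CTR labels.
#' @param humidity `"arid"` or `"humid"` half of the scenario name.
#' @param diet A `DietSpec`.
#' @param months Months per annual run (12 for the full design).
#' @return A `ViabilityMatrix`: `summary` data frame (scenario, rmr, ctr,
#'   annual_me_MJ, target_MJ, ratio, class) and `layers` (per-cell hourly
#'   matrices).
#' @export
run_matrix <- function(animal,
                       scenarios = c("hot", "moderate", "cold"),
                       grades = c("squamate", "monotreme", "ratite"),
                       ctrs = c("broad", "moderate", "narrow"),
                       humidity = "arid",
                       diet = build_diet(if (animal$taxon == "plateosaurus")
                         "high_browser" else "carnivore"),
                       months = 1:12) {
  cells <- expand.grid(scenario = scenarios, rmr = grades, ctr = ctrs,
                       stringsAsFactors = FALSE)
  # the microclimate depends only on the scenario: solve each once
  env_cache <- lapply(stats::setNames(scenarios, scenarios), function(s) {
    sc <- build_scenario(paste(s, humidity, sep = "_"))
    lapply(months, microclimate_day, scenario = sc,
           animal_height = animal$mean_height)
  })
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sc <- build_scenario(paste(cells$scenario[i], humidity, sep = "_"))
    phys <- build_physiology(cells$rmr[i], cells$ctr[i], animal$total_mass,
                             taxon = animal$taxon)
    out[[i]] <- simulate_year(animal, phys, sc, diet = diet, months = months,
                              day_envs = env_cache[[cells$scenario[i]]])
  }
  summary <- cbind(cells, data.frame(
    annual_me_MJ = vapply(out, `[[`, 0, "annual_me"),
    target_MJ = vapply(out, `[[`, 0, "annual_target"),
    ratio = vapply(out, `[[`, 0, "ratio"),
    class = vapply(out, `[[`, "", "viability")
  ))
  layers <- lapply(out, function(yr) {
    list(
      t_core = vapply(yr$days, `[[`, numeric(24), "t_core"),
      me_x_rmr = vapply(yr$days, function(d) d$achieved_met, numeric(24)),
      shade = vapply(yr$days, function(d)
        vapply(d$hourly, function(h) h$state$in_shade, TRUE), logical(24))
    )
  })
  structure(list(summary = summary, layers = layers), class = "ViabilityMatrix")
}

#' Yates effects for a 2^k full factorial design
#'
#' Classical Yates forward pass: k fold-and-difference sweeps over the
#' standard-order response vector; the first entry divided by 2^k is the
#' grand mean, the rest divided by 2^(k-1) are the main effects and
#' interactions.
#'
#' @param responses Numeric vector of length 2^k in standard (Yates) order.
#' @param factor_names Factor labels (k of them).
#' @return An `EffectsTable` data frame with columns `term`, `effect`, and
#'   attribute `mean`; `inverse_yates()` reconstructs the responses.
#' @export
yates_effects <- function(responses,
                          factor_names = c("temperature", "wind",
                                           "humidity", "cloud")) {
  n <- length(responses)
  k <- round(log2(n))
  if (2^k != n) stop_config("response count %d is not a power of two", n)
  if (length(factor_names) != k)
    stop_config("need %d factor names for a 2^%d design", k, k)
  y <- responses
  for (sweep in seq_len(k)) {
    half <- n / 2
    pairs <- matrix(y, nrow = 2)
    y <- c(pairs[1, ] + pairs[2, ], pairs[2, ] - pairs[1, ])
  }
  terms <- vapply(0:(n - 1), function(i) {
    on <- which(bitwAnd(i, 2^(0:(k - 1))) > 0)
    if (!length(on)) "(mean)" else paste(factor_names[on], collapse = ":")
  }, "")
  eff <- data.frame(term = terms,
                    effect = c(y[1] / n, y[-1] / (n / 2)))
  attr(eff, "mean") <- y[1] / n
  attr(eff, "k") <- k
  class(eff) <- c("EffectsTable", "data.frame")
  eff
}

#' Invert a Yates effects table back to responses
#'
#' @param effects An `EffectsTable` from [yates_effects()].
#' @return The standard-order response vector.
#' @export
inverse_yates <- function(effects) {
  k <- attr(effects, "k")
  n <- 2^k
  mean_ <- effects$effect[1]
  half_eff <- effects$effect[-1] / 2
  vapply(0:(n - 1), function(run) {
    v <- mean_
    for (j in 1:(n - 1)) {
      on <- which(bitwAnd(j, 2^(0:(k - 1))) > 0)
      sgn <- prod(ifelse(bitwAnd(run, 2^(on - 1)) > 0, 1, -1))
      v <- v + sgn * half_eff[j]
    }
    v
  }, 0)
}

#' Run the 2^4 climate factorial and compute Yates effects
#'
#' The four climate factors (temperature, wind, humidity, cloud) are set to
#' their scenario-envelope low/high levels ("temperature" moves the min and
#' max of the envelope together); one annual simulation per run of the
#' standard-order design.
#'
#' @param animal An `AnimalSpec`.
#' @param phys A `PhysiologySpec`.
#' @param base_scenario Scenario whose envelope supplies the factor levels.
#' @param months Months per annual run (scaled designs may use fewer).
#' @return List: `effects` (EffectsTable), `responses` (16 annual ME values),
#'   `design` (run matrix).
#' @export
climate_factorial <- function(animal, phys, base_scenario = build_scenario("hot_arid"),
                              months = 1:12) {
  sc <- base_scenario
  # "temperature" moves the whole envelope between the cold and hot regimes;
  # the other factors pin their diurnal curve at the envelope's low or high end
  levels <- list(
    temperature = list(low = c(sc$air_temp_min, sc$air_temp_max) - 10,
                       high = c(sc$air_temp_min, sc$air_temp_max)),
    wind = list(low = c(sc$wind_min, sc$wind_min), high = c(sc$wind_max, sc$wind_max)),
    humidity = list(low = c(sc$rh_min, sc$rh_min), high = c(sc$rh_max, sc$rh_max)),
    cloud = list(low = c(sc$cloud_min, sc$cloud_min), high = c(sc$cloud_max, sc$cloud_max))
  )
  design <- expand.grid(temperature = 0:1, wind = 0:1, humidity = 0:1,
                        cloud = 0:1)
  responses <- numeric(16)
  for (i in 1:16) {
    s <- sc
    tl <- if (design$temperature[i] == 1) levels$temperature$high else levels$temperature$low
    s$air_temp_min <- tl[1]; s$air_temp_max <- tl[2]
    wl <- if (design$wind[i] == 1) levels$wind$high else levels$wind$low
    s$wind_min <- wl[1]; s$wind_max <- wl[2]
    hl <- if (design$humidity[i] == 1) levels$humidity$high else levels$humidity$low
    s$rh_min <- hl[1]; s$rh_max <- hl[2]
    cl <- if (design$cloud[i] == 1) levels$cloud$high else levels$cloud$low
    s$cloud_min <- cl[1]; s$cloud_max <- cl[2]
    yr <- simulate_year(animal, phys, s, months = months)
    responses[i] <- yr$annual_me * sum(month_lengths()) / sum(month_lengths()[months])
  }
  list(effects = yates_effects(responses), responses = responses,
       design = design)
}

#' Single-parameter annual sensitivity sweep
#'
#' One annual simulation per value of the swept parameter with everything
#' else fixed.
#'
#' @param parameter One of `mass`, `wind`, `reflectivity`,
#'   `muscle_efficiency`, `respiratory_extraction`, `digestive_efficiency`,
#'   `latitude`, `insulation_mode`.
#' @param values Values to sweep.
#' @param animal,phys,scenario,diet Base configuration.
#' @param months Months per annual run.
#' @return Data frame: value, annual_me_MJ, annual_food_kg, annual_water_l,
#'   class.
#' @export
sweep_parameter <- function(parameter, values, animal, phys,
                            scenario = build_scenario("hot_arid"),
                            diet = build_diet(if (animal$taxon == "plateosaurus")
                              "high_browser" else "carnivore"),
                            months = 1:12) {
  supported <- c("mass", "wind", "reflectivity", "muscle_efficiency",
                 "respiratory_extraction", "digestive_efficiency",
                 "latitude", "insulation_mode")
  if (!(parameter %in% supported))
    stop_config("unsupported sweep parameter '%s'; supported: %s", parameter,
                paste(supported, collapse = ", "))
  rows <- lapply(values, function(v) {
    a <- animal; p <- phys; s <- scenario; d <- diet; lat <- NULL
    if (parameter == "mass") {
      a <- scale_mass_by_diameter(a, v)
      p <- build_physiology(p$grade, p$ctr_label, v, taxon = a$taxon,
                            activity_multiplier = p$activity_multiplier,
                            muscle_efficiency = p$muscle_efficiency)
    } else if (parameter == "wind") {
      s$wind_min <- v[1]; s$wind_max <- if (length(v) > 1) v[2] else v[1]
    } else if (parameter == "reflectivity") {
      a$skin_reflectivity_pct <- v
      a$segments <- lapply(a$segments, function(seg) {
        for (side in c("insulation_dorsal", "insulation_ventral"))
          if (!is.null(seg[[side]])) seg[[side]]$surface_reflectivity <- v
        seg
      })
    } else if (parameter == "muscle_efficiency") {
      p$muscle_efficiency <- v
    } else if (parameter == "respiratory_extraction") {
      p$o2_extraction_range <- c(min(p$o2_extraction_range), v)
    } else if (parameter == "digestive_efficiency") {
      d$digestive_efficiency <- v
    } else if (parameter == "latitude") {
      lat <- v
    } else if (parameter == "insulation_mode") {
      a <- build_animal(a$taxon, a$total_mass, insulation = v)
    }
    yr <- simulate_year(a, p, s, diet = d, months = months,
                        latitude_override = lat)
    data.frame(value = paste(v, collapse = "-"),
               annual_me_MJ = yr$annual_me,
               annual_food_kg = yr$annual_food_kg,
               annual_water_l = yr$annual_water_l,
               class = yr$viability)
  })
  do.call(rbind, rows)
}
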