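# The hourly thermoregulation controller: physiological options engaged in a
# fixed order (insulation erection, vasomotor flesh conductivity, core
# temperature within the CTR, skin wetting if allowed, panting), then
# behavioural options (shade / night shade, wind shelter, posture), each
# re-solving the whole-animal balance, until the required heat production is
# within tolerance of the target.

#' Daily target metabolic energy
#'
#' RMR times the activity multiplier integrated over a day:
#' `rmr * multiplier * 86400 / 1e6` MJ/day.
#'
#' @param rmr Resting metabolic rate, W.
#' @param activity_multiplier Dimensionless scope (>= 1).
#' @return MJ/day.
#' @examples
#' daily_target_me(301.1, 2)  # 52.03 MJ/day
#' @export
daily_target_me <- function(rmr, activity_multiplier) {
  if (any(rmr < 0)) stop_config("rmr must be non-negative")
  if (any(activity_multiplier < 1)) stop_config("activity_multiplier must be >= 1")
  rmr * activity_multiplier * 86400 / 1e6
}

.neutral_state <- function(phys) {
  list(
    erect_fraction = 0,
    flesh_conductivity = mean(phys$flesh_conductivity_range),
    t_core = phys$ctr_target,
    wet_fraction = 0.005,
    o2_extraction = max(phys$o2_extraction_range),
    in_shade = FALSE, wind_sheltered = FALSE, posture = "standing"
  )
}

# Required heat production H for a given controller state.
.solve_state <- function(animal, phys, env_sun, env_shade, state, w_mech) {
  env <- if (state$in_shade) env_shade else env_sun
  # vegetative wind shelter halves the wind at animal height (not a burrow)
  if (state$wind_sheltered) env$wind_animal <- max(0.1, env$wind_animal * 0.5)
  a <- if (state$posture == "posture3") apply_posture(animal, "posture3") else animal
  q <- animal_balance(a, state$t_core, state, env, q_extra = w_mech)
  list(H = q$q_met, fluxes = q)
}

# Engage one bounded continuous option. `set` writes a value in [from, to]
# into the state; the response H(value) is monotone in the option variable.
# Full engagement is evaluated first: if the animal is still on the same side
# of the target the option is locked at full and the next option engages;
# if the target is crossed the engagement fraction is refined by bisection
# until the heat production is within tolerance. Returns
# list(state, sol, done, crossed).
.engage_option <- function(animal, phys, env_sun, env_shade, state, w_mech,
                           target, tol, from, to, set, steps = 10) {
  eval_at <- function(v) {
    st <- set(state, v)
    list(st = st, sol = .solve_state(animal, phys, env_sun, env_shade, st, w_mech))
  }
  if (from == to) {
    e <- eval_at(from)
    return(list(state = e$st, sol = e$sol, done = abs(e$sol$H - target) <= tol))
  }
  base <- eval_at(from)
  side0 <- sign(base$sol$H - target)
  full <- eval_at(to)
  if (abs(full$sol$H - target) <= tol)
    return(list(state = full$st, sol = full$sol, done = TRUE))
  if (sign(full$sol$H - target) == side0) {
    # option saturates without reaching target: lock at full, not done
    return(list(state = full$st, sol = full$sol, done = FALSE))
  }
  if (steps <= 2) {
    # binary (behavioural) option: engaged or not; pick the closer state
    pick <- if (abs(base$sol$H - target) < abs(full$sol$H - target)) base else full
    return(list(state = pick$st, sol = pick$sol,
                done = abs(pick$sol$H - target) <= tol, crossed = TRUE))
  }
  # crossed: bisect the engagement fraction to tolerance
  lo <- from; hi <- to
  best <- full
  for (i in 1:30) {
    mid <- (lo + hi) / 2
    e <- eval_at(mid)
    if (abs(e$sol$H - target) <= tol)
      return(list(state = e$st, sol = e$sol, done = TRUE, crossed = TRUE))
    if (abs(e$sol$H - target) < abs(best$sol$H - target)) best <- e
    if (sign(e$sol$H - target) == side0) lo <- mid else hi <- mid
  }
  list(state = best$st, sol = best$sol,
       done = abs(best$sol$H - target) <= tol, crossed = TRUE)
}

#' Solve one hour of thermoregulation
#'
#' Starting from the neutral state (flat insulation, mid flesh conductivity,
#' target core temperature, baseline skin wetness and O2 extraction, open
#' site, standing), engages options in order until the metabolic heat
#' production required to hold core temperature is within `tolerance` of the
#' target, or options are exhausted (the closest achievable solution is then
#' returned). Cold-side order: erect insulation, vasoconstrict, lower core
#' temperature, then night shade, wind shelter, posture 3. Hot-side order:
#' vasodilate, raise core temperature, (sweat if enabled), pant, then seek
#' shade. Once an option's full engagement overshoots the target the
#' controller stops at the lattice step nearest the target.
#'
#' @param animal An `AnimalSpec`.
#' @param phys A `PhysiologySpec`.
#' @param env_sun,env_shade One-row environment frames for the open and
#'   deep-shade sites of the same hour.
#' @param behaviors_enabled Character vector drawn from
#'   `c("shade", "night_shade", "wind_shelter", "posture")`.
#' @param activity_multiplier Override of the physiology's multiplier.
#' @param tolerance Relative tolerance on the target heat production (0.01).
#' @return An `HourResult` list: `fluxes`, `state`, `target_met`,
#'   `achieved_met` (W), `stress` (none/cold/heat), `active`, `t_core`.
#' @export
solve_hour <- function(animal, phys, env_sun, env_shade = env_sun,
                       behaviors_enabled = c("shade", "night_shade",
                                             "wind_shelter", "posture"),
                       activity_multiplier = phys$activity_multiplier,
                       tolerance = 0.01) {
  mult <- activity_multiplier
  w_mech <- phys$rmr * (mult - 1) * phys$muscle_efficiency
  target_met <- phys$rmr * mult
  target_h <- target_met - w_mech     # heat production target, W
  tol <- tolerance * target_h

  state <- .neutral_state(phys)
  sol <- .solve_state(animal, phys, env_sun, env_shade, state, w_mech)
  is_night <- env_sun$solar_direct + env_sun$solar_diffuse <= 0

  if (abs(sol$H - target_h) > tol) {
    cold <- sol$H > target_h
    has_erectable <- any(vapply(animal$segments, function(s) {
      isTRUE(s$insulation_dorsal$erectable) || isTRUE(s$insulation_ventral$erectable)
    }, TRUE))
    opts <- list()
    if (cold) {
      if (has_erectable)
        opts <- c(opts, list(list(0, 1, function(st, v) { st$erect_fraction <- v; st })))
      opts <- c(opts, list(
        list(state$flesh_conductivity, min(phys$flesh_conductivity_range),
             function(st, v) { st$flesh_conductivity <- v; st }),
        list(phys$ctr_target, phys$ctr_min,
             function(st, v) { st$t_core <- v; st })))
      if ("night_shade" %in% behaviors_enabled && is_night)
        opts <- c(opts, list(list(0, 1, function(st, v) { st$in_shade <- v > 0.5; st },
                                  2)))  # binary
      if ("wind_shelter" %in% behaviors_enabled)
        opts <- c(opts, list(list(0, 1, function(st, v) { st$wind_sheltered <- v > 0.5; st }, 2)))
      if ("posture" %in% behaviors_enabled)
        opts <- c(opts, list(list(0, 1, function(st, v) {
          st$posture <- if (v > 0.5) "posture3" else "standing"; st }, 2)))
    } else {
      opts <- c(opts, list(
        list(state$flesh_conductivity, max(phys$flesh_conductivity_range),
             function(st, v) { st$flesh_conductivity <- v; st }),
        list(phys$ctr_target, phys$ctr_max,
             function(st, v) { st$t_core <- v; st })))
      if (isTRUE(phys$sweating_enabled))
        opts <- c(opts, list(list(0.005, 1, function(st, v) { st$wet_fraction <- v; st })))
      opts <- c(opts, list(
        list(max(phys$o2_extraction_range), min(phys$o2_extraction_range),
             function(st, v) { st$o2_extraction <- v; st })))
      if ("shade" %in% behaviors_enabled && !is_night)
        opts <- c(opts, list(list(0, 1, function(st, v) { st$in_shade <- v > 0.5; st }, 2)))
    }
    for (op in opts) {
      steps <- if (length(op) >= 4) op[[4]] else 10
      res <- .engage_option(animal, phys, env_sun, env_shade, state, w_mech,
                            target_h, tol, op[[1]], op[[2]], op[[3]], steps)
      state <- res$state
      sol <- res$sol
      if (res$done || isTRUE(res$crossed)) break
    }
  }

  h_final <- sol$H
  stress <- if (abs(h_final - target_h) <= tol) "none"
            else if (h_final > target_h) "cold" else "heat"
  active <- stress != "heat"
  # resting metabolism is obligatory: a heat-stressed hour cannot report heat
  # production below RMR (the excess is transient storage the CTR absorbs)
  achieved <- max(h_final, phys$rmr) + if (active) w_mech else 0
  list(fluxes = sol$fluxes, state = state,
       target_met = target_met, achieved_met = achieved,
       stress = stress, active = active, t_core = state$t_core)
}

#' Simulate one model day
#'
#' Runs [solve_hour()] for each of the day's 24 hours and aggregates
#' metabolic energy and water loss; the food and water budgets follow from
#' the day's metabolic energy and the diet.
#'
#' @param animal An `AnimalSpec`.
#' @param phys A `PhysiologySpec`.
#' @param day_env A `DayEnvironment` from [microclimate_day()], or a list
#'   with `sun`/`shade` 24-row frames.
#' @param diet A `DietSpec` (carnivore default for the theropod shape, high
#'   browser for the prosauropod).
#' @param behaviors_enabled Behavioural options available.
#' @return A `DayResult` list: `hourly` (list of 24 HourResults), `daily_me`
#'   (MJ), `daily_target` (MJ), `food_kg`, `water` (a `MassBudget`),
#'   `shade_hours`, `active_hours`, `stress_hours`, `t_core` (24-vector).
#' @export
simulate_day <- function(animal, phys, day_env,
                         diet = build_diet(if (animal$taxon == "plateosaurus")
                           "high_browser" else "carnivore"),
                         behaviors_enabled = c("shade", "night_shade",
                                               "wind_shelter", "posture")) {
  hourly <- vector("list", 24)
  for (h in 1:24) {
    hourly[[h]] <- solve_hour(animal, phys, day_env$sun[h, ], day_env$shade[h, ],
                              behaviors_enabled = behaviors_enabled)
  }
  achieved <- vapply(hourly, `[[`, 0, "achieved_met")
  daily_me <- sum(achieved) * 3600 / 1e6
  resp_g <- mean(vapply(hourly, function(x) x$fluxes$mass_exchange$resp_water_loss, 0))
  cut_g <- sum(vapply(hourly, function(x) x$fluxes$q_evap, 0)) * 3600 /
    latent_heat(30) * 1000  # J/day over latent heat -> kg, to g/day
  food <- food_requirement(daily_me, diet)
  water <- water_budget(food, diet, resp_g, cut_g)
  list(
    hourly = hourly,
    daily_me = daily_me,
    daily_target = daily_target_me(phys$rmr, phys$activity_multiplier),
    food_kg = food$m_in,
    water = water,
    shade_hours = sum(vapply(hourly, function(x) x$state$in_shade, TRUE)),
    active_hours = sum(vapply(hourly, `[[`, TRUE, "active")),
    stress_hours = sum(vapply(hourly, `[[`, "", "stress") != "none"),
    t_core = vapply(hourly, `[[`, 0, "t_core"),
    achieved_met = achieved
  )
}

#' Simulate a model year
#'
#' Twelve mid-month model days weighted by month lengths.
#'
#' @inheritParams simulate_day
#' @param scenario A `MicroclimateScenario`.
#' @param months Months to simulate (1:12).
#' @param latitude_override Optional latitude replacing the scenario's.
#' @param day_envs Optional precomputed list of `DayEnvironment`s (one per
#'   entry of `months`), e.g. shared across the cells of a viability matrix.
#' @return An `AnnualResult` list: `annual_me`, `annual_target` (MJ),
#'   `annual_food_kg`, `annual_water_l`, `days` (list of DayResults),
#'   `monthly_me` (MJ/day per month), `ratio` (annual/target),
#'   `viability` class.
#' @export
simulate_year <- function(animal, phys, scenario,
                          diet = build_diet(if (animal$taxon == "plateosaurus")
                            "high_browser" else "carnivore"),
                          behaviors_enabled = c("shade", "night_shade",
                                                "wind_shelter", "posture"),
                          months = 1:12, latitude_override = NULL,
                          day_envs = NULL) {
  ml <- month_lengths()
  days <- vector("list", length(months))
  annual_me <- annual_food <- annual_water <- 0
  for (i in seq_along(months)) {
    m <- months[i]
    de <- if (!is.null(day_envs)) day_envs[[i]] else
      microclimate_day(scenario, m, animal_height = animal$mean_height,
                       latitude_override = latitude_override)
    days[[i]] <- simulate_day(animal, phys, de, diet, behaviors_enabled)
    annual_me <- annual_me + days[[i]]$daily_me * ml[m]
    annual_food <- annual_food + days[[i]]$food_kg * ml[m]
    annual_water <- annual_water + days[[i]]$water$discretionary_water / 1000 * ml[m]
  }
  annual_target <- daily_target_me(phys$rmr, phys$activity_multiplier) *
    sum(ml[months])
  ratio <- annual_me / annual_target
  list(
    annual_me = annual_me, annual_target = annual_target,
    annual_food_kg = annual_food, annual_water_l = annual_water,
    days = days,
    monthly_me = vapply(days, `[[`, 0, "daily_me"),
    ratio = ratio,
    viability = classify_viability(annual_me, annual_target)
  )
}
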