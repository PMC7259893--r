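test_that("daily target ME reproduces the activity-scaled arithmetic", {
  expect_equal(daily_target_me(301.1, 2), 52.03, tolerance = 0.005)
  expect_equal(daily_target_me(3.4, 2), 0.59, tolerance = 0.005)
  expect_lt(daily_target_me(1e-9, 2), 1e-9)
  expect_error(daily_target_me(10, 0.5), ">= 1")
})

test_that("an hour inside the thermoneutral zone meets target with a near-neutral state", {
  a <- build_animal("coelophysis", 21, "none")
  p <- build_physiology("ratite", "narrow", 21, taxon = "coelophysis")
  env <- chamber_environment(32)
  hr <- solve_hour(a, p, env, env, behaviors_enabled = character(0))
  expect_equal(hr$stress, "none")
  expect_equal(hr$achieved_met, hr$target_met, tolerance = 0.011 * hr$target_met)
  expect_true(hr$active)
})

test_that("severe cold with options exhausted leaves the animal cold-stressed", {
  a <- build_animal("coelophysis", 21, "none")
  p <- build_physiology("ratite", "narrow", 21, taxon = "coelophysis")
  env <- chamber_environment(p$ctr_min - 20)
  hr <- solve_hour(a, p, env, env, behaviors_enabled = character(0))
  expect_equal(hr$stress, "cold")
  expect_gt(hr$achieved_met, hr$target_met)
  expect_true(hr$active)   # cold-stressed hours stay active
})

test_that("controller state always stays inside its physiological bounds", {
  a <- build_animal("coelophysis", 21, "full")
  p <- build_physiology("ratite", "broad", 21, taxon = "coelophysis")
  for (tt in c(-5, 5, 15, 25, 35, 45, 50)) {
    env <- chamber_environment(tt)
    hr <- solve_hour(a, p, env, env, behaviors_enabled = character(0))
    st <- hr$state
    expect_gte(st$t_core, p$ctr_min)
    expect_lte(st$t_core, p$ctr_max)
    expect_gte(st$erect_fraction, 0); expect_lte(st$erect_fraction, 1)
    expect_gte(st$flesh_conductivity, min(p$flesh_conductivity_range))
    expect_lte(st$flesh_conductivity, max(p$flesh_conductivity_range))
    expect_gte(st$o2_extraction, min(p$o2_extraction_range))
    expect_lte(st$o2_extraction, max(p$o2_extraction_range))
    # sweating disabled: wetness locked at baseline
    expect_equal(st$wet_fraction, 0.005)
  }
})

test_that("options engage in the stated order: earlier options absorb small loads", {
  a <- build_animal("coelophysis", 21, "full")
  p <- build_physiology("ratite", "narrow", 21, taxon = "coelophysis")
  # mildly cold: ptiloerection (option 1) should suffice; later options untouched
  mild_t <- NULL
  for (tt in seq(28, 8, by = -1)) {
    hr <- solve_hour(a, p, chamber_environment(tt), behaviors_enabled = character(0))
    if (hr$stress == "none" && hr$state$erect_fraction > 0 &&
        hr$state$erect_fraction < 1) { mild_t <- tt; mild <- hr; break }
  }
  expect_false(is.null(mild_t))
  expect_equal(mild$state$flesh_conductivity, mean(p$flesh_conductivity_range))
  expect_equal(mild$state$t_core, p$ctr_target)
  # colder: erection saturates before conductivity moves
  cold <- solve_hour(a, p, chamber_environment(mild_t - 6),
                     behaviors_enabled = character(0))
  if (cold$state$flesh_conductivity < mean(p$flesh_conductivity_range)) {
    expect_equal(cold$state$erect_fraction, 1)
  }
})

test_that("hot-side options raise core temperature before panting saturates", {
  a <- build_animal("coelophysis", 21, "none")
  p <- build_physiology("ratite", "narrow", 21, taxon = "coelophysis")
  hot <- solve_hour(a, p, chamber_environment(37), behaviors_enabled = character(0))
  if (hot$stress == "none" && hot$state$o2_extraction < max(p$o2_extraction_range)) {
    # panting engaged only after vasodilation and core rise saturated
    expect_equal(hot$state$flesh_conductivity, max(p$flesh_conductivity_range))
    expect_equal(hot$state$t_core, p$ctr_max)
  }
  expect_gte(hot$state$t_core, p$ctr_target)
})

test_that("behavioural options only help: removing them never improves the fit", {
  a <- build_animal("coelophysis", 21, "none")
  p <- build_physiology("ratite", "narrow", 21, taxon = "coelophysis")
  de <- microclimate_day(build_scenario("cold_arid"), 1, animal_height = 0.45)
  for (h in c(3, 13)) {
    with_b <- solve_hour(a, p, de$sun[h, ], de$shade[h, ])
    without <- solve_hour(a, p, de$sun[h, ], de$shade[h, ],
                          behaviors_enabled = character(0))
    expect_lte(abs(with_b$achieved_met - with_b$target_met),
               abs(without$achieved_met - without$target_met) + 1e-6)
  }
})

test_that("a day pinned inside the TNZ integrates to the daily target", {
  a <- build_animal("coelophysis", 21, "none")
  p <- build_physiology("ratite", "narrow", 21, taxon = "coelophysis")
  sc <- pinned_scenario(32)
  de <- microclimate_day(sc, 7, animal_height = a$mean_height)
  # hold the whole operative environment at chamber-like conditions
  day <- list(sun = do.call(rbind, lapply(1:24, function(h)
    chamber_environment(32, wind = 0.5))), shade = NULL)
  day$sun$hour <- 0:23
  day$shade <- day$sun
  dr <- simulate_day(a, p, day, behaviors_enabled = character(0))
  expect_equal(dr$daily_me, dr$daily_target, tolerance = 0.011 * dr$daily_target)
  expect_equal(dr$active_hours, 24)
  # daily aggregation identity
  expect_equal(dr$daily_me, sum(dr$achieved_met) * 3600 / 1e6, tolerance = 1e-9)
})

test_that("annual aggregation weights mid-month days by month lengths", {
  a <- build_animal("coelophysis", 21, "none")
  p <- build_physiology("ratite", "narrow", 21, taxon = "coelophysis")
  sc <- pinned_scenario(32)
  yr <- simulate_year(a, p, sc, months = c(1, 7))
  ml <- month_lengths()
  expect_equal(yr$annual_me,
               yr$days[[1]]$daily_me * ml[1] + yr$days[[2]]$daily_me * ml[7],
               tolerance = 1e-9)
  expect_equal(yr$annual_target,
               daily_target_me(p$rmr, 2) * (ml[1] + ml[7]), tolerance = 1e-9)
  expect_equal(sum(ml), 365L)
})

test_that("midday heat stress appears for a large animal in the hot scenario", {
  b <- build_animal("plateosaurus", 850)
  p <- build_physiology("ratite", "narrow", 850)
  de <- microclimate_day(build_scenario("hot_arid"), 7, animal_height = b$mean_height)
  dr <- simulate_day(b, p, de)
  midday <- vapply(dr$hourly[12:16], `[[`, "", "stress")
  expect_true(any(midday == "heat"))
  expect_lt(dr$active_hours, 24)
})
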