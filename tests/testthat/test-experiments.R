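test_that("viability classes follow the ratio thresholds with boundary grace", {
  expect_equal(classify_viability(100, 100), "target")
  expect_equal(classify_viability(112, 100), "far_above")
  expect_equal(classify_viability(93, 100), "below")
  expect_equal(classify_viability(85, 100), "far_below")
  expect_equal(classify_viability(107, 100), "above")
  # boundaries assign to the milder class
  expect_equal(classify_viability(95, 100), "target")
  expect_equal(classify_viability(105, 100), "target")
  expect_equal(classify_viability(90, 100), "below")
  expect_equal(classify_viability(110, 100), "above")
  expect_error(classify_viability(10, 0), "positive")
})

test_that("Yates effects equal brute-force contrast averages on random responses", {
  set.seed(7)
  design <- expand.grid(x1 = c(-1, 1), x2 = c(-1, 1), x3 = c(-1, 1),
                        x4 = c(-1, 1))
  for (rep in 1:5) {
    y <- rnorm(16, 100, 20)
    eff <- yates_effects(y)
    # brute force: effect = mean(high) - mean(low) over the contrast column
    for (j in 1:4) {
      contrast <- design[, j]
      expected <- mean(y[contrast == 1]) - mean(y[contrast == -1])
      term <- c("temperature", "wind", "humidity", "cloud")[j]
      expect_equal(eff$effect[eff$term == term], expected, tolerance = 1e-10)
    }
    # two-factor interaction, brute force on the product column
    c12 <- design$x1 * design$x2
    expect_equal(eff$effect[eff$term == "temperature:wind"],
                 mean(y[c12 == 1]) - mean(y[c12 == -1]), tolerance = 1e-10)
    # inverse transform recovers the responses exactly
    expect_equal(inverse_yates(eff), y, tolerance = 1e-9)
  }
})

test_that("a purely additive response has zero interactions", {
  design <- expand.grid(x1 = 0:1, x2 = 0:1, x3 = 0:1, x4 = 0:1)
  y <- 10 + 3 * design$x1 - 2 * design$x2
  eff <- yates_effects(y)
  inter <- grepl(":", eff$term)
  expect_true(all(abs(eff$effect[inter]) < 1e-10))
  expect_equal(eff$effect[eff$term == "temperature"], 3)
  expect_equal(eff$effect[eff$term == "wind"], -2)
  expect_error(yates_effects(rnorm(12)), "power of two")
})

test_that("thermoneutral-zone comparison arithmetic reports widths and shifts", {
  cmpres <- tnz_compare(c(32, 45), c(15, 36))
  expect_equal(cmpres$width_change, 8)
  expect_equal(cmpres$upper_shift, -9)
  expect_equal(cmpres$lower_shift, -17)
})

test_that("the chamber TNZ is a single interval that responds to RMR and insulation", {
  a <- build_animal("coelophysis", 21, "none")
  p_rat <- build_physiology("ratite", "narrow", 21, taxon = "coelophysis")
  p_sq <- build_physiology("squamate", "narrow", 21, taxon = "coelophysis")
  t_rat <- metabolic_chamber(a, p_rat, 10, 45, 1)
  t_sq <- metabolic_chamber(a, p_sq, 10, 45, 1)
  for (tz in list(t_rat, t_sq)) {
    expect_false(is.na(tz$lower_critical))
    expect_lte(tz$lower_critical, tz$upper_critical)
    # the thermoneutral hours form one contiguous block
    neutral <- tz$grid$stress == "none"
    runs <- rle(neutral)
    expect_equal(sum(runs$values), 1)
  }
  # achieved metabolic rate is non-increasing up to the zone
  below <- t_rat$grid$t_air_C <= t_rat$lower_critical
  expect_true(all(diff(t_rat$grid$q_met_W[below]) <= 1e-6))
  # higher RMR grade: wider zone, both bounds lower
  expect_gt(t_rat$width, t_sq$width)
  expect_lt(t_rat$lower_critical, t_sq$lower_critical)
  expect_lt(t_rat$upper_critical, t_sq$upper_critical)

  # insulation: lower critical drops by more than the upper bound
  af <- build_animal("coelophysis", 21, "full")
  t_full <- metabolic_chamber(af, p_rat, 0, 45, 1)
  expect_lt(t_full$lower_critical, t_rat$lower_critical)
  d <- tnz_compare(t_rat, t_full)
  expect_gt(d$width_change, 0)
  expect_lt(abs(d$upper_shift), abs(d$lower_shift))
})

test_that("a one-cell matrix is identical to a direct annual simulation", {
  a <- build_animal("coelophysis", 21, "none")
  vm <- run_matrix(a, scenarios = "hot", grades = "ratite", ctrs = "narrow",
                   months = c(1, 7))
  p <- build_physiology("ratite", "narrow", 21, taxon = "coelophysis")
  yr <- simulate_year(a, p, build_scenario("hot_arid"), months = c(1, 7))
  expect_equal(vm$summary$annual_me_MJ, yr$annual_me, tolerance = 1e-9)
  expect_equal(vm$summary$class, yr$viability)
})

test_that("digestive efficiency sweeps leave annual ME identical, food changing", {
  a <- build_animal("coelophysis", 21, "none")
  p <- build_physiology("ratite", "broad", 21, taxon = "coelophysis")
  tab <- sweep_parameter("digestive_efficiency", c(0.3, 0.6, 0.85), a, p,
                         scenario = build_scenario("hot_arid"),
                         months = 7)
  expect_identical(tab$annual_me_MJ[1], tab$annual_me_MJ[2])
  expect_identical(tab$annual_me_MJ[2], tab$annual_me_MJ[3])
  expect_true(all(diff(tab$annual_food_kg) < 0))
  expect_error(sweep_parameter("gait", 1, a, p), "unsupported")
})

test_that("annual energy responds to mass in the hot scenario direction", {
  a <- build_animal("plateosaurus", 850)
  p <- build_physiology("ratite", "narrow", 850)
  tab <- sweep_parameter("mass", c(850, 3000), a, p,
                         scenario = build_scenario("hot_arid"), months = 7)
  # larger animals are more heat stressed: ratio to target declines
  targets <- vapply(c(850, 3000), function(m)
    daily_target_me(as.numeric(rmr_for_mass("plateosaurus", "ratite", m)), 2) * 31, 0)
  ratios <- tab$annual_me_MJ / targets
  expect_lt(ratios[2], ratios[1])
})

test_that("the climate factorial ranks temperature first and wind second", {
  a <- build_animal("coelophysis", 21, "none")
  p <- build_physiology("ratite", "narrow", 21, taxon = "coelophysis")
  cf <- climate_factorial(a, p, build_scenario("cold_arid"), months = 7)
  eff <- cf$effects
  main <- function(t) abs(eff$effect[eff$term == t])
  expect_gt(main("temperature"), main("wind"))
  expect_gt(main("wind"), main("humidity"))
  expect_gt(main("wind"), main("cloud"))
  # reconstruction of the 16 responses from the effects table
  expect_equal(inverse_yates(eff), cf$responses, tolerance = 1e-6)
})
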