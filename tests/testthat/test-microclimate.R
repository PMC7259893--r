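test_that("diurnal curve anchors the extremes at sunrise and noon + 1 h", {
  expect_equal(diurnal_curve(26, 40, 6, 12, 6), 26)
  expect_equal(diurnal_curve(26, 40, 6, 12, 13), 40)
  # half-phase of the rising cosine: exact midpoint
  expect_equal(diurnal_curve(26, 40, 6, 12, 9.5), 33)
  # inverted phase peaks at sunrise (humidity, cloud)
  expect_equal(diurnal_curve(10, 90, 6, 12, 6, phase = "inverted"), 90)
  expect_equal(diurnal_curve(10, 90, 6, 12, 13, phase = "inverted"), 10)
  expect_error(diurnal_curve(40, 26, 6, 12, 6), "v_min")
})

test_that("diurnal curve is continuous and 24-h periodic", {
  h <- seq(0, 24, by = 0.01)
  v <- diurnal_curve(16, 30, 6.4, 12, h)
  expect_equal(v[1], v[length(v)], tolerance = 1e-9)
  expect_lt(max(abs(diff(v))), 0.05)        # no jumps
  expect_equal(range(v), c(16, 30), tolerance = 1e-6)
})

test_that("solar flux matches the documented transmittance formulation", {
  # midnight: sun below horizon
  s <- solar_flux(12, 80, 0, 0, 0)
  expect_equal(s$direct + s$diffuse, 0)
  # solar noon near equinox: hand-computed S0 * cos(z) * tau^airmass
  doy <- 80
  decl <- 23.45 * sin(2 * pi * (284 + doy) / 365)
  cz <- cos((12 - decl) * pi / 180)
  expected_total <- 1361 * cz * 0.70^(1 / cz)
  s <- solar_flux(12, doy, 12, 0, 0)
  expect_equal(s$direct + s$diffuse, expected_total, tolerance = 1e-6)
  expect_equal(s$diffuse / (s$direct + s$diffuse), 0.15, tolerance = 1e-9)
  # full overcast strictly attenuates
  sc <- solar_flux(12, doy, 12, 100, 0)
  expect_lt(sc$direct + sc$diffuse, expected_total)
  expect_equal((sc$direct + sc$diffuse) / expected_total, 0.35, tolerance = 1e-6)
})

test_that("longwave sky temperature follows the documented emissivity correlation", {
  # overcast sky radiates near air temperature
  expect_equal(longwave_sky(20, 50, 100), 20, tolerance = 2)
  # clear sky is colder than the air
  expect_lt(longwave_sky(20, 50, 0), 20)
  # hand evaluation of the temperature-only correlation at 30 degC, clear
  eps <- 9.365e-6 * 303.15^2
  expected <- eps^0.25 * 303.15 - 273.15
  expect_equal(longwave_sky(30, 80, 0), expected, tolerance = 1e-9)
})

test_that("log profiles interpolate between surface and reference", {
  p <- env_at_height(30, 3, 45, z = 2, roughness = 0.01, ref_height = 2)
  expect_equal(p$t_air, 30)
  expect_equal(p$wind, 3)
  expect_warning(p0 <- env_at_height(30, 3, 45, z = 0.005, roughness = 0.01),
                 "roughness")
  expect_equal(p0$wind, 0)
  expect_equal(p0$t_air, 45)
  # geometric midpoint on the log coordinate gives the arithmetic mean
  zmid <- sqrt(0.01 * 2)
  pm <- env_at_height(30, 3, 45, z = zmid, roughness = 0.01, ref_height = 2)
  expect_equal(pm$t_air, (30 + 45) / 2, tolerance = 1e-9)
  expect_equal(pm$wind, 1.5, tolerance = 1e-9)
})

test_that("constant forcing relaxes the soil column to isothermal equilibrium", {
  soil <- default_soil()
  forcing <- data.frame(t_air = 20, wind = 1, t_sky = 20, solar = 0)[rep(1, 24), ]
  grid <- solve_soil(soil, forcing)
  expect_lt(max(abs(grid$temperatures - 20)), 0.05)
  expect_lt(max(abs(grid$surface_flux$residual)), 0.1)
})

test_that("soil solver reproduces the analytic sinusoidal damping depth", {
  # strong convective coupling pins the surface to a sinusoidal air
  # temperature; conduction then damps the amplitude as exp(-z / D)
  soil <- default_soil()
  soil$node_depths <- seq(0, 1, by = 0.025)
  k <- soil$thermal_conductivity; C <- soil$volumetric_heat_capacity
  omega <- 2 * pi / 86400
  D <- sqrt(2 * k / (C * omega))
  hours <- 0:23
  forcing <- data.frame(
    t_air = 20 + 8 * sin(2 * pi * hours / 24),
    wind = 2000,      # h ~ 7600 W/m^2/K: surface follows air temperature
    t_sky = 20 + 8 * sin(2 * pi * hours / 24),
    solar = 0)
  grid <- solve_soil(soil, forcing, substeps = 30, max_days = 40)
  amp <- apply(grid$temperatures, 2, function(x) (max(x) - min(x)) / 2)
  surf_amp <- amp[1]
  expect_equal(surf_amp, 8, tolerance = 0.02)
  for (z_test in c(0.05, 0.1, 0.15)) {
    i <- which.min(abs(soil$node_depths - z_test))
    expected_ratio <- exp(-soil$node_depths[i] / D)
    expect_equal(amp[i] / surf_amp, expected_ratio, tolerance = 0.02)
  }
})

test_that("a converged scenario day is periodic, spans its envelope, and lags the sun", {
  sc <- build_scenario("hot_arid")
  de <- microclimate_day(sc, 7, animal_height = 0.45)
  env <- month_envelope(sc, 7)
  expect_equal(min(de$sun$t_air_ref), env$t_min, tolerance = 0.01)
  expect_equal(max(de$sun$t_air_ref), env$t_max, tolerance = 0.01)
  # no solar at night, non-negative always
  night <- de$sun$hour < floor(de$sunrise) | de$sun$hour > ceiling(de$sunset)
  expect_true(all(de$sun$solar_direct[night] == 0))
  expect_true(all(de$sun$solar_direct >= 0 & de$sun$solar_diffuse >= 0))
  # shade site: solar reduced by shade_max, canopy radiant temp >= open sky
  expect_true(all(de$shade$solar_direct <=
                    (1 - sc$shade_max / 100) * de$sun$solar_direct + 1e-9))
  expect_true(all(de$shade$t_sky >= de$sun$t_sky - 1e-9))
  # surface maximum occurs after solar noon; deep node near the daily mean
  expect_gt(which.max(de$sun$t_ground_surface), 13)
  deep <- de$soil_sun$temperatures[, ncol(de$soil_sun$temperatures)]
  expect_equal(mean(deep), mean(de$sun$t_air_ref), tolerance = 0.5)
  # surface-node energy closure on the converged day
  expect_lt(max(abs(de$soil_sun$surface_flux$residual)), 0.1)
})

test_that("doubling soil node resolution barely changes the surface temperature", {
  sc <- build_scenario("hot_arid")
  de1 <- microclimate_day(sc, 7, animal_height = 0.45)
  sc2 <- sc
  sc2$substrate <- default_soil(n_nodes = 19)
  de2 <- microclimate_day(sc2, 7, animal_height = 0.45)
  expect_lt(max(abs(de1$sun$t_ground_surface - de2$sun$t_ground_surface)), 0.1)
})
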