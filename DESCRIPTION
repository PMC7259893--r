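Package: dinotherm
Title: Coupled Microclimate and Animal Heat- and Mass-Balance Simulation for Extinct Taxa
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic biophysical modelling of terrestrial vertebrates in
    parameterised microclimates. Generates hourly above- and below-ground
    environments (diurnal sinusoidal forcing, clear-sky solar geometry,
    longwave sky emissivity, a one-dimensional finite-difference soil heat
    solver), builds animals as assemblies of simple geometric segments with
    optional fat and porous feather/fur insulation layers, and solves a
    steady-state heat balance per segment per hour for the metabolic heat
    production that holds a target core temperature. An hourly thermoregulation
    controller engages physiological then behavioural options in a fixed
    order, and experiment drivers reproduce metabolic-chamber thermoneutral
    zone sweeps, annual energy/food/water budgets, viability matrices over
    resting-metabolic-rate grades and core-temperature ranges, parameter
    sweeps, and two-level full-factorial (Yates) climate sensitivity analyses.
    Shipped parameterisations target two Late Triassic dinosaurs (a 21 kg
    theropod and an 850 kg prosauropod) in six bounding tropical
    palaeoclimates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
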