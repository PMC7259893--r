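# Shared fixtures built in code.

neutral_state <- function(k_flesh = 1.6, wet = 0.005, erect = 0, extr = 0.2) {
  list(flesh_conductivity = k_flesh, erect_fraction = erect,
       wet_fraction = wet, o2_extraction = extr)
}

# A single bare cylinder "animal" for composition and oracle tests.
toy_segment <- function(name = "torso", r = 0.05, L = 0.4, density = 0.97) {
  list(name = name, shape = "cylinder", dimensions = list(r = r, L = L),
       flesh_density = density, flesh_conductivity = 1.6,
       fat_layer_thickness = 0, insulation_dorsal = NULL,
       insulation_ventral = NULL, count = 1)
}

toy_animal <- function(segments = list(toy_segment())) {
  m <- sum(vapply(segments, function(s) dinotherm::segment_properties(s)$mass, 0))
  structure(list(taxon = "toy", segments = segments, total_mass = m,
                 mean_height = 0.3, standing_height = 0.3,
                 skin_reflectivity_pct = 15, fat_fraction = 0,
                 insulation_mode = "none", posture = "standing"),
            class = "AnimalSpec")
}

# A chamber-like synthetic scenario whose air temperature is pinned inside a
# typical thermoneutral zone all day (no diurnal range).
pinned_scenario <- function(t = 30) {
  sc <- build_scenario("hot_arid")
  sc$air_temp_min <- t
  sc$air_temp_max <- t
  sc
}
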