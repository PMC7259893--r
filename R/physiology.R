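# Physiology grades (RMR), core temperature ranges, diets and insulation
# parameter sets for the two shipped taxa.

# Tabulated resting metabolic rates (W) by taxon shape and mass (kg).
# Squamate ("ecto"), monotreme ("mono") and ratite grades are tabulated;
# marsupial and eutherian grades are synthesised (see rmr_for_mass).
.rmr_table <- list(
  coelophysis = list(
    mass     = c(15, 21, 30, 40, 50, 60),
    squamate = c(2.6, 3.4, 4.5, 5.7, 6.9, 8.0),
    monotreme = c(9.7, 12.3, 16.0, 19.7, 23.1, 26.4),
    ratite   = c(17.5, 22.2, 28.5, 34.9, 40.9, 46.5)
  ),
  plateosaurus = list(
    mass     = c(600, 850, 1150, 1600, 2000, 3000),
    squamate = c(52.7, 70.1, 89.9, 117.8, 141.5, 197.2),
    monotreme = c(139.8, 179.9, 224.0, 284.4, 334.3, 448.4),
    ratite   = c(235.5, 301.1, 372.6, 470.3, 550.4, 732.5)
  )
)

.ctr_labels <- list(
  broad    = c(26, 40),
  moderate = c(32, 40),
  narrow   = c(36, 40)
)

.rmr_grades <- c("squamate", "monotreme", "marsupial", "ratite", "eutherian")

# Least-squares log-log power-law fit through tabulated (mass, RMR) pairs.
.power_fit <- function(mass, rmr) {
  f <- stats::lm.fit(cbind(1, log(mass)), log(rmr))
  c(a = exp(f$coefficients[[1]]), b = f$coefficients[[2]])
}

#' Resting metabolic rate for a taxon shape, grade and mass
#'
#' Returns the tabulated RMR when `mass` matches a tabulated row exactly;
#' otherwise the prediction of a power law fitted by least squares through the
#' tabulated (mass, RMR) pairs of that grade and taxon shape. The marsupial
#' grade is the geometric mean of the monotreme and ratite laws and the
#' eutherian grade extends the same geometric progression one step above
#' ratite; both are used only in metabolic-chamber comparisons.
#'
#' @param taxon `"coelophysis"` or `"plateosaurus"`.
#' @param grade One of squamate, monotreme, marsupial, ratite, eutherian.
#' @param mass Body mass, kg.
#' @return RMR in W. Warns (and flags via attribute `extrapolated`) when mass
#'   lies outside 1.5x the tabulated span.
#' @export
rmr_for_mass <- function(taxon, grade, mass) {
  taxon <- match.arg(taxon, names(.rmr_table))
  grade <- match.arg(grade, .rmr_grades)
  if (!is.numeric(mass) || mass <= 0) stop_config("mass must be positive")
  tab <- .rmr_table[[taxon]]
  span <- range(tab$mass)
  extrap <- mass < span[1] / 1.5 || mass > span[2] * 1.5
  if (extrap) {
    warning(sprintf("mass %g kg outside 1.5x the tabulated span [%g, %g] for %s; extrapolating",
                    mass, span[1], span[2], taxon))
  }
  value <- if (grade %in% c("squamate", "monotreme", "ratite")) {
    i <- match(mass, tab$mass)
    if (!is.na(i)) tab[[grade]][i] else {
      p <- .power_fit(tab$mass, tab[[grade]])
      p[["a"]] * mass^p[["b"]]
    }
  } else {
    mono <- rmr_for_mass(taxon, "monotreme", mass)
    rat  <- rmr_for_mass(taxon, "ratite", mass)
    if (grade == "marsupial") sqrt(mono * rat) else rat * sqrt(rat / mono)
  }
  structure(value, extrapolated = extrap)
}

#' Build a physiology specification
#'
#' Combines an RMR grade with a core temperature range (CTR) label. CTR labels
#' are nested intervals sharing a 40 degC upper bound and a 38 degC target:
#' broad 26-40, moderate 32-40, narrow 36-40.
#'
#' @param grade RMR grade, one of squamate, monotreme, marsupial, ratite,
#'   eutherian.
#' @param ctr CTR label: broad, moderate or narrow; or a numeric
#'   `c(min, max)` override.
#' @param taxon_mass Body mass in kg, used to look up/interpolate the RMR.
#' @param taxon Taxon shape for the RMR table.
#' @param activity_multiplier Field/resting metabolic scope (2 by default).
#' @param muscle_efficiency Fraction of activity energy converted to external
#'   work (not heat); mammal-like 0.20 by default.
#' @param ctr_target Target core temperature, degC.
#' @param o2_extraction_range Respiratory O2 extraction bounds (panting lowers
#'   extraction toward the minimum).
#' @param flesh_conductivity_range Vasoconstricted..vasodilated flesh
#'   conductivity, W/m/K.
#' @param fat_fraction Subcutaneous fat, percent of body mass.
#' @return A `PhysiologySpec` object.
#' @examples
#' build_physiology("ratite", "narrow", 850)$rmr  # 301.1 W
#' @export
build_physiology <- function(grade, ctr, taxon_mass,
                             taxon = if (taxon_mass < 300) "coelophysis" else "plateosaurus",
                             activity_multiplier = 2,
                             muscle_efficiency = 0.20,
                             ctr_target = 38,
                             o2_extraction_range = c(0.10, 0.20),
                             flesh_conductivity_range = c(0.4, 2.8),
                             fat_fraction = 5) {
  grade <- match.arg(grade, .rmr_grades)
  if (is.character(ctr)) {
    ctr <- match.arg(ctr, names(.ctr_labels))
    bounds <- .ctr_labels[[ctr]]
    label <- ctr
  } else {
    stopifnot(is.numeric(ctr), length(ctr) == 2, ctr[1] <= ctr[2])
    bounds <- ctr
    label <- "custom"
  }
  if (ctr_target < bounds[1] || ctr_target > bounds[2])
    stop_config("ctr_target %g outside CTR [%g, %g]", ctr_target, bounds[1], bounds[2])
  if (activity_multiplier < 1) stop_config("activity_multiplier must be >= 1")
  rmr <- rmr_for_mass(taxon, grade, taxon_mass)
  structure(list(
    grade = grade, ctr_label = label,
    rmr = as.numeric(rmr),
    ctr_min = bounds[1], ctr_target = ctr_target, ctr_max = bounds[2],
    activity_multiplier = activity_multiplier,
    muscle_efficiency = muscle_efficiency,
    o2_extraction_range = o2_extraction_range,
    flesh_conductivity_range = flesh_conductivity_range,
    sweating_enabled = FALSE,
    fat_fraction = fat_fraction,
    mass = taxon_mass, taxon = taxon
  ), class = "PhysiologySpec")
}

#' Field metabolic rate allometry
#'
#' FMR = 4.82 * mass^0.734 in the formula's native units. Exposed as a
#' diagnostic only; it is not used in the heat balance.
#'
#' @param mass Body mass, kg.
#' @return FMR value.
#' @export
fmr_allometric <- function(mass) {
  if (!is.numeric(mass) || any(mass <= 0)) stop_config("mass must be positive")
  4.82 * mass^0.734
}

#' Build a diet specification
#'
#' Three shipped diets: `high_browser` (10 % protein / 0 % fat / 88 %
#' carbohydrate of dry mass, 44 % dry matter, 60 % digestive efficiency),
#' `low_browser` (same macronutrients, 25 % dry matter) and `carnivore`
#' (60/38/0, 66.7 % dry matter, 85 % digestive efficiency). Fecal water and
#' uric-acid percentages follow the same parameter sets.
#'
#' @param name Diet label or `"custom"`.
#' @param ... For `"custom"`, named overrides of any DietSpec field.
#' @return A `DietSpec` object.
#' @export
build_diet <- function(name = c("high_browser", "low_browser", "carnivore", "custom"), ...) {
  name <- match.arg(name)
  cst <- dt_constants()
  base <- switch(name,
    high_browser = list(protein_pct = 10, fat_pct = 0, carb_pct = 88,
                        dry_matter_pct = 44, digestive_efficiency = 0.60,
                        fecal_water_pct = 60, uric_acid_pct = 60),
    low_browser  = list(protein_pct = 10, fat_pct = 0, carb_pct = 88,
                        dry_matter_pct = 25, digestive_efficiency = 0.60,
                        fecal_water_pct = 60, uric_acid_pct = 60),
    carnivore    = list(protein_pct = 60, fat_pct = 38, carb_pct = 0,
                        dry_matter_pct = 66.7, digestive_efficiency = 0.85,
                        fecal_water_pct = 46, uric_acid_pct = 27),
    custom       = list(protein_pct = 10, fat_pct = 0, carb_pct = 88,
                        dry_matter_pct = 30, digestive_efficiency = 0.60,
                        fecal_water_pct = 60, uric_acid_pct = 0)
  )
  base <- utils::modifyList(base, list(...))
  d <- structure(c(list(name = name), base, list(
    energy_density_protein = cst$e_protein,
    energy_density_fat = cst$e_fat,
    energy_density_carb = cst$e_carb
  )), class = "DietSpec")
  with(d, {
    if (protein_pct + fat_pct + carb_pct > 100 + 1e-9)
      stop_config("macronutrient percentages exceed 100")
    if (any(c(protein_pct, fat_pct, carb_pct, dry_matter_pct) < 0) ||
        dry_matter_pct > 100)
      stop_config("diet percentages must lie in 0-100")
  })
  d
}

#' Energy per wet kilogram of a food
#'
#' @param e_dry Energy density of the dry matter, MJ/kg dry.
#' @param dry_matter_pct Dry matter, percent of wet mass.
#' @return MJ per kg wet mass.
#' @examples
#' energy_per_wet_kg(11.6, 30)  # horsetail-like forage, ~3.5 MJ/kg wet
#' @export
energy_per_wet_kg <- function(e_dry, dry_matter_pct) e_dry * dry_matter_pct / 100

#' Build an insulation specification
#'
#' The shipped proto-feather coat: 30 mm element length, 10 mm resting layer
#' depth, 2000 elements/cm^2, 15 % surface reflectivity, erectable.
#'
#' @param length_mm Element length, mm.
#' @param depth_mm Resting layer depth, mm.
#' @param density_cm2 Elements per cm^2.
#' @param diameter_um Element diameter, micrometres.
#' @param reflectivity_pct Insulation/skin surface solar reflectivity, percent.
#' @param erectable Whether pilo/ptiloerection is available.
#' @param conductivity Element (keratin) conductivity, W/m/K.
#' @return An `InsulationSpec` object, or `NULL` when `density_cm2` is 0.
#' @export
build_insulation <- function(length_mm = 30, depth_mm = 10, density_cm2 = 2000,
                             diameter_um = 30, reflectivity_pct = 15,
                             erectable = TRUE,
                             conductivity = dt_constants()$k_keratin) {
  if (density_cm2 <= 0 || depth_mm <= 0) return(NULL)
  if (depth_mm > length_mm) stop_config("insulation depth exceeds element length")
  if (reflectivity_pct < 0 || reflectivity_pct > 100)
    stop_config("reflectivity outside 0-100")
  structure(list(
    element_length = length_mm, layer_depth = depth_mm,
    element_density = density_cm2, element_diameter = diameter_um,
    element_conductivity = conductivity,
    surface_reflectivity = reflectivity_pct,
    erectable = erectable
  ), class = "InsulationSpec")
}
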