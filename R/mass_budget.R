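# Mass balance: food intake from metabolic energy, respiratory gas and water
# exchange, and the daily water budget.

#' Daily food requirement from metabolic energy
#'
#' Dry-matter combustion energy density is the macronutrient-weighted sum of
#' the component energy densities; dry intake is the daily energy divided by
#' that density times digestive efficiency; wet intake divides by the dry
#' matter fraction.
#'
#' @param daily_me Daily metabolic energy, MJ.
#' @param diet A `DietSpec`.
#' @return List: `m_in` (kg wet/day), `m_abs` (kg dry absorbed/day), `m_out`
#'   (kg/day excreted, wet basis: `m_in - m_abs`), `dry_intake` (kg dry/day),
#'   `e_dry` (MJ/kg dry).
#' @export
food_requirement <- function(daily_me, diet) {
  if (daily_me < 0) stop_config("daily_me must be non-negative")
  if (diet$dry_matter_pct <= 0 || diet$digestive_efficiency <= 0)
    stop_config("diet dry matter and digestive efficiency must be positive")
  e_dry <- (diet$protein_pct * diet$energy_density_protein +
            diet$fat_pct * diet$energy_density_fat +
            diet$carb_pct * diet$energy_density_carb) / 100
  dry_intake <- daily_me / (e_dry * diet$digestive_efficiency)
  m_in <- dry_intake / (diet$dry_matter_pct / 100)
  m_abs <- dry_intake * diet$digestive_efficiency
  list(m_in = m_in, m_abs = m_abs, m_out = m_in - m_abs,
       dry_intake = dry_intake, e_dry = e_dry)
}

#' Respiratory gas exchange and evaporative water loss
#'
#' Oxygen demand follows from the metabolic rate through the oxyjoule
#' equivalent (20.1 kJ/L O2); ventilation is oxygen demand divided by the
#' extraction coefficient and the atmospheric O2 fraction. Inhaled air is
#' humidified to saturation at lung (core) temperature; exhaled air leaves at
#' a temperature recovered toward air temperature through the nostrils, so
#' water loss is ventilation times the vapour-density difference between
#' exhaled and inhaled air. A sensible term heats inspired air to exhale
#' temperature.
#'
#' @param metabolic_rate Metabolic rate, W.
#' @param o2_fraction Atmospheric O2, percent.
#' @param extraction Respiratory O2 extraction coefficient (0-1].
#' @param t_lung Lung/core temperature, degC.
#' @param inhaled_rh Relative humidity of inspired air, percent.
#' @param t_air Air temperature, degC.
#' @param nostril_recovery Fraction of the lung-to-air temperature difference
#'   recovered on exhalation (0.5 by default).
#' @return List: `vo2` (L O2/day), `vair` (L air/day), `resp_water_loss`
#'   (g/day), `q_resp` (W, evaporative + sensible respiratory heat loss).
#' @export
respiratory_exchange <- function(metabolic_rate, o2_fraction, extraction,
                                 t_lung, inhaled_rh, t_air,
                                 nostril_recovery = 0.5) {
  if (extraction <= 0 || extraction > 1) stop_config("extraction must be in (0, 1]")
  if (o2_fraction <= 0) stop_config("o2_fraction must be positive")
  cst <- dt_constants()
  vo2_lps <- metabolic_rate / (cst$oxyjoule * 1000)          # L O2 / s
  vair_lps <- vo2_lps / (o2_fraction / 100 * extraction)     # L air / s
  t_exhale <- t_lung - nostril_recovery * (t_lung - t_air)
  rho_in <- vapour_density(t_air, inhaled_rh)                # kg/m^3
  rho_out <- vapour_density(t_exhale, 100)
  water_kgps <- pmax(0, vair_lps / 1000 * (rho_out - rho_in))
  q_evap <- water_kgps * latent_heat(t_exhale)
  q_sens <- vair_lps / 1000 * 1.2 * 1006 * (t_exhale - t_air)
  list(vo2 = vo2_lps * 86400, vair = vair_lps * 86400,
       resp_water_loss = water_kgps * 1000 * 86400,
       q_resp = q_evap + q_sens)
}

#' Complete the daily water budget
#'
#' Food water is the non-dry fraction of wet intake; metabolic water applies
#' the per-gram oxidation-water coefficients to the macronutrient mix
#' actually oxidised; fecal water applies the diet's fecal water percentage
#' to excreted mass; urinary water applies the uric-acid percentage to
#' nitrogenous waste estimated from protein intake. Discretionary water is
#' intake plus metabolic water minus all losses (negative values mean the
#' animal must drink).
#'
#' @param food Result of [food_requirement()].
#' @param diet A `DietSpec`.
#' @param resp_water_loss Respiratory water loss, g/day.
#' @param cutaneous_water_loss Cutaneous evaporation, g/day.
#' @return A `MassBudget` list (masses kg/day, water terms g/day).
#' @export
water_budget <- function(food, diet, resp_water_loss,
                         cutaneous_water_loss = 0) {
  cst <- dt_constants()
  food_water <- food$m_in * (1 - diet$dry_matter_pct / 100) * 1000  # g/day
  ox <- food$m_abs * 1000   # g/day oxidised, split by macronutrient shares
  tot_pct <- diet$protein_pct + diet$fat_pct + diet$carb_pct
  metabolic_water <- ox * (diet$protein_pct * cst$mw_protein +
                           diet$fat_pct * cst$mw_fat +
                           diet$carb_pct * cst$mw_carb) / max(tot_pct, 1e-9)
  fecal_water <- food$m_out * 1000 * diet$fecal_water_pct / 100
  uric <- diet$uric_acid_pct %||% 0
  # protein is ~16 % N; uric acid (C5H4N4O3) carries 33.3 % N by mass
  n_waste <- food$dry_intake * 1000 * diet$protein_pct / 100 * 0.16 / 0.333
  urinary_water <- n_waste * uric / 100
  discretionary <- food_water + metabolic_water -
    (resp_water_loss + fecal_water + urinary_water + cutaneous_water_loss)
  structure(list(
    m_in = food$m_in, m_abs = food$m_abs, m_out = food$m_out,
    food_water = food_water, metabolic_water = metabolic_water,
    fecal_water = fecal_water, urinary_water = urinary_water,
    resp_water_loss = resp_water_loss,
    cutaneous_water_loss = cutaneous_water_loss,
    discretionary_water = discretionary
  ), class = "MassBudget")
}
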