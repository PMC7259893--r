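# Physical constants and small physics helpers shared across modules.

#' Physical and physiological constants
#'
#' Default constants used throughout the package. All are plain numbers so that
#' experiment drivers can override them through configuration.
#'
#' @format A named list:
#' \describe{
#'   \item{sigma}{Stefan-Boltzmann constant, W/m^2/K^4.}
#'   \item{solar_constant}{Top-of-atmosphere solar flux, W/m^2.}
#'   \item{tau_atm}{Clear-sky broadband transmittance per optical air mass.}
#'   \item{diffuse_fraction}{Diffuse fraction of clear-sky horizontal solar.}
#'   \item{cloud_solar_atten}{Fractional solar reduction under full overcast.}
#'   \item{oxyjoule}{Oxyjoule equivalent, kJ per litre O2 (STP).}
#'   \item{e_protein,e_fat,e_carb}{Combustion energy densities, MJ/kg.}
#'   \item{mw_protein,mw_fat,mw_carb}{Metabolic water yields, g water per g
#'     substrate oxidised.}
#'   \item{c_flesh}{Specific heat of flesh, J/kg/K.}
#'   \item{k_fat}{Thermal conductivity of subcutaneous fat, W/m/K.}
#'   \item{k_air_coef}{Intercept/slope of air conductivity vs temperature.}
#' }
#' @export
dt_constants <- function() {
  list(
    sigma            = 5.670374e-8,
    solar_constant   = 1361,
    tau_atm          = 0.70,
    diffuse_fraction = 0.15,
    cloud_solar_atten = 0.65,
    oxyjoule         = 20.1,    # kJ / L O2
    e_protein        = 17.8,    # MJ / kg
    e_fat            = 39.3,
    e_carb           = 17.5,
    mw_protein       = 0.396,   # g metabolic water / g oxidised
    mw_fat           = 1.07,
    mw_carb          = 0.556,
    c_flesh          = 3470,    # J / kg / K
    k_fat            = 0.2,     # W / m / K
    k_keratin        = 0.209    # insulation element conductivity, W / m / K
  )
}

C2K <- function(t) t + 273.15

#' Saturation vapour pressure of water
#'
#' Magnus-Tetens form over liquid water.
#'
#' @param t_c Temperature, degrees C.
#' @return Saturation vapour pressure, Pa.
#' @export
svp <- function(t_c) 610.78 * exp(17.2694 * t_c / (t_c + 238.3))

#' Absolute humidity (vapour density)
#'
#' @param t_c Air temperature, degrees C.
#' @param rh Relative humidity, percent.
#' @return Vapour density, kg/m^3.
#' @export
vapour_density <- function(t_c, rh) {
  (rh / 100) * svp(t_c) / (461.5 * C2K(t_c))
}

# Barometric pressure at elevation (Pa), isothermal approximation.
air_pressure <- function(elevation_m) 101325 * exp(-elevation_m / 8434)

# Dry-air properties at film temperature t_c (degC) and pressure p (Pa).
# Linear fits adequate over -20..60 degC.
air_properties <- function(t_c, p = 101325) {
  tk <- C2K(t_c)
  k  <- 0.02425 + 7.038e-5 * t_c            # W/m/K
  mu <- (1.458e-6 * tk^1.5) / (tk + 110.4)  # Pa s (Sutherland)
  rho <- p / (287.05 * tk)                  # kg/m^3
  list(k = k, mu = mu, rho = rho, nu = mu / rho, pr = 0.71,
       cp = 1006, beta = 1 / tk)
}

# Latent heat of vaporisation of water, J/kg.
latent_heat <- function(t_c) (2501 - 2.37 * t_c) * 1000

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
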