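# Steady-state segment and whole-animal heat balance.
#
# Each segment is a series resistance chain from core to environment:
# distributed-generation flesh (r/2k per unit area), an optional fat shell,
# an optional porous insulation layer, then parallel convection and infrared
# exchange (plus solar gain) at the outer surface. The outer surface
# temperature is found by Brent root-finding (stats::uniroot) at 1e-3 degC
# tolerance; inner temperatures follow algebraically.

#' Combined free and forced convection coefficient
#'
#' Forced convection from the Hilpert cylinder-in-crossflow correlation
#' (piecewise Nu = C Re^m Pr^(1/3)), free convection from the horizontal
#' cylinder Rayleigh correlation Nu = 0.53 Ra^(1/4), combined as
#' (Nu_forced^3 + Nu_free^3)^(1/3). Air properties are evaluated at the film
#' temperature and site elevation.
#'
#' @param characteristic_dimension Diameter, m.
#' @param wind Wind speed, m/s.
#' @param t_surface Surface temperature, degC.
#' @param t_air Air temperature, degC.
#' @param elevation Elevation, m.
#' @return Convection coefficient, W/m^2/K.
#' @export
convection_coefficient <- function(characteristic_dimension, wind, t_surface,
                                   t_air, elevation = 0) {
  d <- characteristic_dimension
  if (d <= 0) stop_config("characteristic dimension must be positive")
  film <- (t_surface + t_air) / 2
  ap <- air_properties(film, air_pressure(elevation))
  nu_forced <- 0
  if (wind > 0) {
    re <- wind * d / ap$nu
    cm <- if (re < 4) c(0.989, 0.330) else if (re < 40) c(0.911, 0.385) else
      if (re < 4000) c(0.683, 0.466) else if (re < 40000) c(0.193, 0.618) else
        c(0.027, 0.805)
    nu_forced <- cm[1] * re^cm[2] * ap$pr^(1 / 3)
  }
  ra <- 9.81 * ap$beta * abs(t_surface - t_air) * d^3 / (ap$nu^2) * ap$pr
  nu_free <- if (ra > 0) 0.53 * ra^0.25 else 0
  nu <- (nu_forced^3 + nu_free^3)^(1 / 3)
  nu * ap$k / d
}

#' Effective conductivity and conductance of a porous insulation layer
#'
#' Heat crosses the coat by parallel paths: conduction along the keratinous
#' elements (area-fraction weighted), conduction through the trapped air, and
#' thermal radiation between elements. The radiation path uses the optically
#' thick diffusion limit k_rad = 16 sigma T^3 / (3 beta) with extinction
#' coefficient beta = N d (element areal density times diameter). Erection
#' multiplies the layer depth by (1 + erect_fraction * depth_gain), capped at
#' the element length.
#'
#' @param spec An `InsulationSpec`, or `NULL` for bare skin.
#' @param erect_fraction Erection state 0-1.
#' @param t_mean Mean layer temperature, degC.
#' @param depth_gain Relative depth increase at full erection (2 by default:
#'   a 10 mm resting layer erects to its 30 mm element length).
#' @return List: `k_eff` (W/m/K), `conductance` (W/m^2/K), `depth` (m).
#'   Bare skin returns infinite conductance and zero depth.
#' @export
insulation_conductance <- function(spec, erect_fraction = 0, t_mean = 20,
                                   depth_gain = 2) {
  cst <- dt_constants()
  if (is.null(spec) || spec$layer_depth <= 0) {
    return(list(k_eff = NA_real_, conductance = Inf, depth = 0))
  }
  gain <- if (isTRUE(spec$erectable)) erect_fraction * depth_gain else 0
  depth <- min(spec$layer_depth * (1 + gain), spec$element_length) / 1000  # m
  n_m2 <- spec$element_density * 1e4            # elements / m^2
  d_m <- spec$element_diameter * 1e-6
  fill <- n_m2 * pi * d_m^2 / 4                 # element area fraction
  ap <- air_properties(t_mean)
  k_cond <- fill * spec$element_conductivity + (1 - fill) * ap$k
  beta <- n_m2 * d_m                            # extinction coefficient, 1/m
  k_rad <- 16 * cst$sigma * C2K(t_mean)^3 / (3 * beta)
  k_eff <- k_cond + k_rad
  list(k_eff = k_eff, conductance = k_eff / depth, depth = depth)
}

# Resolve per-sub-surface geometry/optics for a segment. Each segment exposes
# a dorsal and a ventral half which may carry different insulation; the dorsal
# half exchanges IR with the sky, the ventral half with the ground, and all
# direct solar plus sky diffuse falls on the dorsal half.
.sub_surfaces <- function(segment) {
  list(
    list(side = "dorsal", frac = 0.5, insulation = segment$insulation_dorsal),
    list(side = "ventral", frac = 0.5, insulation = segment$insulation_ventral)
  )
}

#' Steady-state heat balance of one body segment
#'
#' Solves for the outer surface temperature of each (dorsal/ventral)
#' sub-surface such that conduction from the core through flesh, fat and any
#' insulation equals the surface losses (convection + net IR - absorbed
#' solar + cutaneous evaporation on bare skin), and returns the metabolic
#' heat the segment flesh must generate. Solar interception uses the
#' orientation-averaged mean projected area of a convex body (A/4) for the
#' direct beam and half the surface area for diffuse.
#'
#' @param segment A `BodySegment`.
#' @param t_core Core (or effective core) temperature, degC.
#' @param state A `ThermoregState`-like list with `flesh_conductivity`,
#'   `erect_fraction`, `wet_fraction`.
#' @param env A one-row environment data frame (`HourlyEnvironment` fields).
#' @param emissivity IR emissivity of skin/insulation surfaces.
#' @param skin_reflectivity_pct Solar reflectivity of bare skin, percent.
#' @param ground_contact_area Ventral conduction interface, m^2 (posture 3).
#' @return A `HeatFluxes` list (all W): `q_met`, `q_fur`, `q_rad`, `q_conv`,
#'   `q_sol`, `q_evap`, `q_resp` (0 at segment level), `q_st` (0), plus
#'   `t_surface` (area-weighted outer surface temperature, degC).
#' @export
segment_balance <- function(segment, t_core, state, env,
                            emissivity = 0.95, skin_reflectivity_pct = 15,
                            ground_contact_area = 0) {
  cst <- dt_constants()
  sp <- segment_properties(segment)
  A <- sp$surface_area
  dchar <- sp$characteristic_dimension
  r_eq <- dchar / 2
  k_flesh <- state$flesh_conductivity %||% segment$flesh_conductivity
  r_flesh <- r_eq / (2 * k_flesh)                       # m^2 K / W
  r_fat <- (segment$fat_layer_thickness %||% 0) / cst$k_fat
  s_dir <- env$solar_direct; s_dif <- env$solar_diffuse
  cz <- max(env$cos_zenith, 0)
  s_beam_normal <- if (cz > 0.02) s_dir / cz else 0
  tair <- env$t_air_animal; wind <- env$wind_animal
  sigma <- cst$sigma

  q_met <- q_fur <- q_rad <- q_conv <- q_sol <- q_evap <- 0
  t_surf_w <- 0
  for (ss in .sub_surfaces(segment)) {
    A_s <- A * ss$frac
    ins <- insulation_conductance(ss$insulation, state$erect_fraction %||% 0,
                                  t_mean = (t_core + tair) / 2)
    bare <- !is.finite(ins$conductance) || ins$depth == 0
    r_in <- r_flesh + r_fat + if (bare) 0 else 1 / ins$conductance
    t_rad <- if (ss$side == "dorsal") env$t_sky else env$t_ground_surface
    refl <- if (bare) skin_reflectivity_pct else ss$insulation$surface_reflectivity
    absorp <- 1 - refl / 100
    qs <- if (ss$side == "dorsal") {
      absorp * (A / 4 * s_beam_normal + A_s * s_dif)
    } else 0
    wet <- if (bare) (state$wet_fraction %||% 0.005) else 0
    rho_air_v <- vapour_density(tair, env$rh)

    # convection is hoisted out of the root-find (h varies weakly with the
    # surface temperature); the fixed-h solve is re-iterated until the surface
    # temperature used for h agrees with the solution
    lo <- min(tair, t_rad, t_core) - 40
    hi <- max(tair, t_rad, t_core) + 60
    ts_h <- (t_core + tair) / 2
    ts <- ts_h
    for (iter in 1:4) {
      h <- convection_coefficient(dchar, wind, ts_h, tair, env$elevation)
      hm <- h / (1.2 * 1006) * 1.11  # Lewis relation, Le^(-2/3)
      f <- function(ts) {
        qe <- if (wet > 0) {
          max(0, wet * A_s * hm * (vapour_density(ts, 100) - rho_air_v) *
                latent_heat(ts))
        } else 0
        (t_core - ts) * A_s / r_in -
          (h * A_s * (ts - tair) +
             emissivity * sigma * A_s * (C2K(ts)^4 - C2K(t_rad)^4) - qs + qe)
      }
      ts <- tryCatch(
        stats::uniroot(f, c(lo, hi), tol = 1e-3)$root,
        error = function(e) stop_config(
          "segment '%s' (%s): no bracket for surface temperature [%g, %g]",
          segment$name, ss$side, lo, hi))
      if (abs(ts - ts_h) < 0.1) break
      ts_h <- ts
    }
    qc <- h * A_s * (ts - tair)
    qr <- emissivity * sigma * A_s * (C2K(ts)^4 - C2K(t_rad)^4)
    qe <- if (wet > 0) {
      max(0, wet * A_s * hm * (vapour_density(ts, 100) - rho_air_v) *
            latent_heat(ts))
    } else 0
    q_through <- (t_core - ts) * A_s / r_in
    q_met <- q_met + q_through
    if (!bare) q_fur <- q_fur + q_through
    q_rad <- q_rad + qr
    q_conv <- q_conv + qc
    q_sol <- q_sol + qs
    q_evap <- q_evap + qe
    t_surf_w <- t_surf_w + ts * ss$frac
  }

  # ventral conduction to substrate (posture 3): core -> flesh/fat ->
  # compressed ventral insulation -> ground surface
  if (ground_contact_area > 0) {
    ins_v <- segment$insulation_ventral
    r_c <- r_flesh + r_fat
    if (!is.null(ins_v)) {
      compressed <- ins_v
      compressed$layer_depth <- ins_v$layer_depth / 2
      ic <- insulation_conductance(compressed, 0, t_mean = env$t_ground_surface)
      r_c <- r_c + 1 / ic$conductance
    }
    q_gnd <- ground_contact_area * (t_core - env$t_ground_surface) / r_c
    q_met <- q_met + q_gnd
    q_conv <- q_conv + q_gnd   # bookkeeping: substrate conduction with convection
  }
  list(q_met = q_met, q_resp = 0, q_evap = q_evap, q_st = 0, q_fur = q_fur,
       q_rad = q_rad, q_conv = q_conv, q_sol = q_sol, t_surface = t_surf_w)
}

#' Whole-animal steady-state heat balance
#'
#' Sums segment balances. Limbs and tail are solved with an effective core
#' temperature halfway between the torso core and ambient air (appendages
#' reach 50 % of the torso-ambient difference); head, neck and torso use the
#' full core temperature. Whole-animal respiratory loss is computed once from
#' the total metabolic rate (iterated to consistency) and assigned to the
#' torso.
#'
#' @param animal An `AnimalSpec`.
#' @param t_core Core temperature, degC.
#' @param state Thermoregulatory state list (`flesh_conductivity`,
#'   `erect_fraction`, `wet_fraction`, `o2_extraction`).
#' @param env One-row environment data frame.
#' @param q_extra Additional non-segment heat load included in the
#'   respiratory oxygen demand (e.g. external work), W.
#' @return A `HeatFluxes` list for the whole animal plus `mass_exchange`
#'   (the respiratory_exchange result).
#' @export
animal_balance <- function(animal, t_core, state, env, q_extra = 0) {
  appendages <- c("front_legs", "hind_legs", "tail")
  q <- list(q_met = 0, q_resp = 0, q_evap = 0, q_st = 0, q_fur = 0,
            q_rad = 0, q_conv = 0, q_sol = 0)
  for (seg in animal$segments) {
    tc <- if (seg$name %in% appendages) {
      t_core - 0.5 * (t_core - env$t_air_animal)
    } else t_core
    gca <- if (seg$name == "torso") animal$ventral_contact_area %||% 0 else 0
    sb <- segment_balance(seg, tc, state, env,
                          skin_reflectivity_pct = animal$skin_reflectivity_pct,
                          ground_contact_area = gca)
    for (nm in names(q)) q[[nm]] <- q[[nm]] + sb[[nm]]
  }
  # respiratory loss from total metabolic rate, fixed-point iterated
  extraction <- state$o2_extraction %||% 0.20
  q_resp <- 0
  for (i in 1:3) {
    me <- respiratory_exchange(max(q$q_met + q_resp + q_extra, 0),
                               env$o2_fraction, extraction,
                               t_lung = t_core, inhaled_rh = env$rh,
                               t_air = env$t_air_animal)
    q_resp <- me$q_resp
  }
  q$q_resp <- q_resp
  q$q_met <- q$q_met + q_resp
  q$mass_exchange <- me
  q
}

#' Check the energy closure of a converged HeatFluxes decomposition
#'
#' @param q A `HeatFluxes` list.
#' @return Absolute residual of q_met - q_resp - q_st - q_evap =
#'   q_rad + q_conv - q_sol, in W.
#' @export
energy_residual <- function(q) {
  abs((q$q_met - q$q_resp - q$q_st - q$q_evap) - (q$q_rad + q$q_conv - q$q_sol))
}
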