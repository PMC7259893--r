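---
title: "Methods: coupled microclimate and animal heat/mass balance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled microclimate and animal heat/mass balance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dinotherm` couples an hourly microclimate generator to a steady-state animal
heat- and mass-balance model and asks, hour by hour over a model year, how
much metabolic heat an animal of a given geometry, insulation and physiology
must produce to hold its core temperature — and whether that requirement can
be steered to a behaviourally and physiologically realistic target. The
shipped parameter sets describe two Late Triassic dinosaurs (a 21 kg theropod
and an 850 kg prosauropod) in six bounding tropical palaeoclimates, but every
piece is configurable.

## The microclimate model

Each of the six scenarios (`hot`/`moderate`/`cold` x `arid`/`humid`) is an
annual envelope: air temperature (26–40, 20–34, 16–30 °C), relative humidity
(13–65 or 48–96 %), wind 1–4 m/s, cloud 50–90 %, at 12° N and 150 m
elevation under an 18 % O2, 0.13 % CO2 atmosphere. A model year is twelve
mid-month days. The annual envelope is split evenly between a seasonal cosine
(warmest month July) and the diurnal cycle, so the generated hourly air
temperatures span exactly the scenario envelope over the year. This even
split is a package choice — the sources give only the envelope ends and show
smooth seasonality — and is exposed through `month_envelope()`.

Hourly values follow a piecewise-cosine diurnal curve anchored at the
minimum at sunrise and the maximum one hour after solar noon (reversed for
humidity and cloud, which peak at sunrise). Solar flux uses standard
declination/hour-angle geometry and a single broadband transmittance
(`tau = 0.70` per optical air mass, S0 = 1361 W/m², 15 % diffuse under clear
sky), attenuated by cloud as `1 - 0.65 * cloud`. Longwave sky radiant
temperature uses the Swinbank air-temperature-only clear-sky emissivity
(`eps = 9.365e-6 T_K^2`) blended toward 1 under cloud. A temperature-only
correlation was chosen deliberately: vapour-pressure-based forms give
humidity a radiative main effect that the factorial sensitivity analysis is
expected to rank as insignificant.

Substrate temperatures come from a one-dimensional backward-Euler
finite-difference solve on ten log-spaced nodes from the surface to a fixed
deep boundary at 2 m held at the daily mean air temperature. The surface
node balances absorbed solar, net longwave against the sky, and convection
(radiation linearised and re-iterated per sub-step; six 10-minute sub-steps
per hour). The forcing day is repeated until the whole column is 24-hour
periodic to < 0.05 °C (at least 3 spin-up days, up to 30 for the deepest
nodes' slow transient). Grid convergence and the analytic sinusoidal
damping-depth solution are checked in the test suite.

Conditions at animal height interpolate between the ground surface and the
2 m reference on a logarithmic coordinate with a 0.01 m roughness height:
wind vanishes at the roughness height and air temperature reaches the ground
surface temperature there. The deep-shade site blocks 90 % of solar
(configurable) and replaces the sky radiant temperature with air temperature
(overhead canopy); at night only the radiant substitution remains.

## Animal geometry

Animals are assemblies of simple solids (cylinders, elliptical cylinders,
truncated cones, spheres, ellipsoids) for head, neck, torso, paired legs and
tail, with closed-form areas and volumes. Dimension sets for the two taxa
ship as YAML fixtures; at build time radial dimensions are normalised by a
common factor so the closed-form mass matches the requested total at
0.97 kg/L flesh density. Mass sensitivity experiments scale diameters at
fixed lengths (`scale_mass_by_diameter()`), mirroring how skeletal
proportions constrain length but not bulk. Fat is a 5 %-of-body-mass shell
on the torso (conductivity 0.2 W/m/K). The resting/sleeping posture merges
leg volume into the torso at constant total volume, lays the animal down and
opens a ventral conduction interface equal to the torso footprint.

## The heat balance

For each segment and hour the package solves a series chain: flesh with
distributed heat generation (area resistance r/2k, with k the vasomotor
flesh conductivity, 0.4–2.8 W/m/K), the fat shell, an optional porous
insulation layer, and at the outer surface parallel convection and infrared
exchange plus solar gain. The outer surface temperature of each dorsal and
ventral half is found with Brent root-finding to 1e-3 °C; the convection
coefficient is re-evaluated at the solved temperature until consistent.
Convection combines a Hilpert cylinder-in-crossflow forced term with a
Rayleigh free-convection term as `(Nu_f^3 + Nu_n^3)^(1/3)`, with air
properties at film temperature and site pressure.

The insulation layer (proto-feathers: 30 mm elements, 10 mm resting depth,
2000 elements/cm², 15 % surface reflectivity) conducts by three parallel
paths: along the keratin elements (area-fraction weighted), through trapped
air, and by radiation in the optically thick diffusion limit
(`k_rad = 16 sigma T^3 / (3 N d)`). Ptiloerection deepens the layer up to
the element length. Solar interception uses the orientation-averaged mean
projected area of a convex body (A/4, Cauchy's theorem) for the direct beam
plus half the area for diffuse — a deliberate simplification in place of an
explicit view-factor and orientation model; for the near-horizontal trunk
shapes used here A/4 is close to the overhead footprint, and orientation
effects at low sun are not represented. Dorsal halves exchange infrared with
the sky, ventral halves with the ground. Cutaneous evaporation acts only on
bare skin at a baseline 0.5 % wet fraction (sweating is disabled for all
shipped taxa). Limbs and tail run at an effective core temperature halfway
between the torso core and ambient air; whole-animal respiratory loss
(oxyjoule equivalent 20.1 kJ/L O2, ventilation set by the 18 % O2 atmosphere
and the extraction coefficient, inhaled air saturated at lung temperature
with 50 % nostril water recovery) is computed once per hour and iterated to
consistency with the total metabolic rate.

## Thermoregulation

The hourly target heat production is `RMR * multiplier` minus the fraction
of activity energy doing external work (multiplier 2, muscle efficiency
20 %, so the balance target is 1.8 RMR while reported metabolic energy at
target is 2 RMR). From a neutral state the controller engages options in a
fixed order — erect insulation, vasomotor flesh conductivity, core
temperature within the CTR (down when cold, up when hot), skin wetting (only
if sweating is enabled), panting (lower O2 extraction), then behaviours:
night shade, vegetative wind shelter (halves wind at animal height) and the
lying posture on the cold side, daytime shade on the hot side. Each
continuous option is first evaluated fully engaged; if the target is crossed
the engagement fraction is bisected until the required heat production is
within 1 % of target. Bisection (rather than a fixed 10-step lattice) keeps
the thermoneutral zone a clean interval; with a coarse lattice the steep end
of the vasomotor range leaves 1–2 % discretisation gaps. Binary behaviours
pick whichever of on/off lands closer. If options are exhausted the closest
achievable solution is kept: required production above target is cold
stress (the animal stays active and simply eats more), below target is heat
stress (activity stops for that hour and reported production floors at RMR,
which is obligatory maintenance — the unresolved excess is transient storage
already represented by the CTR saturating).

Daily metabolic energy integrates the 24 hourly rates; annual energy weights
the twelve mid-month days by month lengths (365-day calendar). Food and
water budgets follow from diet composition (combustion energy densities
17.8/39.3/17.5 MJ/kg for protein/fat/carbohydrate, oxidation water
0.396/1.07/0.556 g/g), digestive efficiency, dry-matter fraction, fecal
water and a uric-acid urinary term.

## Experiments

The metabolic chamber pins ground, sky and air temperatures together with no
solar, 0.1 m/s wind and 5 % humidity, disables behaviours, and scans
temperature at 0.5 °C (1 °C in the routine test suite), refining critical
temperatures by bisection to 0.1 °C; `resting` mode uses multiplier 1 and
`active` mode the physiology's multiplier. Viability matrices run one annual
simulation per scenario x RMR grade x CTR cell and classify the annual
energy ratio (±5 % target, 5–10 % above/below, >10 % above = cold stress,
>10 % below = heat stress; boundary ratios take the milder class). The 2^4
climate factorial pins wind, humidity and cloud at their envelope ends and
shifts the temperature envelope by the 10 °C hot–cold separation, then
applies Yates' fold-and-difference algorithm; the test suite verifies the
effects against brute-force contrasts and the exact inverse transform.

## Problem sizes and numerical choices

Annual runs use 12 days x 24 hours; a 27-cell matrix therefore performs
7 776 controller hours, each involving a handful of whole-animal balance
solves. The shipped experiment drivers reuse the solved microclimate across
matrix cells that share a scenario. Routine tests run chamber sweeps at 1 °C
and reduced-month annual runs; the full 0.5 °C sweeps and 12-month matrices
are what `scripts/acceptance.R` executes. Root-finding tolerances are
1e-3 °C (surface temperatures), 1 % of target (controller), 0.05 °C over 24 h
(soil periodicity). Degenerate inputs — zero insulation depth, zero
solar at night, heights at or below the roughness length — reduce to the
bare-skin, dark, and surface limits respectively and are covered by tests.

## RMR grades

Squamate, monotreme and ratite resting metabolic rates are tabulated against
mass for both taxa and interpolated by least-squares power laws in log-log
space (tabulated masses return the tabulated value exactly). Marsupial and
eutherian grades — used only in chamber comparisons — are synthesised as a
geometric progression: marsupial the geometric mean of monotreme and ratite,
eutherian one step beyond ratite. The three CTR labels (broad 26–40,
moderate 32–40, narrow 36–40 °C) share a 38 °C target.

## What the generator does and does not emulate

The scenario generator reproduces the *structure* the study prescribes:
sinusoidal diurnal forcing anchored to sunrise/noon+1, smooth seasonality
inside a fixed annual envelope, coupled soil temperatures, and sun/shade
sites. It does not emulate weather — no day-to-day variance, fronts, rain,
or cloud autocorrelation — nor orbital-scale insolation change, so passing
tests demonstrate internal consistency and sensitivity structure, not a
reconstruction of any particular Triassic year. Viability counts from the
matrices are accordingly read as directional patterns (which corner of the
design is stressed) rather than cell-exact predictions; the independent
reference implementation this study family uses is closed-source, and its
absolute stress levels are not reproducible from published material alone.

## Known limitations

Steady state within the hour (no explicit transient PDE; storage only via
the bounded core temperature), slab insulation on curved surfaces, a single
lumped wet fraction for cutaneous evaporation, no ground-reflected solar,
and no orientation behaviour. The appendage rule fixes limb temperature at
50 % of the torso-ambient difference rather than solving limb energy
balances. These are the places to look first when adapting the package to
taxa or climates far from the shipped parameter space.
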