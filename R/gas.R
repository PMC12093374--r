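# Gas-liquid mass transfer for sparged stirred vessels.
#
# Two-film interface flux with Henry's-law equilibrium at the interface, a
# well-mixed (CSTR) gas-phase balance, and a power-input correlation for the
# volumetric transfer coefficient. The reactor simulations treat the gas
# phase as quasi-steady by default (gas residence time of seconds against
# process time scales of hours); the dynamic balance is available for
# verification and for configurations where the quasi-steady assumption is
# not wanted.

.R_ATM <- 0.082057  # L atm / (K mol)

#' Molar density of an ideal gas
#'
#' @param pressure Total pressure (atm).
#' @param temperature Temperature (K).
#' @return mol per m3.
#' @export
gas_molar_density <- function(pressure = 1, temperature = 298.15) {
  1000 * pressure / (.R_ATM * temperature)
}

#' Stirred-tank transfer settings
#'
#' Geometry and operating settings from which k_L.a is estimated; species
#' Henry constants come from the equilibrium-constant set.
#'
#' @param liquid_volume Liquid volume (m3).
#' @param vessel_diameter Inner vessel diameter (m).
#' @param impeller_diameter,impeller_width Impeller dimensions (m).
#' @param rpm Impeller rotation speed (1/min).
#' @param gas_flow Gas feed rate Q (m3/h).
#' @param holdup Fractional gas hold-up (in `[0, 1)`).
#' @param registry Registry list supplying correlation constants.
#' @return Object of class `transfer_settings`.
#' @export
#' @examples
#' ts <- transfer_settings()
transfer_settings <- function(liquid_volume = 1, vessel_diameter = 1.13,
                              impeller_diameter = 0.376,
                              impeller_width = 0.075, rpm = 100,
                              gas_flow = 360, holdup = 0.05,
                              registry = load_registry()) {
  stopifnot(liquid_volume > 0, vessel_diameter > 0, impeller_diameter > 0,
            impeller_width > 0, rpm > 0, gas_flow >= 0,
            holdup >= 0, holdup < 1)
  out <- list(liquid_volume = liquid_volume, vessel_diameter = vessel_diameter,
              impeller_diameter = impeller_diameter,
              impeller_width = impeller_width, rpm = rpm,
              gas_flow = gas_flow, holdup = holdup,
              correlation = registry$kla_correlation,
              diffusivity = unlist(registry$diffusivity))
  class(out) <- "transfer_settings"
  out
}

#' Gas-liquid interface flux
#'
#' Two-film flux into the liquid: `flux = kLa (C* - C_L)` with
#' `C* = H p`. Positive values are absorption, negative stripping.
#'
#' @param kla Volumetric transfer coefficient (1/h).
#' @param henry Henry constant (mol L-1 atm-1).
#' @param p_partial Species partial pressure in the gas (atm).
#' @param c_liquid Dissolved concentration of the transferring species
#'   (mol/L); for weak acids this is the neutral species only.
#' @return Flux in mol L-1 h-1.
#' @export
#' @examples
#' interface_flux(100, 0.034, 4.2e-4, 0)  # absorption of atmospheric CO2
interface_flux <- function(kla, henry, p_partial, c_liquid) {
  kla * (henry * p_partial - c_liquid)
}

#' Well-mixed gas-phase balance
#'
#' CSTR balance per species, concentrations in mol/m3:
#' `V_g dC_g/dt = Q (C_g,in - C_g) - flux * V_L`, outlet composition equal
#' to the in-vessel composition.
#'
#' @param c_gas Named vector of in-vessel gas concentrations (mol/m3).
#' @param c_in Named vector of inlet concentrations (mol/m3).
#' @param flux Named vector of liquid absorption fluxes (mol L-1 h-1),
#'   positive into the liquid.
#' @param gas_flow Q (m3/h).
#' @param gas_volume Effective gas volume (m3).
#' @param liquid_volume Liquid volume (L).
#' @return Named vector of derivatives dC_g/dt (mol m-3 h-1).
#' @export
gas_phase_balance <- function(c_gas, c_in, flux, gas_flow, gas_volume,
                              liquid_volume) {
  stopifnot(gas_flow >= 0, gas_volume > 0, liquid_volume > 0)
  (gas_flow * (c_in - c_gas) - flux * liquid_volume) / gas_volume
}

#' Quasi-steady vessel gas composition and interface flux
#'
#' Solves the steady well-mixed gas balance jointly with the two-film flux
#' for one species: `Q c_g (y_in - y) = kLa (H P y - C_L) V_L`. Returns the
#' in-vessel (= outlet) mole fraction, the flux into the liquid, and the
#' vent rate.
#'
#' @param y_in Inlet mole fraction.
#' @param gas_flow Q (m3/h).
#' @param kla Volumetric transfer coefficient (1/h).
#' @param henry Henry constant (mol L-1 atm-1).
#' @param c_liquid Transferring (neutral) species concentration (mol/L).
#' @param liquid_volume Liquid volume (L).
#' @param pressure Total pressure (atm).
#' @param temperature Temperature (K).
#' @return List: `y` (vessel mole fraction), `flux` (mol L-1 h-1 into the
#'   liquid), `vent` (mol/h leaving in the off-gas), `fed` (mol/h in).
#' @export
quasi_steady_gas <- function(y_in, gas_flow, kla, henry, c_liquid,
                             liquid_volume, pressure = 1,
                             temperature = 298.15) {
  cg <- gas_molar_density(pressure, temperature)          # mol/m3
  qc <- gas_flow * cg                                     # mol/h
  if (qc <= 0) {  # unsparged: no carrier stream, flux against fixed y_in
    flux <- interface_flux(kla, henry, pressure * y_in, c_liquid)
    return(list(y = y_in, flux = flux, vent = -flux * liquid_volume,
                fed = 0))
  }
  y <- (qc * y_in + kla * liquid_volume * c_liquid) /
    (qc + kla * liquid_volume * henry * pressure)
  flux <- interface_flux(kla, henry, pressure * y, c_liquid)
  list(y = y, flux = flux, vent = qc * y, fed = qc * y_in)
}

#' Estimate k_L.a from a power-input correlation
#'
#' Rushton-type power draw `P = Np rho N^3 D^5` gives the specific power
#' input; the coalescing-system correlation
#' `kLa = c (P/V)^alpha v_s^beta` (SI units, 1/s) then yields the O2
#' reference value, scaled to other species by the square root of the
#' diffusivity ratio. With no gas sparging (zero superficial velocity) a
#' configurable surface-aeration floor value is returned.
#'
#' @param settings A [transfer_settings()].
#' @param species One of `"o2"`, `"co2"`, `"h2s"`, `"h2"`.
#' @param warn Warn when the operating point is outside the correlation's
#'   validity range.
#' @return k_L.a in 1/h.
#' @export
#' @examples
#' estimate_kla(transfer_settings(), "co2")
estimate_kla <- function(settings, species = "o2", warn = TRUE) {
  stopifnot(inherits(settings, "transfer_settings"))
  co <- settings$correlation
  scale <- sqrt(settings$diffusivity[[species]] / settings$diffusivity[["o2"]])
  if (settings$gas_flow <= 0) {
    return(co$surface_kla_floor * scale)
  }
  N <- settings$rpm / 60                                   # 1/s
  P <- co$power_number * 1000 * N^3 * settings$impeller_diameter^5  # W
  pv <- P / settings$liquid_volume                         # W/m3
  vs <- (settings$gas_flow / 3600) /
    (pi / 4 * settings$vessel_diameter^2)                  # m/s
  if (warn && (pv < 10 || pv > 1e4 || vs > 0.3)) {
    warning(sprintf(
      "operating point (P/V = %.3g W/m3, v_s = %.3g m/s) outside the k_L.a correlation validity range",
      pv, vs))
  }
  kla_o2 <- co$c * pv^co$alpha * vs^co$beta * 3600         # 1/h
  kla_o2 * scale
}
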