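# bioswing default parameter registry (isothermal model, 25 C, 1 atm).
# Every block can be overridden from R (see equilibrium_constants(),
# oxidizer_params(), reducer_params(), transfer_settings()) or by pointing
# the loaders at a modified copy of this file.
#
# Sources are noted per entry. Entries marked "assumed" or "calibrated" are
# package defaults chosen where the primary literature does not pin a value;
# they are deliberately exposed here so they can be replaced.

equilibria:                 # thermodynamic constants at 25 C, infinite dilution
  K1_carbonate: 4.45e-7     # CO2(aq) + H2O = H+ + HCO3-, pK1 6.352 (Plummer & Busenberg 1982)
  K2_carbonate: 4.69e-11    # HCO3- = H+ + CO3--, pK2 10.329 (Plummer & Busenberg 1982)
  Kw: 1.0e-14               # water autoprotolysis, 25 C
  Ka1_H2S: 8.9e-8           # H2S(aq) = H+ + HS-, pKa1 7.05 (Millero 1986)
  Ka2_H2S: 1.0e-13          # HS- = H+ + S--; poorly constrained, S-- disabled by default
  Ksp:
    magnesite: 9.33e-9      # MgCO3, 10^-8.03 (Benezeth et al. 2011)
    calcite: 3.31e-9        # CaCO3, 10^-8.48 (Plummer & Busenberg 1982)
    dolomite: 8.13e-18      # CaMg(CO3)2, ordered, 10^-17.09
    gypsum: 2.63e-5         # CaSO4.2H2O, 10^-4.58
    brucite: 5.61e-12       # Mg(OH)2 = Mg++ + 2 OH-; used by the saturation monitor only

henry:                      # mol L-1 atm-1 at 25 C (Sander 2015 compilation)
  co2: 0.0340
  o2: 0.00126
  h2s: 0.1020
  h2: 0.00078

diffusivity:                # 1e-9 m2 s-1 in water at 25 C; used for k_L.a species scaling
  o2: 2.10
  co2: 1.92
  h2s: 1.61
  h2: 4.50

activity:
  davies_A: 0.5085          # Debye-Huckel A at 25 C (kg^0.5 mol^-0.5)
  davies_b: 0.3             # Davies linear-term coefficient
  ionic_strength_cap: 0.7   # mol/L; Davies validity cap, I clamped above this

organisms:
  oxidizer:                 # sulfur oxidizer, A. thiooxidans-like; block version 1
    mu_max: 0.04            # h-1; assumed (batch oxidation of 0.5 mol/L substrate in ~10^2 h)
    k_d: 0.002              # h-1; assumed first-order decay
    K_S_s2o3: 20.0          # mg/L; thiosulfate half-saturation (assumed)
    K_S_h2s: 0.2            # mg/L; dissolved-H2S half-saturation (sub-mg/L, as for
                            # sulfide-oxidizer biofilter kinetics; assumed)
    K_O: 1.0                # mg/L; oxygen kinetic constant (typical aerobic value)
    yield: 0.05             # mg biomass per mg substrate oxidized (autotroph on reduced S; assumed)
  reducer:                  # sulfate reducer, D. vulgaris-like on H2; block version 1
    mu_max_S: 0.08          # h-1; assumed (doubling ~9 h on H2/sulfate)
    k_d: 0.002              # h-1
    K_S_sulfate: 2.0e-4     # mol/L; Monod constant for sulfate
    K_H: 1.0e-6             # mol/L; Monod constant for dissolved H2
    Y_S: 4.0                # g biomass per mol sulfate reduced

seeds:                      # MgCO3 seed crystals in the reduction reactor
  area: 1.0                 # m2 per L initial total surface area
  radius: 1.0e-6            # m; initial per-seed radius (sets seed count; assumed)
  molar_mass: 84.31         # g/mol MgCO3
  density: 3.0e+6           # g/m3 magnesite
  rate_constant: 2.0e-3     # mol m-2 h-1; calibrated so seeded growth keeps pace with
                            # air-CO2 supply over a ~10^2 h precipitation window
  exponent: 1               # affinity-law exponent p in r_prec = k (Omega - 1)^p

kla_correlation:            # van 't Riet (1979) coalescing correlation, O2 reference
  c: 0.026                  # kLa[s-1] = c * (P/V)[W m-3]^alpha * v_s[m s-1]^beta
  alpha: 0.4
  beta: 0.5
  power_number: 5.0         # Rushton-type turbine, turbulent regime
  surface_kla_floor: 1.0    # h-1; surface-aeration value used when superficial velocity = 0

gas:
  co2_ppm: 420              # atmospheric CO2 inlet mole fraction (ppm)
  pressure: 1.0             # atm
  temperature: 298.15       # K
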