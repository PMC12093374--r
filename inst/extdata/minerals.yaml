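# bioswing mineral-phase database.
#
# Rate law (far-from-equilibrium, proton-promoted mechanism):
#   r_dis = A * exp(-E / (R T)) * a_H+^n        [mol m-2 h-1]
# where A is back-computed from log_k25, the log10 surface rate at 25 C and
# a_H+ = 1 in mol m-2 s-1, as tabulated by Palandri & Kharaka (2004, USGS
# OFR 2004-1068), acid mechanism. Entries without a primary-source anchor are
# marked "placeholder" and should be replaced when better data are available.
#
# cations: moles of dissolved cation released per formula unit (charge 2+ for
# mg and ca). protons: moles H+ consumed per formula unit; must equal the
# total charge of released cations (silica and alumina are treated as inert
# neutral solutes and are excluded from the charge balance). dic: moles of
# carbonate carbon released per formula unit (carbonate phases only).
# carbonate: name of the Ksp entry used for the equilibrium cap (dissolution
# is suppressed as the solution approaches saturation with that phase).

forsterite:
  formula: Mg2SiO4
  molar_mass: 140.69        # g/mol
  density: 3.27e+6          # g/m3
  log_k25: -6.85            # Palandri & Kharaka 2004, olivine (forsterite), acid
  activation_energy: 67200  # J/mol
  order: 0.47               # reaction order in a_H+
  cations: {mg: 2}
  protons: 4

plagioclase:                # labradorite-like intermediate plagioclase
  formula: Ca0.6Na0.4Al1.6Si2.4O8
  molar_mass: 270.8
  density: 2.69e+6
  log_k25: -7.87            # Palandri & Kharaka 2004, labradorite, acid
  activation_energy: 42100
  order: 0.626
  cations: {ca: 0.6}        # Na release ignored (background cation already in medium)
  protons: 1.2

clinopyroxene:              # diopside
  formula: CaMgSi2O6
  molar_mass: 216.55
  density: 3.28e+6
  log_k25: -6.36            # Palandri & Kharaka 2004, diopside, acid
  activation_energy: 96100
  order: 0.71
  cations: {ca: 1, mg: 1}
  protons: 4

orthopyroxene:              # enstatite
  formula: MgSiO3
  molar_mass: 100.39
  density: 3.20e+6
  log_k25: -9.02            # Palandri & Kharaka 2004, enstatite, acid
  activation_energy: 80000
  order: 0.60
  cations: {mg: 1}
  protons: 2

serpentine:                 # chrysotile; placeholder kinetics
  formula: Mg3Si2O5(OH)4
  molar_mass: 277.11
  density: 2.53e+6
  log_k25: -5.81            # placeholder (chrysotile acid-mechanism estimate)
  activation_energy: 75000
  order: 0.24
  cations: {mg: 3}
  protons: 6

talc:                       # placeholder kinetics
  formula: Mg3Si4O10(OH)2
  molar_mass: 379.27
  density: 2.75e+6
  log_k25: -8.40            # placeholder
  activation_energy: 42000
  order: 0.40
  cations: {mg: 3}
  protons: 6

quartz:                     # effectively inert on 10^2-10^3 h time scales
  formula: SiO2
  molar_mass: 60.08
  density: 2.65e+6
  log_k25: -13.40           # Palandri & Kharaka 2004, quartz, neutral
  activation_energy: 90900
  order: 0.0
  cations: {}
  protons: 0

calcite:
  formula: CaCO3
  molar_mass: 100.09
  density: 2.71e+6
  log_k25: -0.30            # Palandri & Kharaka 2004, calcite, acid
  activation_energy: 14400
  order: 1.0
  cations: {ca: 1}
  protons: 2
  dic: 1
  carbonate: calcite

dolomite:
  formula: CaMg(CO3)2
  molar_mass: 184.40
  density: 2.84e+6
  log_k25: -3.76            # Palandri & Kharaka 2004, dolomite (ordered), acid
  activation_energy: 56700
  order: 0.50
  cations: {ca: 1, mg: 1}
  protons: 4
  dic: 2
  carbonate: dolomite
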