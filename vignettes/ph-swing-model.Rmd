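---
title: "The sulfur-cycle pH-swing carbonation model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The sulfur-cycle pH-swing carbonation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bioswing)
```

bioswing simulates mineral carbonation driven by a *biological pH swing*: a
sulfur compound is cycled between its oxidized (sulfate) and reduced (H2S or
thiosulfate) states by two microbial populations in two stirred 1 m³ tanks.
Oxidation releases protons and dissolves forsterite; reduction consumes
protons, letting air CO₂ accumulate as carbonate and precipitate with the
dissolved Mg²⁺ as MgCO₃ — durable carbon storage at ambient temperature and
pressure. This vignette documents the model equations, the parameter choices
and their provenance, the numerical design, and what the shipped tests do
and do not establish.

## Model structure

Each reactor is a coupled differential–algebraic system. The *slow*
processes are ODEs in total (analytical) component concentrations:

* **Microbial kinetics.** Oxidizer:
  $dX/dt = \mu_{max}\gamma X - k_d X$, with the dual-Monod modifier
  $\gamma = \frac{C_{LS}}{K_S + C_{LS}}\cdot\frac{C_{LO}}{K_O + C_{LO}}$;
  substrate oxidation is tied to gross growth through the yield
  ($q_S = \mu_{max}\gamma X / Y$), and O₂, sulfate and proton rates follow
  the reaction stoichiometry (2 O₂ and 2 H⁺ per substrate molecule; 1 or
  2 SO₄²⁻ for H₂S or thiosulfate respectively). Reducer:
  $r_X = \mu_{max,S} X \frac{S}{K_S+S}\frac{C_{LH}}{K_H+C_{LH}}$,
  $r_S = r_X / Y_S$, with 4 H₂ and 2 H⁺ consumed per sulfate reduced to
  H₂S, or 2 H₂ and 1 H⁺ per sulfate reduced to thiosulfate. A
  multiplicative `modifier` hook (default identity) is provided so a lag
  (Gompertz-type) or pH-window term can be switched on without changing the
  interface; the product (not minimum) form of the dual-Monod modifier was
  chosen, as is conventional.
* **Mineral dissolution.** Monodisperse shrinking spheres:
  $r_{dis} = A\,e^{-E/RT}\,a_{H^+}^n$ (mol m⁻² h⁻¹),
  cation release $= \nu\, r_{dis}\, 4\pi R_p^2 n_p$, and
  $dR_p/dt = -r_{dis} M/\rho$. Proton consumption always equals the charge
  of the released cations; Si and Al are treated as inert neutral solutes.
  For multi-mineral tailings each phase forms its own monodisperse
  population (one mineral per particle). Carbonate phases (calcite,
  dolomite) carry an equilibrium cap — their rate is scaled by
  $\max(0, 1-\Omega)$ — because an uncapped proton-promoted law would
  dissolve them past saturation; silicates are treated as far from
  equilibrium throughout, which is the operating regime of interest.
* **Seeded precipitation.** Growth-only MgCO₃ crystallization on seeds:
  $r_{prec} = k(\Omega-1)^p$ for $\Omega>1$ (else 0; seeds never
  redissolve), CO₂ capture $r_{cap} = r_{prec}A$, and spherical-seed area
  growth $dA/dt = 8\pi n_s r\,dr/dt$ with $dr/dt = r_{prec}M/\rho$. No
  nucleation term is included. Brucite (Mg(OH)₂) is *not* precipitated;
  instead a saturation monitor warns when its Ω exceeds 1 (it does at pH 10
  with 0.5 mol/L Mg²⁺, which is why the hydrogen controller caps the pH).
* **Gas–liquid transfer.** Two-film flux $k_La(Hp - C_L)$ per species,
  where only the neutral species (CO₂(aq), H₂S(aq)) crosses the interface.
  The vessel gas phase is treated as a quasi-steady well-mixed CSTR (its
  residence time at 360 m³/h is under a second against process time scales
  of hours); the dynamic balance is implemented and verified separately and
  can be used where the quasi-steady assumption is not wanted. H₂ enters as
  a dissolved-phase feed (no hydrogen bubble phase), throttled by the pH
  controller and by liquid saturation. `estimate_kla()` provides the
  van 't Riet power-input correlation
  ($k_La = 0.026\,(P/V)^{0.4}v_s^{0.5}$ s⁻¹, Rushton power number 5) with
  per-species diffusivity scaling and a configurable surface-aeration floor
  for unsparged vessels.

The *fast* acid–base chemistry is an algebraic constraint eliminated inside
the right-hand side: given the totals (DIC, ΣS(-II), sulfate, thiosulfate,
Mg²⁺, Ca²⁺ and conservative background ions), `speciate()` solves the charge
balance for pH by bracketed root finding, iterated to a joint fixed point
with Davies activity coefficients. Because reactions are expressed as changes
in conservative totals, proton bookkeeping is implicit and exact: e.g.
oxidizing one thiosulfate (2−) to two sulfates (4−) forces two protons into
solution through the charge balance. pH never needs its own ODE.

## Parameters: values, units, provenance

All defaults live in `inst/extdata/parameters.yaml` and
`inst/extdata/minerals.yaml`, each entry with a source note; everything is
overridable from R or by editing a copy of the registry.

* **Equilibria (25 °C, I = 0):** carbonate pK₁ 6.35 / pK₂ 10.33, water
  pK\_w 14, H₂S pK\_a1 7.05, magnesite pK\_sp 8.03, plus calcite, dolomite,
  gypsum and brucite; Henry constants for CO₂, O₂, H₂S, H₂. The model is
  isothermal at 25 °C — no temperature corrections are implemented.
* **Activity model:** Davies equation (A = 0.5085, b = 0.3), neutral
  species coefficient 1, S²⁻ excluded below pH 12 by default. The process
  liquors reach ionic strengths of several mol/L, far beyond Davies
  validity, so I is clamped at 0.7 mol/L (flagged in every result). This is
  the standard minimal choice; a Pitzer-level model would change activity
  values but not the stoichiometry-dominated cycle totals.
* **Organisms:** oxidizer μ\_max 0.04 h⁻¹, k\_d 0.002 h⁻¹, K\_O 1 mg/L,
  yield 0.05 mg biomass/mg substrate; K\_S is substrate-specific
  (20 mg/L for thiosulfate, 0.2 mg/L for dissolved H₂S — under a dilute gas
  feed the dissolved H₂S ceiling is ~0.3 mg/L, and sulfide oxidizers
  operating on trace H₂S are known to have sub-mg/L half-saturations).
  Reducer μ\_max,S 0.08 h⁻¹, K\_S 2×10⁻⁴ mol/L, K\_H 10⁻⁶ mol/L, Y\_S
  4 g/mol. These are literature-scale values chosen once; the cycle *totals*
  are insensitive to them (they shift timing only), which is also the
  study's own sensitivity finding. The validation-culture growth rate is
  the calibrated 0.0117 h⁻¹.
* **Minerals:** forsterite (and the tailings phases) use published
  far-from-equilibrium proton-promoted kinetics (log k₂₅ = −6.85 mol m⁻² s⁻¹,
  E = 67.2 kJ/mol, n = 0.47 for forsterite); serpentine and talc entries
  are marked placeholders. The tailings mass fractions shipped for the
  validation scenario are a documented placeholder for a silicate-rich
  tailing (22% serpentine, 18% plagioclase, 24% pyroxenes, 6% talc, 12%
  quartz, 18% carbonates) and should be replaced when a measured modal
  composition is available.
* **Seeds:** initial area 1 m²/L; the seed radius (1 μm, hence the count)
  is a geometric assumption. The growth-rate constant k = 2×10⁻³
  mol m⁻² h⁻¹ is *calibrated* so that seeded growth keeps pace with the
  air-CO₂ supply over a ~10² h precipitation window — with seeded growth
  fast, capture is CO₂-transfer-limited and the exponent p (default 1,
  configurable) barely matters.
* **Operating conditions** (the study conditions, used by the default
  scenarios and the acceptance script): 1 m³ liquid, 1.13 m vessel, 0.376 m
  impeller at 100 rpm, 360 m³/h gas feed, 420 ppm CO₂, 200 g/L forsterite
  at 50 μm, 0.5 mol/L sulfur charge, H₂-feed cap at pH 10. The reduction
  influent (0.5 mol/L Mg²⁺ with 0.5 or 1.0 mol/L sulfate by variant) is the
  0.5 mol/L-scale MgSO₄-type liquor the operating conditions define.
  Amounts printed as "mol" for the 1 m³ reactor are interpreted as mol per
  litre of liquid, consistent with the concentration axes of the reported
  time series.

## Numerical design

* Integration uses `deSolve::lsodar` (stiff BDF with root finding);
  tolerances rtol 10⁻⁸, per-state atol (10⁻¹² for concentrations, tighter
  for radii). A property test checks results are invariant (10⁻⁴ relative)
  under halved tolerances.
* The charge balance is solved per right-hand-side call: Brent bracketing
  (warm-started within ±0.5 pH of the previous solution, full bracket
  [−2, 16] otherwise) plus Newton polish *to machine level*. The polish
  matters: if the residual is left larger than the integrator's
  finite-difference Jacobian perturbations, the right-hand side looks noisy
  and step control collapses in poorly buffered solutions. The residual at
  every reported state is below 10⁻¹⁰ mol/L.
* The Davies/pH fixed point iterates to 10⁻⁸ pH units; the residual is
  monotone in pH, so the bracket is guaranteed.
* Particle exhaustion: dissolution rates taper linearly to zero over the
  last 10 nm of radius. A hard cutoff at R = 0 is a discontinuity on which
  the integrator chatters; 10 nm is far below any particle size of interest
  and the tapered mass is negligible.
* The H₂-feed controller is implemented as continuous proportional
  throttling across a 0.05 pH deadband below the setpoint, multiplied by a
  liquid-saturation factor (1 − C_LH/C_sat), rather than an on/off relay: a
  relay injects discontinuities a stiff integrator must re-detect at every
  switching, while the proportional law is smooth, respects the same cap,
  and the pH trace never exceeds setpoint + deadband.
* Stage-termination events: the oxidation stage ends when the feed window
  is over, residual substrate < 10⁻⁶ mol/L and pH ≥ 6.5; the reduction
  stage when sulfate < 10⁻⁶ mol/L and Ω\_magnesite < 1.05. The Ω threshold
  is applied at the first crossing (not held for a sustained window):
  by the time sulfate is exhausted Mg²⁺ is monotonically depleted, so the
  crossing cannot recur.
* Degenerate inputs: totals are clamped at zero before speciation (the
  integrator may probe slightly negative states); zero-substrate, zero-Mg
  and zero-particle scenarios are exercised in the tests.
* In the H₂S cycle the two reactors are coupled by the off-gas: the
  reduction stage is simulated first and its H₂S generation (stripping)
  profile, diluted into the 360 m³/h stream, becomes the oxidation
  reactor's feed on a common clock — there is no feedback in the other
  direction within a cycle, so sequential simulation is exact. In the
  thiosulfate cycle the completed reduction liquor (thiosulfate plus
  background cation) is transferred as the oxidation charge; trace
  residuals (≲1 mmol/L Mg, residual DIC) are not carried over.

## The synthetic-data generator

`generate_synthetic()` emulates the validation experiment's measurement
structure: biomass, Ca²⁺, Mg²⁺ and pH sampled every 24 h over 500 h from the
200 mL static-culture simulation. Concentration-like observables get
median-parameterized multiplicative lognormal noise (positive by
construction, median equal to the model trajectory); pH gets additive
Gaussian noise truncated to [0, 14]; a missingness fraction can drop
observations. Replicates share one trajectory and differ only in noise, and
everything is reproducible from the seed. What it deliberately does *not*
emulate: instrument drift, detection limits, autocorrelated sampling error,
or real particle-size distributions (the model is monodisperse; the
radius-sweep utility brackets the PSD effect instead). Consequently, passing
recovery tests show the calibration machinery is unbiased and precise *under
the stated error model* — they cannot certify the kinetic parameters against
real cultures.

## What the tests establish

The suite checks: speciation against an independent brute-force bisection
of the charge balance (100 randomized compositions); component and charge
conservation to 10⁻¹²/10⁻¹⁰; elemental ledgers (S, Mg, C, H₂) closed across
liquid, gas, mineral and precipitate phases to 10⁻⁶ relative along entire
trajectories; closed-form limits (exponential decay, linear radius
shrinkage, quadratic seed-area growth, exponential gas absorption) to 10⁻⁶;
the stoichiometric endpoints of both cycle variants; mass-transfer-limited
H₂S absorption; sweep properties (CO₂ per cycle invariant to particle
radius and impeller speed, cycle time monotone in both); and growth-rate
recovery within 5% under 5% noise. Sweep and recovery tests run on scaled
charges (0.1 mol/L sulfur, 40 g/L forsterite) and a trimmed validation
configuration (single phase, 240 h) — the checked invariants are
scale-free, and the full-scale study conditions are exercised separately by
the acceptance checks and `scripts/acceptance.R`.

## Known limitations

* The single proton-promoted rate mechanism overestimates silicate
  dissolution in neutral-to-alkaline water; with very fine particles
  (2.5 μm) the validation scenario can drift to pH ~12 where a
  neutral/base-mechanism law would slow down much earlier.
* Davies clamping at I = 0.7 mol/L means activity coefficients in the
  concentrated process liquor are rough; cycle totals are
  stoichiometry-dominated and insensitive, but reported pH extremes carry
  that uncertainty.
* No oxygen inhibition of the reducer, no carbon source for autotrophic
  reducer growth, no lactate route, no Mg-carbonate hydrates or Ostwald
  ripening, no polydisperse PSD evolution, no silica passivation, no
  multi-cycle operation with sulfur make-up, no H₂S recirculation to
  recover vented sulfur.
* Timing results (stage lengths) depend on kinetic parameters that are
  order-of-magnitude defaults; mass and stoichiometry results are the
  robust outputs.
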