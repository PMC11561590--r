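---
title: "Modelling freeze-thaw injury in cryopreserved skin: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling freeze-thaw injury in cryopreserved skin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryoskin)
```

## The problem

Skin grafts are cryopreserved by loading them with a cryoprotective agent
(CPA), cooling slowly (-1 °C/min) to -80 °C, storing in liquid nitrogen, and
rewarming rapidly in a 37 °C water bath.  Two physical processes damage the
tissue along the way: ice formation (nucleating preferentially at the
liquid-skin interface) and mechanical stress, generated by the volume change
of the water/ice transition and by differential thermal contraction between
the tissue and the surrounding solution.  `cryoskin` models the thermal and
mechanical side of this process on a 2D cross-section — a 20 mm x 20 mm
square of solution with a 10 mm x 2 mm skin sample embedded in it — and
implements the companion bench-data computations: CPA permeation kinetics
from freezing-point osmometry, DSC melting-enthalpy and nonfreezing-water
analysis, and supercooling/recalescence detection on thermocouple traces.

## Thermal model

Heat conduction with phase change is solved with the apparent heat capacity
method.  The liquid fraction $\theta_2(T)$ is a C1 smoothstep rising from 0
to 1 across $T_m \pm \Delta T_{tr}$ (default half-width 0.5 K): the
solver that inspired this geometry uses a smoothed transition interval but
its width is not published, and a compact-support polynomial makes every
latent-heat integral available in closed form.  Mixture properties follow
the standard phase-interpolation rules

$$\rho = \theta_1\rho_1 + \theta_2\rho_2,\qquad
  k = \theta_1 k_1 + \theta_2 k_2,\qquad
  C_P = \tfrac1\rho(\theta_1\rho_1 C_{P,1} + \theta_2\rho_2 C_{P,2})
        + L_{1\to2}\,\frac{\partial\alpha_m}{\partial T},$$

with $\alpha_m = \tfrac12(\theta_2\rho_2-\theta_1\rho_1)/(\theta_1\rho_1+
\theta_2\rho_2)$ the bounded mass-fraction function whose derivative
concentrates the latent heat $L_{1\to2}$ on the transition window.  (Some
published statements of this closure place the latent term inside the
$1/\rho$ bracket; that form is dimensionally inconsistent, and the package
uses the standard convention above.  Note also that $\alpha_m$ is a mass
fraction despite sometimes being called a thermal expansion coefficient;
thermal expansion proper is the per-phase $\alpha$ of the mechanics.)

Discretisation is cell-centred finite volumes with harmonic-mean face
conductivities and backward-Euler time stepping.  The apparent-capacity
spike is handled by a *chord* (secant-enthalpy) Picard linearisation,
$\bar{C} = (H_v(T_k) - H_v(T^n))/(T_k - T^n)$ with $H_v$ the closed-form
volumetric enthalpy: unlike the pointwise $C_P(T)$, the chord cannot step
over the latent spike, so at Picard convergence (tolerance $10^{-6}$ K) the
discrete enthalpy change equals the boundary flux exactly.  The energy
ledger in every run log measures this closure; drifts are parts in $10^6$
of the exchanged heat, far inside the 1% acceptance bound.

Natural convection in the liquid is deliberately dropped ($u = 0$): no flow
model or parameters are available for this system, so conduction-only is
the reproducible reading.  This is the model's main documented limitation —
see "Known limitations" below for its observable consequences.

## Mechanical model

Stress follows a Maxwell viscoelastic decomposition of the strain rate into
elastic, creep and thermal parts,
$\dot\varepsilon = \dot\varepsilon_{el} + \dot\varepsilon_{cr} +
\dot\varepsilon_{th}$ with $\dot\varepsilon_{cr} = S/2\mu$ and
$\dot\varepsilon_{th} = \alpha\dot{T}I$, plus a phase-change eigenstrain
$\theta_2[(\rho_1/\rho_2)^{1/3}-1]$ that converts the frozen/liquid density
contrast into a linear strain (freezing expands, melting contracts).  The
quasi-static equilibrium problem is solved each time step on bilinear
plane-strain finite elements sharing the thermal grid, one-way coupled:
thermal step first, then the mechanical update driven by the per-cell
$\Delta T$ and $\Delta\theta_2$.

The backward-Euler stress update is exact per step: deviatoric stress
relaxes by the unconditionally stable factor $1/(1+G\Delta t/\mu)$ and the
volumetric response is elastic, so the element stiffness splits into fixed
bulk and shear templates scaled by per-cell moduli.  Supports follow the
cryovial setup: rollers on the lateral walls, fixed base, free top.  Liquid
cells stay within the same linear-elastic constitutive family but get a
soft, fast-relaxing surrogate (E = 0.1 MPa, mu = 1e3 Pa s), so they carry
negligible deviatoric stress — a genuine fluid cannot be represented in a
linear-elastic model, and this surrogate is the standard compromise.
Mechanical constants interpolate linearly in $\theta_2$ between the frozen
and liquid values.

Both von Mises and maximum-principal scalars are tracked per region (skin,
solution, interface band): "tensile stress" claims are evaluated on the
maximum principal stress, which is what tensile means, while von Mises maps
the overall distortion energy.

## The stated world: parameters and defaults

The instrument-calibrated parameter table behind the original simulations
is not published; the package ships literature defaults, chosen once:

| quantity | frozen | liquid | source of the choice |
|---|---|---|---|
| solution density (kg/m³) | ~993 (ice + residual brine) | ~1048 (15 wt% CPA) | mixture rule over ice 917 / brine 1150 |
| solution k (W/m K) | ~1.9 | 0.56 | ice 2.25 scaled by brine inclusions / water |
| solution E (Pa) | 9e9 | 1e5 (surrogate) | polycrystalline ice / see above |
| solution Maxwell mu (Pa s) | 1e13 | 1e3 | ice creep near melt / fast-relaxing fluid |
| skin k (W/m K) | 1.9 | 0.45 | frozen / fresh soft tissue |
| skin E (Pa) | 1e9 | 5e5 | frozen / fresh dermis |
| skin water mass fraction | 0.70 | | soft-tissue composition |

CPA presets (15 wt% betaine, trehalose, glycerol, DMSO and the
betaine/trehalose blends BT-1/2/3) modify parameters only — no solute
transport is simulated.  The melt point is depressed colligatively from the
formulation ($\Delta T_f = K_f m$ plus the PBS background), the latent heat
is reduced by the formulation's nonfreezing-water fraction (0.27 for the
betaine-containing groups, matching the reported DSC deficit), and the BT
blends reduce the frozen skin's thermal expansion coefficient by the
measured 40%.  The default scenario uses BT-2 (10% betaine + 5% trehalose),
the formulation the underlying study selected.

Two values the source does not print had to be chosen: the initial
temperature of cooling runs (4 °C, the CPA loading temperature) and the
water-bath film coefficient for rewarming.  The latter is set to
600 W/(m² K) from a series combination of stirred-water immersion
(~1000 W/(m² K)) with a polyethylene bag wall — consistent with the bench
observation that bagged samples melt completely within a few minutes.  The
LN2 plunge uses h = 200 W/(m² K) (film boiling).  Temperatures are kelvin
internally, Celsius at every user-facing interface.

## Numerical choices

* Default grid 100 x 100 cells; the skin rectangle resolves to 50 x 10
  cells.  Milestones shift by well under 5% between half and double
  resolution (tested).
* Time steps: 1 s during cooling's transition window (0-1500 s; the default
  scenario is fully frozen by ~1100 s), 5 s afterwards; 0.5 s for the first
  120 s of rewarming (resolving the early stress transient), 1 s after
  (backward Euler is unconditionally stable).  These are coarser than the
  smallest steps one could take, chosen so a full graded scenario runs in
  minutes in plain R; step-halving leaves milestones essentially unchanged
  (tested), because the implicit chord scheme is conservative at any step.
* The mechanical stiffness is refactorised only when the phase field has
  moved by more than 0.02 anywhere since the last factorisation; stress and
  stiffness always use the same (possibly slightly lagged) moduli, so the
  discrete equilibrium residual stays at direct-solver precision
  (~1e-12 of max stress) every step.
* Milestone conventions: per-cell ice onset at liquid fraction < 0.99
  (robust to smoothing tails); freeze completion at domain-mean ice
  fraction 0.999; melt completion at 0.001; all crossings linearly
  interpolated.  Ties in peak scans break to earliest time, then lowest
  cell index.

## Probes

The probe pair reports the interface lag: Point 1 is the skin-side cell at
the midpoint of the upper long interface edge (0, 0.75 mm), Point 2 free
solution at (0, 5 mm).  The description of these probes carries two
constraints — Point 1 at the interface midpoint, Point 2 in solution on the
same circle about the domain centre — that cannot both hold: every point of
the r = 1 mm circle except its poles lies inside the skin, and placing the
pair on the r = 5 mm circle instead (skin short edge) puts both probes at
equal conduction distance from the boundary, which cancels the asymmetry
the probes exist to show (we measured a lag of ~-1 s).  The long-edge
placement preserves the mechanism: the skin-side probe completes its phase
transition after the free-solution probe because heat must cross 9 mm of
solution plus the tissue's lower conductivity and its own latent load.

## Synthetic data: what it does and does not establish

The generators emulate the *structure* of the bench measurements with exact
ground truth: thermocouple traces as a piecewise model (imposed ramp,
supercooled nucleation, exponential recalescence, plateau, resumed
cooling) with additive Gaussian noise; DSC thermograms as a Gaussian
endotherm on a linear baseline whose area withholds the nonfreezing
fraction of the water's latent heat; osmometry series by exact inversion of
the four-step permeation chain from a first-order uptake curve.  A single
seed expands into per-stream seeds by a fixed counter scheme, so adding
generators never perturbs existing streams.

Green round-trip tests therefore establish that the analysis operations are
correct inverses of the stated measurement models at the stated noise — not
that real instruments follow those models.  Real DSC baselines curve,
real recalescence is not exactly exponential, real osmometer noise is not
Gaussian; none of that is claimed.

## Known limitations

* **No natural convection.**  During rewarming, real melt water convects
  and the bench trace warms faster than conduction alone allows.  The
  conduction-only model's melt front crosses the 5 mm solution gap to the
  skin in roughly 300 s; with convective enhancement the reference
  simulations put the stress culmination near the skin boundary at ~88 s.
  The package reproduces the *locations* and *orderings* (tensile peak at
  the skin boundary; boundary-first nucleation; interface lag; rewarming
  peak exceeding cooling peak) but front-arrival timings during rewarming
  are systematically late, and the late-arriving front also lowers the
  early-time stress transient.  This is analysed quantitatively in the
  acceptance suite rather than hidden by parameter tuning.
* Corner stress at the skin's short edges is mesh-sensitive (a re-entrant
  material-mismatch corner), as in any linear FE model; peaks are reported
  at the stated default resolution.
* No solute transport, no pressure dependence of the melt point, no
  fracture, no large-deformation kinematics, no container wall.

## Assay conventions

Permeation (Eq.-chain) analysis keeps the measurement convention that CPA
residue left on the skin is not corrected for.  The unit conventions
(osmol/kg, L, g, g/mL) are fixed in `osmometry_record()`, the single entry
point where unit errors could arise.  The intratissue solution density in
the concentration denominator defaults to 1 g/mL and is configurable, as is
the latent heat used in the nonfreezing-water deficit (default: pure water;
lower it to correct for freezing-point depression).  DSC onset uses the
tangent-intersection construction and nucleation detection uses
Savitzky-Golay local-polynomial derivatives — both standard practice; the
event temperature itself is read from the raw trace so noiseless traces
give exact supercooling depths.
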