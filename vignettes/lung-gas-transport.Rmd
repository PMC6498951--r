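---
title: "Gas transport and optimal ventilation in an idealized lung"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gas transport and optimal ventilation in an idealized lung}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

ventopt models how oxygen reaches the blood and carbon dioxide leaves it in a
human lung reduced to its core physics, and asks which breathing pattern moves
those gases at the least mechanical cost. This vignette is the package's own
account of the model, its numerical treatment, and the choices made where the
design was genuinely open.

## The model

### Geometry

The airway tree is a symmetric dichotomous cascade. The first 17 generations
(indices 0–16) form the conductive tree: radius and length shrink by a fixed
homothety ratio at each bifurcation, $r_{i+1} = h\,r_i$, $l_{i+1} = h\,l_i$,
with $l_0 = 6 r_0$. The last 6 generations form the acinus, where gas exchange
happens; all acinar branches keep the size of generation 16. Defaults are
$r_0 = 1$ cm and $h = 0.7937$, for which $2h^3 \approx 1$: every conductive
generation then holds about the same total air volume, and every generation
contributes about equally to the viscous resistance. Air is incompressible, so
the mean branch velocity obeys $u_i S_i = 2\, u_{i+1} S_{i+1}$, i.e.
$u_i = (2h^2)^{-i} u_0$, and halves at each acinar bifurcation. Ventilation is
a sinusoidal trachea velocity $u_0(t) = A \sin(2\pi t/T)$.

### Transport

Each representative branch carries a 1-D convection–diffusion equation for the
partial pressure $P(x,t)$ (mmHg) of each gas,

$$\partial_t P - D\, \partial_x^2 P + u_i(t)\, \partial_x P = 0,$$

with, on acinar branches only, a reaction term $\beta (P - P_{blood})$ for
exchange across the alveolo-capillary membrane. Bifurcations are small mixing
volumes $V_{bif} = \pi (r_i^3/2 + r_{i+1}^3)$ with their own mass-balance ODE
coupling parent and daughter branch ends. The trachea inlet is held at the
ambient partial pressure at all times; the distal end of the last acinar
generation carries a membrane-flux (Robin) condition
$-D \partial_x P = \alpha k (P - P_{blood})$.

The exchange coefficient is $\beta = (2 k / r_A)\, \alpha$ with membrane
permeability $\alpha = D_{water}\, \sigma / \tau$ and $k = R T_{body}/H$ the
pressure-to-concentration ratio obtained from the dimensionless Henry
solubility $H$. Three adimensional groups organise the physics per generation:
$\alpha_i = l_i^2/(DT)$ (transient vs diffusion), $Pe_i = l_i u_i / D$
(convection vs diffusion) and, in the acinus, $\gamma_i = \beta l_i^2 / D$
(blood absorption vs diffusion, of order one at the defaults).

### Blood

$P_{blood}$ is a local equilibrium, recomputed per acinar node and per time
step. For O2 the membrane flux balances hemoglobin loading plus plasma
solubility,

$$\alpha\,(P_{alv} - P_b) = 4 Z_0\,\bigl(f(P_b) - f(\tilde P_a)\bigr)\,v_s
  + \sigma\, v_s\, (P_b - \tilde P_a),$$

with the Hill saturation $f(P) = P^{2.6}/(P^{2.6} + 26^{2.6})$. The balance is
monotone, so the root is unique and bracketed between the arterial and
alveolar pressures; a safeguarded Newton iteration solves it vectorized over
all exchanging nodes. For CO2 the analogous balance is linear in $P_b$
(bicarbonate buffering enters through the factor
$(1 + 10^{pH-pK})(1 - 0.0289 Z_0 (3.352 - 0.456\,SO_2)(8.142 - pH))$) and is
solved in closed form. $SO_2$ is the local oxygen saturation **as a fraction**;
with a percentage the hemoglobin factor changes sign and the relation loses
its meaning as a buffering correction.

The incoming-blood O2 pressure is an *efficace* (effective) value $\tilde P_a$
rather than the mixed-venous 40 mmHg: capillary blood may already have
exchanged upstream, and the model absorbs that unknown history into one
calibrated pressure. `calibrate_arterial_pressure()` fits $\tilde P_a$ by a
bracketed root find so that the rest simulation reaches the physiological
respiratory exchange ratio (RER = VCO2/VO2 = 0.8); each evaluation is a full
periodic simulation. With the default parameter set the fit lands near 94–95
mmHg; the package default `Pa_o2_eff = 88` is the conventional reference
value and can be replaced by the fitted one.

### Power and the constrained optimum

The mechanical cost of breathing splits into an elastic part, stored in tissue
during inspiration and lost in passive expiration,
$P_e = A^2 S_0^2 T / (2 \pi^2 C)$, and a viscous part dissipated in the
airways, $P_v = R A^2 S_0^2 / 2$, so that
$P = P_e (1 + \pi^2 R C / T)$. The viscous integral is taken over the full
cycle: that reading makes the closed form and the factored total mutually
consistent (an inspiration-only integral would halve $P_v$ and break the
factorization). The shape of $P(T)$ depends on mechanics only through the
product $RC$; with the defaults $R = 2\times 10^5$ Pa s m$^{-3}$ and
$C = 5\times 10^{-7}$ m$^3$ Pa$^{-1}$, $\pi^2 RC \approx 1$ and the viscous
share at $T = 5$ s is about 17%.

Holding the oxygen uptake at a metabolic demand $F$ defines a constraint curve
$A(T)$ — for each period, the smallest amplitude whose periodic-cycle uptake
equals $F$ — computed by warm-started bracketed root finds, each evaluation a
full simulation. The optimum minimizes $P(A(T), T)$ along this curve, located
as the zero of

$$G(T) = A'(T)\left(1 + \frac{T}{\pi^2 R C}\right) + \frac{A(T)}{2 \pi^2 R C},$$

with $A'(T)$ from central differences (step 0.1 s) on a natural cubic spline
through the sampled curve, cross-checked against a direct minimization of the
interpolated power (`T_star_direct`); the two agree to well under 0.1 s at the
default grids.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| $r_0$, $h$ | m, – | 0.01, 0.7937 | trachea radius and homothety ratio; $2h^3 \approx 1$ |
| $D_{air}$ (O2, CO2) | m²/s | 2.0e-5, 1.4e-5 | axial diffusion in air |
| $D_{water}$, $\sigma$ | m²/s, mol m⁻³ mmHg⁻¹ | 3.3e-9 / 1.34e-3 (O2); 2.505e-9 / 3.07e-2 (CO2) | membrane permeability $\alpha = D_{water}\sigma/\tau$ |
| Henry $H$ | – | 2.592e-2 (O2), 0.594 (CO2) | sets $k = RT_{body}/H$ in $\beta$ |
| $\tau$ | m | 1e-6 | membrane thickness; oedema sweeps multiply it |
| $Z_0$, $v_s$, pH, pK | – | 9.93, 5e-4, 7.4, 6.09072 | blood-side equilibria |
| $P_{aO_2}$, $P_{aCO_2}$, $\tilde P_a$ | mmHg | 40, 47, 88 | arterial pressures; $\tilde P_a$ calibrated |
| $P_{air}$ (O2, CO2) | mmHg | 150, 0.3 | ambient pressures, calibrated against the reference rest flows; altitude scales the O2 value |
| $R$, $C$ | Pa s m⁻³, m³/Pa | 2e5, 5e-7 | lumped mechanics; optimum depends on $RC$ only |
| rest demand $F$ | mol/s | 1.604e-4 | 3.5 mL O2 kg⁻¹ min⁻¹ × 70 kg (1 MET), ideal gas at 310.15 K / 1 atm |

The rest-demand convention deserves a note. Two anchors are defensible: the
uptake of the calibrated rest simulation itself (1.32e-4 mol/s), or the
textbook resting metabolic rate of 3.5 mL O2/kg/min (1.60e-4 mol/s for 70 kg,
same conversion as the activity table). The package defaults to the MET value:
under it the constrained optimum sits at $T^\ast = 7.9$ s, $A^\ast = 0.86$ m/s
with a +5% power band spanning [5.3, 11.6] s — the reference rest ventilation —
whereas the weaker anchor pushes the optimum to $T^\ast \approx 9.4$ s. Both
are available through `rest_oxygen_demand(convention=)`.

## Numerical treatment

The symmetric tree collapses to one representative branch per generation, so
the fully coupled implicit system — all branch grids plus all junction scalars
— is a single tridiagonal chain of $23(M-1)$ unknowns for $M$ nodes per
branch. Time stepping is backward Euler with centered diffusion and
first-order upwind convection, the upwind direction flipping with the sign of
$u_0$; the scheme is unconditionally stable at the conductive-tree Peclet
numbers. The linear operators are periodic in time, so one sparse LU per time
step of the cycle is factorized up front and reused across cycles.

Details that affect fidelity:

* **Junction convection is upwinded.** Writing both faces of the bifurcation
  balance at the junction value makes the convective terms cancel exactly
  (mass conservation), leaving the junction coupled by diffusion alone — a
  spurious ~100 s relaxation time. The inflow face therefore takes the
  upstream branch node, the outflow face the junction value.
* **Half-cell exchange attribution.** Branch-end half-cells are absorbed into
  the junction control volumes; acinar junctions keep the reaction term of
  those half-cells ($\beta V_{ex} (P_{bif} - P_{blood})$), so the full acinar
  branch length exchanges and the reaction quadrature is consistent with the
  equations actually solved.
* **Lagged blood coupling.** $P_{blood}$ is evaluated from the previous time
  level (and the CO2 relation consumes the O2 saturation of the previous
  level), keeping each step linear; the associated error is first order in
  $\Delta t$, the same as the scheme.
* **Periodicity.** Cycles are marched until the relative L2 change of both
  pressure fields between consecutive cycle starts falls below tolerance
  (default 1e-6, typically 3–15 cycles from the analytic initial profile). The
  initial condition is the explicit steady conductive profile
  $P_i(x) = P_{air} + \frac{P_{blood}-P_{air}}{\sum_k (2h)^{-k}} \left(
  \sum_{k<i}(2h)^{-k} + (2h)^{-i} x/l_i\right)$ (normalizing sum over the 17
  conductive generations), acinus constant at its distal value.
* **Validation oracle.** With $u = 0$ the discrete steady state reproduces
  this closed form to round-off at any resolution — the scheme is exact on
  piecewise-linear steady solutions, junction rows included — which pins the
  assembly of diffusion, junction coupling and boundary rows.
* **Degenerate inputs.** $h = 1$ (identical branches), $A = 0$ (pure
  diffusion), conductive-only trees, and closed or Dirichlet distal ends are
  all supported; they are used by the test suite as limits with known
  behavior.

Problem sizes: single reference simulations use 10 nodes/branch and 200 steps
per cycle (207 unknowns per gas); optimization loops, where every constraint
evaluation is a periodic simulation, use 8 nodes and 100 steps with a 1e-5
periodicity tolerance. At those sizes a rest simulation takes about a second
and a full constrained optimization about ten seconds; cycle-averaged flows
move by under ~5% between the two settings, and the optimum location is stable
to ~0.2 s.

## What the model does and does not capture

All inputs are physical constants and configuration; there is no measured
data. The geometry is a strictly symmetric tree with a constant
length-to-radius ratio, no upper airway, no bronchial deformation, and a
constant compliance — a linearized mechanics that ignores the
pressure–volume nonlinearity of large breaths. The inlet Dirichlet condition
holds ambient composition at the trachea mouth even during expiration.
Ventilation is strictly sinusoidal. Blood-side transport is a local
equilibrium with fixed incoming pressures: no perfusion heterogeneity, no
transit-time dynamics, no acclimatization. Passing tests therefore demonstrate
internal consistency and agreement with the reference physiology of this
idealized system, not predictive accuracy for an individual lung.

Behaviors the model does reproduce at the defaults: physiological rest flows
(VO2 ≈ 1.3e-4 mol/s at $A = 1$ m/s, $T = 5$ s, within the 1–2e-4 band), the
rest optimum near 8 s with its broad low-power plateau, the sharpening of that
plateau and the rise of amplitude with exercise demand, faster/shallower
optima under geometry-linked resistance increases (6.7 s at +30%, 10.6 s at
−30%), increased amplitude and shortened period under altitude hypoxia with
infeasibility at severe O2 depletion, and the oedema screening plateau —
oxygen flow is nearly flat over the first doublings of membrane thickness and
collapses only once the spare exchange surface is exhausted.

## Known limitations

The respiratory exchange ratio is underpredicted. At rest the simulated acinus
equilibrates almost completely to the blood plateaus (88 mmHg O2, 47 mmHg
CO2), which caps RER near the gradient ratio
$(47 - 0.3)/(150 - 88) \approx 0.75$; diffusion corrections pull it slightly
below, to ≈ 0.72, and it stays in the 0.72–0.75 range across exercise
intensities instead of rising toward 0.9. The physiological rest value 0.8 is
reached by recalibrating the efficace pressure (to ≈ 94–95 mmHg), but the
exercise rise would additionally require the CO2 membrane exchange to outpace
the O2 exchange per unit gradient; with $k \propto 1/H$ the Henry factors
almost exactly cancel CO2's seventeen-fold permeability advantage
($\alpha_{CO_2}/\alpha_{O_2}$), making the two gases' $\gamma$ nearly equal.
Treating $k$ as the species-independent gas-phase factor $RT_{body}$ restores
that asymmetry and raises rest RER to ≈ 0.76 while dropping the uncalibrated
value to ≈ 0.43, but overshoots badly at exercise (RER > 1.2); the package
keeps the Henry-based reading. Cycle-averaged VCO2 is correspondingly ~10–15%
below VO2 × 0.8 at the reference grid. These are structural properties of the
printed parameter set, not discretization artifacts: they persist under grid
and time-step refinement.

Second, first-order upwinding adds numerical diffusion in the
convection-dominated conductive tree; absolute flows drift down by ~10% from
the default grid to a doubled resolution. The default grid is the package's
reference condition; comparisons across scenarios (sweeps, optima) are made at
matched resolution, where the bias largely cancels.
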