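---
title: "A switched two-compartment model of unidirectional avian airflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A switched two-compartment model of unidirectional avian airflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aviflow)
```

## Background

Airflow through the parabronchi — the gas-exchanging tubes of the avian
lung — is unidirectional, from the caudal to the cranial air sacs, during
both halves of the breathing cycle. No mechanical valve enforces this;
rectification is aerodynamic. `aviflow` implements the simplest model that
captures the mechanism: an electrical analogue with two capacitors (the
elastic air sacs) and five resistors (airway segments), two of which switch
value with the direction of their own flow. This vignette records the model
equations as implemented, the parameter conventions, the numerical design,
and the package's assumptions and limitations.

## The model

### States, forcing and flows

One side of the (symmetric) respiratory system is modelled. The states are
the air-sac pressure deviations from atmosphere,

$$x_1 = P_1 - P_{atm}, \qquad x_2 = P_2 - P_{atm},$$

for the caudal (1) and cranial (2) sacs. Both sacs sit in the coelomic
cavity, whose pressure oscillates sinusoidally with period $T$ and
peak-to-peak amplitude $P_{amp}$:

$$P_{ext}(t) = P_c - \tfrac{1}{2} P_{amp} \cos(2\pi t / T).$$

`external_pressure()` and `external_pressure_rate()` implement the waveform
and its derivative. At $t = 0$ the cavity pressure is at its minimum.

The airway network joins the trachea/primary bronchus (resistance $R_T$,
from atmosphere), the mesobronchus ($R_1$, to the caudal sac), and the
ventrobronchus ($R_2$, from the cranial sac) at a junction with pressure
$P_J$; the parabronchial pathway ($R_P$) connects the two sacs directly.
Eliminating $P_J$ from Ohm's law on each branch and conservation at the
junction ($q_T + q_2 = q_1$) gives, with
$\bar R = R_1 R_2 + R_2 R_T + R_T R_1$:

$$q_T = \frac{-R_2 x_1 - R_1 x_2}{\bar R}, \quad
  q_1 = \frac{-R_2 x_1 - R_T (x_1 - x_2)}{\bar R}, \quad
  q_2 = \frac{R_1 x_2 - R_T (x_1 - x_2)}{\bar R}, \quad
  q_P = \frac{x_1 - x_2}{R_P}.$$

`compute_flows()` evaluates these; the test suite checks them against a
first-principles junction solve and verifies conservation on random
parameter draws.

### Compartment dynamics

The sacs are linear bellows: $V_i = C_i\,(P_i - P_{ext}) + V_{i,res}$
(`airsac_volumes()`). Mass balance gives

$$\frac{dX}{dt} = A\,X + \frac{dP_{ext}}{dt}\begin{pmatrix}1\\1\end{pmatrix},
\qquad
A = \begin{pmatrix}
 -\dfrac{\beta + R_P R_2}{C_1 \bar R R_P} & \dfrac{\beta}{C_1 \bar R R_P}\\[1ex]
 \dfrac{\beta}{C_2 \bar R R_P} & -\dfrac{\beta + R_P R_1}{C_2 \bar R R_P}
\end{pmatrix},
\qquad \beta = R_T R_P + \bar R,$$

with compliances in L/cmH2O (`system_matrix()`, `state_derivative()`).

### Aerodynamic valving: the switching rule

The two valves are modelled as flow-direction-dependent resistances:

- $R_1 = R_{1,insp}$ while $q_1 > 0$ (air entering the caudal sac),
  $R_1 = R_{1,exp} \ge R_{1,insp}$ otherwise;
- $R_2 = R_{2,insp} \ge R_{2,exp}$ while $q_2 \le 0$ (inspiratory branch),
  $R_2 = R_{2,exp}$ while $q_2 > 0$.

Each combination of branches freezes an affine-linear system. The phase
plane splits into regions: region 1 ($q_1 > 0$, $q_2 < 0$), regions 2/3
($q_1 < 0$, $q_2 < 0$; the tracheal flow changes sign inside them), and
region 4 ($q_1 < 0$, $q_2 > 0$). The combination ($R_1$ inspiratory, $R_2$
expiratory) would require $q_1 > 0$ and $q_2 > 0$ simultaneously, which the
junction balance forbids along the breath cycle; `flow_regime()` rejects
it. A steady-state breath traverses

$$1 \xrightarrow{q_1 = 0} 2/3 \xrightarrow{q_T = 0} 2/3
  \xrightarrow{q_2 = 0} 4 \xrightarrow{q_2 = 0} 2/3
  \xrightarrow{q_T = 0} (1),$$

four resistance switches plus two tracheal-flow reversals that mark the
inspiration/expiration boundary without switching any resistance.
`classify_region()` evaluates each boundary under the resistances that
govern it and breaks exact ties toward region 1, so the rest state belongs
to region 1.

### Phase-plane analysis and the unidirectionality condition

Scaling time by $C_1 \bar R R_P$ gives the matrix

$$\hat A = \begin{pmatrix} -(R_2 R_P + \beta) & \beta \\
  \gamma \beta & -\gamma (R_1 R_P + \beta)\end{pmatrix},
  \qquad \gamma = C_1 / C_2,$$

whose trace is negative, determinant positive and discriminant positive for
all positive parameters: each frozen regime is a stable node with real,
distinct eigenvalues. `eigen_analysis()` returns the closed-form
eigenvalues

$$\lambda_{1,2} = \tfrac{1}{2}\left(\mathrm{tr}\,\hat A \mp
  \sqrt{(\mathrm{tr}\,\hat A)^2 - 4 \det \hat A}\right),
  \qquad V_i = \begin{pmatrix}1\\ (\lambda_i + R_P R_2 + \beta)/\beta
  \end{pmatrix},$$

and `special_case_eigen()` the simplified $\gamma = 1$ forms. The slow
eigenvector lies on the diagonal $x_2 = x_1$ exactly when
$\gamma R_1 = R_2$; its orientation relative to the diagonal determines the
sign of $q_P \propto x_1 - x_2$ along the slow manifold the trajectory
hugs. This yields the certificate implemented in
`unidirectional_flow_condition()`: parabronchial flow is unidirectional
when

$$\gamma R_{1,insp} \le R_{2,insp} \quad\text{and}\quad
  \gamma R_{1,exp} \ge R_{2,exp},$$

with at least one inequality strict; when both hold with equality the
trajectory is confined to the diagonal and $q_P \equiv 0$ (the
"borderline" verdict, confirmed by simulation in the tests).

## Parameters

`airflow_params()` carries the duck-calibrated default set in conventional
units (resistances cmH2O/(L/s), compliances mL/cmH2O, volumes mL, pressures
cmH2O, time s); all internal computation converts to the consistent set
{cmH2O, L, s}. Linked quantities resolve from their parents unless given
explicitly:

| symbol | default | meaning |
|---|---|---|
| `R_trachea`, `R_EPPB` | 1, 8 | trachea and extrapulmonary primary bronchus |
| `R_T` | `2*R_trachea + R_EPPB` = 10 | single-side reduction of the shared airway |
| `R_P` | 2.5 | dorsobronchi + parabronchi |
| `R1_insp`, `R2_exp` | 1, 5 | open-branch resistances |
| `k_insp`, `k_exp` | 100, 10 | valving multipliers: `R2_insp = k_insp*R1_insp`, `R1_exp = k_exp*R2_exp` |
| `gamma`, `C_tot` | 1.35, 450 | compliance ratio `C1/C2` and total `C1 + C2` |
| `V1_res`, `V2_res` | 105.6, 103.6 | resting sac volumes (single side) |
| `P_c`, `P_amp`, `T` | 1033.6, 0.5, 3 | coelomic baseline, drive amplitude, period |

Validation enforces positivity, `R2_insp >= R2_exp`, `R1_exp >= R1_insp`,
and consistency (to 1e-9 relative) when both a derived value and its
parents are supplied. `single_valve_params()` provides the two single-valve
contrast configurations used in the examples and tests
(`R1_insp = R2_exp = 3`, $\gamma = 1$, with only one valving multiplier
above 1).

## Numerical design

**Exact propagation per regime.** Within a regime the system is
affine-linear with sinusoidal forcing, so the package does not use a
numerical ODE stepper. Each leg is propagated in closed form: the
particular solution is $X_p(t) = \Im\{z e^{i\omega t}\}$ with
$z = (i\omega I - A)^{-1} \alpha [1,1]'$, $\omega = 2\pi/T$,
$\alpha = P_{amp}\pi/T$, and the homogeneous part decays along the
eigenvectors of $A$. This is deterministic and accurate to machine
precision; a deliberately naive fixed-step RK4 integrator that re-classifies
the regime every step (`simulate_fixed_step()`) is retained purely as an
independent cross-check and agrees with the event-driven trajectories to
better than $10^{-4}$ cmH2O in the tests.

**Event location.** Along each leg the next zero crossing of the watched
flow numerators ($q_1$, $q_2$, and $q_T$ for the phase boundary) is
bracketed by a vectorised scan (logarithmically refined near the leg start,
then a uniform 1 ms grid) and polished with `uniroot` to a time tolerance
of $10^{-13}$ s. Sign violations below a relative noise floor of
$10^{-9} \times \max|q|$ over the horizon are ignored: near the rest state
the flow numerators fall below double-precision cancellation noise and
would otherwise trigger spurious events. Genuinely simultaneous crossings —
which occur at borderline configurations, where all boundaries coincide on
the diagonal — are handled as zero-length legs; a flow that re-crosses zero
immediately after causing a switch (chatter, i.e. a sliding mode) raises an
error rather than being silently regularised.

**Steady state and alignment.** Breaths (four switches each) are iterated
from the rest state until the *exact* net tracheal volume over a breath —
computed analytically from the per-leg integrals of $q_T$, not by
quadrature — falls below `steady_tol` (default $10^{-5}$ L, interpreted in
litres as the consistent-unit reading of the convergence criterion; the
duck defaults converge in 18 breaths). The converged breath is then re-run
densely and re-timed so $t = 0$ is the upward zero crossing of $q_T$ (start
of inspiration). The output step `dt` (default $10^{-4}$ s) controls
sampling only; exact event times are inserted as sample points, so phase
integrals are cut at event-located boundaries rather than grid samples.

**Metrics.** `breath_metrics()` integrates the sampled flows by the
trapezoidal rule: efficiency
$\int_{breath} q_P / \int_{INSP} q_T$, inspiratory valving efficacy
$\int_{INSP} q_1 / \int_{INSP} q_T$, expiratory valving efficacy
$\int_{EXP} q_2 / \int_{EXP} (-q_T)$, and an alternative expiratory
efficacy $\int_{EXP} q_P / \int_{EXP} (q_P + \max(-q_1, 0))$ — the share of
the caudal-sac outflow that leaves through the lung rather than leaking
back up the mesobronchus. The back-leak term is clamped at zero
sample-wise so the share stays in $[0, 1]$ even if $q_1$ grazes zero near a
phase boundary. The two expiratory definitions answer different questions
(composition of the exhaled air at the trachea versus routing of the
caudal-sac outflow) and differ materially for weakly valved configurations;
both are reported. Volumes are single-side and doubled by default
(`whole_animal = TRUE`); dimensionless ratios are unaffected.

## Design rationale

- A classed simulation object (`airflow_sim`) with `print`, `summary`,
  `coef` and `plot` methods keeps the workflow in the classic base-R
  modelling idiom; internals are base R plus `jsonlite` for file I/O.
- Closed-form propagation was chosen over an adaptive ODE solver because
  the regimes are affine-linear: event times then limit the overall
  accuracy, and they are located to near machine precision. It also makes
  runs bit-reproducible across platforms to within floating-point
  evaluation order.
- The steady-state criterion uses exact leg integrals so that convergence
  is a property of the dynamics, not of the output sampling.
- Sweeps (`run_sweep()`, `resistance_ratio_sweep()`) re-resolve all linkage
  rules at every point from the raw base configuration so that derived
  resistances and compliances cannot drift across a sweep, and
  `fit_gamma_to_ventilation_fraction()` uses bracketing bisection on the
  simulated caudal ventilation fraction, which is monotone in $\gamma$.

## Assumptions and limitations

- **Linearity within a regime.** Resistances are constant within each flow
  regime and compliances are constant everywhere; the switch is an
  idealised Heaviside dependence on the branch flow sign. Real aerodynamic
  valving (jet inertia at the junctions, the segmentum accelerans) is
  smooth and flow-magnitude-dependent.
- **Two sacs, one lung path.** The cervical/clavicular sacs are lumped
  into the cranial compartment, the neopulmonic parabronchi are not
  represented separately, and gas exchange (O2/CO2 transport) is outside
  the model: flows are of incompressible bulk air.
- **Symmetric sides.** One side is simulated; whole-animal volumes are
  exact doublings. Asymmetric disease or occlusion states are out of scope.
- **Sinusoidal drive.** The coelomic pressure is a single sinusoid;
  panting, biphasic drives, or measured pressure traces would need a new
  forcing term (only `external_pressure()`/`external_pressure_rate()` and
  the particular-solution construction would change).
- **Sliding modes are errors.** Parameter sets whose trajectories would
  chatter on a switching boundary stop with an error instead of being
  regularised; none of the physiological configurations shipped with the
  package does so.
- The linear bellows law admits non-positive volumes for extreme pressures;
  `airsac_volumes()` warns when the elastic model leaves its physical
  range.
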