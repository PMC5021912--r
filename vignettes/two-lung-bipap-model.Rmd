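---
title: "A two-lung model of BIPAP mechanical ventilation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-lung model of BIPAP mechanical ventilation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bipapsim)
```

## The model

Single-compartment models of mechanical ventilation cannot describe how two
lungs with unequal mechanics share the flow delivered by one ventilator.
`bipapsim` models a bi-level positive airway pressure (BIPAP) circuit as an
equivalent pneumatic system: an ideal pressure source (the ventilator)
connected through two equivalent throttles (the lumped airway and tubing
resistance of each side) to two variable-volume containers of isothermal
ideal gas (the lungs).

**Ventilator.** The source pressure follows the five clinical controls:
within each cycle of period $T = 60/\mathrm{BPM}$ the setpoint ramps
linearly from EPAP to IPAP over the rise time $T_r$, holds at IPAP until
the end of inspiration $T_i$, then steps back to EPAP. The shape is a
choice: only the five scalars are clinically specified, and a linear ramp
with a step release is the simplest waveform consistent with a "rise time"
control and with how BIPAP ventilators behave. The waveform is isolated
behind `pressure_setpoint()`, so an exponential-rise variant could be
swapped in without touching the rest of the model. Whether the fall to
EPAP also has a finite ramp is equally unspecified; a step is used. The
source is ideal (no flow limit): the circuit gives no source impedance to
model.

**Throttles.** Each airway carries the compressible orifice mass flow
$$ q = A_e\, p_u \sqrt{\tfrac1\theta}\,
   \sqrt{\frac{2k}{k-1}\frac1R\left(r^{2/k} - r^{(k+1)/k}\right)},
   \qquad r = p_d/p_u, $$
with effective area $A_e = C_d\,\pi (d/2)^2$, and the choked (sonic)
branch — the same expression frozen at the critical ratio
$b = (2/(k+1))^{k/(k-1)} \approx 0.528$ for air — when $r \le b$. The two
branches join continuously at $b$. Flow is signed along the pressure
gradient, so one throttle per lung carries both inspiration and
expiration (the exhalation path is not modelled separately). In practice
the reference scenario never leaves the subsonic regime: the minimum
pressure ratio across a cycle stays near 0.98, far above $b$ (this is
verified by a test, not assumed). No discharge coefficient is clinically
given, so $C_d$ defaults to 1 (the inlet diameter is the diameter of the
effective area) and is exposed as configuration.

**Lungs.** Each lung holds mass $m$ of ideal gas at pressure $p$ in
volume $V$ with $pV = mR\theta$ at fixed $\theta$ (the process is treated
as isothermal — the 2–40 cmH2O swings involved are far too small for
significant gas heating). The wall responds with a constant linear
compliance $C = dV/dp$. Substituting $dV = C\,dp$ into the differential
gas law $V\dot p + p\dot V = R\theta q$ gives the closed-form rates
$$ \dot p = \frac{R\theta\, q\, V}{V^2 + C m R \theta}, \qquad
   \dot V = C\dot p, \qquad \dot m = q. $$
The state is integrated as $(p, V, m)$ with the gas law *monitored* as an
algebraic invariant rather than eliminated: its residual is a free
integration-accuracy diagnostic, available as `residuals()` on a
simulation object.

Nonlinear compliance curves, airway inertance, time-varying resistance,
leaks and patient effort are out of scope; the compartments interact only
through the shared setpoint, which an ideal source pins, so with these
assumptions the two lungs are dynamically decoupled.

## Parameters, units and defaults

Clinical units appear only at the boundaries; everything internal is SI
(Pa absolute, m³, kg, s, K).

| Parameter | Units | Default | Why |
|---|---|---|---|
| IPAP / EPAP | cmH2O gauge | 22 / 4 | reference operating point |
| BPM | min⁻¹ | 20 | reference |
| $T_i$, $T_r$ | s | 1, 0.3 | reference |
| $C$ | mL/cmH2O | 10 | reference lung |
| $d$ | mm | 3.2 | reference throttle |
| $C_d$ | — | 1 | no clinical value; exposed |
| $V_0$ | L | 1.5 | adult-lung-simulator scale; see below |
| $\theta$ | K | 293.15 | room temperature; one $\theta$ everywhere |
| $R$ | J kg⁻¹ K⁻¹ | 287.05 | dry air |
| 1 cmH2O | Pa | 98.0665 | standard |
| atmosphere | Pa | 101325 | standard |

The resting volume $V_0$ is not clinically specified. It enters the
pressure rate only through the denominator $V^2 + CmR\theta$, where the
compliance term dominates ($CmR\theta \approx 7\times$ the $V^2$ term at
the defaults), so tidal volumes are insensitive to $V_0$ within any
plausible range; 1.5 L per lung is a representative adult test-lung
scale. Initial pressure defaults to EPAP — steady cycling starts from the
expiratory baseline, and warm-up cycles absorb any residual transient.

## Numerical integration

The setpoint is only piecewise smooth, so `simulate_bipap()` restarts the
integrator (`deSolve::lsoda`, `rtol` 1e−8, `atol` 1e−10, maximum step
$T_r/10$) at the waveform breakpoints $\{0, T_r, T_i\}$ of every cycle,
handing each segment the smooth extension of its own waveform piece. An
adaptive step never crosses the expiratory discontinuity, which would
degrade the integration order and corrupt tidal-volume metrics. Output is
recorded on a uniform 1 ms grid, half-open per cycle, after 5 warm-up
cycles; 3 cycles are recorded by default. The reference scenario becomes
periodic within 2–3 cycles, and a steadiness flag compares per-cycle
volume excursions of the last two warm-up cycles (relative tolerance
1e−4); a non-steady run warns but still returns.

One property of the flow law shapes much of the observed dynamics: near
pressure equality the orifice flow behaves as $q \propto \sqrt{\Delta p}$,
so each lung reaches the setpoint in *finite* time and the flow is then
exactly zero until the next phase. Consequences:

* Within a phase the state can sit exactly at equilibrium; the integrator
  chatters by at most ~1 mPa around it (harmless, but visible if you look
  at flows at the 1e−7 kg/s scale).
* The total flow $q_s$ is exactly zero on the tails of both phases, so
  the flow-split ratio $q_r/q_s$ is undefined there. `flow_ratio_series()`
  masks samples with $|q_s| \le$ 1e−7 kg/s (≈0.005 L/min) instead of
  clamping; at the reference point about 6% of the cycle is masked. On
  unmasked samples the ratio may legitimately leave $[0,1]$ when the two
  lung flows have opposite signs (transient redistribution between
  compartments with unequal time constants); it is reported raw.
* In sweeps of the throttle diameter, once $d$ is large enough that the
  lung fully equilibrates in both phases (above ≈3.6 mm at the reference
  settings), the tidal volume saturates at exactly
  $C\,(\mathrm{IPAP}-\mathrm{EPAP})$ and the share curve flattens; the
  increase across the last grid points is then at the edge of integrator
  resolution.

Tidal volume is defined as the per-cycle volume excursion
$\max V - \min V$, which for a periodic breath equals the integrated
inspiratory volumetric flow; the share is $VT_r/(VT_r+VT_l)$. Ratios are
fractions internally and percent at reporting boundaries.

## The study design

`reference_sweep_suite()` returns the one-at-a-time design around the
reference point as data: for each of $C_r$, $d_r$, IPAP, EPAP, BPM,
$T_i$, $T_r$, a three-point grid for flow-ratio comparisons (where the
design defines one) and a grid for the tidal-volume share curve
($C \in \{5,\dots,30\}$ step 5 mL/cmH2O; $d \in [1.6, 4.0]$ mm — the
design fixes only the endpoints, and a 0.4 mm step is used here;
IPAP $\{18, 22, 24\}$; EPAP $\{4, 6, 8\}$ cmH2O; BPM $\{20, 25, 30\}$;
$T_i$ $\{1, 1.2, 1.4\}$ s; $T_r$ $\{0.2, 0.3, 0.4\}$ s). `run_sweep()`
validates every perturbed scenario before simulating any of them and
orders results by swept value; scenarios are independent, so results do
not depend on execution order.

```{r, eval = FALSE}
sw <- run_sweep(sweep_spec("C_r", seq(5, 30, by = 5)))
plot(sw)
```

The physics behind the headline orderings: a softer right lung
accommodates more volume per unit pressure, and a wider right throttle
lets it track the setpoint more completely within the fixed inspiratory
window — either way $VT_r/VT_s$ rises with the right-lung parameter, is
exactly 50% by symmetry when both lungs match, and the instantaneous
split can reach 0% or 100% when one lung has finished equilibrating
while the other still flows.

## What the simulations do and do not show

Everything here is a forward simulation of the idealised circuit. Model
symmetry (identical lungs → exact 50/50 split), conservation laws, the
quasi-static compliance limit $VT \to C\,\Delta p$ and the subsonic-regime
check are *internal consistency* properties — they validate the
implementation, not the physiology. Real measurements add leak flows,
sensor dynamics, nonlinear compliance and ventilator control behaviour
that this model deliberately omits, so agreement with bench data can only
be qualitative (orderings and magnitudes, not waveform detail).

Problem sizes used throughout the tests — 5 warm-up plus 1–3 recorded
cycles at a 1 ms grid, with 2-cycle warm-ups for short property checks —
are the package's default study conditions; the reference scenario is
periodic well before recording starts in all of them.
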