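---
title: "Predicting transient dosing errors in multi-pump infusion systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting transient dosing errors in multi-pump infusion systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infusim)
```

## The problem

Intensive-care patients routinely receive several drugs through a single
vascular access point: pump lines join at a manifold, and the mixed fluid
travels through a shared "dead volume" and the catheter lumen into the
bloodstream. Whenever a set flow changes (or a syringe is exchanged), the
dose rates that actually reach the patient deviate transiently from the
rates set on the pumps. For low-flow, high-concentration medication —
catecholamines in a neonate, for instance — these transients are clinically
relevant, and their shape is hard to predict by intuition, especially with
thin catheters. `infusim` simulates them from the physical parameters of
the setup.

## Model

### Hydraulics: a lumped compliance–resistance network

Each pump branch is modelled as an ideal flow source (the motor drive)
feeding a lumped mechanical compliance $C_i$ (mL/mbar, dominated by the
air-filled rubber syringe plunger) at pressure $P_i$, connected to the
mixing-point junction through its line resistance $R_i$. The junction
drains through the catheter resistance $R_c$ to a constant venous pressure
$P_v$. The junction itself stores no volume, so its pressure is algebraic,

$$\sum_i \frac{P_i - P_j}{R_i} = \frac{P_j - P_v}{R_c},$$

and each compliant branch obeys

$$C_i \frac{dP_i}{dt} = Q_{\mathrm{set},i}(t) - \frac{P_i - P_j}{R_i}.$$

Branches with $C_i = 0$ are solved algebraically: a rigid branch delivers
its set flow instantly. For a single branch the step response of the flow
into the patient is the RC exponential $1 - e^{-t/\tau}$ with
$\tau = C\,(R_\mathrm{branch} + R_c)$; this closed form is used as an
oracle in the test suite.

Tube resistances come from the Hagen–Poiseuille law for laminar flow in a
cylinder, $R = 128\,\mu L / (\pi d^4)$, evaluated in SI and converted once
to clinical units (mbar·h/mL). The $d^{-4}$ scaling is what makes a 1 Fr
neonatal catheter three to four orders of magnitude more resistive than a
7 Fr central line, and with it the compliance mechanism dominant.

### Transport: a volume-slice shift register

The composition of the shared volume (manifold dead volume plus catheter
lumen) is tracked as an ordered chain of volume slices, each carrying
per-drug volume fractions — the time-domain realization of a Z-transform
(shift-register) description of the catheter contents. Every time step the
junction mixture is pushed onto the proximal end and the same volume is
emitted from the distal end; pushed slices take exactly the volume the step
advects, so plug transport over the chain is exact volume bookkeeping and
the only smearing of a front is the per-step advected volume.

When a branch's flow into the junction turns negative (backflow), the
junction mixture pressed into that line is stored in a per-branch
last-in-first-out buffer — plug flow is reversible at infusion Reynolds
numbers — and re-enters the junction before fresh stock solution once the
branch flows forward again. Net aspiration at the access point (negative
catheter outflow) is outside the supported regime and raises an error.

### Laminar (Poiseuille) dispersion

Fully developed laminar flow has the parabolic profile
$v(r) = 2\bar v\,(1 - (r/R)^2)$: the centerline moves at twice the mean
velocity, so the first new fluid arrives after half the mean transit time,
and with no radial mixing the washout fraction after a front is

$$F(t) = 1 - \left(\frac{\tau}{2t}\right)^2, \quad t \ge \tau/2, \qquad
  \tau = V/Q.$$

Because the curve depends on flow only through cumulative volume, the
kernel is applied in cumulative-volume coordinate, which generalizes it to
time-varying flow: the junction-entry composition history is convolved
(FFT) with the residence-volume density $f(u) = V^2/(2u^3)$, $u \ge V/2$,
on a uniform volume grid, with the analytic tail weight assigned to the
pre-existing segment content. Dispersion is applied to the shared
dead-volume + catheter segment, where the mixture composition matters;
branch lines upstream of the junction carry single drugs (or reversible
backflow plugs) and use plug transport.

### Error decomposition

The tool reports, per drug, the deviation of delivered from set dose rate
and its split into mechanisms, computed by nested ablation: (a) rigid
syringes + plug transport isolates **push-out**; (b) rigid + laminar minus
(a) isolates the **Poiseuille** contribution; (c) the full model minus (b)
isolates **compliance**. The three components sum to the full-model
deviation exactly, by construction. No canonical definition of such a split
exists — the mechanisms interact — so the nesting order is a design choice:
compliance is differenced last because it interacts with both transport
effects; the order is documented rather than discoverable from the output.

## Parameters and defaults

| Parameter | Unit | Default | Rationale |
|---|---|---|---|
| viscosity | mPa·s | 1.0 | water-like infusates; overridable per branch |
| syringe compliance (50 mL) | mL/mbar | 0.002 | order-of-magnitude estimate for an air-backed rubber plunger; manufacturers publish none |
| tubing | — | 1 m × 1.0 mm ID | standard pump extension line |
| manifold dead volume | mL | 0.5 | typical 3-gang manifold with its luer connections |
| 7 Fr catheter | — | 1.6 mm ID × 0.16 m | adult central line estimate |
| 1 Fr catheter | — | 0.3 mm ID × 0.30 m | neonatal PICC estimate |
| venous pressure | mbar | 0 (gauge) | patient-side dynamics not modelled |

Lumen diameters of the named catheters are not printed in any single
authoritative source; the catalog values are documented engineering
estimates, flagged as such in `inst/extdata/component_catalog.yaml`, and
only the qualitative contrast (1 Fr ≫ 7 Fr resistance) is load-bearing for
the thin-catheter regime. Every value can be overridden in a scenario file
or by constructing specs directly.

The built-in cases fix the illustrative flow rates 10 → 20 mL/h (step up),
20 → 10 mL/h (step down) for pump A against 1 mL/h on pump B: what the
cases demonstrate is the *shape* and *mechanism* of the transients, which
are insensitive to the exact magnitudes.

## Numerical choices

* **Integrator.** Implicit (backward) Euler on the linear pressure ODE.
  The thin-catheter case couples a small compliance to a very large
  resistance; the resulting stiffness makes explicit schemes impractical,
  while backward Euler is unconditionally stable and, the system being
  linear with piecewise-constant inputs, each schedule segment reuses one
  precomputed update matrix. The scheme is first-order; tests compare
  against closed-form responses at `dt = τ/100` with a 2 % band.
* **Automatic grid.** Unless given, `dt` is the smallest of: a twentieth of
  the fastest branch time constant $C(R+R_c)$, the time to advect half a
  slice at the largest scheduled total flow, and 1/200 of the duration
  (floored so a run never exceeds 2×10⁵ steps). The slice volume defaults
  to 1/200 of the shared volume (floor 10⁻⁵ mL), which resolves the
  push-out front to well under a percent of the dead volume.
* **Laminar convolution.** Volume grid of 1/512 of the shared volume
  (capped at 2×10⁵ points); the untruncated $u^{-3}$ tail is handled
  analytically by assigning its weight to the initial segment content, so
  no tail truncation error enters the composition. Fractions are clipped to
  $[0,1]$ and renormalized to sum to one, removing discretization slack of
  order the grid volume.
* **Degenerate inputs.** Zero total flow advances nothing and holds the
  last effluent composition; zero compliance switches a branch to its
  algebraic solution; zero dead volume is floored only by the catheter
  lumen volume; schedules shorter than the grid, negative set flows,
  non-positive geometry and junction imbalances all raise typed errors.
* **Event alignment.** Set-flow events are evaluated on the time grid
  (right-continuous step functions); a step from $t_k$ to $t_{k+1}$ is
  driven by the schedule at $t_{k+1}$, the implicit-Euler evaluation point,
  so reported set and actual flows refer to the same instant.

## What the scenario generator emulates — and what it does not

`generate_fixture()` draws 1–4 pump networks with flows in 0.5–15 mL/h,
dead volumes in 0.2–1 mL, compliances in 0.5–3 µL/mbar and one set-flow
step on pump A, all within the physical ranges of a paediatric/adult
multi-infusion setup, reproducibly per seed. Together with the built-in
cases it exercises every regime the model distinguishes: push-out-dominated
(wide catheter), compliance-dominated (thin catheter), backflow, and pure
plug limits with closed-form answers.

Passing these tests shows the *model* is solved correctly; it does not show
the model captures everything in real infusion lines. Not represented:
molecular and Taylor–Aris diffusion (fronts stay sharper than reality over
long lines), density- or viscosity-driven layering and mixing at the
junction (mixing is ideal and instantaneous at a zero-volume node),
pump-mechanism artefacts (stepper ripple, start-up backlash, alarm
behaviour), hydrostatic height changes, syringe-exchange pressure
transients, anti-siphon/non-return valves, and drug compatibility
chemistry. The venous pressure is a constant reference.

## Problem sizes

The built-in cases simulate 0.6–1.5 h of therapy at automatic time steps of
roughly 10⁻⁵–10⁻³ h (6×10³–5×10⁴ steps); each runs in seconds on one core.
These sizes were chosen because refining them further changes
delivered-dose curves by less than the documented first-order bounds (see
the grid-refinement test).

## Known limitations

* The decomposition is one of several defensible ablation orderings;
  component magnitudes (not their sum) depend on the order.
* First-order time stepping: sharp compliance transients are resolved to
  O(dt); choose an explicit `dt` well below $C(R+R_c)$ when the default
  grid is too coarse for a stiff, fast case.
* The laminar kernel assumes the shared segment is a single cylinder; a
  chain of very different lumens would disperse differently per segment.
* Backflow exceeding a branch line's volume is buffered with a warning
  (displacement toward the syringe), not modelled as reaching the syringe
  dead space.
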