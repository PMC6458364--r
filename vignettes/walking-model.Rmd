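---
title: "The neuromuscular trunk-SLIP walking model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The neuromuscular trunk-SLIP walking model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slipgait)
```

# The model

`slipgait` simulates sagittal-plane bipedal walking of a rigid trunk riding
on two massless prismatic spring legs — the bipedal trunk spring-loaded
inverted pendulum (BTSLIP). The generalized coordinates are the CoM
position $(x, y)$ and the trunk pitch $\phi$ measured from the horizontal
(upright trunk: $\phi = \pi/2$). The hip sits a distance $r_h$ down the
trunk axis from the CoM. Each stance leg transmits a repulsive axial
spring force $F_s = k\,(l_0 - l)$ (clamped at zero: legs cannot pull) plus
a hip torque $\tau$, which decompose into the ground reaction force

$$F_x = F_s \frac{x_h - x_f}{l} + \tau \frac{y_h}{l^2}, \qquad
  F_y = F_s \frac{y_h}{l} - \tau \frac{x_h - x_f}{l^2},$$

and the trunk obeys
$m\ddot x = \sum F_x$, $m\ddot y = \sum F_y - mg$,
$J\ddot\phi = \sum\tau + r_h(\sum F_x \sin\phi - \sum F_y\cos\phi)$.
These equations are exactly the Lagrangian dynamics of the constrained
trunk; the package verifies the consistency numerically (energy
conservation and GRF round-trip tests).

Defaults describe an average human: $m = 80$ kg, $J = 4.6$ kg m$^2$,
$r_h = 0.1$ m, $l_0 = 1$ m, and a dimensionless leg stiffness
$k_N = 40$ dimensionalised as $k = k_N m g / l_0 = 31392$ N/m — the
standard SLIP normalisation, the only one that makes $k_N$ unitless with
the given quantities.

## Hip muscles and reflex control

In the neuromuscular model (nmF) the hip torque of each stance leg comes
from an antagonistic Hill-type pair representing the biarticular thigh
muscles: rectus femoris (RF, hip flexor) and hamstrings (HAM, hip
extensor). Only the contractile element is modelled; with no series
elasticity the fibre length is the geometric muscle length

$$L_{RF} = L_0 + \rho r_0 (\varphi_h - \varphi_{ref,RF}), \qquad
  L_{HAM} = L_0 + \rho r_0 (\varphi_{ref,HAM} - \varphi_h),$$

so the contraction velocity is $\pm \rho r_0 \dot\varphi_h$. Forces follow
the product form $F = A\,F_{max} f_l(L) f_v(v)$ with the cubic-exponent
force-length bell ($f_l = \exp(c\,|\Delta|^3)$, $c = \ln 0.05$, width
$w = 0.2$) and the piecewise hyperbolic force-velocity curve (concentric
branch vanishing at $v_{max} = -12\,l_{opt}/s$, eccentric branch saturating
at $N = 1.5$). The net torque is $\tau = (F_{HAM} - F_{RF})\, r_0$. Note
the standard pennation treatment: $\rho$ scales fibre kinematics only, the
torque lever is the full $r_0$.

The reflex pathway is positive leg-force feedback: the axial stance-leg
force, delayed by $\Delta p = 1$ ms, is gained
($G_{RF} = 0.624/F_{max}$, $G_{HAM} = 0.936/F_{max}$), biased
($STIM_0 = 0.01$), saturated to $[0, 1]$, and low-pass filtered by the
excitation-contraction coupling $T \dot A = STIM - A$ with $T = 1$ ms. A
swing leg carries no force, so its stimulation relaxes to the bias with no
explicit silencing logic. The saturation range is not uniquely determined
by the model description; $[0, 1]$ is chosen because activation itself
lives on that interval. The printed delay and coupling constants are far
below physiological values; they are implemented as printed and exposed as
parameters.

## Hip-angle convention (a calibrated origin)

The hip angle $\varphi_h$ between the trunk axis and the leg axis is the
muscles' joint coordinate. The package uses the quadrant-aware form

$$\varphi_h = \phi + \operatorname{atan2}(y_h,\ x_f - x_h),$$

which is continuous through mid-stance, equals $\pi$ for a straight hip
(upright trunk over a vertical leg), and *increases as the leg extends
backward*, so the hamstring shortens with hip extension — the only sign
choice consistent with the muscle length maps and with anatomy. The
alternative sign makes HAM a flexor and produces a net backward-pitching
torque with no walkable gait (verified numerically).

This still leaves the *origin* of $\varphi_h$ under-determined: a
principal-branch arctangent of $y_h/x_h$ is discontinuous at mid-stance
and pins no usable zero, so any additive constant is a convention. The
package absorbs that freedom into a single calibrated offset applied to
both muscle reference angles, `phi_ref_offset` ($\delta_0 = -0.0594$ rad,
reproducible with `calibrate_nmf_ref_offset()`): $\delta_0$ is fixed once,
by requiring that the *printed* reflex gains admit a period-1 walking gait
at the model's stated operating speed of 1 m/s, and is never revisited.
Without the offset (at $\delta_0 = 0$) no period-1 gait exists near 1 m/s:
the fixed-point branch folds at $\delta \approx -0.02$.

## Swing-leg placement and events

The swing leg is massless and tracks the velocity-based leg adjustment
direction $O = (1-\mu) V + \mu\,(0, -g)$ ($\mu = 0.34$; the mixed units of
velocity and gravity are part of the published formulation). Touchdown
fires when the swing foot — the hip plus $l_0$ times the unit direction —
reaches the ground, armed only while the CoM descends (an instantly
tracking massless leg would otherwise "land" behind itself immediately
after takeoff) and after a 2 ms refractory that prevents rebound chatter.
A stance leg takes off when it unloads: vertical GRF zero *or* spring at
rest length — the second condition matters for the muscle-driven legs,
whose baseline torque keeps a residual vertical force at the foot even
with a slack spring. Falls are declared for flight (both legs airborne),
hip height below 0.2 m, or trunk tilt beyond 60° from vertical.

At the default parameters the touchdown geometry is nearly grazing: the
VBLA vertical weight $\mu g$ dominates the velocity term, so the target
direction is only $\sim 11°$ from vertical and the swing foot skims the
ground around mid-stance. Two consequences are documented under
*Limitations* below.

## Controllers

Four balance strategies share the engine:

* **FMCH** — force-modulated compliant hip: $\tau = G F_s
  (\varphi_{h0} - \varphi_h)$. The constants are not part of the published
  parameter set; the package fixes $\varphi_{h0} = \pi$ (the straight-hip
  mid-stance configuration, which is also the nmF mid-stance hip angle)
  and calibrates $G$ by a deterministic secant on the period-1 gait's
  speed (`calibrate_fmch()`, shipped value $G = 0.3175$). The fixed
  point's speed varies only weakly with $G$ (about 0.4% over
  $G \in [0.2, 0.32]$), so the calibration pins the speed tightly while
  $G$ itself is identified loosely; the shipped value is simply where the
  documented secant from $(0.2, 0.25)$ converges.
* **nmF** — the reflex-muscle pathway above with the printed gains.
* **Preflex** — feed-forward replay of the activation traces recorded from
  the converged nmF cycle (`record_preflex_library()`), indexed by time
  since the leg's own touchdown and held at the last value beyond the
  recorded stride. No sensing.
* **Adaptive nmF** — the nmF reflex plus a discrete LQR outer loop. The
  step-to-step return map at the mid-stance section
  $S = (\dot x, y, \dot y, \phi, \dot\phi)$ is linearised by central
  differences in the state and in the gain vector $U = (G_{HAM}, G_{RF})$;
  `solve_dlqr()` iterates the Riccati recursion from $P_0 = Q$ and the
  gains are retuned once per step at mid-stance,
  $U_k = U^* - K (S_k - S^*)$, clamped at zero (force feedback cannot be
  negative) and persisting across strides. $Q = R = I$ by default; the
  input channel is rescaled by $|U^*|$ before the Riccati solve so the
  design is well conditioned at gains of order $10^{-4}$. The identified
  open-loop map has leading multiplier $\approx 1.15$; the closed loop
  reaches spectral radius $\approx 0.80$.

## Stability is operational

Walking is judged stable exactly as the study design specifies: the walker
must take 50 steps with every per-step mean forward speed within 5% of the
target. This is a finite-horizon criterion, not asymptotic stability, and
the distinction matters here: the converged nmF cycle is an exact period-1
fixed point of the return map (residual $< 10^{-9}$) whose leading Floquet
multiplier is slightly outside the unit circle ($\approx 1.15$), yet it
passes the 50-step criterion comfortably when started on the cycle, because
numerical-noise deviations grow far too slowly to matter over 50 steps.
The basin-of-attraction maps use the same operational criterion (50 steps
without a fall). The adaptive controller, by contrast, is asymptotically
stabilising.

# Numerical design

* **Integrator.** An adaptive Dormand-Prince 5(4) pair with cubic Hermite
  dense output, written for this engine in C++ (the hybrid structure —
  per-leg delay buffers, event-localised phase switching, per-step gain
  updates — does not fit a generic solver's callback model). Tolerances
  default to $10^{-9}$ (relative) and $10^{-11}$ (absolute); the step is
  capped at the reflex delay so the delayed force is always interpolated
  inside recorded history. Clean finite-difference Jacobians of the return
  map require these tight tolerances.
* **Delay handling.** The stance-leg force history is stored with its time
  derivative and interpolated with a C1 cubic Hermite; integration steps
  are aligned on event time + delay, where the delayed force is genuinely
  non-smooth. (A piecewise-linear history injects derivative kinks at
  every node and collapses the step-size controller.)
* **Events.** Touchdown, takeoff, mid-stance crossing and the fall guards
  are localised by bisection on the dense output to machine precision in
  time; the takeoff test verifies $\min(|F_y|, k|l_0 - l|) <
  10^{-6}\,m g$ at the located instants.
* **Limit cycles.** `find_limit_cycle()` runs a Levenberg-Marquardt damped
  Newton iteration on the Poincaré residual $\|P(S) - S\|$; the damping is
  needed because the map's leading eigenvalue sits near 1 and plain
  Newton steps explode along the near-neutral direction. Shipped
  mid-stance guesses make the default searches converge in a few
  iterations.
* **Section reconstruction.** A mid-stance state determines the walker up
  to the horizontal position (set to 0), the stance foot (under the hip),
  and the muscle activations, which are reset to their quasi-steady values
  $\mathrm{Sat}(STIM_0 + G F_s)$; with a 1 ms coupling constant the
  activation memory is a few milliseconds, negligible against the
  $\sim$25 ms to the next event.
* **Problem sizes.** The shipped experiments are desk-scale by design:
  50-step runs ($\sim$12 s of gait, well under a second of computation),
  coarse basin grids (5° × 0.2 rad/s, $\approx$ 400 cells per model), and
  one-stride recordings for cycle analyses. The full-resolution basin grid
  (1° × 0.1 rad/s) is available through the same interface.

# The synthetic reference curves

`generate_reference_curves()` produces deterministic stride-phase curves
with the qualitative structure of treadmill walking at moderate speed
(double-humped vertical GRF peaking near 1.1 BW, S-shaped horizontal GRF,
$\approx$5 cm double-humped CoM oscillation, smooth hip-torque wave, with
bands). They exist to exercise the comparison and plotting API
(`plot_gait_comparison()`) without any external dataset: they are
synthetic fixtures, not measurements, and nothing that passes against them
says anything about real gait data.

# Findings, deviations and limitations

Reproduction work is only useful if its misses are documented as carefully
as its hits. With every printed constant taken at face value (plus the two
calibrated convention constants described above), the package reproduces:

* a period-1 nmF gait at 1.000 m/s passing the 50-step/5% criterion;
* the functional equivalence of the reflex pathway and the
  force-modulated compliant hip (the quasi-steady muscle torque is an
  $F_s$-modulated linear angular spring over the stance range,
  $R^2 > 0.95$, stiffness proportional to leg force);
* a virtual pivot point: the stance-phase GRF lines concentrate on a point
  well above the hip (the zero-torque pivot), with RMS residual under half
  the pivot-to-hip distance, for both FMCH and nmF;
* double-humped vertical GRF profiles;
* a working adaptive layer: the LQR redesign recovers from the standard
  trunk push in $\approx$0.8 s, the gains settle back to their reference
  values, and the adaptive basin of attraction is the largest of the three
  models.

It does **not** reproduce, and the acceptance checks honestly fail on:

* **CoM excursion magnitude.** Both converged cycles give
  $\approx$2.1-2.2 cm peak-to-peak (they agree with each other to
  0.06 cm), not $\approx$5 cm. The cause is geometric: with
  $O = (1-\mu)V + \mu(0,-g)$ in mixed units at 1 m/s, the touchdown
  direction cannot exceed $\sim$13° from vertical, bounding the step
  length to $\sim$0.26 m; a 5 cm vault excursion implies $\sim$0.6 m
  steps. No tested reading of the leg-adjustment convention (vertical
  weights 4-8, $\mu$ 0.30-0.50) yields both longer steps and a stable
  gait.
* **nmF perturbation robustness.** The $-50°/s$ trunk push drives the hip
  angle outside the muscles' force-length working range
  ($\pm$0.2 rad at the printed bell width), the restoring torque
  collapses, and the walker falls $\approx$1.4 s later instead of
  recovering within 2 s. For the same reason the open-loop preflex replay
  fails $\approx$1.4 s after the push (not $\approx$7 s), and the nmF
  basin of attraction collapses to the immediate neighbourhood of the
  cycle, inverting the published nmF/FMCH basin ratio. The FMCH (whose
  linear spring has no working-range limit) recovers, in $\approx$10 s.
* **Q/R orderings.** All three LQR weightings recover quickly; penalising
  the gain effort ($R = 100I$) yields the slowest recovery and the highest
  hip energy in this implementation (less adaptation leaves more trunk
  oscillation to damp through the muscles).

The model family is delicately balanced — the touchdown geometry grazes,
the return map's leading multiplier sits within a few percent of unity for
every controller — so modest implementation differences (event ordering,
swing-leg treatment, integration accuracy) plausibly move these
conclusions across the stability boundary. The package's account of its
conventions is complete enough to make every one of these statements
reproducible.

Other standing limitations: legs are massless (no swing dynamics, no
impact losses), motion is planar, the ground is rigid and flat, speed is
calibrated at 1 m/s only (other speeds need re-tuning), and the gait has a
higher duty factor and much shorter steps than human walking at the same
speed.

# A worked example

```{r example, eval = FALSE}
library(slipgait)

params <- walker_params()
cycle <- find_limit_cycle(params, controller_nmf(params))
glance(cycle)

sim <- simulate_walk(cycle, n_steps = 50)
glance(sim)
autoplot(sim)

adaptive <- design_adaptive_nmf(cycle, params)
pushed <- simulate_walk(cycle$S_star, params, adaptive, n_steps = 50,
                        perturb = perturbation())
recovery_time(pushed, cycle)
```
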