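---
title: "The fused compass-pendulum / spring-mass gait model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The fused compass-pendulum / spring-mass gait model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitfuse)
```

gaitfuse simulates the sagittal centre-of-gravity (CoG) trajectory of
human walking as a hybrid dynamical system, regularizes it with learned
heel paths, and recovers hip and knee flexion-extension angles by
inverse kinematics.  This vignette is the package's own account of the
model: the equations, the conventions and tunable parameters, the
numerical choices, what the synthetic data emulate, and where the model
stops being a faithful picture of real gait.

## The two phases of the centre-of-gravity model

A gait cycle runs from the heel strike of one foot to the next heel
strike of the same foot.  It alternates **single stance** (one foot on
the ground, about 80% of the cycle) and **double stance** (both feet on
the ground, about 20%, split into two episodes per cycle).

### Single stance: a compass pendulum

During single stance the body is a compass pendulum: a point hip mass
$M$ on a rigid stance leg of length $l_0$ pivoting about the contact,
plus a point foot mass $m = \beta M$ at the end of the swing leg.  With
$\theta$ the stance-leg angle from the slope normal (positive when the
hip is ahead of the contact) and $\phi$ the inter-leg angle
(stance to swing), the Euler-Lagrange equations in units of $M l_0^2$
are
$$
\begin{pmatrix} 1 + 2\beta(1-\cos\phi) & -\beta(1-\cos\phi)\\
                -\beta(1-\cos\phi)     & \beta \end{pmatrix}
\begin{pmatrix}\ddot\theta\\ \ddot\phi\end{pmatrix} =
\begin{pmatrix}
\beta\sin\phi\,\dot\phi(\dot\phi-2\dot\theta) +
  \tfrac{g}{l_0}\big[(1{+}\beta)\sin(\theta{+}\gamma) -
  \beta\sin(\theta{-}\phi{+}\gamma)\big]\\[2pt]
\beta\big[\tfrac{g}{l_0}\sin(\theta{-}\phi{+}\gamma) +
  \dot\theta^2\sin\phi\big]
\end{pmatrix}
$$
with $\gamma$ the ground slope.  The printed sources for this model are
typographically unreliable, so the implementation was re-derived from
the Lagrangian of the two point masses and validated by properties that
do not depend on typography: the returned accelerations satisfy both
equation residuals to $10^{-10}$, total mechanical energy drifts by less
than $10^{-6}$ relative along integrated arcs, and integration is
time-reversible to $10^{-6}$.  A frozen set of accelerations from an
independent computer-algebra derivation is kept in the test suite.

The system is linear in the accelerations, so each evaluation assembles
the $2\times 2$ mass matrix and solves it (`single_stance_derivatives()`);
a condition-number guard (default $10^{12}$) reports a singular mass
matrix, although for $\beta > 0$ the matrix is well conditioned
(condition number $\approx 1/\beta$).

**Heel strike.** The swing foot reaches the ground ahead of the contact
when $\phi - 2\theta$ crosses zero *from above* (the residual decreases
as the foot descends) while $\theta > \theta_{\min}$ (default 0.02 rad;
the legs also pass through the symmetric configuration near mid-swing,
which must not count).  `deSolve::lsodar` locates the crossing; invalid
crossings are stepped over and integration resumes.  Because a stance
phase *begins* on the event surface (the toe-off configuration is
symmetric, see below), the integrator first takes a tiny fourth-order
step off the surface.

### Double stance: a two-leg spring-mass system

From heel strike to toe-off the CoG of mass $M$ hangs on two leg
springs anchored at the trailing contact (origin) and the leading
contact $(d, 0)$:
$$ M\ddot x = \lambda_l x - \lambda_r (d - x), \qquad
   M\ddot y = (\lambda_l + \lambda_r)\, y - gM, $$
with force-per-unit-length coefficients
$$ \lambda_l = k\!\left(\frac{l_0}{\sqrt{x^2+y^2}} - 1\right), \qquad
   \lambda_r = k\!\left(\frac{l_0}{\sqrt{(d-x)^2+y^2}} - 1\right), $$
i.e. each leg pushes with force $k\,(l_0 - l)$ along its axis — the
standard bipedal spring-loaded-inverted-pendulum force law, positive in
compression.  The two legs can carry different stiffnesses
(`k_left`, `k_right`), which reproduces the asymmetric ground-reaction
profiles of disorders that affect one leg more than the other.  The
spring potential $\tfrac12 k (l - l_0)^2$ is available in closed form,
so energy conservation is testable here too.

For two coincident feet ($d = 0$) the vertical mode oscillates, in the
linear regime, with period $2\pi\sqrt{M/(2k)}$: the oscillating mass is
the body mass $M$ and the two parallel springs act as stiffness $2k$.
A frequently quoted shorthand for this period, $2\pi\sqrt{m/k}$, is
only consistent with the model if its $m$ is read as the mass carried
per spring; the package tests the mode against the mass actually
oscillating.

**Toe-off** ends double stance when the trailing leg returns to its
rest length — its force coefficient crosses zero from above, so the leg
takes off with exactly zero force, which is also the condition under
which the force is continuous into the swing phase.  Double stance
*starts* with the trailing leg exactly at rest length and the entry
velocity perpendicular to it (pendulum motion), so the radial rate is
zero at entry; the event guard requires a strictly positive radial rate
and the integrator again starts with a small step off the root surface.

### Units and the scale of k

The published stiffness values for the pathological presets span
$k \approx 52$–$500$.  No body mass makes these numbers support a
70 kg walker in the equations above; they are only coherent as
*mass-normalized* stiffnesses.  The package therefore integrates the
double-stance equations per unit body mass ($M = 1$) in every preset,
which renders all published $k$ values directly usable and makes the
dynamics scale-free.  Users who want dimensional forces can set `M`
and `k` jointly in `gait_params()`.

## Assembling cycles: hand-offs and their consequences

`simulate_gait()` alternates the two integrators.  The hand-offs are
where the modelling choices live:

* **Heel strike (pendulum → springs).**  The CoG position and velocity
  transfer exactly; the landing foot is placed at the configured
  inter-foot distance $d$.  The pendulum geometry implies a separation
  of $2 l_0 \sin\theta$; if that disagrees with $d$ by more than a
  tolerance (default 2 cm) the hand-off warns and projects onto the
  configured frame.  Note that $d$ is the distance from the landing
  *heel* to the trailing *toe-off point*, not the heel-to-heel step
  length (see rollover below).

* **Toe-off (springs → pendulum).**  At trailing-leg toe-off the
  leading leg still carries some compression, so no point at distance
  $l_0$ from the CoG coincides with the leading heel: a rigid-leg
  pendulum anchored at the heel would make the CoG jump.  The package
  instead relocates the pivot to the *ground point at distance $l_0$
  ahead of the CoG* — a heel-to-toe rollover, the sagittal analogue of
  the centre of pressure travelling along the foot.  The CoG is then
  exactly continuous (the continuity audit in the `events` table stays
  at machine precision), the pivot stays on the ground, and the
  realized step length (pivot to pivot) is slightly larger than $d$.
  `simulate_gait()` records this realized `step_length`; stride length
  is twice it and remains monotone in $d$, so short-stepped disease
  presets keep their ordering.  The new stance angle comes from the
  pivot-to-CoG orientation, the angular rate from the tangential CoG
  velocity, and the swing-leg state from the still-planted trailing
  contact by the chain rule.

Both hand-offs shed energy: the planted-foot impact discards the swing
foot's momentum (small, order $\beta$), and the toe-off discards the
elastic energy still stored in the leading spring.  A strictly level,
strictly periodic gait is therefore impossible; like any passive
walker, the model walks down a shallow slope that replenishes exactly
what the hand-offs dissipate.  Every preset carries a calibrated slope
between 0.02 and 0.05 rad.

### Presets and their calibration

`preset_params()` freezes one parameter set per gait class.  The
pathological classes use the published cohort values verbatim
(crouch $k = 400$, $d = 0.65$ m, leg shortened by 5% to 0.95 m;
generic Parkinsonian $k = 500$, $d = 0.58$ m; stage-wise Parkinson
$(k, d)$ = (52.3, 0.761), (67.42, 0.558), (96.8, 0.436)).  The normal
class has no published parameters; the package's choice is
$l_0 = 1$ m, $\beta = 0.01$, with $k = 104.43$, $d = 0.176$ m and
slope 0.0238 rad calibrated once so that the steady cycle spends 20.0%
of its time in double stance with the ipsilateral toe-off at 60.0% of
the cycle — the standard clinical phase timing.

Each preset's initial state is a *fixed point of the stride map* (the
map from one toe-off state to the next), found by Newton iteration or
by numerical continuation in $(k, d)$; stage 2, whose very soft spring
and long step make the map fragile, uses a state that survives four
strides, enough for a full cycle.  The stride-map fixed points are
unstable (leading multiplier $\approx 9$ for the normal preset), which
is typical of passive walking gaits on steeper slopes: simulations are
intended for a handful of cycles (2–4), and the periodicity checks
compare cycles 1 and 2, which agree to better than 0.1% RMS.  The
double-stance share of 20% is only attainable in a short-stride regime:
the swing leg is passive, its natural period pins the step duration
near a second, and faster or longer steps leave it unable to catch the
stance leg.  This is a genuine regime of the model, not of human
walking, and is the main caveat when reading the normal preset's
absolute step length.

Timing quantities are measured on the cycle after the first
(`normalize_to_cycle()` skips the transient cycle by default), on a
101-point 0–100% grid, the gait-analysis convention.

## Learned heel paths

`generate_synthetic_heel_data()` stands in for a gait-laboratory corpus
(default layout: 30 cycles from 10 subjects, 3 cycles each).  Per
cycle it produces a lab-frame heel trajectory: planted through stance
(0–60%), a physiological pre-swing heel rise (0.10–0.15 m), a swing
clearance arc, and a landing one stride ($2d$) ahead, built from
$C^2$ quintic smoothsteps.  Crouch gait gets reduced clearance and a
persistent forward offset (flexed posture); Parkinsonian classes get a
reduced, shuffling clearance and inherit their short step from the
preset $d$.  Subject-level offsets and smooth cycle-level noise
(half-sine harmonics, which vanish at both cycle ends so the stride is
preserved exactly) are layered on top, deterministically in the seed.
What the generator does *not* emulate: marker noise spectra, foot-angle
kinematics, inter-subject timing variability (all cycles share the
percent grid), and any coupling between heel path and CoG dynamics —
passing tests on this corpus shows the machinery works, not that it
reproduces any particular patient population.

`fit_heel_mixture()` represents the per-percent mean trajectory as a
weighted sum of Gaussian densities per coordinate,
$\psi(t) = \sum_{i=1}^{I} w_i\, N(t \mid \mu_i, \sigma_i^2)$, plus a
constant intercept.  The weights are signed basis coefficients — the
mixture models a coordinate trajectory, not a probability density, and
non-negative weights could not represent it.  By default the means sit
on a uniform grid over [0, 100] with a shared width equal to the grid
spacing and the weights come from linear least squares (reproducible
and well conditioned; the basis condition number is checked against
$10^{10}$); `refine = TRUE` releases means and widths to a
Levenberg-Marquardt refinement, which recovers an exactly-Gaussian
generating path to $10^{-6}$.  The default $I = 12$ fits the synthetic
corpora below their injected noise.  `sample_heel_variation()` perturbs
the weights by a relative Gaussian factor to produce within-class gait
variants; the perturbation is linear, so the ensemble mean is the mean
path.

## Inverse kinematics and the fusion rule

The leg is a two-link chain with equal thigh and shank lengths
$l_0/2$ (the knee sits midway along the leg).  For hip-to-heel distance
$c$ the knee flexion is the law-of-cosines angle
$\gamma = \arccos\!\big((c^2 - l_0^2/2)/(l_0^2/2)\big) \in [0, \pi]$,
$\gamma = 0$ fully straight; the hip flexion is the heel bearing from
vertical-down plus the interior correction
$\operatorname{atan2}(r\sin\gamma,\, r + r\cos\gamma)$, so forward
kinematics lands on the heel exactly (round-trip identity to
$10^{-12}$).  The knee bends backward (anatomical branch), chosen
globally rather than per sample, so angle series cannot flip branches
mid-cycle.  Targets beyond reach are clamped onto the reach sphere and
counted; `fuse_trajectories()` fails if more than 5% of samples clamp.

`fuse_trajectories()` evaluates the class heel path per percent sample
(the contralateral heel is the same path shifted by 50% of the cycle
and one step back), anchors the chain, and solves the analytic IK.
Two reconciliations make the fusion geometrically coherent:

* **Hip offset.**  The rigid-leg CoG rides at height $\approx l_0$; a
  chain anchored there cannot reach a planted heel through mid-stance.
  The chain is anchored at the hip, `hip_offset` below the CoG —
  0.10 $l_0$ for normal gait (the pelvis sits below the whole-body mass
  centre), deepened to 0.26 $l_0$ for crouch and 0.15–0.20 $l_0$ for
  the Parkinsonian classes, where the dropped or stooped pelvis is
  itself the clinical signature and directly produces the flexed-knee
  pattern.
* **Stride rescaling.**  The mixture stores the class heel *shape*; its
  forward sweep is rescaled affinely so the per-cycle heel displacement
  matches the simulated stride.  Any corpus therefore fuses with any
  simulated cycle, including ones whose realized step differs from the
  corpus' configured $d$.

The stage-2 Parkinson preset is the one exception: its surviving gait
vaults with a realized step beyond two-link reach, so fusion is not
geometrically possible there; its heel corpora and mixtures remain
usable for the similarity metrics.

`ccd_solve()` provides the same solution by cyclic coordinate descent:
the knee points the shank at the target, the hip rotates the whole
chain, each step an exact one-joint minimization, so the end-effector
error is non-increasing.  Two numerical facts matter.  First, the fully
straight chain is a coordinate-descent ridge: once the hip aligns a
straight chain with the target ray, the knee sees the target dead ahead
and clamps straight; the solver starts with a bent knee and, if it
still lands on the ridge, flexes the hip past the target bearing and
continues.  Second, convergence is linear with a rate that degrades
near the workspace singularities (targets close to the hip, or knee
flexion beyond $\approx 130^\circ$), so the default iteration cap is
generous (5000) and the solver reports non-convergence with its final
residual rather than returning silently.

## Similarity metrics

`compare_trajectories()` scores the five clinical channels (R.Hip,
R.Knee, L.Hip, L.Knee, CoG) with the Pearson correlation and the
**discrete** Fréchet distance — the minimum over monotone couplings of
the maximal coupled point distance, computed by the standard dynamic
program.  The discrete variant is the computable surrogate appropriate
for sampled series on the 101-point grid; the test suite checks it
against exhaustive coupling enumeration on short curves.  Angle
channels are embedded as angle-vs-percent planar curves with the
percent axis scaled to the channel's range (a plain 1-D value mode is
also available); the CoG is compared as a planar curve, with its
correlation averaged over the two coordinates.  The Hausdorff distance
is included for contrast: it ignores the direction of travel, so a
curve that backtracks can sit close to another as a point set while
being far in the Fréchet sense — both distances are computed from the
same exact pairwise distances, so the ordering
Fréchet $\ge$ Hausdorff holds to machine precision.

## Skeleton and interfaces

`build_pose()` assembles the 12-segment sagittal figure (pelvis, trunk,
two thighs, shanks, feet, upper arms, forearms) with anthropometric
lengths fixed as fractions of $l_0$; lower limbs by forward kinematics
from the fused angles, upper limbs from synthetic arm-swing templates
(`arm_swing_template()` — parametric curves, not patient data).
Connected segments share endpoints and lengths are constant across
frames to $10^{-9}$.  All results export to plain-text CSV/JSON with
documented schemas, and the `gaitfuse` command-line tool (a thin
wrapper over `cli_main()`) chains the whole pipeline:
`gen-fixtures → fit-heel → simulate → ik → evaluate → animate`.

## Known limitations

* Sagittal plane only; no feet with rollover *dynamics*, no ankle
  degree of freedom, no damping or ground compliance.
* The passive swing leg caps step length for the normal preset; the
  printed 20% double-stance share is reached at a stride shorter than
  a human's.
* Stride-map fixed points are unstable; the presets are certified for
  a handful of cycles, not for indefinite walking.
* The slope is a modelling device that balances the hand-off energy
  losses, not a claim about treadmill grade.
* Joint-angle magnitudes depend on the hip-offset convention; the
  package reports flexion positive in degrees for plots and CSV,
  radians internally.
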