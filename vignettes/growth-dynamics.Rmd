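---
title: "Modelling growth-driven movement of rod-like organs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling growth-driven movement of rod-like organs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`growrod` simulates slender organs — plant shoots, roots, tendrils, and
rod-like growing robots — that move *by growing*: one flank of the
cylindrical organ elongates faster than the other, so the organ bends. No
elastic forces are involved; the dynamics are purely kinematic consequences
of differential growth.

The organ is a cylinder of radius $R$ described by its centerline
$\vec r(s,t)$, parameterized by arc-length $s \in [0, L]$. Rather than the
Frenet-Serret triad $(\hat T, \hat N, \hat B)$ — whose normal is undefined
wherever the curvature vanishes, which is exactly the initial condition of
interest — the implementation carries a *natural* (Bishop) frame
$(\hat m_1, \hat m_2, \hat T)$, which never rotates about the tangent and is
well-defined on straight segments. Its evolution along the arc is generated
by two curvature components:

$$\partial_s \hat T = \kappa_1 \hat m_1 + \kappa_2 \hat m_2, \qquad
  \partial_s \hat m_i = -\kappa_i \hat T ,$$

from which the Frenet descriptors are recovered as
$\kappa = \sqrt{\kappa_1^2 + \kappa_2^2}$, $\phi = \arctan(\kappa_2/\kappa_1)$
(the angle of the normal in the cross-section) and the torsion
$\tau = \partial_s \phi$. Where $\kappa = 0$ the package reports $\phi$ and
$\tau$ as `NA` rather than an arbitrary value, since the normal does not
exist there.

**Growth.** Elongation is confined to a sub-apical growth zone of length
$L_{gz}$ with uniform relative growth rate $\dot E$. Material flows through
the zone with velocity $v(s) = \dot E\,(L_{gz} - (L - s))$ (zero in the
mature region, $\dot E L_{gz}$ at the tip), so Eulerian fields evolve by the
material derivative $D/Dt = \partial_t + v\,\partial_s$.

**Differential growth.** The curvature components obey

$$\frac{D\kappa_i}{Dt} = \frac{\dot E}{R}\, \vec\Delta \cdot \hat m_i ,$$

where $\vec\Delta$ is the differential growth vector, the additive sum of:

* **tropic terms** — a stimulus field $\vec I(\vec r) = I \hat n$ is sensed
  only through its component perpendicular to the tangent,
  $\vec I_\perp = \hat T \times (\vec I \times \hat T)$, of magnitude
  $I \sin\theta$; a sensitivity law $\lambda(I_\perp)$ (constant,
  Weber-Fechner $a + b\log(I/I_0)$, or Stevens $aI^b$) converts intensity to
  response;
* a **circumnutation oscillator**
  $\lambda_c(\cos\psi(t)\,\hat m_1 + \sin\psi(t)\,\hat m_2)$ with
  $\psi = \omega t$, an internal cue that rotates the bending direction and
  produces the circular tip movement used by climbing plants in search
  behavior;
* **proprioception** $-\gamma \kappa \hat N$, the organ's active tendency to
  straighten in proportion to its own curvature, required for stable
  posture. In natural-frame components this is simply
  $-\gamma(\kappa_1, \kappa_2)$, which is what the code evaluates — the
  undefined $\hat N$ at $\kappa = 0$ never needs to be touched.

With *apical sensing* the response is evaluated at the tip only and its
cross-sectional components $(\vec\lambda \cdot \hat m_1(L),
\vec\lambda \cdot \hat m_2(L))$ are broadcast to every cross-section. The
transport is component-wise through the natural frames; on a straight organ
it reduces to the identity, so apical and local sensing coincide there —
`test-stimuli.R` checks exactly this.

**Sign convention.** The response vector carries the conventional minus
sign, $\vec\lambda = -\lambda(I_\perp)\hat n_\perp$; `response_vector()`
implements that literally, and the attract/repel choice is owned by each
`tropic_term(sign = ±1)`. The scenario builders use a linear Stevens law on
a unit-magnitude field, which makes the evaluated term equal
$\pm\lambda_0 \hat n$ projected onto the cross-section — the exact form the
scenario equations are written in. Each formula is thereby implemented once,
with no duplicated special cases.

## Numerical scheme

The organ is divided into $N$ segments of length $ds$; the frame of segment
$n$ is attached at its base-side endpoint and positions are the cumulative
sum $\vec r(n) = \sum_{k \le n} \hat T(k)\,ds$. Consecutive frames are
related by the rotation $\exp(U\,ds)$ of the skew Darboux matrix $U$,
evaluated in closed form by Rodrigues' formula (with a series branch below
$\kappa\,ds < 10^{-6}$ and the identity at $\kappa = 0$). Because each
update is an exact rotation, frames stay orthonormal to rounding error for
arbitrarily many steps — the suite asserts $< 10^{-9}$ deviation over full
runs. The sequential accumulation of rotations is the only O(N)-per-step
loop that cannot be vectorized, and is implemented in C++.

Curvature components advance by an explicit first-order step with *upwind*
(backward) spatial differences for the advection term — the stable choice,
since the growth flow always moves material tipward ($v \ge 0$):

$$\kappa_i(n, m+1) = \kappa_i(n, m) + dt\left[\frac{\dot E}{R}\Delta_i(n,m)
  - v(n,m)\,\frac{\kappa_i(n,m) - \kappa_i(n-1,m)}{ds}\right].$$

The base is clamped ($\kappa_i(0, \cdot) = 0$) and one new segment is
appended at the tip per step, inheriting its predecessor's curvature (the
result of initializing it curvature-free one step earlier with tip velocity
and no differential growth). Requiring exactly one segment per step while
the tip advances at $\dot E L_{gz}$ fixes the grid relation

$$ds = L_{gz}\,\dot E\,dt ,$$

which `sim_config()` enforces as a hard constraint (violations are rejected
with the three offending values, never silently adjusted).

**Stability.** The explicit step is subject to two limits: the advection
CFL number $v\,dt/ds$ equals 1 exactly at the tip (marginal, and exactly the
regime the tip-segment rule is built for), and the proprioceptive relaxation
requires $\gamma < R/(\dot E\, dt)$ (= 10 at defaults). Outside these the
curvature field diverges; `grow_sim()` detects non-finite curvature and
aborts with a diagnostic rather than returning garbage.

## Parameters

All quantities are dimensionless model units. Defaults:

| parameter | default | meaning |
|---|---|---|
| `R` | 0.1 | organ radius; sets the lever arm of differential growth |
| `gamma` | 0.01 | proprioceptive sensitivity (length units) |
| `lambda0` | 0.1 | primary tropic / circumnutation sensitivity |
| `lambda1` | 0.05 | secondary sensitivity (line term, superposed oscillator) |
| `Lgz` | 1.0 | growth-zone length |
| `L0` | 1.0 | initial organ length (straight, vertical) |
| `dt` | 0.1 | time step |
| `ds` | 0.01 | segment length, `= Lgz * growth_rate * dt` |
| `growth_rate` | 0.1 | relative elongation rate in the growth zone |
| `omega` | `0.2/dt` | circumnutation angular frequency |

These are the reference conditions for the whole test suite. They give
balance numbers $B = \lambda L_{gz} / \gamma$ of 10 (at $\lambda_0$) and 5
(at $\lambda_1$), within the range observed in real plants, and a predicted
steady-state curvature $\kappa_{max} = \lambda_0/\gamma = 10$, so
$\kappa R \le 1$ throughout — consistent with the low-curvature
linearization the model rests on.

The stimulus geometries the scenario builders default to are our choice (the
reference parameter set fixes only the physical scalars): the distant
stimulus points along $\hat x$, perpendicular to the initial vertical organ;
the point source sits at $(1.5, 0, 1.5)$, off-axis and within a few organ
lengths so the near-field geometry matters; the line stimulus is vertical
through $(0.3, 0, 0)$, a support one organ-third away.

## Scenarios

`build_scenario()` translates a configuration into differential-growth
terms:

* `distant` — $\vec\Delta = \lambda_0\hat n - \gamma\kappa\hat N$;
* `point` — $\vec\Delta = \lambda_0 \frac{\vec r_p - \vec r}{|\vec r_p -
  \vec r|} - \gamma\kappa\hat N$;
* `line_twine` — $\vec\Delta = \lambda_0\hat z - \lambda_1\hat\rho -
  \gamma\kappa\hat N$, with $\vec\rho$ the shortest displacement from the
  line: attraction to a support plus an axial cue;
* `circumnutation` — the oscillator term alone;
* `superposition` — distant stimulus plus oscillator.

A geometric point worth knowing: when the organ's initial plane contains
the stimulus (as it does for the default `distant` and `line_twine`
geometries), every term of $\vec\Delta$ lies in that plane and the dynamics
remain exactly planar — $\kappa_2$ and the out-of-plane coordinate stay at
machine zero, which the suite asserts at $10^{-10}$ over 1000 steps.
Genuinely three-dimensional trajectories require a symmetry-breaking
ingredient: the circumnutation oscillator, apical geometry off the plane,
or a non-planar initial state.

## Validation strategy

Two independent integrators back the 3D scheme:

* **Planar reduction.** For in-plane constant stimuli the model reduces to
  a 1D angle/curvature equation,
  $D\kappa/Dt = (\dot E/R)(-\lambda\sin\theta - \gamma\kappa)$ with
  $\partial_s\theta = \kappa$. `ace_oracle_2d()` integrates it on the same
  grid using only scalar arithmetic on the angle field — no shared geometry
  code — and the 3D run's $\kappa_1$ field must agree to $10^{-8}$
  (`test-acceptance.R`; the agreement is in fact near machine precision,
  so any regression in the curvature update or frame propagation trips this
  first).
* **Accretive-growth comparison.** `bressan_oracle_2d()` integrates the
  related model in which material is deposited at the tip and older material
  stiffens as $e^{-\eta(t-s)}$ instead of carrying an explicit growth zone
  and proprioception. It is used qualitatively: at the tip the instantaneous
  response matches the no-proprioception limit of the planar model, and
  large $\eta$ confines the response to the newest material.

The steady-state prediction $\kappa_{max} = \lambda_0/\gamma$ is checked by
running the distant-stimulus scenario to the steady-state criterion
(max $|\dot\kappa| < 10^{-6}$ for 50 consecutive steps, reached after
roughly 12,000 steps at defaults) and comparing within 5%; the simulated
value lands within $10^{-5}$ relative of 10. The damped-oscillation regime
at $B = 10$ is asserted via the tip-tangent overshoot, and the
circumnutation revolution period is measured by unwrapping the tip-tangent
azimuth and averaging over the settled part of a 1000-step run (the
instantaneous rate breathes by a few percent around $\omega$ as the organ
elongates, so a many-revolution mean is the robust estimator; it lands
within $10^{-2}$ time units of $2\pi/\omega$, against a tolerance of one
time step).

Problem sizes used by the suite — organs of 100–300 segments for unit
tests, 500–1000-step runs for the planarity/oracle/period checks, and the
single ~12,000-step steady-state run — were chosen as the smallest sizes
that exercise the respective regimes (several convergence times, several
tens of revolutions).

## Optimal tip steering (2D)

The control module treats tropic alignment as a control problem on a
fixed-length planar organ: the tip tangent $\hat T(L,t)$ is steered by a
control $\vec u(t)$ acting as $d\hat T(s)/dt = s\,\vec u(t)$ (apical
sensing), restricted to the admissible half-plane
$\hat n \cdot \vec u \ge 0$ (controls pushing away from the stimulus cause
curling). Among the cost-optimal family — controls perpendicular to the tip
tangent, which preserve the arc-length parameterization and zero the cost
$\int (\hat T(L)\cdot\vec u)^2 dt$ — the implemented member is
$\vec u^* = \beta\,\hat T^\perp(L)(\hat n \cdot \hat T^\perp(L))$.

Two numerical choices matter here. First, the vector form does not preserve
$\|\hat T\| = 1$ under explicit stepping, so the integrator works in the
angle variable: $\partial_t \theta(s) = -s\,\beta\sin\theta(L)$, which keeps
tangents exactly unit-norm; the vector form is retained only for cost and
admissibility evaluation. Second, $\beta$ has no canonical value — the
dynamics are identified with the apical-sensing angle equation
$\partial_t\partial_s\theta = -\sin\theta(L)$ at $\beta = 1$, which the
package adopts as the default and cross-checks against a second,
independent discretization of that equation (`apical_dynamics_theta()`,
agreement to $10^{-8}$). The tip angle then decreases strictly
monotonically to alignment from any $\theta_0 \in (0, \pi)$ with no
oscillation (the Lyapunov distance $\|\hat T(L)-\hat n\|$ decreases at
every step), in contrast to the damped overshoot of the distributed
proprioceptive model at high $B$.

## What the synthetic conditions do and do not show

Everything the package simulates is generated internally — straight initial
organs, analytically constructed curved states, and idealized stimulus
fields. Passing tests therefore demonstrate the *mathematical* fidelity of
the scheme (conservation of frame orthonormality, exact planar reduction,
correct steady states and periods), not agreement with any particular
plant: real organs have heterogeneous growth profiles, sensing delays,
elastic sagging under gravity, and stimulus fields with shadowing and
occlusion, none of which are modelled. In particular:

* there is no elasticity — no forces or torques, so heavy organs that sag
  or supports that deflect are outside scope;
* self-contact is not detected; the organ will grow through itself and
  through the line stimulus (twining here is attraction-based, not
  touch-based — the organ does not grip the support);
* no branching; a single centerline only;
* the explicit first-order scheme was chosen for exactness of comparison
  with the planar reduction, not efficiency; halving `dt` requires halving
  `ds` through the grid relation;
* the proprioceptive stability limit $\gamma < R/(\dot E\,dt)$ is a
  property of the explicit discretization, not of the continuous model.

## Reproducing a run

```{r example}
library(growrod)

cfg <- sim_config("distant", n_steps = 2000, record_every = 100,
                  stop_on_steady = TRUE)
traj <- grow_sim(cfg)
summary(traj)
plot(traj)

# persist and reload losslessly
write_trajectory(traj, "run.csv")
df <- read_trajectory("run.csv")
```

Every trajectory CSV is accompanied by a JSON manifest holding the fully
resolved configuration; rebuilding a `sim_config()` from the manifest and
re-running reproduces the trajectory bit-identically (runs contain no
randomness).
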