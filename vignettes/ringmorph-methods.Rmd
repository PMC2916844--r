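---
title: "Correlated ring maps in a continuous attractor network: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlated ring maps in a continuous attractor network: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringmorph)
```

## The model

`ringmorph` studies a recurrent network of threshold-linear rate units that
stores **two ring maps** — two assignments of circular coordinates to the
same neurons — or a morph sequence interpolating between two uncorrelated
maps. In the place-coding reading, the two maps are two similar circular
environments, and a localized packet of activity ("bump") represents the
animal's position in the active environment.

Each neuron carries a middle-map angle $\psi \sim U[0, 2\pi)$ and a distance
coordinate $\phi \sim U[-\pi/2, \pi/2]$, from which its angles on the two
stored maps are

$$\theta_A = \psi + d\,\phi, \qquad \theta_B = \psi - d\,\phi,$$

with $d \in [0,1]$ the **map distance**: $d=0$ gives identical maps, $d=1$
uncorrelated ones, and the two angles never differ by more than $d\pi$ along
the shortest arc. The synaptic kernel is the superposition of one cosine
ring kernel per stored map minus a uniform inhibition,

$$J(i,j) = \frac{1}{N}\Big[J_{\mathrm{mod}}\big(\cos(\theta_A^i-\theta_A^j)
  + \cos(\theta_B^i-\theta_B^j)\big) - J_{\mathrm{inh}}\Big],$$

and the rates obey $\tau \dot m_i = -m_i + [\,\textstyle\sum_j J_{ij} m_j +
I_i\,]_+$ with a threshold-linear transfer function and external input
$I_i = I_0\,(1 + \varepsilon \cos(\theta_M^i - \xi))$, tuned to location
$\xi$ on a selected map $M$ (map A, map B, or any intermediate morph map).

## The exact five-variable reduction

Because the kernel contains only first circular harmonics, the recurrent
current at any point of the neural manifold depends on the activity only
through **five real numbers**: the mean activity $m_0$ and the complex first
harmonics $z_A = \langle m\,e^{i\theta_A}\rangle$,
$z_B = \langle m\,e^{i\theta_B}\rangle$. The dynamics of these moments
closes *exactly* — no truncation is involved — and the package integrates
the moment equations directly. The familiar order parameters are an
invertible reparametrisation of the moments:

* `amp` — amplitude of the activity profile in units of $I_0$ (hence
  invariant under rescaling the uniform input);
* `size` — the angular half-width $\delta$ of the active region, with
  threshold $\cos\delta$ (extended monotonically beyond $[0, \pi]$ so that
  sub-threshold and fully-active states remain representable);
* `mu` — map preference in $[-1, 1]$; $\pm 1$ is a bump living purely in
  one map;
* `psi0` — the bump angle on the middle map (marginal: the attractor
  direction);
* `x_phi` — the bump offset along the distance coordinate.

The steady profile is
$m(\psi,\phi) = I_0\,\mathrm{amp}\,[\cos(\psi-\psi_0)\cos(d(\phi-x_\phi))
 - \mu \sin(\psi-\psi_0)\sin(d(\phi-x_\phi)) - \cos\delta]_+$.

A point worth flagging because it matters for estimation: the profile's
$\mu$ parametrises the *current*, so the harmonic imbalance of the
*activity* equals $\mu$ only at self-consistent fixed points. The
order-parameter estimator (`estimate_order_params()`) therefore inverts the
full moment map of the profile family (a two-dimensional solve in
$(\delta, \mu)$) rather than reading $\mu$ off the raw imbalance; this is
what makes recovery from an arbitrary member of the profile family
consistent as $N$ grows.

### Numerical evaluation of the right-hand sides

The angular moments of the rectified current can be done in closed form for
each value of $\phi$ (integrals of $[\rho\cos x + b]_+$ times $1$ or
$e^{ix}$ over the circle), leaving a one-dimensional trapezoidal quadrature
over $\phi$ (default 257 nodes). This "reduced" path is exact in the angle
and is the default. A brute-force two-dimensional trapezoid on a product
grid (default $256 \times 129$) is retained as the reference path; the test
suite checks the two against each other and checks convergence under grid
refinement. The translation mode of the bump along $\phi$ is exactly
marginal in the continuum; under the trapezoid it carries an
$O(n_\phi^{-2})$ spurious eigenvalue, which is why the stability module
identifies marginal modes structurally (by overlap with the symmetry
generators) rather than by a machine-zero test.

Deterministic integration uses an adaptive Dormand–Prince RK4(5) pair with
tolerances $10^{-8}/10^{-6}$. Noisy runs use the current-based formulation
and fixed-step Euler–Maruyama with $\mathrm{d}t = \tau/100$; noise enters
as independent white input currents (per neuron in the network simulator,
per grid node in the mean-field field mode) and never drives the reduced
deterministic equations directly. Amplitude divergence is detected with a
sentinel (`amp` $> 10^6$) and reported as an event rather than an error:
the unstable regime is characterised analytically, so runtime detection
only needs a robust flag.

## Phase diagram

With the bump gauge $\psi_0 = 0$, the fixed-point shape $(\delta, \mu)$
solves two scalar equations (total modulation and map preference), after
which the amplitude is $1/(J_{\mathrm{inh}} M - \cos\delta)$ with $M$ the
mean of the rescaled profile. Four boundaries organise the
$(J_{\mathrm{mod}}, d)$ plane:

* **Turing boundary** $J_c(d) = 2/(1 + \mathrm{sinc}(\pi d))$: the uniform
  state destabilises into a bump. At $d=0$ it reduces to the classical
  single-ring threshold; the same expression follows from inserting the
  maximal bump size $\delta = \pi$ into the shape equation.
* **Amplitude boundary** $J_{\mathrm{inh}}^c = \cos\delta / M$: below this
  inhibition the amplitude diverges. In the homogeneous limit
  ($\delta = \pi$) the critical value is exactly $-1$.
* **Double-ring onset**: expanding the map-preference equation to first
  order in $\mu$ gives a gain integral; the $\mu \neq 0$ pair of branches
  exists where the gain exceeds one. This happens only in a pocket of high
  $d$ (weak correlation) and weak coupling; at the morph-equivalent
  distance $1/\sqrt3$ it never happens.
* **Cylinder onset**: the bump support along $\phi$ fits strictly inside
  the admissible interval when $\delta < d\pi/2$ (activity exactly zero at
  $\phi = \pm\pi/2$ at the boundary), freeing `x_phi` as a second marginal
  direction. Since $\delta$ decreases with coupling, the cylinder occupies
  strong coupling for every $d > 0$.

Classification tolerances: $|\mu| > 10^{-3}$ calls a double ring; the
cylinder marginality probe requires a drift below $10^{-6}$ per unit time.
At $d = 0$, where the preference is formally undefined, $\mu$ is reported
as 0 by convention.

## Stability

The homogeneous state has exactly two independent conditions — the uniform
(amplitude) mode at rate $-(1+J_{\mathrm{inh}})/\tau$ and the Turing mode
at $(-1 + J_{\mathrm{mod}}(1+\mathrm{sinc}(\pi d))/2)/\tau$ — verified in
the tests against a dense discretized-operator eigenvalue oracle. For
localized states the package linearizes the moment dynamics numerically
(central differences on the semi-analytic right-hand side). The analytic
linearization matrices are not carried separately: the numerical Jacobian
*is* the primary path, cross-checked against differencing the
grid-quadrature right-hand side. Zero modes from the continuous symmetries
are projected out of the stability verdict — marginality is structural,
not an instability.

## Protocols and their parameter choices

All published constants of the source experiments that matter here
(stimulus velocities, durations, input fractions, network sizes) were not
recoverable from the available text, so the package fixes its own defaults
once, chosen by the model's geometry, and keeps them in
`regime_presets()`:

* **Time constant** $\tau = 10$ (read: milliseconds); all durations are in
  the same unit.
* **Pattern separation** (`cylinder` preset: $d=0.8$,
  $J_{\mathrm{mod}}=50$, $J_{\mathrm{inh}}=80$, $\varepsilon=0.3$): clean
  separation needs a bump that is small compared to the admissible range
  of the distance coordinate (support half-width $\delta/d$ well below
  $\pi/4$ plus margin), which demands strong coupling, and an input slow
  and strong enough that the bump crawls steadily rather than being
  lapped (one revolution per 4 s at $\varepsilon = 0.3$).
* **Shortest-path task** (`cylinder_task` preset: $d=0.5$,
  $J_{\mathrm{mod}}=22$, $J_{\mathrm{inh}}=40$, $\varepsilon=0.2$): the
  bump offset moves by about $\Delta\theta/(2d)$ when the bump travels an
  arc $\Delta\theta$, so the offset flip threshold from a saturated state
  is roughly twice $d$ times the admissible half-range. The task needs
  that threshold below the smallest graded stimulus step ($\pi/8$), i.e. a
  bump that nearly fills the distance coordinate — the opposite geometry
  from pattern separation, which is why the two protocols get different
  presets. Stimulus/delay/stimulus durations default to 800 ms each,
  enough for the bump to complete its travel between presentations.
* **Slow morph**: 20 s morph duration, the input location sweeping one
  full circle over the morph, $\varepsilon = 0.1$. The run starts from
  the state reached under environment-A stimulation with the same input
  trajectory continued seamlessly backwards in time (equal location and
  velocity at the junction) — a velocity discontinuity at morph onset
  would otherwise kick the bump offset in a phase-dependent direction.
  The readout is the map-preference trace (double ring) or the
  bump-offset trace (cylinder), plus instantaneous Pearson correlations
  with reference runs driven by the identical input trajectory in the
  fixed environments (same seed stream, so noise realizations cancel
  where possible).
* A neuron is "silent in map M" when its peak averaged response is below
  1% of the population peak; the undecided band of the task readout is 5%
  of the admissible offset half-range. Both are configurable.

The sign convention for the memory effect in this implementation: with the
input on map A, CCW travel of the bump drives `x_phi` positive. The
package asserts the symmetry relations (map swap flips the sign, velocity
reversal flips it, doing both restores it) rather than any absolute sign.

## Morph sequences

A neuron at morph index $t$ sits at $\psi + (1-2t)d\phi$ — the linear
interpolation along the shortest arc between its two reference angles.
Storing the whole continuum of morph maps between two *uncorrelated*
references yields the kernel $2J_{\mathrm{mod}}\cos(\Delta\psi)\,
\mathrm{sinc}(\Delta\phi) - J_{\mathrm{inh}}$ (exact integral over the
morph index); matching the quadratic term of the sinc factor against a
two-map kernel gives the equivalent distance $d_{\mathrm{eq}} = 1/\sqrt3
\approx 0.577$, exposed as `MORPH_EQUIV_D`. The `full_morph` mode of the
slow-morph protocol stores a finite number of maps (default 25) in the
finite-size simulator; `morph_equiv` uses the two-map surrogate in the
mean field.

## The finite-size simulator

`build_coupling()` assembles the $1/N$-normalised coupling either as a
dense matrix or as an implicit low-rank product through the per-map
population harmonics. The two are the same operator to floating-point
precision — the kernel family is exactly low-rank — so the implicit route
is used for large $N$ and scans, and the dense route is kept as the
brute-force reference. Mean-field limits are approached as $N$ grows; the
map-preference estimate is the most sensitive to finite size (its
ensemble scatter dominates the Fig-9-style comparisons), which the test
suite asserts as a variance ordering rather than a tight tolerance.

## What the tests do and do not establish

The validation suite is property-based: exact closure of the reduction,
agreement of closed-form boundaries with brute-force detection, mean-field
vs microscopic agreement within ensemble scatter, the pattern-separation
overlaps, the chained-task accuracy profile, and the ordering of
slow-morph transition times. The generator of synthetic networks draws
labels i.i.d. uniform — it does not emulate place-field irregularities,
heterogeneous peak rates, context-selective neurons, spiking, or synaptic
plasticity, and segment (non-circular) manifolds are only reachable
through the documented extension point. A green suite therefore
establishes the attractor-level phenomenology of the stated model, not a
fit to any recorded data.

## Known limitations

* Near $d = 1$ the cylinder degenerates toward a torus and the finite-size
  bump can settle at large offsets selected by quenched disorder; the
  estimator stays finite there but mean-field comparisons of the offset
  are not meaningful.
* The fixed-point solver is a damped Newton iteration on the two shape
  equations; far outside the physical region it is not guaranteed to
  converge and reports its residual.
* Very weak tuned inputs rotate the bump slowly; tuning-curve estimation
  scales its settling time as $1/\varepsilon$ and becomes expensive below
  $\varepsilon \approx 0.02$.
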