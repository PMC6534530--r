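---
title: "Anisotropic particle dynamics for fingerprint ridge patterns: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anisotropic particle dynamics for fingerprint ridge patterns: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ridgesim)
```

## The model

Fingerprint ridges are laid down before birth when Merkel cells rearrange
from a random configuration into parallel lines that follow the directions
of smallest compressive stress in the epidermis. `ridgesim` models this
second phase of development as a first-order interacting particle system on
the unit torus $\mathbb{T}^2 = [0,1)^2$:

$$\frac{dx_j}{dt} = \frac{1}{N} \sum_{k \ne j} F\!\left(x_j - x_k,\, T(x_j)\right),
\qquad j = 1, \dots, N,$$

where displacements $d = x_j - x_k$ are taken in the minimum-image sense
(componentwise in $[-0.5, 0.5)$). The anisotropy enters through a stress
tensor field $T(x) = \chi\, s(x) s(x)^T + l(x) l(x)^T$ with $\chi \in [0,1]$:
$s(x)$ is the unit direction of smallest stress (a *line* field, defined
only up to sign), $l(x)$ its perpendicular. The pair force is resolved in
this local frame,

$$F(d, T(x_j)) = f_s(|d|)\,(s \cdot d)\, s \;+\; f_l(|d|)\,(l \cdot d)\, l,$$

so the coefficient $f_s$ acts along the ridge direction and $f_l$ across
it. Particles align along $s$ when $f_s$ is purely repulsive while $f_l$ is
short-range repulsive and medium-range attractive: repulsion along the
ridge spreads cells into lines, cross-ridge attraction collects them onto
discrete ridges.

### Force families

Five coefficient families are provided (`force_preset()`):

* **kc2012** — the classical quadratic-exponential pair
  $f_R(r) = (\alpha r^2 + \beta)e^{-e_R r}$,
  $f_A(r) = -\gamma r e^{-e_A r}$, combined as
  $f_s = \chi f_A + f_R$, $f_l = f_A + f_R$, with
  $\alpha = 270$, $\beta = 0.1$, $\gamma = 35$, $e_A = 95$, $e_R = 100$,
  $\chi = 0.2$. With these constants the cross-ridge attraction is so
  strong that complex patterns coarsen into few lines over time.
* **kc-adapted** — the same constants, with the attraction along $l$
  damped to $0.3 f_A$, which stops the coarsening and stabilizes
  multi-ridge patterns.
* **kc-reparam** — the equivalent reparameterization folding the damping
  into the amplitude, $\gamma = 0.3 \times 35 = 10.5$; with it $f_l$ is
  repulsive below $r \approx 0.012$, attractive on
  $r \approx (0.012, 0.045)$ and weakly repulsive beyond.
* **piecewise** — kc2012 constants with the long-range tail of $f_l$
  flipped in sign between two cutoffs $c_1 = 0.06 < c_2 = 0.07$ (linear
  interpolation in between keeps the coefficient continuous), producing a
  weak long-range attraction so the model tolerates range rescaling with
  $\eta > 1$.
* **oscillator2014** — damped-harmonic-oscillator ansatz
  $f_s(r) = c e^{e_{s1} r} + c_s \sin(\pi r/a_s) e^{e_{s2} r}$,
  $f_l(r) = c \cos(\pi r/a_l) e^{e_{l1} r} + c_l \sin(\pi r/a_l) e^{e_{l2} r}$
  with $c = 0.1$, $c_s = -0.05$, $e_{s1} = -65$, $e_{s2} = -100$,
  $a_s = 0.03$, $c_l = 0.005$, $e_{l1} = -160$, $e_{l2} = -40$,
  $a_l = 0.022$ — a closed-form alternative to the piecewise family with
  the same short-repulsive / medium-attractive / weakly-varying structure.

All families carry a hard cutoff: the force is identically zero for
$\eta|d| \ge R_c$ (default $R_c = 0.5$, the largest separation the torus
allows). The cutoff is *closed* at $R_c$ — this exact convention is what
makes the equidistant-line steady state exact (see below) — and is a hard
truncation, not a smooth taper. For a cutoff of 0.1 the jump this leaves in
the kc2012 coefficients is $f_s(0.1^-) \approx 7.5\times 10^{-5}$ and
$f_l(0.1^-) \approx -1.3\times 10^{-4}$, several orders below the
short-range values the dynamics are driven by.

The factor `delta_scale` ($\delta$) multiplies the attraction coefficient
in **both** frame components, i.e. the total force is
$F = \delta F_A + F_R$. With $\chi = 1$ this is a radially symmetric
model, which is exactly the configuration of the attraction-strength sweep:
$\delta = 0.1$ leaves a nearly pure repulsion that spreads a small initial
circle over the whole domain, while $\delta \ge 0.5$ collapses it onto a
single thin ring. (An alternative reading would scale only the $l$
component; it breaks the radial symmetry that the sweep relies on, so the
radially symmetric form is used.)

### Rescaling the ridge distance

Replacing $F(d, T)$ by $F(\eta d, T)$ shrinks the effective interaction
range to $R_c/\eta$. Since the stationary ridge spacing is set by the range
of $f_l$, larger $\eta$ produces more, closer ridges and $\eta < 1$ fewer,
wider-spaced ones. The literal reading — coefficients evaluated at
$\eta|d|$ *and* projections of $\eta d$, hence one extra factor of $\eta$
in the magnitude — is the default in `pair_force()`.

## Steady states

On a homogeneous vertical field ($s = (0,1)$), $n$ parallel equidistant
vertical lines of spacing $1/n$, each carrying $N/n$ equally spaced
particles, are an exact steady state for every force family
(`line_configuration()`, `verify_proposition1()`). The proof structure is
visible in the numerics: contributions cancel pairwise by the antisymmetry
$F(d) = -F(-d)$, and the lone unpaired partner (present when $N/n$ or $n$
is even) sits at torus distance exactly $0.5$, where the closed cutoff
makes the force vanish. The package verifies residuals below $10^{-10}$
(typically $10^{-14}$ or better; the residual is reported as the
*unnormalized* force sum so tolerances do not depend on $N$). Parallel but
**non**-equidistant lines are not steady: an arrangement with spacings
$(0.05, 0.35, 0.2, 0.2, 0.2)$ leaves a residual above $10^{-6}$.

## Orientation fields

Analytic fields are built from the two singular-point types of fingerprint
orientation fields. In complex coordinates $z$, a **delta** at $\zeta$ is
the line field solving $(z-\zeta)\,dz^2 > 0$, giving
$\theta(x) = -\arg(x-\zeta)/2 \bmod \pi$ (three straight ridges meeting at
$2\pi/3$); a **core** solves $dz^2/(z-\zeta) > 0$, giving
$\theta = +\arg(x-\zeta)/2$ (a single terminating ridge). Composite fields
use the quadratic differential
$\phi(z) = \prod_i (z - \zeta^{\mathrm{delta}}_i) / \prod_j (z - \zeta^{\mathrm{core}}_j)$,
whose positivity condition yields the additive rule implemented in
`composite_orientation()` — the unique combination consistent with the
single-point fields. Singular-point layouts for the shipped composite
fixtures are package choices: the core–delta pair defaults to a compact
vertical dipole (core at $(0.5, 0.55)$, delta at $(0.5, 0.45)$, a loop).
A compact pair has total index $0$ and a nearly constant far field, so the
unit-square field is almost seam-compatible on the torus; a lone delta, by
contrast, has Poincaré index $-1/2$, which no defect-free pattern on the
torus can carry — its stationary particle patterns necessarily contain
compensating defects and seam-interpolation bands (see limitations).

Two conventions worth stating explicitly:

* $\theta$ is measured from the **horizontal** axis, so
  $s = (\cos\theta, \sin\theta)$; angles are stored in radians in the
  half-open interval $[0, \pi)$.
* Analytic singular fields live on the unit square and are generally
  discontinuous across the torus seam; the dynamics nevertheless use torus
  displacements. Smoothness and periodicity of the field are not needed
  for stationary alignment, and no attempt is made to periodize.

Sampled fields (`angle_grid()`) interpolate through the doubled-angle
embedding $(\cos 2\theta, \sin 2\theta)$ — never linearly in $\theta$ —
so averaging is correct across the $\pi$ wraparound. Missing cells are
filled by Jacobi relaxation of the same embedding
(`fill_missing_orientations()`, 50 sweeps by default), a deliberately
minimal harmonic stand-in for image-based orientation extrapolation: exact
for constant boundary data, smooth elsewhere, and not claimed to
reproduce any published extrapolation method.

## Numerics

* **Integration**: explicit Euler by default; a fixed-step Dormand–Prince
  5(4) stage combination is available (`integrator = "rk_dopri"`). The
  tableau is evaluated at fixed $\Delta t$ with no error control, keeping
  trajectories deterministic and comparable across integrators.
* **Time step**: the default $\Delta t = 0.2$ follows the classical
  choice. Because velocities carry the $1/N$ factor, the relative
  contraction rate of a close pair is of order
  $2 f(0)/N \approx 3\times 10^{-4}$ for the shipped parameter sets at
  $N = 600$, so explicit Euler remains stable up to $\Delta t$ of order
  $10^3$. Pattern formation from random initial data happens on the time
  scale $t \sim 10^5$–$10^6$; the stationarity studies in this package
  therefore run with $\Delta t = 20$–$100$ for $2\,000$–$10\,000$ steps
  (a package choice, documented per experiment) rather than millions of
  $\Delta t = 0.2$ steps. At these steps $\lambda \Delta t \lesssim 0.03$,
  two orders below the stability boundary, and the runs reproduce the same
  stationary patterns.
* **Neighbour search**: velocities are accumulated either by a vectorized
  $O(N^2)$ reference (`rhs_velocities()`) or by compiled linked-cell lists
  (`rhs_velocities_celllist()`), with cells no smaller than the effective
  range $R_c/\eta$ and 3×3 periodic neighbourhoods; with fewer than three
  cells per side the search degenerates to the direct double loop. The two
  paths agree to $10^{-12}$ per component and the compiled path is the
  default inside `integrate_particles()`.
* **Convergence**: stationarity is tracked by
  $\tau(t) = \sum_j \lVert x_j(t+\Delta t) - x_j(t) \rVert_{L^1}$ with
  minimum-image displacements (otherwise a particle crossing the seam
  would spike $\tau$ and defeat early stopping).
* **Degenerate inputs**: a particle exactly on a field singular point
  raises an error for analytic fields; sampled fields fall back to the
  nearest valid cell. Positions are wrapped into $[0,1)^2$ after every
  step.

## Synthetic data and what it does (not) show

The package generates all of its own inputs: canonical angle maps
(`make_angle_map()`), cosine stripe gratings (`stripe_image()`), and
particle renderings (`render_particles()`, Gaussian splats with circular
boundary so mass wraps across the seam). A simplified structure-tensor
estimator (`estimate_orientation()`: central differences, Gaussian-smoothed
gradient outer products, ridge orientation = eigenvector of the smaller
eigenvalue) closes the loop from images back to orientation fields. On
synthetic stripes it is unbiased to better than 0.02 rad in the interior;
near image boundaries oblique gratings are not seam-periodic and the
circular smoothing contaminates a margin. It is a stand-in for published
fingerprint orientation estimators, asserted accurate only on synthetic
imagery; real fingerprint images bring contrast variation, moisture
artifacts and masks that none of the tests here exercise.

The round-trip experiment — sample a field, simulate to stationarity,
render, re-estimate the orientation, compare to the input field — is the
operational form of "particles align along the lines of smallest stress".
Agreement within 0.15 rad on ≥ 90 % of unmasked cells shows alignment of
the *synthetic* pipeline; it does not validate the model against biological
imagery.

## Experiment defaults

| experiment | force | $N$ | $\Delta t$ | steps |
|---|---|---|---|---|
| attraction-strength sweep | kc2012, $\chi = 1$, $\delta$ varies, cutoff 0.5 | 600 | 20 | 2000 |
| line alignment / round trip | kc-reparam, cutoff 0.1 | 600 | 100 | 20000 |
| $\eta$ rescaling sweep | oscillator2014, cutoff 0.15 | 600 | 100 | 8000 |

The short cutoffs follow the classical practice of truncating these
exponentially decaying forces (0.1 is the standard short cutoff for the
kc-type coefficients; the oscillator coefficients are below $10^{-4}$ of
their peak beyond $r = 0.15$) and shrink the pair search correspondingly.
Initial data are uniform on the torus (the biological assumption of random
initial Merkel-cell placement) except for the attraction sweep, which uses
the equiangular circle of radius 0.005 so that the stationary solutions
inherit radial symmetry.

## Known limitations

* No second-order (inertial) dynamics and no macroscopic PDE limit.
* No linear-stability spectra: stability of line patterns is asserted by
  perturb-and-relax smoke tests only.
* Analytic fields are not periodized; fields with singular points have
  seam discontinuities that the (local) forces tolerate but that a global
  analysis would not.
* The ridge-spacing estimator assumes an essentially parallel pattern;
  on strongly curved fields it reports the spacing along the chosen
  projection axis only.
* `delta_scale` and $\eta$ interact: both rescale the attraction range,
  and no attempt is made to disentangle them when both differ from 1.
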