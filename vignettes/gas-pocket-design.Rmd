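---
title: "Gas pockets in conical cavities: model, assumptions and design rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gas pockets in conical cavities: model, assumptions and design rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conepocket)
```

## The physical problem

A cone-shaped recess in a solid surface, submerged under a liquid, can trap a
pocket of gas. Whether that pocket exists, whether it is mechanically stable,
and whether keeping it is energetically preferable to flooding the recess are
the three questions this package answers analytically. The geometry is
abstracted from the pit chambers connecting water-transporting conduits in
plant xylem, where a stable air body in the funnel-shaped chamber is thought
to isolate a refilling conduit from its neighbours; the same mechanics
applies to engineered recesses meant to keep liquid iron off a water-cooled
copper tuyère, with air pockets acting as thermal insulation.

Two scenarios ship as presets: liquid iron (σ = 1.6 N/m, ρ = 7000 kg/m³) on
bare copper (θ ≈ 37°) or on a corundum coating (θ ≈ 130°), and water
(σ = 0.0728 N/m, ρ = 998 kg/m³ at room temperature) for the xylem mode. The
water-side constants are ordinary handbook values, not scenario-specific
measurements, and the contact angle of water on pit-chamber walls is left as
a required user input — no reliable preset exists for it.

## Model

**Geometry.** The cavity is a cone of acute half-opening angle ε (measured
from the axis, so tan ε = mouth radius / depth) and mouth radius $s_c$. The
gas/liquid interface is a spherical cap whose contact line is a circle of
radius $s$ on the cone wall, meeting it at the material contact angle θ.
With $\delta = \theta - \varepsilon$:

$$V(s) = \frac{\pi s^3}{3}\left[\cot\varepsilon +
  \frac{(1-\sin\delta)^2(2+\sin\delta)}{\cos^3\delta}\right]
  \equiv C(\theta,\varepsilon)\, s^3, \qquad
  H(s) = \frac{\cos\delta}{s},$$

$$A_\mathrm{lg} = \frac{2\pi s^2}{1+\sin\delta}, \qquad
  A_\mathrm{sg} = \frac{\pi s^2}{\sin\varepsilon}.$$

$H$ is the signed mean curvature: positive for a convex cap (gas bulging
into the liquid), negative for a concave one, zero exactly at δ = 90°. At
that flat-interface point the bracketed cap term of $V$ is a removable 0/0;
the implementation switches to the analytic limit (cap term = 0) whenever
$|\cos\delta| < 10^{-8}$, since a series expansion shows the term decays
linearly in the offset from 90°.

**Equilibrium.** The Young–Laplace balance $p_g = p_l + 2\sigma H$ combined
with the isothermal gas law $p_g V = nRT$ (the product $nRT$ is carried as a
single invariant, in joules) gives a cubic in the contact radius:

$$p_l\, C\, s^3 + 2\sigma\cos\delta\; C\, s^2 - nRT = 0.$$

For $p_l > 0$ this cubic has exactly one positive real root (the sign
pattern of its coefficients allows exactly one Descartes sign change), and
`equilibrium_radius()` treats any numerical deviation from that as an error.
For $p_l \le 0$ — water under tension in the xylem — the uniqueness guarantee
does not apply; the solver enumerates all positive real roots (zero to
three) and defers the physical choice to stability classification. Formal
roots with $p_g \le 0$ are excluded and reported as unphysical; roots with
$s > s_c$ are flagged *overfilled* rather than silently clamped, because the
wall-attached cap model stops being valid there. Non-existence of any root
is a regular result object, not an exception: it is the "completely flooded"
state of the design diagrams.

**Stability.** An equilibrium is stable iff

$$\Psi = \left[\frac{p_g}{V} + 2\sigma\frac{dH}{dV}\right]_0 > 0.$$

In a cone both $H$ and $V$ depend on the single variable $s$, so
$dH/dV = (dH/ds)/(dV/ds) = -\cos\delta/(3Cs^4)$; `stability_psi()` uses this
chain-rule form and cross-checks it against central finite differences with
relative step $10^{-6}$ in $s$ (agreement to $10^{-4}$ relative is part of
the report's contract). For positive liquid pressure the cone always gives
$\Psi > 0$, whichever sign $H$ has — substituting $p_g = p_l + 2\sigma\cos\delta/s$
gives $\Psi\,Cs^3 = p_l + \tfrac{4}{3}\sigma\cos\delta/s$, which is positive
whenever $p_g > 0$ and $p_l > 0$. Under tension ($p_l < 0$) that argument
fails, and convex equilibria can be unstable; this is exactly why the xylem
scenario classifies each enumerated root individually.

**Formation energy.** Flooding the recess versus keeping the pocket differ by

$$\Delta E = \Delta E_V + \Delta E_\mathrm{lg} + \Delta E_\mathrm{sg}
  = \sigma\left[-2HV + A_\mathrm{lg} + A_\mathrm{sg}\cos\theta\right].$$

Substituting the geometry collapses this to
$\Delta E = \sigma\, C(\theta,\varepsilon)\, s^2 \cos(\theta-\varepsilon)$
(the tests verify this independently derived closed form against the
component sum), so the sign depends only on the angles: the pocket is
favourable exactly when **θ > ε + 90°**, equivalently the admissible cone
angles for a given θ are the open interval (0, θ − 90°). Since $C > 0$, the
verdict is independent of $s$ — which is why `design_scan()` can evaluate
ΔE at an arbitrary reference radius without changing any sign.

**Capillary bound.** Gravity is not part of the cap model; its influence is
bounded by requiring the typical structure dimension — the mouth radius
$s_c$, not the depth — to stay below the capillary length
$l_c = \sqrt{\sigma/(\rho g)}$ (≈ 4.8 mm for liquid iron, ≈ 2.7 mm for
water).

## The energy-profile oracle

As an independent check on both the cubic and the Ψ criterion, the package
assembles the total quasi-static energy of the one-parameter family of
pinned-cap states:

$$E(s) = \sigma\left[A_\mathrm{lg}(s) + A_\mathrm{sg}(s)\cos\theta\right]
  + p_l V(s) - nRT\,\ln\frac{V(s)}{V_\mathrm{ref}}.$$

Differentiating and using the same geometric identity that collapses ΔE
shows $dE/ds = (p_lV' + 2\sigma H V' - nRT V'/V)$, which vanishes exactly at
the roots of the cubic; local minima are the stable equilibria. The
reference volume $V_\mathrm{ref}$ (taken at $s_c$) and the optional additive
`offset` fix the energy gauge only — the tests assert that changing them
never moves a stationary point. The reference state is the fully wetted
cavity, matching the convention in which ΔE measures displacement of liquid
by gas.

## Parameters, units, conventions

* Internal computation is strictly SI (m, Pa, N/m, J, radians). Degrees are
  accepted at every user-facing boundary (`degrees = TRUE` on constructors,
  always at the CLI) and converted on ingestion; the CLI additionally parses
  length suffixes (`2.5mm`, `8um`).
* ε is restricted to $[10^{-6}, \pi/2 - 10^{-6}]$ rad so cot ε and
  1/sin ε stay finite; physical cones have finite depth.
* The contact line is assumed to sit on the cone wall, never pinned at the
  rim: $s$ is validated against $(0, s_c]$ and larger roots are flagged,
  not clamped.
* Gas content can be given directly as `nRT` (J) or as an initial-fill
  specification (`nRT_from_fill()`): a fill pressure and the fraction of the
  cone volume charged with gas before immersion, matching how a recess
  charges with ambient air.
* Tolerances are fixed constants surfaced by `default_tolerances()`:
  gas-law residual $10^{-9}$ relative, Young–Laplace residual $10^{-6}$
  relative, complex-root filter $10^{-9}$, finite-difference agreement
  $10^{-4}$.

## Numerical choices

* The cubic is solved by `polyroot()` after nondimensionalising $s$ by
  $s_c$; near-zero leading coefficients (flat interface, $p_l \to 0$) are
  stripped relative to the largest coefficient, complex roots are discarded
  by the $|\mathrm{Im}| \le 10^{-9}|z|$ filter, and surviving roots are
  polished with a few Newton steps on the dimensional gas-law defect. This
  is robust across the degeneracies where closed-form (Cardano) solutions
  lose accuracy.
* The per-cell Ψ map of `design_scan()` needs a gas content to define an
  equilibrium; the scan constructs one at half the reference radius by
  setting $nRT = p_g(s)V(s)$ there, and reports `NA` where that gas pressure
  would be non-positive. Any other choice of construction radius gives the
  same qualitative map, since Ψ > 0 holds throughout the $p_l>0$ regime.
* `fixture_suite()` (the seeded scenario generator used by the property
  tests) draws surface tensions in 0.05–2 N/m, densities in 800–8000 kg/m³,
  positive pressures in 10–500 kPa and xylem tensions down to −2 MPa, with
  millimetre-scale cones for positive pressure and micrometre-scale cones
  for tension — the two regimes the model is meant for. Anchored scenarios
  guarantee coverage of all three qualitative states (no interface;
  interface but wetting favourable; persistent pocket).

## What the synthetic scenarios do and do not show

The generator emulates *parameter ranges*, not real measurement error: every
scenario is an exact instance of the model itself (spherical caps, perfect
cones, a sharp uniform contact angle, isothermal ideal gas, no dissolution,
no contact-angle hysteresis, no line tension). Passing tests therefore show
internal consistency — the closed forms agree with quadrature, the solver
with a bracketing scan, the stability flag with the energy landscape — and
reproduce the printed design numbers. They cannot show that a real corundum
coating holds θ = 130° at 1500 °C, that pit walls are smooth cones, or that
gas does not slowly dissolve; those are physical questions outside the
model.

## Worked example: the tuyère prototype

```{r prototype}
sys <- preset_system("iron-corundum", p_l = 1e5)
cav <- cone_cavity(30, s_c = 2.5e-3, degrees = TRUE)
prototype_check(cav, sys, depth = 4.5e-3)

admissible_cone_angles(130, degrees = TRUE)
1e3 * capillary_length(sys)  # mm

# charge the cone with ambient air, then immerse
nRT <- nRT_from_fill(1e5, fill_fraction = 1, cav)
eq <- equilibrium_radius(sys, cav, nRT)
eq
stability_psi(eq$pockets[[1]])
formation_energy(2.5e-3, sys, cav)
```

## Xylem mode

```{r xylem}
pit <- pit_chamber(30, chamber_radius = 5e-6, channel_radius = 1e-6,
                   degrees = TRUE)
water <- preset_system("water", p_l = -5e5, theta = 130)
xylem_scenario(pit, water, nRT = 2e-14)
```

The pit-to-cone mapping keeps the chamber half-angle and radius and discards
the narrow channel; whether the channel contributes trapped gas during
refilling is not modelled (and not claimed as biological fact either way).

## Known limitations

* Only axisymmetric conical cavities; the general curved-interface PDE for
  arbitrary cavity shapes, and the pillar-lattice existence results for
  protruding structures, are out of scope.
* Statics only: no dynamics of interface motion, no heat transfer, no gas
  dissolution, no non-isothermal behaviour.
* Rim-pinned contact lines are not modelled; gravity enters only through
  the capillary-length bound, not as a distortion of the cap shape.

## Problem sizes used in the checks

The test suite verifies the volume formula against solid-of-revolution
quadrature on a 100-triple (s, θ, ε) grid at $10^{-6}$ relative tolerance,
uniqueness and residuals of the cubic on 1000 random positive-pressure
systems, Ψ > 0 on 1000 equilibria spanning both curvature signs, the
formation-energy sign on a 200×200 angle grid with exact cancellation on the
boundary line, and root/stationary-point coincidence of the energy profile
on 50 random systems with 1500-point grids — sizes at which all checks
complete in seconds while sampling the full admissible angle ranges.
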