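# conepocket

Analytic design and analysis of gas pockets trapped in cone-shaped surface
cavities — the geometry of xylem pit chambers, reused as a recipe for
liquid-repellent engineered surfaces (e.g. keeping liquid iron off blast
furnace tuyères by insulating air pockets).

## Who this is for

Anyone sizing recessed, air-retaining surface structures: how steep may the
cone be for a given contact angle, how large before gravity ruins the
interface, does an interface exist for a given gas charge and liquid
pressure, and is it mechanically stable — including the plant-hydraulics
case of an air pocket in a pit chamber separating an embolised, refilling
conduit from a water-filled neighbour under tension.

## The model in brief

A spherical-cap gas/liquid interface is pinned on the wall of a cone with
acute half-angle ε (from the axis) and mouth radius s_c, meeting it at
contact angle θ. With δ = θ − ε:

- geometry: `V = (π/3) s³ [cot ε + (1 − sin δ)²(2 + sin δ)/cos³ δ]`,
  `H = cos δ / s`, `A_lg = 2πs²/(1 + sin δ)`, `A_sg = πs²/sin ε`;
- equilibrium: Young–Laplace `p_g = p_l + 2σH` plus the isothermal gas law
  `p_g V = nRT` give the cubic
  `p_l C s³ + 2σ cos δ · C s² − nRT = 0` (C = V/s³), with exactly one
  positive root for `p_l > 0` and an enumerated root set under tension;
- stability: `Ψ = p_g/V + 2σ dH/dV > 0` at the equilibrium;
- energetics: `ΔE = σ[−2HV + A_lg + A_sg cos θ]`, negative — the air pocket
  persists — exactly when **θ > ε + 90°**;
- scale: structures must not exceed the capillary length
  `l_c = sqrt(σ/(ρg))`.

See `vignettes/gas-pocket-design.Rmd` for derivations, conventions and
numerical choices.

## Worked example

```r
library(conepocket)

sys <- preset_system("iron-corundum", p_l = 1e5)   # theta = 130 deg
cav <- cone_cavity(30, s_c = 2.5e-3, degrees = TRUE)

admissible_cone_angles(130, degrees = TRUE)
#> <angle_interval> (0, 40) degree, open

1e3 * capillary_length(sys)
#> [1] 4.826991            # mm; s_c = 2.5 mm is comfortably below

# charge 90% of the cone volume with ambient air, then immerse
eq <- equilibrium_radius(sys, cav, nRT = nRT_from_fill(1e5, 0.9, cav))
eq
#> <equilibrium_report> 1 equilibrium pocket(s)
#> <gas_pocket> [equilibrium] s = 2.48 mm, p_g = 9.978e+04 Pa, V = 25.56 mm^3, H = -70.02 1/m

stability_psi(eq$pockets[[1]])
#> <stability_report> Psi = 3.906e+12 Pa/m^3 -> stable; l_c = 4.827 mm (s_c <= l_c)

formation_energy(2.5e-3, sys, cav)
#> <energy_report> delta_E = -2.91e-06 J ... -> air pocket favourable
```

Reading: for the prototype cone (ε = 30°, s_c = 2.5 mm) under liquid iron on
a corundum coating, the cone angle lies inside the admissible interval
(0°, 40°), a concave (H < 0) equilibrium interface exists at a contact
radius of 2.48 mm, it is mechanically stable (Ψ > 0), and retaining the
pocket beats flooding the cone (ΔE < 0). (Charging 100 % of the cone at
ambient pressure gives a root just past the mouth, which the solver flags
as `overfilled` rather than clamping.) The same functions
with `p_l < 0` and a `pit_chamber()` run the xylem scenario
(`xylem_scenario()`), where multiple roots may exist and each is classified.

## Command line

```sh
Rscript inst/cli/conepocket.R energy --preset iron-corundum --theta 130 --epsilon 30
Rscript inst/cli/conepocket.R scan --preset iron-corundum --theta 91:180:1 --epsilon 1:89:1 --out scan.csv
Rscript inst/cli/conepocket.R prototype --preset iron-corundum --epsilon 30 --sc 2.5mm --depth 4.5mm
```

Angles are degrees, lengths take unit suffixes, grids are `from:to:step`
(half-open). Reports are JSON with units in the field names; scans are CSV.
`--dump-config file.yaml` writes the resolved inputs so `--config file.yaml`
reproduces a run byte for byte.

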