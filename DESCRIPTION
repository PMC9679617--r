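Package: conepocket
Title: Gas Pockets in Conical Surface Cavities: Existence, Stability and
    Wetting Energetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic design and analysis of gas pockets trapped in
    cone-shaped surface recesses, the geometry abstracted from the pit
    chambers of plant xylem. Solves the Young-Laplace pressure balance
    coupled to the isothermal gas law for the equilibrium contact radius
    of a spherical-cap gas/liquid interface pinned on the cone wall,
    classifies mechanical stability by the perturbation criterion
    Psi = p_g/V + 2*sigma*dH/dV, evaluates the formation-energy criterion
    for air-pocket persistence (theta > epsilon + 90 degrees) and the
    capillary-length design bound sqrt(sigma/(rho*g)). Ships material
    presets for the liquid-iron/tuyere application and a negative-pressure
    mode for xylem pit refilling, with a command-line interface for
    design scans and scenario reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
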