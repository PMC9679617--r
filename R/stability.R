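# Mechanical stability of an equilibrium interface (the Psi criterion), the
# capillary-length design bound, and the formation-energy (wetting) criterion.

#' Capillary length
#'
#' `l_c = sqrt(sigma / (rho g))`: the length scale below which surface
#' tension dominates gravity. Structures holding a gas pocket should not
#' exceed it, or gravity will distort the interface.
#'
#' @param sigma Surface tension (N/m) or a [fluid_solid_system()] (in which
#'   case `rho` and `g` are taken from it).
#' @param rho Liquid density (kg/m^3).
#' @param g Gravitational acceleration (m/s^2).
#' @return Capillary length in metres.
#' @export
#' @examples
#' capillary_length(1.6, 7000)           # liquid iron: ~4.8 mm
#' capillary_length(0.0728, 998)         # water: ~2.7 mm
capillary_length <- function(sigma, rho, g = 9.81) {
  if (inherits(sigma, "fluid_solid_system")) {
    sys <- sigma
    sigma <- sys$sigma; rho <- sys$rho; g <- sys$g
  }
  check_scalar_positive(sigma, "sigma")
  check_scalar_positive(rho, "rho")
  check_scalar_positive(g, "g")
  sqrt(sigma / (rho * g))
}

#' Mechanical stability of an equilibrium pocket
#'
#' Evaluates `Psi = p_g/V + 2 sigma dH/dV` at the equilibrium. A positive
#' `Psi` means a small shift of the contact line generates restoring forces
#' (the interface returns); a negative one means the interface runs away.
#' In the cone both `H` and `V` are single-variable functions of `s`, so
#' `dH/dV = (dH/ds)/(dV/ds) = -cos(theta - epsilon) / (3 C s^4)`; the
#' analytic value is cross-checked against central finite differences.
#' Also reports the capillary-length bound `s_c <= l_c`.
#'
#' @param pocket An equilibrium `gas_pocket` with `p_g > 0`.
#' @return Object of class `stability_report` with fields `psi`, `stable`
#'   (`psi > 0`), `dH_dV_analytic`, `dH_dV_numeric`, `capillary_length`,
#'   `within_capillary_bound`.
#' @export
stability_psi <- function(pocket) {
  if (!inherits(pocket, "gas_pocket")) {
    stop_domain("pocket", "must be a gas_pocket object")
  }
  if (pocket$p_g <= 0) {
    stop("unphysical state: gas pressure must be positive for stability analysis")
  }
  tol <- default_tolerances()
  theta <- pocket$system$theta
  epsilon <- pocket$cavity$epsilon
  s <- pocket$s
  co <- cone_shape_coefficient(theta, epsilon)
  dH_dV <- -cos(theta - epsilon) / (3 * co * s^4)
  h <- tol$fd_step_rel * s
  dH_num <- (cap_curvature(s + h, theta, epsilon) -
               cap_curvature(s - h, theta, epsilon)) /
    (cap_volume(s + h, theta, epsilon) - cap_volume(s - h, theta, epsilon))
  psi <- pocket$p_g / pocket$V + 2 * pocket$system$sigma * dH_dV
  lc <- capillary_length(pocket$system)
  structure(
    list(psi = psi, stable = psi > 0,
         dH_dV_analytic = dH_dV, dH_dV_numeric = dH_num,
         capillary_length = lc,
         within_capillary_bound = pocket$cavity$s_c <= lc),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(
    "<stability_report> Psi = %.4g Pa/m^3 -> %s; l_c = %.4g mm (s_c %s l_c)\n",
    x$psi, if (x$stable) "stable" else "unstable",
    1e3 * x$capillary_length,
    if (x$within_capillary_bound) "<=" else ">"))
  invisible(x)
}

#' Formation energy of a gas pocket
#'
#' Energy difference between retaining a gas pocket of contact radius `s`
#' and wetting the cavity completely:
#' `dE = sigma [ -2 H V + A_lg + A_sg cos(theta) ]`, split into the
#' displacement work `dE_V = -2 sigma H V`, the cost of the liquid/gas cap
#' `dE_lg = sigma A_lg`, and the dewetting of the wall
#' `dE_sg = sigma cos(theta) A_sg`. Negative `dE` means the air pocket is
#' the energetically favourable state ("ferrophobic" in the liquid-iron
#' application), which happens exactly when `theta > epsilon + 90` degrees.
#'
#' @param s Contact radius (m), `0 < s <= s_c`.
#' @param system A [fluid_solid_system()] (supplies `sigma` and `theta`).
#' @param cavity A [cone_cavity()] (supplies `epsilon` and `s_c`).
#' @return Object of class `energy_report` with fields `delta_E`,
#'   `delta_E_V`, `delta_E_lg`, `delta_E_sg` (J) and `ferrophobic`
#'   (`delta_E < 0`).
#' @export
#' @examples
#' sys <- fluid_solid_system(1.6, 7000, theta = 130, p_l = 1e5, degrees = TRUE)
#' cav <- cone_cavity(30, s_c = 2.5e-3, degrees = TRUE)
#' formation_energy(2.5e-3, sys, cav)  # delta_E < 0: pocket persists
formation_energy <- function(s, system, cavity) {
  check_scalar_positive(s, "s")
  if (any(s > cavity$s_c)) {
    stop_domain("s", "must not exceed the cavity mouth radius s_c")
  }
  cap <- cap_state(s, system$theta, cavity$epsilon)
  sigma <- system$sigma
  dE_V <- -2 * sigma * cap$H * cap$V
  dE_lg <- sigma * cap$A_lg
  dE_sg <- sigma * cos(system$theta) * cap$A_sg
  dE <- dE_V + dE_lg + dE_sg
  structure(
    list(delta_E = dE, delta_E_V = dE_V, delta_E_lg = dE_lg,
         delta_E_sg = dE_sg, ferrophobic = dE < 0),
    class = "energy_report"
  )
}

#' @export
print.energy_report <- function(x, ...) {
  cat(sprintf(
    "<energy_report> delta_E = %.4g J (V: %.3g, lg: %.3g, sg: %.3g) -> %s\n",
    x$delta_E, x$delta_E_V, x$delta_E_lg, x$delta_E_sg,
    if (x$ferrophobic) "air pocket favourable" else "wetting favourable"))
  invisible(x)
}

#' Air-pocket persistence criterion
#'
#' `TRUE` iff `theta > epsilon + 90` degrees: retaining the gas pocket is
#' energetically favourable over complete wetting of the cone. The boundary
#' case is excluded (zero energy difference).
#'
#' @param theta Contact angle (rad unless `degrees = TRUE`).
#' @param epsilon Acute cone angle (rad unless `degrees = TRUE`).
#' @param degrees If `TRUE`, both angles are in degrees.
#' @return Logical (vectorised).
#' @export
#' @examples
#' ferrophobicity_criterion(130, 30, degrees = TRUE)  # TRUE
#' ferrophobicity_criterion(37, 10, degrees = TRUE)   # FALSE: iron wets copper
ferrophobicity_criterion <- function(theta, epsilon, degrees = FALSE) {
  if (isTRUE(degrees)) {
    theta <- deg2rad(theta); epsilon <- deg2rad(epsilon)
  }
  check_theta(theta)
  check_epsilon(epsilon)
  theta > epsilon + pi / 2
}

#' Admissible cone angles for a given contact angle
#'
#' For contact angle `theta`, air pockets persist only for cone angles in
#' the open interval `(0, theta - 90 degrees)`; empty when
#' `theta <= 90` degrees (no cone works, whatever its angle).
#'
#' @param theta Contact angle (rad unless `degrees = TRUE`).
#' @param degrees If `TRUE`, input and output are in degrees.
#' @return Object of class `angle_interval`: list with `lower`, `upper`,
#'   `empty` and the unit used.
#' @export
#' @examples
#' admissible_cone_angles(130, degrees = TRUE)  # (0, 40) degrees
admissible_cone_angles <- function(theta, degrees = FALSE) {
  theta_rad <- if (isTRUE(degrees)) deg2rad(theta) else theta
  check_theta(theta_rad)
  upper_rad <- theta_rad - pi / 2
  empty <- upper_rad <= 0
  upper <- if (empty) 0 else upper_rad
  if (isTRUE(degrees)) upper <- rad2deg(upper)
  structure(
    list(lower = 0, upper = upper, empty = empty,
         unit = if (isTRUE(degrees)) "degree" else "radian"),
    class = "angle_interval"
  )
}

#' @export
print.angle_interval <- function(x, ...) {
  if (x$empty) cat("<angle_interval> empty (no admissible cone angle)\n")
  else cat(sprintf("<angle_interval> (0, %.6g) %s, open\n", x$upper, x$unit))
  invisible(x)
}

#' Quasi-static energy profile over contact radii
#'
#' Total energy of the constrained states in which the interface is a
#' spherical cap pinned at radius `s` with fixed gas content `nRT`:
#' surface terms `sigma (A_lg + A_sg cos theta)`, displacement work against
#' the liquid `p_l V`, and isothermal gas work `-nRT log(V / V_ref)`.
#' Stationary points of this profile are exactly the equilibrium roots of
#' [equilibrium_radius()]; interior local minima are the stable equilibria.
#' The reference volume `V_ref` (and the additive `offset`) only shift the
#' profile by a constant and never move its stationary points.
#'
#' @inheritParams cubic_coefficients
#' @param s_grid Sorted positive vector of contact radii (m).
#' @param offset Additive constant (J) fixing the energy gauge; default 0
#'   (energies relative to the state at the largest reference volume).
#' @return `data.frame` with columns `s`, `E_total`, `E_surface`,
#'   `E_pressure`, `E_gas`.
#' @export
energy_profile <- function(system, cavity, nRT, s_grid, offset = 0) {
  check_scalar_positive(s_grid, "s_grid")
  if (is.unsorted(s_grid, strictly = TRUE)) {
    stop_domain("s_grid", "must be strictly increasing")
  }
  check_scalar_positive(nRT, "nRT")
  theta <- system$theta
  epsilon <- cavity$epsilon
  areas <- interface_areas(s_grid, theta, epsilon)
  V <- cap_volume(s_grid, theta, epsilon)
  V_ref <- cap_volume(cavity$s_c, theta, epsilon)
  E_surface <- system$sigma * (areas$A_lg + cos(theta) * areas$A_sg)
  E_pressure <- system$p_l * V
  E_gas <- -nRT * log(V / V_ref)
  data.frame(
    s = s_grid,
    E_total = E_surface + E_pressure + E_gas + offset,
    E_surface = E_surface,
    E_pressure = E_pressure,
    E_gas = E_gas
  )
}
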