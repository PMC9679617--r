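# Applied layers: material presets, design scans over (theta, epsilon),
# prototype geometry checks, the xylem-pit refilling scenario, and the seeded
# fixture generator used by the property tests.

.PRESETS <- list(
  "iron-copper" = list(name = "iron-copper", theta_deg = 37,
                       sigma = 1.6, rho = 7000),
  "iron-corundum" = list(name = "iron-corundum", theta_deg = 130,
                         sigma = 1.6, rho = 7000),
  # water constants for the xylem mode; the contact angle on pit walls is a
  # required user input (no preset value exists for it)
  "water" = list(name = "water", theta_deg = NA_real_,
                 sigma = 0.0728, rho = 998)
)

#' Built-in material presets
#'
#' Liquid-iron pairings (`"iron-copper"`: theta = 37 deg, `"iron-corundum"`:
#' theta = 130 deg, both with sigma = 1.6 N/m and rho = 7000 kg/m^3) and
#' `"water"` (sigma = 0.0728 N/m, rho = 998 kg/m^3 at ~20 C; contact angle
#' left `NA` — it depends on the wall material and must be supplied).
#'
#' @param name Preset name; `material_preset()` with no argument lists them.
#' @return List with fields `name`, `theta_deg`, `sigma`, `rho`.
#' @export
#' @examples
#' material_preset("iron-corundum")
material_preset <- function(name) {
  if (missing(name)) return(names(.PRESETS))
  if (!name %in% names(.PRESETS)) {
    stop_domain("name", sprintf("unknown preset; available: %s",
                                paste(names(.PRESETS), collapse = ", ")))
  }
  .PRESETS[[name]]
}

#' Build a fluid/solid system from a preset
#'
#' @param preset Preset name or list from [material_preset()].
#' @param p_l Liquid pressure (Pa).
#' @param theta Contact angle in degrees; overrides the preset value
#'   (required for presets without one, e.g. `"water"`).
#' @param g Gravitational acceleration (m/s^2).
#' @return A [fluid_solid_system()].
#' @export
preset_system <- function(preset, p_l, theta = NULL, g = 9.81) {
  if (is.character(preset)) preset <- material_preset(preset)
  theta_deg <- if (!is.null(theta)) theta else preset$theta_deg
  if (is.na(theta_deg)) {
    stop_domain("theta", sprintf(
      "preset '%s' has no contact angle; supply theta (degrees)", preset$name))
  }
  fluid_solid_system(preset$sigma, preset$rho, theta_deg, p_l, g = g,
                     degrees = TRUE)
}

#' Design scan over contact and cone angles
#'
#' Evaluates, for every (theta, epsilon) cell: the persistence criterion
#' `theta > epsilon + 90` degrees, the formation energy at a reference
#' contact radius, whether a reference equilibrium exists, and its stability
#' `Psi`. The reference equilibrium is constructed at `s = reference_s / 2`
#' by setting `nRT = p_g(s) V(s)` there (cells where that gas pressure is
#' non-positive get `NA`).
#'
#' @param theta_grid Contact angles in degrees.
#' @param epsilon_grid Acute cone angles in degrees.
#' @param system A [fluid_solid_system()] supplying `sigma`, `rho`, `p_l`,
#'   `g`; its `theta` is overridden cell by cell.
#' @param reference_s Reference contact radius (m), also used as the cell
#'   cavity mouth radius `s_c`.
#' @return Object of class `design_scan`: a `data.frame` with columns
#'   `theta_deg`, `epsilon_deg`, `admissible`, `delta_E`, `psi`, `exists`.
#' @export
design_scan <- function(theta_grid, epsilon_grid, system, reference_s) {
  if (length(theta_grid) == 0 || length(epsilon_grid) == 0) {
    stop_domain("theta_grid/epsilon_grid", "grids must be non-empty")
  }
  check_scalar_positive(reference_s, "reference_s")
  grid <- expand.grid(theta_deg = theta_grid, epsilon_deg = epsilon_grid,
                      KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  admissible <- logical(n); delta_E <- numeric(n)
  psi <- rep(NA_real_, n); exists <- logical(n)
  for (i in seq_len(n)) {
    th <- deg2rad(grid$theta_deg[i]); ep <- deg2rad(grid$epsilon_deg[i])
    cav <- cone_cavity(ep, reference_s)
    sys <- fluid_solid_system(system$sigma, system$rho, th, system$p_l,
                              g = system$g)
    admissible[i] <- ferrophobicity_criterion(th, ep)
    delta_E[i] <- formation_energy(reference_s, sys, cav)$delta_E
    s_eq <- reference_s / 2
    p_g <- sys$p_l + 2 * sys$sigma * cos(th - ep) / s_eq
    if (p_g > 0) {
      nRT <- p_g * cap_volume(s_eq, th, ep)
      eq <- equilibrium_radius(sys, cav, nRT)
      exists[i] <- eq$exists
      if (eq$exists) psi[i] <- stability_psi(eq$pockets[[1]])$psi
    }
  }
  out <- data.frame(theta_deg = grid$theta_deg,
                    epsilon_deg = grid$epsilon_deg,
                    admissible = admissible, delta_E = delta_E,
                    psi = psi, exists = exists)
  class(out) <- c("design_scan", "data.frame")
  attr(out, "reference_s") <- reference_s
  out
}

#' Check a cavity design against the persistence rules
#'
#' Three checks on a cone intended to hold a gas pocket under a given
#' liquid: (i) the cone angle lies in the admissible interval for the
#' contact angle; (ii) the mouth radius does not exceed the capillary
#' length; (iii) if a depth is supplied, it is geometrically consistent with
#' the angle (`|epsilon - atan(s_c / depth)| < 2` degrees).
#'
#' @param cavity A [cone_cavity()].
#' @param system A [fluid_solid_system()].
#' @param depth Optional measured cone depth (m) for the consistency check.
#' @return Object of class `prototype_report`: list of per-check results and
#'   an `all_pass` flag. Failures are reported, never raised as errors.
#' @export
#' @examples
#' sys <- preset_system("iron-corundum", p_l = 1e5)
#' cav <- cone_cavity(30, s_c = 2.5e-3, degrees = TRUE)
#' prototype_check(cav, sys, depth = 4.5e-3)
prototype_check <- function(cavity, system, depth = NULL) {
  interval <- admissible_cone_angles(system$theta)
  admissible <- !interval$empty &&
    cavity$epsilon > interval$lower && cavity$epsilon < interval$upper
  lc <- capillary_length(system)
  capillary_ok <- cavity$s_c <= lc
  geometry_ok <- NA
  epsilon_from_depth <- NA_real_
  if (!is.null(depth)) {
    check_scalar_positive(depth, "depth")
    epsilon_from_depth <- atan(cavity$s_c / depth)
    geometry_ok <- abs(cavity$epsilon - epsilon_from_depth) < deg2rad(2)
  }
  checks <- c(admissible = admissible, capillary = capillary_ok,
              geometry = geometry_ok)
  structure(
    list(admissible = admissible,
         admissible_interval = interval,
         capillary_ok = capillary_ok,
         capillary_length = lc,
         geometry_ok = geometry_ok,
         epsilon_from_depth = epsilon_from_depth,
         failures = names(checks)[!is.na(checks) & !checks],
         all_pass = all(checks[!is.na(checks)])),
    class = "prototype_report"
  )
}

#' @export
print.prototype_report <- function(x, ...) {
  cat("<prototype_report>\n")
  cat(sprintf("  admissible cone angle: %s\n",
              if (x$admissible) "pass" else "FAIL"))
  cat(sprintf("  s_c <= capillary length (%.3g mm): %s\n",
              1e3 * x$capillary_length,
              if (x$capillary_ok) "pass" else "FAIL"))
  if (!is.na(x$geometry_ok)) {
    cat(sprintf("  angle/depth consistency: %s\n",
                if (x$geometry_ok) "pass" else "FAIL"))
  }
  invisible(x)
}

#' Air pocket in a xylem pit chamber
#'
#' Maps a pit chamber to its equivalent cone, enumerates the equilibrium
#' interfaces of a gas pocket of content `nRT` under the (possibly strongly
#' negative) xylem water pressure, classifies each by the `Psi` criterion,
#' and reports whether a stable air pocket exists — the condition for the
#' pit to isolate a refilling conduit from its water-filled neighbour.
#'
#' @param pit A [pit_chamber()].
#' @param system A [fluid_solid_system()]; `p_l` may be negative (tension).
#' @param nRT Gas content (J), positive.
#' @return Object of class `xylem_report` with the equivalent cone, the
#'   [equilibrium_radius()] report, a per-pocket table (`s`, `p_g`, `V`,
#'   `H`, `psi`, `stable`, `overfilled`) and `stable_pocket_exists`.
#' @export
xylem_scenario <- function(pit, system, nRT) {
  cone <- pit_to_cone(pit)
  eq <- equilibrium_radius(system, cone, nRT)
  rows <- lapply(eq$pockets, function(pk) {
    st <- stability_psi(pk)
    data.frame(s = pk$s, p_g = pk$p_g, V = pk$V, H = pk$H,
               psi = st$psi, stable = st$stable, overfilled = pk$overfilled)
  })
  pockets <- if (length(rows)) do.call(rbind, rows) else
    data.frame(s = numeric(0), p_g = numeric(0), V = numeric(0),
               H = numeric(0), psi = numeric(0), stable = logical(0),
               overfilled = logical(0))
  structure(
    list(cone = cone, equilibria = eq, pockets = pockets,
         stable_pocket_exists = any(pockets$stable & !pockets$overfilled),
         notes = eq$notes),
    class = "xylem_report"
  )
}

#' @export
print.xylem_report <- function(x, ...) {
  cat(sprintf("<xylem_report> stable air pocket: %s\n",
              if (x$stable_pocket_exists) "yes" else "no"))
  if (nrow(x$pockets)) print(x$pockets)
  for (nt in x$notes) cat(" note:", nt, "\n")
  invisible(x)
}

#' Deterministic scenario suite for property tests
#'
#' Seeded generator of valid (system, cavity, nRT) scenarios spanning both
#' curvature signs, both sides of the persistence criterion, and xylem-range
#' negative pressures, including at least one scenario in each of the three
#' qualitative interface states: no interface possible (`"a"`), interface
#' possible but wetting favourable (`"b"`), and persistent pocket (`"c"`).
#'
#' @param seed Integer seed.
#' @param n Number of random scenarios in addition to the fixed regime
#'   anchors.
#' @return List of scenarios, each a list with `system`, `cavity`, `nRT` and
#'   a `label` naming the targeted regime.
#' @export
fixture_suite <- function(seed, n = 24) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))

  make <- function(theta_deg, epsilon_deg, p_l, s_c, s_target_frac, label) {
    th <- deg2rad(theta_deg); ep <- deg2rad(epsilon_deg)
    sys <- fluid_solid_system(stats::runif(1, 0.05, 2),
                              stats::runif(1, 800, 8000), th, p_l)
    cav <- cone_cavity(ep, s_c)
    s_t <- s_target_frac * s_c
    p_g <- sys$p_l + 2 * sys$sigma * cos(th - ep) / s_t
    nRT <- if (p_g > 0) p_g * cap_volume(s_t, th, ep) else
      0.1 * abs(sys$p_l) * cap_volume(s_t, th, ep)
    list(system = sys, cavity = cav, nRT = nRT, label = label)
  }

  scenarios <- list(
    # state c: persistence criterion met, positive pressure, concave cap
    make(130, 30, 1e5, 2.5e-3, 0.6, "c"),
    # state b: interface exists (convex cap) but wetting is favourable
    make(60, 20, 1e5, 2.5e-3, 0.5, "b"),
    # state a: no interface — strong xylem tension, concave geometry, gas
    # content too small for any positive root
    make(130, 30, -1.5e6, 5e-6, 0.4, "a"),
    # xylem regime with a stable pocket candidate (negative p_l, convex cap)
    make(70, 25, -5e5, 5e-6, 0.3, "xylem")
  )

  for (i in seq_len(n)) {
    repeat {
      theta_deg <- stats::runif(1, 5, 175)
      epsilon_deg <- stats::runif(1, 2, 88)
      negative <- stats::runif(1) < 0.3
      p_l <- if (negative) -stats::runif(1, 1e4, 2e6) else
        stats::runif(1, 1e4, 5e5)
      s_c <- if (negative) stats::runif(1, 1e-6, 2e-5) else
        stats::runif(1, 5e-4, 5e-3)
      sc <- try(make(theta_deg, epsilon_deg, p_l, s_c,
                     stats::runif(1, 0.2, 0.9), "random"), silent = TRUE)
      if (!inherits(sc, "try-error") && sc$nRT > 0) break
    }
    scenarios <- c(scenarios, list(sc))
  }
  scenarios
}
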