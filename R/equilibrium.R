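# Existence and computation of the equilibrium interface: the Young-Laplace
# balance p_g = p_l + 2*sigma*H combined with the isothermal gas law
# p_g * V = nRT yields a cubic in the contact radius s.

#' Liquid/solid pairing and ambient state
#'
#' @param sigma Surface tension of the liquid (N/m), positive.
#' @param rho Liquid density (kg/m^3), positive.
#' @param theta Contact angle of the liquid on the solid, measured through the
#'   liquid (radians unless `degrees = TRUE`), in `[0, pi]`.
#' @param p_l Liquid pressure (Pa). May be negative: water in transpiring
#'   xylem is under tension.
#' @param g Gravitational acceleration (m/s^2), default 9.81.
#' @param degrees If `TRUE`, `theta` is given in degrees.
#' @return Object of class `fluid_solid_system`.
#' @export
#' @examples
#' # liquid iron on corundum-coated copper at ambient pressure
#' fluid_solid_system(sigma = 1.6, rho = 7000, theta = 130, p_l = 1e5,
#'                    degrees = TRUE)
fluid_solid_system <- function(sigma, rho, theta, p_l, g = 9.81,
                               degrees = FALSE) {
  if (isTRUE(degrees)) theta <- deg2rad(theta)
  check_scalar_positive(sigma, "sigma")
  check_scalar_positive(rho, "rho")
  check_scalar_positive(g, "g")
  check_theta(theta)
  if (!is.numeric(p_l) || !is.finite(p_l)) stop_domain("p_l", "must be finite")
  structure(
    list(sigma = sigma, rho = rho, theta = theta, p_l = p_l, g = g),
    class = "fluid_solid_system"
  )
}

#' @export
print.fluid_solid_system <- function(x, ...) {
  cat(sprintf(
    "<fluid_solid_system> sigma = %.4g N/m, rho = %.4g kg/m^3, theta = %.4g deg, p_l = %.4g Pa\n",
    x$sigma, x$rho, rad2deg(x$theta), x$p_l))
  invisible(x)
}

#' Isothermal gas content from an initial-fill specification
#'
#' A recess charges with ambient gas before immersion: if a fraction
#' `fill_fraction` of the empty cone volume holds gas at pressure `p0`, the
#' isothermal invariant is `nRT = p0 * fill_fraction * V_cone` with
#' `V_cone = (pi/3) s_c^3 cot(epsilon)`.
#'
#' @param p0 Fill pressure (Pa), positive.
#' @param fill_fraction Fraction of the cone volume initially gas-filled,
#'   in (0, 1].
#' @param cavity A [cone_cavity()].
#' @return `nRT` in joules.
#' @export
nRT_from_fill <- function(p0, fill_fraction, cavity) {
  check_scalar_positive(p0, "p0")
  if (!is.numeric(fill_fraction) || fill_fraction <= 0 || fill_fraction > 1) {
    stop_domain("fill_fraction", "must lie in (0, 1]")
  }
  v_cone <- (pi / 3) * cavity$s_c^3 / tan(cavity$epsilon)
  p0 * fill_fraction * v_cone
}

#' Coefficients of the equilibrium cubic
#'
#' Substituting the cap volume `V = C(theta, epsilon) s^3` and curvature
#' `H = cos(theta - epsilon)/s` into `p_g V = nRT` with
#' `p_g = p_l + 2 sigma H` gives
#' `p_l C s^3 + 2 sigma cos(theta - epsilon) C s^2 - nRT = 0`.
#'
#' @param system A [fluid_solid_system()].
#' @param cavity A [cone_cavity()].
#' @param nRT Isothermal gas content (J), positive.
#' @return Numeric vector `c(c3, c2, c1, c0)` in descending powers of `s`;
#'   evaluating the polynomial at any `s` reproduces `p_g(s) V(s) - nRT`.
#' @export
cubic_coefficients <- function(system, cavity, nRT) {
  check_scalar_positive(nRT, "nRT")
  co <- cone_shape_coefficient(system$theta, cavity$epsilon)
  cd <- cos(system$theta - cavity$epsilon)
  c(c3 = system$p_l * co,
    c2 = 2 * system$sigma * cd * co,
    c1 = 0,
    c0 = -nRT)
}

# polynomial value p_g(s) V(s) - nRT (the gas-law defect at radius s)
gas_law_defect <- function(s, system, cavity, nRT) {
  coef <- cubic_coefficients(system, cavity, nRT)
  coef[[1]] * s^3 + coef[[2]] * s^2 + coef[[4]]
}

# Positive real roots of the cubic. Nondimensionalised by s_c for
# conditioning; near-zero leading coefficients (flat interface, p_l = 0)
# are stripped before polyroot; roots are polished by Newton iterations.
positive_real_roots <- function(system, cavity, nRT) {
  tol <- default_tolerances()
  coef <- cubic_coefficients(system, cavity, nRT)
  sc <- cavity$s_c
  # ascending powers in x = s / s_c
  a <- c(coef[[4]], 0, coef[[2]] * sc^2, coef[[1]] * sc^3)
  amax <- max(abs(a))
  a <- a / amax
  while (length(a) > 1 && abs(a[length(a)]) < 1e-14) a <- a[-length(a)]
  if (length(a) <= 1) return(numeric(0))
  z <- polyroot(a)
  real <- Re(z)[abs(Im(z)) <= tol$root_imag_rel * pmax(Mod(z), 1e-300)]
  roots <- sort(unique(real[real > 0])) * sc
  # Newton polish on the dimensional defect g(s)
  for (i in seq_along(roots)) {
    s <- roots[i]
    for (k in 1:3) {
      f <- coef[[1]] * s^3 + coef[[2]] * s^2 + coef[[4]]
      df <- 3 * coef[[1]] * s^2 + 2 * coef[[2]] * s
      if (!is.finite(df) || df == 0) break
      step <- f / df
      if (!is.finite(step)) break
      s <- s - step
      if (s <= 0) { s <- roots[i]; break }
    }
    roots[i] <- s
  }
  sort(unique(roots))
}

# internal constructor; equilibrium = TRUE enforces the Young-Laplace and
# gas-law contracts
new_gas_pocket <- function(s, system, cavity, nRT, equilibrium = FALSE) {
  cap <- cap_state(s, system$theta, cavity$epsilon)
  p_g <- nRT / cap$V
  pocket <- structure(
    list(cavity = cavity, system = system, nRT = nRT, s = s, cap = cap,
         V = cap$V, H = cap$H, p_g = p_g,
         overfilled = s > cavity$s_c,
         equilibrium = equilibrium),
    class = "gas_pocket"
  )
  if (equilibrium) {
    tol <- default_tolerances()
    res <- young_laplace_residual(pocket)
    scale <- max(abs(system$p_l), p_g, 1)
    if (abs(res) >= tol$young_laplace_rel * scale) {
      stop(sprintf(
        "equilibrium contract violated: Young-Laplace residual %.3g Pa (scale %.3g Pa)",
        res, scale))
    }
    if (abs(p_g * cap$V - nRT) >= tol$gas_law_rel * nRT) {
      stop("equilibrium contract violated: gas law p_g*V != nRT")
    }
  }
  pocket
}

#' Gas pocket state at a prescribed contact radius
#'
#' Constructs the (generally non-equilibrium) state of a pocket of gas
#' content `nRT` whose contact line sits at radius `s`: gas pressure is
#' `nRT/V(s)` by the isothermal gas law; the Young-Laplace balance need not
#' hold. Used for perturbation analysis around an equilibrium.
#'
#' @param s Contact radius (m), positive.
#' @inheritParams cubic_coefficients
#' @return A `gas_pocket` object with `equilibrium = FALSE`.
#' @export
pocket_at <- function(s, system, cavity, nRT) {
  check_scalar_positive(s, "s")
  check_scalar_positive(nRT, "nRT")
  new_gas_pocket(s, system, cavity, nRT, equilibrium = FALSE)
}

#' @export
print.gas_pocket <- function(x, ...) {
  cat(sprintf(
    "<gas_pocket>%s s = %.4g mm, p_g = %.4g Pa, V = %.4g mm^3, H = %.4g 1/m%s\n",
    if (x$equilibrium) " [equilibrium]" else "",
    1e3 * x$s, x$p_g, 1e9 * x$V, x$H,
    if (x$overfilled) " (overfilled: s > s_c)" else ""))
  invisible(x)
}

#' Equilibrium contact radius of the gas/liquid interface
#'
#' Solves the cubic `p_l C s^3 + 2 sigma cos(theta-eps) C s^2 - nRT = 0`
#' for the contact radius. For `p_l > 0` the cubic has exactly one positive
#' real root (an error is raised if that is violated numerically). For
#' `p_l <= 0` — the xylem tension regime — all positive real roots are
#' returned, for downstream stability classification. Roots with
#' non-positive gas pressure are reported as unphysical and excluded; roots
#' with `s > s_c` are flagged `overfilled`, never clamped.
#'
#' @inheritParams cubic_coefficients
#' @return Object of class `equilibrium_report` with fields
#'   \describe{
#'     \item{exists}{`TRUE` if at least one physical equilibrium was found.}
#'     \item{pockets}{list of `gas_pocket` objects (equilibria).}
#'     \item{excluded_unphysical}{radii of formal roots with `p_g <= 0`.}
#'     \item{notes}{character diagnostics.}
#'   }
#'   Non-existence is a valid result, not an error: a system that admits no
#'   interface simply floods the cavity.
#' @export
#' @examples
#' sys <- fluid_solid_system(1.6, 7000, theta = 135, p_l = 1e5, degrees = TRUE)
#' cav <- cone_cavity(45, s_c = 2.5e-3, degrees = TRUE)
#' equilibrium_radius(sys, cav, nRT = (pi / 3) * 1e5 * 1e-9)  # s = 1 mm, flat
equilibrium_radius <- function(system, cavity, nRT) {
  roots <- positive_real_roots(system, cavity, nRT)
  if (system$p_l > 0 && length(roots) != 1) {
    stop(sprintf(
      "expected exactly one positive real root for p_l > 0, found %d",
      length(roots)))
  }
  cd <- cos(system$theta - cavity$epsilon)
  pockets <- list()
  excluded <- numeric(0)
  notes <- character(0)
  for (s in roots) {
    p_g <- system$p_l + 2 * system$sigma * cd / s
    if (p_g <= 0) {
      excluded <- c(excluded, s)
      notes <- c(notes, sprintf(
        "root s = %.6g m excluded: formal gas pressure %.4g Pa is unphysical",
        s, p_g))
      next
    }
    pk <- new_gas_pocket(s, system, cavity, nRT, equilibrium = TRUE)
    if (pk$overfilled) {
      notes <- c(notes, sprintf(
        "root s = %.6g m exceeds s_c = %.6g m: gas content overfills the cavity",
        s, cavity$s_c))
    }
    pockets <- c(pockets, list(pk))
  }
  if (length(pockets) == 0) {
    notes <- c(notes,
               "no gas/liquid interface: the system does not admit an equilibrium")
  }
  structure(
    list(exists = length(pockets) > 0, pockets = pockets,
         excluded_unphysical = excluded, notes = notes,
         system = system, cavity = cavity, nRT = nRT),
    class = "equilibrium_report"
  )
}

#' @export
print.equilibrium_report <- function(x, ...) {
  cat(sprintf("<equilibrium_report> %d equilibrium pocket(s)\n",
              length(x$pockets)))
  for (pk in x$pockets) print(pk)
  for (nt in x$notes) cat(" note:", nt, "\n")
  invisible(x)
}

#' Young--Laplace residual of a pocket state
#'
#' `p_g - p_l - 2 sigma H` with `p_g = nRT/V(s)`. Zero (to tolerance) at an
#' equilibrium; non-zero for a perturbed state, with sign indicating the
#' direction of the net restoring pressure.
#'
#' @param pocket A `gas_pocket` (from [equilibrium_radius()] or [pocket_at()]).
#' @return Residual pressure in Pa.
#' @export
young_laplace_residual <- function(pocket) {
  pocket$p_g - pocket$system$p_l - 2 * pocket$system$sigma * pocket$H
}
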