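# Closed-form geometry of a spherical-cap gas/liquid interface pinned on the
# wall of a conical cavity. All internal computation is SI (metres, radians).

# epsilon is kept away from 0 and pi/2 so cot(eps) and 1/sin(eps) stay finite
.EPSILON_MIN <- 1e-6
.EPSILON_MAX <- pi / 2 - 1e-6
# below this |cos(theta - epsilon)| the cap term of the volume is evaluated by
# its analytic limit (it vanishes as O(delta); see the methods vignette)
.FLAT_COS_TOL <- 1e-8

#' Default numerical tolerances
#'
#' The fixed tolerances used throughout the package for equilibrium residuals,
#' root filtering and finite-difference cross-checks.
#'
#' @return Named list of tolerances:
#' \describe{
#'   \item{gas_law_rel}{relative tolerance on `p_g * V = nRT` at equilibrium.}
#'   \item{young_laplace_rel}{relative tolerance on the Young--Laplace residual.}
#'   \item{root_imag_rel}{relative imaginary-part threshold below which a
#'     complex cubic root is accepted as real.}
#'   \item{dHdV_fd_rel}{relative agreement required between analytic and
#'     finite-difference dH/dV.}
#'   \item{fd_step_rel}{relative step used for finite differences in `s`.}
#'   \item{flat_cos}{|cos(theta - epsilon)| below which the interface is
#'     treated as flat.}
#' }
#' @export
#' @examples
#' default_tolerances()$gas_law_rel
default_tolerances <- function() {
  list(
    gas_law_rel      = 1e-9,
    young_laplace_rel = 1e-6,
    root_imag_rel    = 1e-9,
    dHdV_fd_rel      = 1e-4,
    fd_step_rel      = 1e-6,
    flat_cos         = .FLAT_COS_TOL
  )
}

## ---- error helpers ---------------------------------------------------------

stop_domain <- function(param, msg) {
  cnd <- structure(
    class = c("cp_domain_error", "error", "condition"),
    list(message = sprintf("invalid `%s`: %s", param, msg), call = sys.call(-1),
         param = param)
  )
  stop(cnd)
}

check_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop_domain(name, "must be finite and > 0")
  }
  invisible(x)
}

check_theta <- function(theta, name = "theta") {
  if (!is.numeric(theta) || any(!is.finite(theta)) ||
      any(theta < 0) || any(theta > pi)) {
    stop_domain(name, "contact angle must lie in [0, pi] radians")
  }
  invisible(theta)
}

check_epsilon <- function(epsilon, name = "epsilon") {
  if (!is.numeric(epsilon) || any(!is.finite(epsilon)) ||
      any(epsilon < .EPSILON_MIN) || any(epsilon > .EPSILON_MAX)) {
    stop_domain(name, sprintf(
      "acute cone angle must lie in [%g, pi/2 - %g] radians",
      .EPSILON_MIN, 1e-6))
  }
  invisible(epsilon)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## ---- domain types ----------------------------------------------------------

#' Conical surface cavity
#'
#' One cone-shaped recess, defined by its acute half-opening angle `epsilon`
#' (measured between the cone wall and the cone axis, so
#' `tan(epsilon) = mouth radius / depth`) and the radius `s_c` of the cone
#' mouth at the flat surface.
#'
#' @param epsilon Acute cone angle, in radians unless `degrees = TRUE`.
#'   Restricted to the open interval (0, pi/2).
#' @param s_c Mouth radius in metres; must be positive.
#' @param degrees If `TRUE`, `epsilon` is given in degrees.
#' @return An object of class `cone_cavity` with fields `epsilon`, `s_c`
#'   and the derived `depth = s_c / tan(epsilon)`.
#' @export
#' @examples
#' cone_cavity(30, s_c = 2.5e-3, degrees = TRUE)  # the tuyere prototype cone
cone_cavity <- function(epsilon, s_c, degrees = FALSE) {
  if (isTRUE(degrees)) epsilon <- deg2rad(epsilon)
  check_epsilon(epsilon)
  check_scalar_positive(s_c, "s_c")
  structure(
    list(epsilon = epsilon, s_c = s_c, depth = s_c / tan(epsilon)),
    class = "cone_cavity"
  )
}

#' @export
print.cone_cavity <- function(x, ...) {
  cat(sprintf(
    "<cone_cavity> epsilon = %.4g deg, s_c = %.4g mm, depth = %.4g mm\n",
    rad2deg(x$epsilon), 1e3 * x$s_c, 1e3 * x$depth))
  invisible(x)
}

#' Xylem pit chamber (double funnel)
#'
#' The pore connecting two xylem conduits resembles two funnels joined at
#' their wide ends; each half is a truncated cone (the pit chamber) whose
#' narrow end (the pit channel) opens into a conduit.
#'
#' @param chamber_half_angle Half-opening angle of the funnel wall measured
#'   from the pore axis, radians unless `degrees = TRUE`.
#' @param chamber_radius Radius of the wide end (m).
#' @param channel_radius Radius of the narrow channel (m); must be strictly
#'   smaller than `chamber_radius`.
#' @param degrees If `TRUE`, the angle is given in degrees.
#' @return An object of class `pit_chamber`.
#' @seealso [pit_to_cone()]
#' @export
pit_chamber <- function(chamber_half_angle, chamber_radius, channel_radius,
                        degrees = FALSE) {
  if (isTRUE(degrees)) chamber_half_angle <- deg2rad(chamber_half_angle)
  check_epsilon(chamber_half_angle, "chamber_half_angle")
  check_scalar_positive(chamber_radius, "chamber_radius")
  check_scalar_positive(channel_radius, "channel_radius")
  if (channel_radius >= chamber_radius) {
    stop_domain("channel_radius", "must be smaller than chamber_radius")
  }
  structure(
    list(chamber_half_angle = chamber_half_angle,
         chamber_radius = chamber_radius,
         channel_radius = channel_radius),
    class = "pit_chamber"
  )
}

#' @export
print.pit_chamber <- function(x, ...) {
  cat(sprintf(
    "<pit_chamber> half angle = %.4g deg, chamber radius = %.4g um, channel radius = %.4g um\n",
    rad2deg(x$chamber_half_angle), 1e6 * x$chamber_radius,
    1e6 * x$channel_radius))
  invisible(x)
}

#' Map a pit chamber to its equivalent cone
#'
#' Only the wide chamber part of a pit funnel is functional for interface
#' formation; elongating the tilted chamber walls to a point closes the
#' funnel into a simple cone. The narrow pit channel is discarded (its
#' possible contribution to trapped gas volume is not modelled).
#'
#' @param pit A [pit_chamber()] object.
#' @return A [cone_cavity()] with `epsilon = chamber_half_angle` and
#'   `s_c = chamber_radius`.
#' @export
pit_to_cone <- function(pit) {
  if (!inherits(pit, "pit_chamber")) {
    stop_domain("pit", "must be a pit_chamber object")
  }
  cone_cavity(pit$chamber_half_angle, pit$chamber_radius)
}

## ---- interface geometry ----------------------------------------------------

# Shape coefficient C(theta, epsilon) = V / s^3: cone term plus spherical-cap
# term. The cap term has a removable 0/0 singularity at |theta - epsilon| =
# pi/2 where it vanishes; evaluated by that limit when |cos| < .FLAT_COS_TOL.
cone_shape_coefficient <- function(theta, epsilon) {
  delta <- theta - epsilon
  cd <- cos(delta)
  sd <- sin(delta)
  cap <- ifelse(abs(cd) < .FLAT_COS_TOL, 0, (1 - sd)^2 * (2 + sd) / cd^3)
  co <- (pi / 3) * (1 / tan(epsilon) + cap)
  if (any(co <= 0)) {
    stop_domain("theta/epsilon",
                "degenerate geometry: enclosed gas volume would be non-positive")
  }
  co
}

#' Gas volume under a spherical-cap interface in a cone
#'
#' Volume enclosed between the cone apex, the cone wall up to the contact
#' circle of radius `s`, and the spherical-cap interface that meets the wall
#' at contact angle `theta`:
#' `V = (pi/3) s^3 [cot(eps) + (1 - sin d)^2 (2 + sin d) / cos^3 d]` with
#' `d = theta - epsilon`. The cap term vanishes in the flat-interface limit
#' `|theta - epsilon| = 90` degrees, leaving the pure cone volume.
#'
#' @param s Contact-circle radius (m), positive; may be a vector.
#' @param theta Contact angle (rad), in `[0, pi]`.
#' @param epsilon Acute cone angle (rad), in `(0, pi/2)`.
#' @return Gas volume in cubic metres, strictly positive and strictly
#'   increasing in `s`.
#' @export
#' @examples
#' cap_volume(1e-3, theta = 3 * pi / 4, epsilon = pi / 4)  # (pi/3) * 1e-9
cap_volume <- function(s, theta, epsilon) {
  check_scalar_positive(s, "s")
  check_theta(theta)
  check_epsilon(epsilon)
  s^3 * cone_shape_coefficient(theta, epsilon)
}

#' Signed mean curvature of the cap interface
#'
#' `H = cos(theta - epsilon) / s`. Positive for a convex interface
#' (`H = 1/R`, gas bulging into the liquid), negative for a concave one
#' (`H = -1/R`), zero exactly when `theta - epsilon = 90` degrees.
#'
#' @inheritParams cap_volume
#' @return Mean curvature in 1/m.
#' @export
cap_curvature <- function(s, theta, epsilon) {
  check_scalar_positive(s, "s")
  check_theta(theta)
  check_epsilon(epsilon)
  cos(theta - epsilon) / s
}

#' Interface and wetted-wall areas
#'
#' Area of the liquid/gas cap `A_lg = 2 pi s^2 / (1 + sin(theta - epsilon))`
#' and of the solid/gas cone wall `A_sg = pi s^2 / sin(epsilon)` (the lateral
#' cone area `pi * s * slant` with slant height `s / sin(epsilon)`).
#'
#' @inheritParams cap_volume
#' @return Named list with components `A_lg` and `A_sg` (square metres).
#' @export
interface_areas <- function(s, theta, epsilon) {
  check_scalar_positive(s, "s")
  check_theta(theta)
  check_epsilon(epsilon)
  den <- 1 + sin(theta - epsilon)
  if (any(den <= .FLAT_COS_TOL)) {
    stop_domain("theta", "1 + sin(theta - epsilon) must be positive")
  }
  list(A_lg = 2 * pi * s^2 / den, A_sg = pi * s^2 / sin(epsilon))
}

#' Full geometric state of a pinned cap
#'
#' Bundles contact radius, angles, gas volume, signed curvature and the two
#' interface areas into one object.
#'
#' @inheritParams cap_volume
#' @return An object of class `cap_state` with fields `s`, `theta`,
#'   `epsilon`, `V`, `H`, `A_lg`, `A_sg`.
#' @export
cap_state <- function(s, theta, epsilon) {
  areas <- interface_areas(s, theta, epsilon)
  structure(
    list(s = s, theta = theta, epsilon = epsilon,
         V = cap_volume(s, theta, epsilon),
         H = cap_curvature(s, theta, epsilon),
         A_lg = areas$A_lg, A_sg = areas$A_sg),
    class = "cap_state"
  )
}

#' @export
print.cap_state <- function(x, ...) {
  cat(sprintf(
    "<cap_state> s = %.4g mm, V = %.4g mm^3, H = %.4g 1/m (%s)\n",
    1e3 * x$s, 1e9 * x$V, x$H,
    if (abs(x$H) < .Machine$double.eps * 10 / x$s) "flat"
    else if (x$H > 0) "convex" else "concave"))
  invisible(x)
}
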