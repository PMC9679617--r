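# Independent numerical oracles used by the tests. These deliberately avoid
# the package's closed-form volume/root paths.

deg <- function(x) x * pi / 180

# Solid-of-revolution quadrature for the gas volume: cone integrated in z,
# spherical cap integrated along the axis from the contact-circle plane.
quad_volume <- function(s, theta, epsilon, rel.tol = 1e-10) {
  delta <- theta - epsilon
  cd <- cos(delta)
  zc <- s / tan(epsilon)
  vcone <- stats::integrate(function(z) pi * (z * tan(epsilon))^2, 0, zc,
                            rel.tol = rel.tol)$value
  if (abs(cd) < 1e-12) return(vcone)
  R <- s / abs(cd)
  u0 <- -R * sin(delta)            # sphere centre, measured from the plane
  h <- R * (1 - sin(delta))        # cap height along the bulge direction
  vcap <- stats::integrate(function(u) pi * (R^2 - (u - u0)^2), 0, h,
                           rel.tol = rel.tol, abs.tol = 0)$value
  vcone + sign(cd) * vcap
}

# Gas-law defect p_g(s) V(s) - nRT, assembled from exported primitives only
gas_defect <- function(s, system, cavity, nRT) {
  (system$p_l + 2 * system$sigma * cos(system$theta - cavity$epsilon) / s) *
    cap_volume(s, system$theta, cavity$epsilon) - nRT
}

# Bracketing-scan root oracle: sign changes of the defect on a dense log grid.
# The scan window is widened until it provably contains every positive root:
# for p_l > 0 the defect is eventually positive; for p_l <= 0 any root needs
# p_l * s + 2 * sigma * cos(theta - epsilon) > 0, which bounds s above.
scan_roots <- function(system, cavity, nRT, s_max = NULL, n = 8000) {
  if (is.null(s_max)) {
    cd <- cos(system$theta - cavity$epsilon)
    s_max <- 10 * cavity$s_c
    if (system$p_l > 0) {
      while (gas_defect(s_max, system, cavity, nRT) <= 0) s_max <- 2 * s_max
    } else if (cd > 0) {
      s_max <- max(s_max, 2.01 * system$sigma * cd / abs(system$p_l))
    }
  }
  grid <- exp(seq(log(s_max * 1e-7), log(s_max), length.out = n))
  f <- vapply(grid, gas_defect, numeric(1), system = system,
              cavity = cavity, nRT = nRT)
  idx <- which(f[-1] * f[-n] < 0)
  roots <- vapply(idx, function(i) {
    stats::uniroot(gas_defect, c(grid[i], grid[i + 1]), system = system,
                   cavity = cavity, nRT = nRT, tol = 1e-15)$root
  }, numeric(1))
  exact <- grid[f == 0]
  sort(c(roots, exact))
}

# indices of interior local minima / stationary sign changes of a profile
interior_minima <- function(E) {
  n <- length(E)
  which(E[2:(n - 1)] < E[1:(n - 2)] & E[2:(n - 1)] < E[3:n]) + 1
}

stationary_points <- function(s, E) {
  dE <- diff(E)
  idx <- which(dE[-1] * dE[-length(dE)] <= 0 &
                 (dE[-1] != 0 | dE[-length(dE)] != 0)) + 1
  s[idx]
}

# deterministic positive-pressure equilibrium scenarios on a seeded grid,
# spanning both curvature signs while staying away from the flat degeneracy
random_equilibria <- function(n, seed, cos_min = 0) {
  set.seed(seed)
  out <- vector("list", n)
  i <- 1
  while (i <= n) {
    theta <- runif(1, deg(5), deg(175))
    epsilon <- runif(1, deg(2), deg(88))
    if (abs(cos(theta - epsilon)) <= cos_min) next
    sys <- fluid_solid_system(runif(1, 0.05, 2), runif(1, 800, 8000),
                              theta, runif(1, 1e4, 5e5))
    cav <- cone_cavity(epsilon, runif(1, 5e-4, 5e-3))
    s_t <- runif(1, 0.2, 0.9) * cav$s_c
    p_g <- sys$p_l + 2 * sys$sigma * cos(theta - epsilon) / s_t
    if (p_g <= 0) next
    nRT <- p_g * cap_volume(s_t, theta, epsilon)
    out[[i]] <- list(system = sys, cavity = cav, nRT = nRT, s_target = s_t)
    i <- i + 1
  }
  out
}
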