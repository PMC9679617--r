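test_that("flat-interface stability reduces to the gas compression term", {
  sys <- fluid_solid_system(1.6, 7000, 135, p_l = 1e5, degrees = TRUE)
  cav <- cone_cavity(45, 3e-3, degrees = TRUE)
  eq <- equilibrium_radius(sys, cav, nRT = (pi / 3) * 1e5 * 1e-9)
  pk <- eq$pockets[[1]]
  st <- stability_psi(pk)
  expect_equal(st$psi, pk$p_g / pk$V, tolerance = 1e-10)
  expect_true(st$stable)
})

test_that("analytic dH/dV matches central finite differences", {
  scens <- random_equilibria(100, seed = 17, cos_min = 0.02)
  for (sc in scens) {
    pk <- equilibrium_radius(sc$system, sc$cavity, sc$nRT)$pockets[[1]]
    st <- stability_psi(pk)
    expect_equal(st$dH_dV_analytic, st$dH_dV_numeric, tolerance = 1e-4)
  }
})

test_that("cone equilibria under positive liquid pressure are stable for both curvature signs", {
  scens <- random_equilibria(150, seed = 23)
  signs <- integer(0)
  for (sc in scens) {
    pk <- equilibrium_radius(sc$system, sc$cavity, sc$nRT)$pockets[[1]]
    st <- stability_psi(pk)
    expect_gt(st$psi, 0)
    expect_true(st$stable)
    signs <- c(signs, sign(pk$H))
  }
  expect_true(any(signs > 0) && any(signs < 0))
})

test_that("capillary length reproduces printed constants and scales correctly", {
  expect_equal(1e3 * capillary_length(1.6, 7000, 9.81), 4.8, tolerance = 0.1 / 4.8)
  expect_equal(capillary_length(9.81 * 1234, 1234, 9.81), 1, tolerance = 1e-12)
  expect_equal(1e3 * capillary_length(0.0728, 998, 9.81), 2.7, tolerance = 0.02)
  # homogeneity: degree 1/2 in sigma, -1/2 in rho*g
  lc <- capillary_length(0.5, 2000, 9.81)
  expect_equal(capillary_length(0.5 * 9, 2000, 9.81), 3 * lc, tolerance = 1e-12)
  expect_equal(capillary_length(0.5, 2000 * 4, 9.81), lc / 2, tolerance = 1e-12)
  expect_error(capillary_length(-1, 1000), class = "cp_domain_error")
  # a system object is accepted directly
  sys <- fluid_solid_system(1.6, 7000, 130, 1e5, degrees = TRUE)
  expect_equal(capillary_length(sys), capillary_length(1.6, 7000, 9.81))
})

test_that("formation energy cancels exactly on the criterion boundary", {
  for (ep in deg(c(5, 20, 40, 60, 80))) {
    s <- 1.5e-3
    sys <- fluid_solid_system(1.6, 7000, ep + pi / 2, 1e5)
    en <- formation_energy(s, sys, cone_cavity(ep, s))
    expect_lt(abs(en$delta_E), 1e-12 * sys$sigma * s^2)
    expect_equal(en$delta_E_lg, sys$sigma * pi * s^2, tolerance = 1e-12)
    expect_equal(en$delta_E_sg, -sys$sigma * pi * s^2, tolerance = 1e-10)
  }
})

test_that("formation energy components sum and the sign follows the persistence criterion", {
  # prototype regime: pocket favourable
  sys_hi <- fluid_solid_system(1.6, 7000, 130, 1e5, degrees = TRUE)
  en <- formation_energy(2.5e-3, sys_hi, cone_cavity(30, 2.5e-3, degrees = TRUE))
  expect_lt(en$delta_E, 0)
  expect_true(en$ferrophobic)
  # iron on bare copper wets for every cone angle
  sys_lo <- fluid_solid_system(1.6, 7000, 37, 1e5, degrees = TRUE)
  for (ep in deg(seq(5, 85, by = 10))) {
    en_i <- formation_energy(1e-3, sys_lo, cone_cavity(ep, 1e-3))
    expect_gt(en_i$delta_E, 0)
    expect_false(en_i$ferrophobic)
  }
  # random checks: components sum; value matches the independently derived
  # closed form sigma * C * s^2 * cos(theta - epsilon)
  set.seed(2)
  for (i in 1:40) {
    th <- runif(1, deg(5), deg(175)); ep <- runif(1, deg(2), deg(88))
    s <- runif(1, 1e-4, 4e-3)
    sys <- fluid_solid_system(runif(1, 0.05, 2), 7000, th, 1e5)
    en_i <- formation_energy(s, sys, cone_cavity(ep, s))
    expect_equal(en_i$delta_E,
                 en_i$delta_E_V + en_i$delta_E_lg + en_i$delta_E_sg,
                 tolerance = 1e-12)
    closed <- sys$sigma * (cap_volume(s, th, ep) / s^3) * s^2 * cos(th - ep)
    expect_equal(en_i$delta_E, closed, tolerance = 1e-10)
    expect_identical(en_i$ferrophobic, ferrophobicity_criterion(th, ep))
  }
  expect_error(formation_energy(2e-3, sys_hi, cone_cavity(30, 1e-3, degrees = TRUE)),
               class = "cp_domain_error")
})

test_that("persistence criterion and admissible interval agree with the angle algebra", {
  expect_true(ferrophobicity_criterion(130, 30, degrees = TRUE))
  expect_false(ferrophobicity_criterion(130, 40, degrees = TRUE))  # boundary excluded
  expect_false(ferrophobicity_criterion(37, 1, degrees = TRUE))
  iv <- admissible_cone_angles(130, degrees = TRUE)
  expect_false(iv$empty)
  expect_equal(iv$upper, 40, tolerance = 1e-12)
  expect_true(admissible_cone_angles(90, degrees = TRUE)$empty)
  expect_true(admissible_cone_angles(45, degrees = TRUE)$empty)
  iv180 <- admissible_cone_angles(180, degrees = TRUE)
  expect_equal(iv180$upper, 90, tolerance = 1e-12)
})

test_that("energy profile is stationary at the equilibrium and gauge invariant", {
  sys <- fluid_solid_system(1.6, 7000, 135, p_l = 1e5, degrees = TRUE)
  cav <- cone_cavity(45, 3e-3, degrees = TRUE)
  nRT <- (pi / 3) * 1e5 * 1e-9
  s_grid <- seq(3e-3 / 1e4, 3e-3, length.out = 1e4)
  prof <- energy_profile(sys, cav, nRT, s_grid)
  i_min <- which.min(prof$E_total)
  expect_lt(abs(prof$s[i_min] - 1e-3), diff(s_grid[1:2]) * 1.5)
  # adding a constant reference offset does not move the minimum
  prof2 <- energy_profile(sys, cav, nRT, s_grid, offset = 1)
  expect_identical(which.min(prof2$E_total), i_min)
  expect_equal(prof2$E_total - prof$E_total, rep(1, nrow(prof)),
               tolerance = 1e-9)
})

test_that("a system without equilibrium roots has a monotone energy profile", {
  sys <- fluid_solid_system(0.0728, 998, 130, p_l = -1.5e6, degrees = TRUE)
  cav <- cone_cavity(30, 5e-6, degrees = TRUE)
  nRT <- 1e-15
  expect_false(equilibrium_radius(sys, cav, nRT)$exists)
  s_grid <- seq(5e-6 / 2e3, 3 * 5e-6, length.out = 4e3)
  prof <- energy_profile(sys, cav, nRT, s_grid)
  expect_length(interior_minima(prof$E_total), 0)
})

test_that("stable classification coincides with local minima of the energy profile", {
  scens <- random_equilibria(12, seed = 41)
  for (sc in scens) {
    pk <- equilibrium_radius(sc$system, sc$cavity, sc$nRT)$pockets[[1]]
    st <- stability_psi(pk)
    s_grid <- seq(pk$s * 0.2, pk$s * 2, length.out = 4001)
    prof <- energy_profile(sc$system, sc$cavity, sc$nRT, s_grid)
    mins <- prof$s[interior_minima(prof$E_total)]
    near <- any(abs(mins - pk$s) <= diff(s_grid[1:2]))
    expect_identical(st$stable, near)
  }
})

test_that("stability analysis refuses unphysical gas pressure", {
  sys <- fluid_solid_system(0.0728, 998, 20, p_l = -5e5, degrees = TRUE)
  cav <- cone_cavity(25, 5e-6, degrees = TRUE)
  pk <- pocket_at(4e-6, sys, cav, nRT = 1e-16)
  # force a formally negative gas pressure state
  pk$p_g <- -1
  expect_error(stability_psi(pk), "unphysical")
})
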