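test_that("effective viscosity follows the pore-size dependent law", {
  p0 <- gel_params(eta = 1000, zeta = 0, tau_a = 100, R_L = 1e-5)
  # R = 0: the quadratic term vanishes
  expect_equal(effective_viscosity(p0, 0), 1000)
  # zeta = 0 at the contact radius doubles the viscosity
  expect_equal(effective_viscosity(p0, 1e-5), 2000)
  # direct evaluation with density coupling, both signs
  pm <- gel_params(eta = 1000, zeta = -2, rho0 = 1, tau_a = 100, R_L = 1e-5)
  expect_equal(effective_viscosity(pm, 1e-5), 2400)
  pp <- gel_params(eta = 1000, zeta = 2, rho0 = 1, tau_a = 100, R_L = 1e-5)
  expect_equal(effective_viscosity(pp, 1e-5), 1600)
  expect_lt(effective_viscosity(pp, 1e-5), effective_viscosity(pm, 1e-5))
  # floor: strongly fluidized combinations are rejected as unphysical
  pbad <- gel_params(eta = 100, zeta = 2, tau_a = 100, R_L = 1e-5)
  expect_error(effective_viscosity(pbad, 1e-5), "unphysical")
  expect_error(effective_viscosity(p0, 2e-5), "R_L")
})

test_that("opening rate and critical radius agree with hand evaluation", {
  p <- gel_params(eta = 1000, sigma0 = 1, zeta = 0, tau_a = 100,
                  gamma = 1e-4, f_adh = 1e7, R_L = 1e-5)
  # hand evaluation: numerator (1 + 66.67 Pa)*5e-6 - 2e-4, eta_eff = 1250
  expect_equal(pore_opening_rate(p, 5e-6), 1.106667e-7, tolerance = 1e-6)
  # critical radius 6e-4 / 203 Pa
  expect_equal(critical_radius(p), 6e-4 / 203, tolerance = 1e-12)
  # gamma = 0 gives R_c = 0; doubling gamma doubles R_c
  expect_equal(critical_radius(with_params(p, gamma = 0)), 0)
  expect_equal(critical_radius(with_params(p, gamma = 2e-4)),
               2 * critical_radius(p))
  # rate vanishes at the critical radius, and a large tension seals
  expect_equal(pore_opening_rate(p, critical_radius(p)), 0,
               tolerance = 1e-15)
  expect_lt(pore_opening_rate(with_params(p, gamma = 1e-2), 5e-6), 0)
})

test_that("critical adhesion inverts the critical radius and clamps at zero", {
  p <- gel_params(eta = 1000, sigma0 = 0, gamma = 1e-4, f_adh = 0,
                  R_L = 1e-5)
  # derived: (6e-4 / 3e-6) / 2e-5
  expect_equal(critical_adhesion(p, 3e-6), 1e7)
  # substituting back reproduces R_init
  f_c <- critical_adhesion(p, 3e-6)
  expect_equal(critical_radius(with_params(p, f_adh = f_c)), 3e-6,
               tolerance = 1e-12)
  # clamp when the active stress alone suffices
  p3 <- gel_params(eta = 1000, sigma0 = 100, gamma = 1e-7, R_L = 1e-5)
  expect_equal(critical_adhesion(p3, 5e-6), 0)
  expect_error(critical_adhesion(p, -1), "R_init")
})

test_that("simulate_pore matches a fine-step RK4 oracle and handles events", {
  p <- liposome_params("actin")
  R_c <- critical_radius(p)
  # opening regime: strictly increasing, terminates at the contact radius
  tg <- seq(0, 600, length.out = 301)
  traj <- simulate_pore(p, 1.1 * R_c, tg)
  expect_true(traj$terminated)
  expect_true(all(diff(traj$radii) > 0))
  expect_equal(max(traj$radii), p$R_L, tolerance = 1e-6)
  # agreement with the independent fixed-step oracle at the output times
  tg_fine <- seq(0, max(traj$times), length.out = 16001)
  oracle <- rk4_pore(p, 1.1 * R_c, tg_fine)
  oracle_at <- stats::approx(tg_fine, oracle, xout = traj$times)$y
  expect_lt(max(abs(traj$radii - oracle_at) / oracle_at), 1e-3)
  # sealing regime: strictly decreasing toward zero
  tg_dn <- seq(0, 2000, length.out = 201)
  traj_dn <- simulate_pore(p, 0.9 * R_c, tg_dn)
  expect_true(all(diff(traj_dn$radii) < 0))
  tg_dn_fine <- seq(0, 2000, length.out = 16001)
  oracle_dn <- rk4_pore(p, 0.9 * R_c, tg_dn_fine)
  oracle_dn_at <- stats::approx(tg_dn_fine, oracle_dn,
                                xout = traj_dn$times)$y
  expect_lt(max(abs(traj_dn$radii - oracle_dn_at)) / (0.9 * R_c), 1e-3)
  # a pore started exactly at the fixed point stays there
  traj_fp <- simulate_pore(p, R_c, seq(0, 200, length.out = 51))
  expect_lt(max(abs(traj_fp$radii - R_c)) / R_c, 1e-6)
  expect_error(simulate_pore(p, 2 * p$R_L, tg), "R_init")
})

test_that("time-rescaling: with no active terms doubling eta doubles times", {
  base <- gel_params(eta = 500, sigma0 = 0, zeta = 0, tau_a = 100,
                     gamma = 1e-5, f_adh = 1e7, R_L = 1e-5)
  dbl <- with_params(base, eta = 1000)
  tg <- seq(0, 400, length.out = 2001)
  tr1 <- simulate_pore(base, 5e-7, tg)
  tr2 <- simulate_pore(dbl, 5e-7, seq(0, 800, length.out = 2001))
  # time to reach a set of probe radii doubles exactly
  for (Rp in c(1e-6, 3e-6, 8e-6)) {
    t1 <- stats::approx(tr1$radii, tr1$times, xout = Rp)$y
    t2 <- stats::approx(tr2$radii, tr2$times, xout = Rp)$y
    expect_equal(t2 / t1, 2, tolerance = 1e-5)
  }
})

test_that("phase diagram labels flip exactly across the fixed-point curve", {
  p <- liposome_params("actin")
  f_grid <- seq(1e5, 3e7, length.out = 15)
  R_grid <- seq(1e-8, p$R_L * 0.99, length.out = 25)
  pd <- phase_diagram(p, f_grid, R_grid)
  # R_c decreases monotonically with adhesion
  expect_true(all(diff(pd$R_c) < 0))
  # exhaustive oracle: sign of the printed rate at every grid point
  for (j in seq_along(f_grid)) {
    pj <- with_params(p, f_adh = f_grid[j])
    for (i in seq_along(R_grid)) {
      rate <- pore_opening_rate(pj, R_grid[i])
      want <- if (abs(rate) <= 1e-18) "stalls"
              else if (rate > 0) "opens_to_rupture" else "seals"
      expect_identical(pd$regime[i, j], want)
    }
    # labels flip from seals to opens exactly at R_c(f_adh)
    below <- R_grid < pd$R_c[j]
    expect_true(all(pd$regime[below, j] == "seals"))
    expect_true(all(pd$regime[!below & R_grid > pd$R_c[j], j] ==
                      "opens_to_rupture"))
  }
  expect_error(phase_diagram(p, numeric(0), R_grid), "non-empty")
})

test_that("fixed-point analysis classifies the three regimes", {
  p <- liposome_params("actin")
  fp <- fixed_points(p)
  expect_equal(fp$regime, "opens_to_rupture")
  expect_equal(fp$stable_radius, p$R_L)
  fp2 <- fixed_points(with_params(p, gamma = 1e-2))
  expect_equal(fp2$regime, "seals")
  expect_equal(fp2$stable_radius, 0)
})

test_that("pore trajectories round-trip through CSV", {
  p <- liposome_params("bare")
  traj <- simulate_pore(p, 5e-7, seq(0, 100, length.out = 101))
  f <- tempfile(fileext = ".csv")
  write_pore_trajectory(traj, f)
  back <- read_pore_trajectory(f)
  expect_equal(back$radii, traj$radii, tolerance = 1e-12)
  expect_identical(back$terminated, traj$terminated)
  header <- readLines(f, n = 1)
  expect_match(header, "t_s", fixed = TRUE)
  expect_match(header, "R_m", fixed = TRUE)
})
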