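test_that("box edge follows from molecule count and density", {
  # independent closed form: V = n M / (N_A rho), L = V^(1/3)
  L <- (400 * 18.0153 / (6.02214076e23 * 0.997))^(1 / 3) * 1e7
  expect_equal(box_edge_from_density(400, 0.997), L)
  expect_equal(L, 2.289, tolerance = 1e-3)
})

test_that("initial configurations are gas-phase molecules without clashes", {
  pp <- potential_params()
  fr <- build_initial_configuration(2, 0.001, seed = 9, params = pp)
  for (m in 0:1) {
    o <- fr$positions[3 * m + 1, ]
    h1 <- fr$positions[3 * m + 2, ]
    h2 <- fr$positions[3 * m + 3, ]
    d1 <- minimum_image_displacement(o, h1, fr$box)
    d2 <- minimum_image_displacement(o, h2, fr$box)
    expect_equal(sqrt(sum(d1^2)), pp$r_e, tolerance = 1e-10)
    expect_equal(sqrt(sum(d2^2)), pp$r_e, tolerance = 1e-10)
    ang <- acos(sum(d1 * d2) / (pp$r_e^2)) * 180 / pi
    expect_equal(ang, pp$theta_e, tolerance = 1e-8)
  }
  fr2 <- build_initial_configuration(24, 0.997, seed = 4)
  o_idx <- 3 * (1:24 - 1) + 1
  omat <- fr2$positions[o_idx, ]
  dmin <- Inf
  for (i in 1:23) for (j in (i + 1):24) {
    d <- minimum_image_displacement(omat[i, ], omat[j, ], fr2$box)
    dmin <- min(dmin, sqrt(sum(d^2)))
  }
  expect_gte(dmin, 0.24)
  # determinism
  expect_identical(build_initial_configuration(24, 0.997, seed = 4)$positions,
                   fr2$positions)
  expect_error(build_initial_configuration(8, 20, seed = 1), "packing")
})

test_that("Boltzmann velocities have the right variance and zero momentum", {
  fr <- build_initial_configuration(334, 0.997, seed = 2)  # ~1000 sites
  fr <- sample_boltzmann_velocities(fr, 300, seed = 3)
  m <- site_masses(334)
  mom <- colSums(fr$velocities * m)
  p_site <- mean(sqrt(rowSums(fr$velocities^2)) * m)
  expect_lt(max(abs(mom)), 1e-12 * p_site)
  # kinetic energy per degree of freedom -> kB T / 2 within 5%
  ke <- 0.5 * sum(m * rowSums(fr$velocities^2)) / 1e-6
  kbT2 <- 0.0083144621 * 300 / 2
  expect_equal(ke / (3 * 1002), kbT2, tolerance = 0.05)
  # sqrt(T) scaling of the spread
  f300 <- sample_boltzmann_velocities(fr, 300, seed = 5)
  f1200 <- sample_boltzmann_velocities(fr, 1200, seed = 5)
  expect_equal(sd(f1200$velocities) / sd(f300$velocities), 2, tolerance = 1e-6)
  expect_error(sample_boltzmann_velocities(fr, -5), "positive")
})

test_that("a zero-velocity start moves only through forces and keeps momentum", {
  fr <- build_initial_configuration(8, 0.997, seed = 6)
  fr$velocities <- matrix(0, 24, 3)
  cfg <- md_config(8, n_production_steps = 1,
                   annealing = data.frame(temperature = numeric(0),
                                          steps = numeric(0)),
                   store_interval = 0.1, seed = 1)
  out <- run_nve(cfg, initial_frame = fr)
  f0 <- compute_forces_energies(fr)$forces
  moved <- minimum_image_displacement(fr$positions, out$trajectory$positions[, , 1],
                                      fr$box)
  # displacement after one step from rest is (dt^2/2) a
  pred <- 0.5 * 0.1^2 * f0 * 1e-6 / site_masses(8)
  expect_equal(moved, pred, tolerance = 1e-8, ignore_attr = TRUE)
  m <- site_masses(8)
  mom <- colSums(out$trajectory$velocities[, , 1] * m)
  expect_lt(max(abs(mom)), 1e-10)
})

test_that("NVE runs are deterministic and conserve momentum", {
  cfg <- md_config(8, n_production_steps = 500, annealing_stage_steps = 100,
                   store_interval = 1, seed = 13)
  r1 <- run_nve(cfg)
  r2 <- run_nve(cfg)
  expect_identical(r1$trajectory$positions, r2$trajectory$positions)
  expect_identical(r1$trajectory$velocities, r2$trajectory$velocities)
  m <- site_masses(8)
  for (f in c(1, r1$trajectory$n_frames)) {
    mom <- colSums(r1$trajectory$velocities[, , f] * m)
    expect_lt(max(abs(mom)), 1e-9)
  }
  expect_s3_class(r1$energy, "energy_report")
  expect_true(all(r1$energy$energy$E_kin >= 0))
})

test_that("energy divergence is reported with the failing step", {
  cfg <- md_config(8, timestep = 15, n_production_steps = 3000,
                   annealing = data.frame(temperature = numeric(0),
                                          steps = numeric(0)),
                   store_interval = 15, seed = 21)
  expect_error(run_nve(cfg), "diverged at production step")
})

test_that("the 4th-order integrator conserves energy much tighter than Verlet", {
  mk <- function(integ) md_config(8, n_production_steps = 2000,
                                  annealing_stage_steps = 400,
                                  store_interval = 1, seed = 31,
                                  integrator = integ)
  e_vv <- run_nve(mk("velocity-verlet"))$energy
  e_y4 <- run_nve(mk("yoshida4"))$energy
  range_vv <- diff(range(e_vv$energy$E_tot))
  range_y4 <- diff(range(e_y4$energy$E_tot))
  expect_lt(range_y4, range_vv / 10)
})
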