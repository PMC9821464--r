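test_that("a free particle with no forces moves ballistically", {
  geom <- planar_geometry(50, 50, 50)
  pos <- matrix(c(10, 10, 25), 1, 3)
  vel <- matrix(c(0.3, -0.2, 0.1), 1, 3)
  sys <- particle_system(pos, vel, 1L, list(), matrix(integer(0), ncol = 2),
                         FALSE, matrix(numeric(0), ncol = 3),
                         matrix(numeric(0), ncol = 3), geom, 1)
  p <- md_params(temperature = 1, gamma = 0, n_steps_equil = 0,
                 n_steps_prod = 0)
  out <- step_md(sys, force_field(), p, n_steps = 1000)
  expect_equal(out$positions[1, ], pos[1, ] + vel[1, ] * 1000 * 0.005,
               tolerance = 1e-12)
  expect_equal(out$velocities, vel)
})

test_that("neighbor-list pair energies equal the all-pairs double loop", {
  for (seed in 1:3) {
    sys <- random_gas(24, box = c(6, 6, 12), frac_np = 0.4, seed = seed)
    ff <- force_field(sigma_n = 1, eps_b = 1.3)
    got <- system_energies(sys, ff)
    ref <- all_pairs_energy(sys, ff)
    expect_equal(got$E_pair, ref$E_pair, tolerance = 1e-12)
    expect_equal(got$E_wall, ref$E_wall, tolerance = 1e-12)
  }
  # particles hugging the periodic boundary keep correct minimum images
  geom <- planar_geometry(8, 8, 20)
  pos <- rbind(c(0.05, 4, 10), c(7.97, 4, 10),    # close across x boundary
               c(4, 0.02, 5), c(4, 7.95, 5.3))    # close across y boundary
  sys <- particle_system(pos, matrix(0, 4, 3), rep(0L, 4), list(),
                         matrix(integer(0), ncol = 2), rep(FALSE, 4),
                         matrix(numeric(0), ncol = 3),
                         matrix(numeric(0), ncol = 3), geom, 1)
  ff <- force_field()
  expect_equal(system_energies(sys, ff)$E_pair,
               all_pairs_energy(sys, ff)$E_pair, tolerance = 1e-12)
  expect_gt(system_energies(sys, ff)$E_pair, 0)
})

test_that("energies also agree on a bonded brush with walls and cylinder", {
  sys <- build_planar(4, 8, n_np = 12, seed = 2)
  ff <- force_field(eps_b = 1.2)
  sys <- step_md(sys, ff, md_params(n_steps_equil = 0, n_steps_prod = 0,
                                    seed = 3), n_steps = 500)
  got <- system_energies(sys, ff)
  ref <- all_pairs_energy(sys, ff)
  expect_equal(got$E_pair, ref$E_pair, tolerance = 1e-10)
  expect_equal(got$E_bond, ref$E_bond, tolerance = 1e-10)
  expect_equal(got$E_wall, ref$E_wall, tolerance = 1e-10)

  sc <- build_cylinder(28, 12, R = 8, n_np = 40, box_pad = 6, seed = 5)
  got <- system_energies(sc, ff)
  ref <- all_pairs_energy(sc, ff)
  expect_equal(got$E_pair, ref$E_pair, tolerance = 1e-10)
  expect_equal(got$E_wall, ref$E_wall, tolerance = 1e-10)
})

test_that("pair forces cancel internally (Newton's third law)", {
  sys <- random_gas(30, box = c(7, 7, 14), frac_np = 0.5, seed = 4)
  f <- system_energies(sys, force_field(eps_b = 1.1))$forces
  # gas is away from walls, so the only forces are pair forces
  expect_lt(max(abs(colSums(f))), 1e-10)
})

test_that("with the thermostat off the integrator conserves energy", {
  sys <- build_planar(8, 20, n_np = 0, seed = 7)
  ff <- force_field()
  # equilibrate gently with the thermostat, then measure drift in NVE
  sys <- step_md(sys, ff, md_params(temperature = 1, gamma = 1, seed = 1),
                 n_steps = 5000)
  p_nve <- md_params(temperature = 1, gamma = 0, log_stride = 10, seed = 1)
  out <- step_md(sys, ff, p_nve, n_steps = 10000)
  log <- attr(out, "log")
  e <- log[, "E_tot"]
  n_free <- sum(!sys$frozen)
  # energy stays bounded: no systematic gain or loss beyond the small
  # random accumulation from pairs crossing the cutoffs
  drift <- abs(mean(tail(e, 100)) - mean(head(e, 100))) / n_free
  expect_lt(drift, 5e-4)
  expect_lt((max(e) - min(e)) / n_free, 0.02)
})

test_that("the Langevin thermostat reaches equipartition", {
  # dilute nanoparticle gas at T = 1.5, started on a loose grid
  n <- 125
  geom <- planar_geometry(20, 20, 20)
  g <- seq(2, 18, length.out = 5)
  pos <- as.matrix(expand.grid(g, g, g))
  dimnames(pos) <- NULL
  sys <- particle_system(pos, matrix(0, n, 3), rep(1L, n), list(),
                         matrix(integer(0), ncol = 2), rep(FALSE, n),
                         matrix(numeric(0), ncol = 3),
                         matrix(numeric(0), ncol = 3), geom, 1)
  p <- md_params(temperature = 1.5, gamma = 1, log_stride = 100, seed = 8)
  out <- step_md(sys, force_field(), p, n_steps = 60000)
  log <- attr(out, "log")
  Tbar <- mean(log[log[, "step"] > 10000, "T_inst"])
  expect_equal(Tbar, 1.5, tolerance = 0.02)
  # per-component velocity variance ~ kB T / m
  v <- out$velocities
  expect_equal(mean(v^2), 1.5, tolerance = 0.1)
})

test_that("runs are deterministic per seed and empty production is fine", {
  sys <- build_planar(4, 8, n_np = 10, seed = 3)
  p <- md_params(temperature = 1.2, n_steps_equil = 300,
                 n_steps_prod = 300, snapshot_stride = 100, seed = 17)
  t1 <- run_md(sys, force_field(), p)
  t2 <- run_md(sys, force_field(), p)
  expect_identical(t1$coords, t2$coords)
  p2 <- p; p2$seed <- 18L
  t3 <- run_md(sys, force_field(), p2)
  expect_false(identical(t1$coords, t3$coords))
  p0 <- p; p0$n_steps_prod <- 0L
  t0 <- run_md(sys, force_field(), p0)
  expect_equal(n_frames(t0), 0L)
})

test_that("FENE bonds stay below r0 for a whole production run", {
  sys <- build_planar(6, 15, n_np = 30, seed = 13)
  tr <- run_md(sys, force_field(eps_b = 1.5), md_params(
    temperature = 2, n_steps_equil = 2000, n_steps_prod = 8000,
    snapshot_stride = 200, seed = 4))
  for (k in seq_len(n_frames(tr))) {
    d <- apply_min_image(tr$coords[tr$bonds[, 1], , k] -
                         tr$coords[tr$bonds[, 2], , k], tr$geometry)
    expect_lt(max(sqrt(rowSums(d^2))), 1.5)
  }
})

test_that("an overstretched bond aborts the run with the step index", {
  geom <- planar_geometry(10, 10, 10)
  pos <- rbind(c(5, 5, 5), c(5, 5, 6.6))   # bond r = 1.6 > r0
  sys <- particle_system(pos, matrix(0, 2, 3), c(0L, 0L), list(1:2),
                         matrix(1:2, 1), c(FALSE, FALSE),
                         matrix(numeric(0), ncol = 3),
                         matrix(numeric(0), ncol = 3), geom, 1)
  expect_error(system_energies(sys, force_field()), "overstretched")
})

test_that("the cylinder wall is permeable to nanoparticles only", {
  sys <- build_cylinder(28, 12, R = 8, n_np = 80, box_pad = 6, seed = 6)
  tr <- run_md(sys, force_field(eps_b = 1), md_params(
    temperature = 1.5, n_steps_equil = 15000, n_steps_prod = 15000,
    snapshot_stride = 500, seed = 9))
  g <- tr$geometry
  cy <- g$box[2] / 2; cz <- g$box[3] / 2
  np <- tr$species == 1L
  mobile_mon <- tr$species == 0L & !sys$frozen   # anchors sit exactly on R
  rad_np <- sqrt((tr$coords[np, 2, ] - cy)^2 + (tr$coords[np, 3, ] - cz)^2)
  rad_m <- sqrt((tr$coords[mobile_mon, 2, ] - cy)^2 +
                (tr$coords[mobile_mon, 3, ] - cz)^2)
  # nanoparticles equilibrate across the wall: some in, some out
  expect_gt(sum(rad_np < 8), 0)
  expect_gt(sum(rad_np > 8), 0)
  # monomers never leave the pore
  expect_lt(max(rad_m), 8)
})

test_that("equilibrated brush runs satisfy equipartition too", {
  sys <- build_planar(8, 16, n_np = 40, seed = 10)
  tr <- run_md(sys, force_field(), md_params(
    temperature = 0.9, n_steps_equil = 10000, n_steps_prod = 20000,
    snapshot_stride = 2000, log_stride = 200, seed = 12))
  expect_equal(mean(tr$log_prod[, "T_inst"]), 0.9, tolerance = 0.02)
})
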