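test_that("planar builder produces the brush geometry the parameters imply", {
  sys <- build_planar(n_chains = 16, N = 40, sigma_g = 0.0625, n_np = 50,
                      seed = 11)
  g <- sys$geometry
  expect_equal(g$box[1], sqrt(16 / 0.0625))   # Lx = Ly = sqrt(nch/sigma_g)
  expect_equal(g$box[1], g$box[2])
  expect_equal(g$box[3], 1.5 * 40)
  expect_equal(sum(sys$species == 0L), 16 * 40)
  expect_equal(sum(sys$species == 1L), 50)
  # every chain has exactly N beads, bead 1 frozen at its anchor on z = 0
  expect_true(all(lengths(sys$chains) == 40))
  first <- vapply(sys$chains, `[`, 1L, 1L)
  expect_true(all(sys$frozen[first]))
  expect_equal(sys$positions[first, ], unname(sys$anchors),
               ignore_attr = TRUE)
  expect_true(all(sys$positions[first, 3] == 0))
  # stretched perpendicular with bond length 0.97, all bonds < r0
  bl <- sqrt(rowSums((sys$positions[sys$bonds[, 1], ] -
                      sys$positions[sys$bonds[, 2], ])^2))
  expect_equal(unname(bl), rep(0.97, nrow(sys$bonds)), tolerance = 1e-12)
  # nanoparticles above the chains
  expect_true(all(sys$positions[sys$species == 1L, 3] > 0.97 * 39))
})

test_that("random grafting respects the minimum separation and density", {
  sys <- build_planar(n_chains = 25, N = 4, sigma_g = 0.0625, seed = 3)
  a <- sys$anchors
  L <- sys$geometry$box[1]
  dmin <- rep(Inf, nrow(a))
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(a))) {
    if (i == j) next
    dx <- abs(a[i, 1] - a[j, 1]); dx <- min(dx, L - dx)
    dy <- abs(a[i, 2] - a[j, 2]); dy <- min(dy, L - dy)
    dmin[i] <- min(dmin[i], sqrt(dx^2 + dy^2))
  }
  expect_true(all(dmin >= 1))
  # average grafting distance scale is 1/sqrt(sigma_g) = 4; random grafting
  # puts the mean nearest-neighbour distance at the same order
  expect_gt(mean(dmin), 1.2)
  expect_lt(mean(dmin), 4.5)
})

test_that("rebuilding is bit-identical per seed and differs across seeds", {
  a <- build_planar(8, 10, n_np = 20, seed = 5)
  b <- build_planar(8, 10, n_np = 20, seed = 5)
  c <- build_planar(8, 10, n_np = 20, seed = 6)
  expect_identical(a$positions, b$positions)
  expect_identical(a$velocities, b$velocities)
  expect_false(identical(a$positions, c$positions))
  expect_equal(dim(a$positions), dim(c$positions))
})

test_that("freshly built configurations have no overlaps above 50 epsilon", {
  expect_lt(max_pair_energy(build_planar(16, 40, n_np = 192, seed = 1)), 50)
  expect_lt(max_pair_energy(build_planar(9, 20, n_np = 20, sigma_n = 3,
                                         Lz = 45, seed = 2)), 50)
  sc <- build_cylinder(40, 25, R = 12, n_np = 300, box_pad = 6, seed = 4)
  expect_lt(max_pair_energy(sc), 50)
})

test_that("cylinder builder grafts on the surface and fills the pore", {
  sys <- build_cylinder(n_chains = 40, N = 25, sigma_g = 0.0625, R = 12,
                        n_np = 100, box_pad = 6, seed = 2)
  g <- sys$geometry
  expect_equal(g$L_cyl, 40 / (0.0625 * 2 * pi * 12))
  expect_equal(g$box[2], 2 * 12 + 2 * 6)
  cy <- g$box[2] / 2; cz <- g$box[3] / 2
  rad_anchor <- sqrt((sys$anchors[, 2] - cy)^2 + (sys$anchors[, 3] - cz)^2)
  expect_equal(rad_anchor, rep(12, 40), tolerance = 1e-12)
  # monomers inside the pore, nanoparticles in the solution outside
  mon <- sys$species == 0L
  rad_m <- sqrt((sys$positions[mon, 2] - cy)^2 +
                (sys$positions[mon, 3] - cz)^2)
  expect_true(all(rad_m <= 12 + 1e-9))
  rad_n <- sqrt((sys$positions[!mon, 2] - cy)^2 +
                (sys$positions[!mon, 3] - cz)^2)
  expect_true(all(rad_n > 12))
  # fully stretched growth: every bond is 0.97, shorter than r0
  bl <- sqrt(rowSums((apply_min_image(
    sys$positions[sys$bonds[, 1], ] - sys$positions[sys$bonds[, 2], ],
    g))^2))
  expect_equal(unname(bl), rep(0.97, nrow(sys$bonds)), tolerance = 1e-9)
})

test_that("degenerate short cylinders warn about periodic-image overlap", {
  expect_warning(build_cylinder(n_chains = 8, N = 10, R = 45, seed = 1),
                 "interaction range")
})

test_that("wall potentials repel the right species and only inside cutoff", {
  gp <- planar_geometry(10, 10, 20)
  expect_equal(wall_energy(c(5, 5, 2^(1 / 6)), "monomer", gp), 0)
  z <- seq(1.0, 0.3, by = -0.05)
  e <- vapply(z, function(zz) wall_energy(c(5, 5, zz), "monomer", gp), 0)
  expect_true(all(diff(e) > 0))          # strictly increasing approaching z=0
  gc <- cylinder_geometry(R = 10, L_cyl = 8, box_pad = 5)
  # monomer at wall distance 2^(1/6): exactly at cutoff, zero energy
  expect_equal(wall_energy(c(1, gc$box[2] / 2 + 10 - 2^(1 / 6),
                             gc$box[3] / 2), "monomer", gc), 0)
  # nanoparticle feels nothing on either side of the permeable wall
  for (rr in c(9, 9.9, 10.1, 12)) {
    expect_identical(wall_energy(c(1, gc$box[2] / 2 + rr, gc$box[3] / 2),
                                 "nanoparticle", gc), 0)
  }
  expect_false(gc$wall_spec$acts_on_np)
  expect_true(gp$wall_spec$acts_on_np)
})

test_that("graft anchors never move during dynamics", {
  sys <- build_planar(4, 8, n_np = 10, seed = 9)
  first <- vapply(sys$chains, `[`, 1L, 1L)
  tr <- run_md(sys, force_field(), md_params(
    temperature = 1.5, n_steps_equil = 500, n_steps_prod = 500,
    snapshot_stride = 100, seed = 2))
  expect_identical(tr$final_system$positions[first, ],
                   sys$positions[first, ])
  for (k in seq_len(n_frames(tr)))
    expect_equal(tr$coords[first, , k], sys$positions[first, ],
                 ignore_attr = TRUE)
})
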