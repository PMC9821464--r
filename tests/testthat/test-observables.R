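test_that("planar profiles honour their normalization identities", {
  # single static snapshot, all monomers at z = 5: one bin holds everything
  geom <- planar_geometry(16, 16, 60)
  nch <- 16; N <- 40
  pos <- cbind(runif(nch * N, 0, 16), runif(nch * N, 0, 16), 5)
  chains <- lapply(seq_len(nch), function(c) (c - 1L) * N + seq_len(N))
  tr <- synth_traj(pos, rep(0L, nch * N), geom, chains)
  pf <- profile_flat(tr, "monomer", bin_width = 1)
  expect_equal(profile_integral(pf), 0.0625 * 40, tolerance = 1e-10)
  expect_equal(sum(pf$values > 0), 1)
  expect_equal(pf$mid[pf$values > 0], 5.5)

  # nanoparticle profile integrates to unity regardless of configuration
  npos <- cbind(runif(200, 0, 16), runif(200, 0, 16), runif(200, 0, 60))
  tr2 <- synth_traj(rbind(pos, npos), c(rep(0L, nch * N), rep(1L, 200)),
                    geom, chains)
  pn <- profile_flat(tr2, "nanoparticle")
  expect_equal(profile_integral(pn), 1, tolerance = 1e-10)
  expect_s3_class(pn, "density_profile")
  expect_equal(pn$mode, "np_phibar")
  expect_error(profile_flat(synth_traj(pos, rep(0L, nch * N), geom, chains),
                            "nanoparticle"), "no particles")
})

test_that("normalization holds on every profile from a real short run", {
  sys <- build_planar(8, 12, n_np = 40, seed = 21)
  tr <- run_md(sys, force_field(), md_params(
    temperature = 1, n_steps_equil = 1000, n_steps_prod = 2000,
    snapshot_stride = 200, seed = 5))
  expect_equal(profile_integral(profile_flat(tr, "monomer")), 0.0625 * 12,
               tolerance = 1e-8)
  expect_equal(profile_integral(profile_flat(tr, "nanoparticle")), 1,
               tolerance = 1e-8)
})

test_that("radial profile has the cylindrical Jacobian right", {
  # uniform random points inside the cylinder must give a flat psi(r)
  set.seed(31)
  R <- 12; nch <- 40; N <- 25
  geom <- cylinder_geometry(R, 8.4883, box_pad = 6)
  n <- 60000
  # uniform in the disc via sqrt-sampling
  rad <- R * sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
  pos <- cbind(runif(n, 0, geom$box[1]),
               geom$box[2] / 2 + rad * cos(th),
               geom$box[3] / 2 + rad * sin(th))
  chains <- lapply(seq_len(nch), function(c) (c - 1L) * N + seq_len(N))
  # chain bookkeeping only matters for the normalization target
  tr <- synth_traj(pos, rep(0L, n), geom, chains[seq_len(min(nch, n))])
  pr <- profile_radial(tr, "monomer", bin_width = 0.5)
  expect_equal(profile_integral(pr), nch * N, tolerance = 1e-8)
  # flatness away from the axis (inner bins have few counts by geometry)
  sel <- pr$mid < 9
  cv <- sd(pr$values[sel]) / mean(pr$values[sel])
  expect_lt(cv, 0.15)

  # all mass on the wall surface lands in the first bin
  pos2 <- cbind(runif(500, 0, geom$box[1]),
                geom$box[2] / 2 + R * cos(th[1:500]),
                geom$box[3] / 2 + R * sin(th[1:500]))
  tr2 <- synth_traj(pos2, rep(0L, 500), geom, chains)
  pr2 <- profile_radial(tr2, "monomer", bin_width = 0.5)
  expect_true(all(pr2$values[-1] == 0))
  expect_gt(pr2$values[1], 0)
})

test_that("projection profile follows chains beyond the cylinder axis", {
  s <- synth_radial_chains(nch = 12, N = 30, R = 10)   # length 28.1 > R
  pp <- profile_projection(s$traj, bin_width = 0.25)
  expect_equal(profile_integral(pp), 0.0625 * 30, tolerance = 1e-10)
  support <- max(pp$mid[pp$values > 0])
  expect_gt(support, 10)                    # beyond R
  expect_equal(support, 0.97 * 29, tolerance = 0.3)
  expect_error(profile_projection(s$traj, species = "nanoparticle"),
               "monomers")
  bare <- s$traj; bare$chains <- NULL
  expect_error(profile_projection(bare), "chain")
})

test_that("brush height is the interpolated 0.995 quantile", {
  geom <- planar_geometry(10, 10, 40)
  # uniform density on [0, 40]
  edges <- seq(0, 40, by = 0.25)
  prof <- structure(list(
    bin_edges = edges, mid = (edges[-1] + edges[-length(edges)]) / 2,
    bin_width = 0.25, values = rep(1, length(edges) - 1), mode = "flat_psi",
    normalization_constant = 1, target_integral = 40,
    geometry_kind = "planar_slab"), class = "density_profile")
  expect_equal(brush_height(prof), 39.8, tolerance = 1e-9)
  expect_equal(brush_height(prof, fraction = 0.5), 20)
  # two equal spikes at z = 10 and z = 30: the quantile sits in the z=30 bin
  v2 <- rep(0, length(edges) - 1)
  v2[c(which(edges == 10), which(edges == 30))] <- 1
  prof2 <- prof; prof2$values <- v2
  h2 <- brush_height(prof2)
  expect_gte(h2, 30); expect_lte(h2, 30.25)
  # invariance under rescaling, monotone growth when mass is added above h
  prof3 <- prof; prof3$values <- prof$values * 7.3
  expect_equal(brush_height(prof3), brush_height(prof))
  prof4 <- prof; prof4$values[length(prof4$values)] <- 50
  expect_gt(brush_height(prof4), brush_height(prof))
  prof0 <- prof; prof0$values[] <- 0
  expect_error(brush_height(prof0), "all-zero")
})

test_that("solution concentration counts nanoparticles outside the brush", {
  geom <- planar_geometry(10, 10, 30)
  # static uniform gas, no brush: c = n/(Lx Ly Lz) exactly at h = 0
  set.seed(41)
  n <- 300
  pos <- cbind(runif(n, 0, 10), runif(n, 0, 10), runif(n, 0, 30))
  tr <- synth_traj(pos, rep(1L, n), geom)
  expect_equal(solution_concentration(tr, h = 0), 300 / 3000,
               tolerance = 1e-12)
  # all nanoparticles below h: zero concentration
  expect_equal(solution_concentration(tr, h = 30 - 1e-9), 0)
  expect_error(solution_concentration(tr, h = 30), "solution region")

  # cylinder: half in, half out by construction
  R <- 5; L <- 8
  gc <- cylinder_geometry(R, L, box_pad = 5)
  n2 <- 200
  rad <- c(runif(n2 / 2, 0, 4), runif(n2 / 2, R + 0.5, 9.5))
  th <- runif(n2, 0, 2 * pi)
  pos2 <- cbind(runif(n2, 0, L), gc$box[2] / 2 + rad * cos(th),
                gc$box[3] / 2 + rad * sin(th))
  tr2 <- synth_traj(pos2, rep(1L, n2), gc)
  vsol <- prod(gc$box) - pi * R^2 * L
  expect_equal(solution_concentration(tr2), (n2 / 2) / vsol,
               tolerance = 1e-12)
})

test_that("h-c diagrams aggregate replicates and order by concentration", {
  pts <- data.frame(
    temperature = rep(c(1, 1, 1.5), each = 2),
    eps_b = 1, sigma_n = 1,
    n_np = rep(c(100, 200, 100), each = 2),
    h = c(20, 20, 15, 15, 21, 21),
    c = c(0.02, 0.02, 0.01, 0.01, 0.03, 0.03))
  d <- hc_diagram(pts)
  expect_s3_class(d, "hc_diagram")
  expect_equal(nrow(d), 3)
  expect_equal(d$h_sd, rep(0, 3))         # duplicated replicates
  expect_equal(d$n_replicates, rep(2, 3))
  curve1 <- d[d$temperature == 1, ]
  expect_true(all(diff(curve1$c_mean) > 0))
  # single point still forms a one-row curve
  d1 <- hc_diagram(pts[1:2, ])
  expect_equal(nrow(d1), 1)
  expect_error(hc_diagram(data.frame(x = 1)), "columns")
})

test_that("scaling collapse scores identical and offset curves correctly", {
  base <- data.frame(
    temperature = rep(c(1.0, 1.5), each = 3),
    eps_b = rep(c(1.0, 1.5), each = 3),
    sigma_n = 1,
    n_np = rep(c(50, 100, 200), 2),
    h_mean = rep(c(20, 16, 14), 2),
    c_mean = rep(c(0.005, 0.01, 0.02), 2),
    h_sd = 0.1, c_sd = 0.001, n_replicates = 5)
  class(base) <- c("hc_diagram", "data.frame")
  sc <- scaling_collapse(base, ratio = 1)
  expect_equal(sc$max, 0)
  expect_equal(sc$mean, 0)
  expect_equal(sc$n_curves, 2)
  off <- base
  off$h_mean[off$temperature == 1.5] <- off$h_mean[off$temperature == 1.5] + 1
  sc2 <- scaling_collapse(off, ratio = 1)
  expect_equal(sc2$mean, 1, tolerance = 1e-12)
  expect_equal(sc2$max, 1, tolerance = 1e-12)
  # non-overlapping concentration ranges are an error
  apart <- base
  apart$c_mean[apart$temperature == 1.5] <- c(0.05, 0.06, 0.07)
  expect_error(scaling_collapse(apart, ratio = 1), "overlap")
  expect_error(scaling_collapse(base[1:3, ], ratio = 1), "at least two")
})
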