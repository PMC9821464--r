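#' @rdname build_planar
#' @export
particle_system <- function(positions, velocities, species, chains, bonds,
                            frozen, anchors, anchor_normals, geometry,
                            sigma_n = 1) {
  stopifnot(nrow(positions) == length(species),
            nrow(velocities) == nrow(positions),
            length(frozen) == nrow(positions))
  structure(list(
    positions = positions, velocities = velocities, species = species,
    chains = chains, bonds = bonds, frozen = frozen,
    anchors = anchors, anchor_normals = anchor_normals,
    geometry = geometry, sigma_n = sigma_n
  ), class = "particle_system")
}

#' @export
print.particle_system <- function(x, ...) {
  cat(sprintf("particle_system: %d monomers in %d chains, %d nanoparticles\n",
              sum(x$species == 0L), length(x$chains), sum(x$species == 1L)))
  print(x$geometry)
  invisible(x)
}

species_codes <- c(monomer = 0L, nanoparticle = 1L)

# chain index lists + consecutive-bead bond table for nch chains of length N
chain_topology <- function(nch, N, offset = 0L) {
  N <- as.integer(N)
  chains <- lapply(seq_len(nch), function(c) offset + (c - 1L) * N + seq_len(N))
  bonds <- do.call(rbind, lapply(chains, function(idx)
    cbind(idx[-length(idx)], idx[-1])))
  list(chains = chains, bonds = bonds)
}

maxwell_velocities <- function(n, temperature, frozen) {
  v <- matrix(rnorm(3 * n, sd = sqrt(temperature)), ncol = 3)
  v[frozen, ] <- 0
  v
}

#' Build a plane-grafted brush system
#'
#' Constructs the initial configuration for the flat geometry: a box with
#' \eqn{L_x = L_y = \sqrt{n_{chains}/\sigma_g}}, graft points drawn uniformly
#' at random on the z = 0 wall with minimum pair separation \code{sigma_m},
#' chains fully stretched perpendicular to the wall with initial bond length
#' 0.97, nanoparticles inserted uniformly at random in the region above the
#' chains without overlaps, and Maxwell-Boltzmann velocities at temperature
#' \code{temperature}.  The first bead of each chain is frozen at its graft
#' anchor.
#'
#' @param n_chains number of grafted chains.
#' @param N beads per chain.
#' @param sigma_g grafting density (chains per unit area).
#' @param n_np number of nanoparticles.
#' @param sigma_n nanoparticle diameter.
#' @param Lz slab height; default \code{1.5 * N} so stretched chains fit with
#'   a solution reservoir above.
#' @param temperature temperature for the initial velocities.
#' @param seed integer seed; rebuilding with the same seed is bit-identical.
#' @return a \code{particle_system} (geometry attached).
#' @examples
#' sys <- build_planar(n_chains = 4, N = 5, n_np = 10, seed = 1)
#' range(sys$positions[, 3])
#' @export
build_planar <- function(n_chains, N, sigma_g = 0.0625, n_np = 0,
                         sigma_n = 1, Lz = NULL, temperature = 1, seed = 1) {
  stopifnot(n_chains >= 1, N >= 2, sigma_g > 0, n_np >= 0)
  b0 <- 0.97
  L <- sqrt(n_chains / sigma_g)
  if (is.null(Lz)) Lz <- 1.5 * N
  z_top <- b0 * (N - 1)
  if (Lz <= z_top + 2)
    stop("geometry error: Lz too small for fully stretched chains")
  set.seed(seed)
  geom <- planar_geometry(L, L, Lz, sigma_g,
                          wall_spec = list(sigma_nanoparticle = sigma_n))
  grafts <- cpp_insert_points(n_chains, c(0, 0, 0), c(L, L, 0), 1.0,
                              geom$box, geom$pbc, -1, seed)
  top <- chain_topology(n_chains, N)
  pos_m <- do.call(rbind, lapply(seq_len(n_chains), function(c) {
    cbind(rep(grafts[c, 1], N), rep(grafts[c, 2], N), b0 * (0:(N - 1)))
  }))
  n_m <- n_chains * N
  if (n_np > 0) {
    lo <- c(0, 0, z_top + sigma_n)
    hi <- c(L, L, Lz - sigma_n)
    if (hi[3] - lo[3] < sigma_n)
      stop("geometry error: no room above the chains for nanoparticles")
    pos_n <- cpp_insert_points(n_np, lo, hi, sigma_n, geom$box, geom$pbc,
                               -1, seed + 1L)
  } else pos_n <- matrix(numeric(0), ncol = 3)
  positions <- rbind(pos_m, pos_n)
  species <- c(rep(0L, n_m), rep(1L, n_np))
  frozen <- c(rep(c(TRUE, rep(FALSE, N - 1)), n_chains), rep(FALSE, n_np))
  vel <- maxwell_velocities(nrow(positions), temperature, frozen)
  normals <- matrix(rep(c(0, 0, 1), n_chains), ncol = 3, byrow = TRUE)
  particle_system(positions, vel, species, top$chains, top$bonds, frozen,
                  grafts, normals, geom, sigma_n)
}

#' Build an inside-grafted cylindrical brush system
#'
#' Constructs a brush grafted to the inner surface of a cylinder of radius
#' \code{R} immersed in a fully periodic box.  The cylinder length follows
#' from the grafting density, \eqn{L = n_{chains}/(\sigma_g 2 \pi R)}.  Graft
#' points are drawn uniformly at random on the inner surface with minimum
#' separation \code{sigma_m}.  Chains are grown fully stretched (bond length
#' 0.97) descending inward from their anchors; because at large \code{N} all
#' chains cannot simultaneously reach the axis, each chain follows a nearly
#' straight line tilted along the cylinder axis with a per-chain random
#' radial descent rate, with collision rejection, terminating between
#' \code{r_min} and mid-radius.  Nanoparticles are inserted uniformly at
#' random in the solution region outside the cylinder (the wall is permeable
#' to them, so they equilibrate across it during dynamics).
#'
#' @param R cylinder radius.
#' @param box_pad solution annulus thickness around the cylinder.
#' @inheritParams build_planar
#' @examples
#' sys <- build_cylinder(n_chains = 8, N = 10, R = 45, seed = 1)
#' # anchors sit exactly on the inner surface
#' @export
build_cylinder <- function(n_chains, N, sigma_g = 0.0625, R = 45, n_np = 0,
                           sigma_n = 1, box_pad = 10, temperature = 1,
                           seed = 1) {
  stopifnot(n_chains >= 1, N >= 2, sigma_g > 0, R > 0, n_np >= 0)
  b0 <- 0.97
  L_cyl <- n_chains / (sigma_g * 2 * pi * R)
  if (L_cyl < 2 * 3.4)
    warning("cylinder length ", signif(L_cyl, 3),
            " is below twice the interaction range; periodic images of ",
            "nearby particles interact (degenerate box, fine for ",
            "construction checks only)")
  set.seed(seed)
  geom <- cylinder_geometry(R, L_cyl, box_pad, sigma_g,
                            wall_spec = list(sigma_nanoparticle = sigma_n))
  cy <- geom$box[2] / 2
  cz <- geom$box[3] / 2
  # random sequential insertion of graft points on the inner surface
  grafts <- matrix(NA_real_, n_chains, 3)
  placed <- 0L
  for (try in seq_len(1e6)) {
    if (placed >= n_chains) break
    th <- runif(1, 0, 2 * pi)
    p <- c(runif(1, 0, L_cyl), cy + R * cos(th), cz + R * sin(th))
    if (placed > 0) {
      dx <- abs(grafts[seq_len(placed), 1] - p[1])
      dx <- pmin(dx, L_cyl - dx)
      d2 <- dx^2 + (grafts[seq_len(placed), 2] - p[2])^2 +
        (grafts[seq_len(placed), 3] - p[3])^2
      if (min(d2) < 1) next
    }
    placed <- placed + 1L
    grafts[placed, ] <- p
  }
  if (placed < n_chains)
    stop("packing error: could not place graft points on the cylinder surface")
  # per-chain radial descent rate: full length R - r_min where it fits,
  # otherwise a random rate so chain ends are spread between r_min and R/2
  r_min <- 1.5
  len <- b0 * (N - 1)
  # chains descend ~2 sigma radially before tilting; budget the rest
  ca_max <- if (len <= R - r_min) 1 else (R - r_min - 2) / (len - 2)
  ca_min <- min(ca_max, max(0.15, (R / 2) / len))
  cos_alpha <- runif(n_chains, ca_min, ca_max)
  x_sign <- sample(c(-1, 1), n_chains, replace = TRUE)
  pos_m <- cpp_grow_chains(grafts, cos_alpha, x_sign, N, b0, geom$box,
                           R, 1.0, R - 0.5, 0.85, 0.25, seed)
  pos_m[, 1] <- pos_m[, 1] %% geom$box[1]
  top <- chain_topology(n_chains, N)
  n_m <- n_chains * N
  if (n_np > 0) {
    pos_n <- cpp_insert_points(n_np, c(0, 0, 0), geom$box, sigma_n,
                               geom$box, geom$pbc, R + sigma_n, seed + 1L)
  } else pos_n <- matrix(numeric(0), ncol = 3)
  positions <- rbind(pos_m, pos_n)
  species <- c(rep(0L, n_m), rep(1L, n_np))
  frozen <- c(rep(c(TRUE, rep(FALSE, N - 1)), n_chains), rep(FALSE, n_np))
  vel <- maxwell_velocities(nrow(positions), temperature, frozen)
  normals <- cbind(0, -(grafts[, 2] - cy) / R, -(grafts[, 3] - cz) / R)
  particle_system(positions, vel, species, top$chains, top$bonds, frozen,
                  grafts, normals, geom, sigma_n)
}

#' Maximum pair energy in a configuration
#'
#' Scans all pairs (and bonds and walls) of a system and returns the largest
#' single-pair energy; used to verify that freshly built configurations have
#' no overlaps above a threshold (default contract: 50 epsilon).
#'
#' @param sys a \code{particle_system}.
#' @param ff a \code{\link{force_field}}.
#' @export
max_pair_energy <- function(sys, ff = force_field(sigma_n = sys$sigma_n)) {
  pos <- sys$positions
  n <- nrow(pos)
  box <- sys$geometry$box
  pbc <- sys$geometry$pbc
  emax <- 0
  cut <- max(ff$rc_m, ff$r_cut_nm, ff$rc_nn)
  for (i in seq_len(n - 1)) {
    d <- sweep(pos[(i + 1):n, , drop = FALSE], 2, pos[i, ])
    for (k in 1:3) if (pbc[k]) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    r <- sqrt(rowSums(d^2))
    js <- which(r < cut)
    for (jj in js) {
      j <- i + jj
      key <- sys$species[i] + sys$species[j]
      e <- if (key == 0L) u_mm(r[jj], ff)
      else if (key == 2L) u_nn(r[jj], ff)
      else u_nm(r[jj], ff)
      if (e > emax) emax <- e
    }
  }
  for (b in seq_len(nrow(sys$bonds))) {
    d <- pos[sys$bonds[b, 1], ] - pos[sys$bonds[b, 2], ]
    for (k in 1:3) if (pbc[k]) d[k] <- d[k] - box[k] * round(d[k] / box[k])
    e <- u_fene(sqrt(sum(d^2)), ff)
    if (e > emax) emax <- e
  }
  for (i in which(!sys$frozen)) {
    kind <- if (sys$species[i] == 0L) "monomer" else "nanoparticle"
    e <- wall_energy(pos[i, ], kind, sys$geometry)
    if (e > emax) emax <- e
  }
  emax
}
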