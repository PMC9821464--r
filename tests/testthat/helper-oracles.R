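# Independent oracles used against the engine's neighbor-list code path.

# all-pairs double-loop total pair energy (minimum image), built on the
# R-level potential functions only
all_pairs_energy <- function(sys, ff) {
  pos <- sys$positions
  n <- nrow(pos)
  box <- sys$geometry$box
  pbc <- sys$geometry$pbc
  e_pair <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- pos[i, ] - pos[j, ]
      for (k in 1:3) if (pbc[k]) d[k] <- d[k] - box[k] * round(d[k] / box[k])
      r <- sqrt(sum(d^2))
      key <- sys$species[i] + sys$species[j]
      e_pair <- e_pair + if (key == 0L) u_mm(r, ff)
        else if (key == 2L) u_nn(r, ff)
        else if (ff$eps_b > 0) u_nm(r, ff) else 0
    }
  }
  e_bond <- 0
  for (b in seq_len(nrow(sys$bonds))) {
    d <- pos[sys$bonds[b, 1], ] - pos[sys$bonds[b, 2], ]
    for (k in 1:3) if (pbc[k]) d[k] <- d[k] - box[k] * round(d[k] / box[k])
    e_bond <- e_bond + u_fene(sqrt(sum(d^2)), ff)
  }
  e_wall <- 0
  for (i in which(!sys$frozen)) {
    kind <- if (sys$species[i] == 0L) "monomer" else "nanoparticle"
    e_wall <- e_wall + wall_energy(pos[i, ], kind, sys$geometry)
  }
  list(E_pair = e_pair, E_bond = e_bond, E_wall = e_wall)
}

# minimum-image convention applied row-wise to displacement vectors
apply_min_image <- function(d, geometry) {
  for (k in 1:3) {
    if (geometry$pbc[k])
      d[, k] <- d[, k] - geometry$box[k] * round(d[, k] / geometry$box[k])
  }
  d
}

# central finite difference of a scalar potential
num_deriv <- function(f, r, h = 1e-6) (f(r + h) - f(r - h)) / (2 * h)

# a free-floating random mixed-species gas in a planar box, away from walls
random_gas <- function(n, box = c(10, 10, 10), frac_np = 0.5, sigma_n = 1,
                       seed = 1) {
  set.seed(seed)
  pos <- cbind(runif(n, 0, box[1]), runif(n, 0, box[2]),
               runif(n, 0.2 * box[3], 0.8 * box[3]))
  species <- as.integer(runif(n) < frac_np)
  geom <- planar_geometry(box[1], box[2], box[3],
                          wall_spec = list(sigma_nanoparticle = sigma_n))
  particle_system(pos, matrix(0, n, 3), species, list(),
                  matrix(integer(0), ncol = 2), rep(FALSE, n),
                  matrix(numeric(0), ncol = 3), matrix(numeric(0), ncol = 3),
                  geom, sigma_n)
}
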