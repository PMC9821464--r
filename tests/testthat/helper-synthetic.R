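# Construct synthetic trajectories directly (no MD) for analysis tests.

synth_traj <- function(frames, species, geometry, chains = NULL,
                       anchors = NULL, anchor_normals = NULL) {
  if (is.matrix(frames)) frames <- list(frames)
  n <- nrow(frames[[1]])
  coords <- array(0, dim = c(n, 3, length(frames)))
  for (k in seq_along(frames)) coords[, , k] <- frames[[k]]
  structure(list(
    coords = coords, frame_steps = seq_along(frames),
    species = species, chains = chains, bonds = NULL,
    anchors = anchors, anchor_normals = anchor_normals,
    geometry = geometry, sigma_n = 1,
    log_equil = NULL, log_prod = NULL, params = NULL, final_system = NULL
  ), class = "md_trajectory")
}

# fully stretched radial chains in a cylinder (synthetic, no dynamics)
synth_radial_chains <- function(nch, N, R, b = 0.97, sigma_g = 0.0625) {
  L <- nch / (sigma_g * 2 * pi * R)
  geom <- cylinder_geometry(R, L, box_pad = 5, sigma_g = sigma_g)
  cy <- geom$box[2] / 2; cz <- geom$box[3] / 2
  th <- seq(0, 2 * pi, length.out = nch + 1)[seq_len(nch)]
  anchors <- cbind(runif(nch, 0, L), cy + R * cos(th), cz + R * sin(th))
  normals <- cbind(0, -cos(th), -sin(th))
  pos <- do.call(rbind, lapply(seq_len(nch), function(c) {
    s <- b * (0:(N - 1))
    cbind(anchors[c, 1], anchors[c, 2] + s * normals[c, 2],
          anchors[c, 3] + s * normals[c, 3])
  }))
  chains <- lapply(seq_len(nch), function(c) (c - 1L) * N + seq_len(N))
  list(traj = synth_traj(pos, rep(0L, nch * N), geom, chains, anchors,
                         normals),
       geom = geom, anchors = anchors, normals = normals)
}
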