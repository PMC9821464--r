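# Plain-text trajectory and configuration formats: species-tagged XYZ, a
# LAMMPS-dump-compatible dialect, a LAMMPS-data-like structure block and
# tab-separated thermodynamic logs.  Numbers are written with %.17g so a
# write/read round trip reproduces doubles exactly.

species_tag <- c("M", "NP")

traj_frames <- function(x) {
  if (inherits(x, "particle_system"))
    return(list(frames = list(x$positions), steps = 0L, species = x$species,
                geometry = x$geometry))
  if (inherits(x, "md_trajectory")) {
    nf <- n_frames(x)
    return(list(frames = lapply(seq_len(nf), function(k) x$coords[, , k]),
                steps = x$frame_steps, species = x$species,
                geometry = x$geometry))
  }
  stop("expected a particle_system or md_trajectory")
}

#' Write a configuration or trajectory as species-tagged XYZ
#'
#' One XYZ block per snapshot: atom count, a comment line carrying the step
#' and box, then \code{tag x y z} lines (tags \code{M} for monomers,
#' \code{NP} for nanoparticles).
#'
#' @param x a \code{particle_system} or \code{md_trajectory}.
#' @param path output file.
#' @export
write_xyz <- function(x, path) {
  tf <- traj_frames(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(tf$frames)) {
    p <- tf$frames[[k]]
    writeLines(c(
      as.character(nrow(p)),
      sprintf("step=%d box=%.17g %.17g %.17g", tf$steps[k],
              tf$geometry$box[1], tf$geometry$box[2], tf$geometry$box[3]),
      sprintf("%s %.17g %.17g %.17g", species_tag[tf$species + 1L],
              p[, 1], p[, 2], p[, 3])), con)
  }
  invisible(path)
}

#' Read a species-tagged XYZ trajectory
#'
#' @param path file written by \code{\link{write_xyz}} (or any XYZ whose tag
#'   column uses \code{M} / \code{NP}).
#' @return list with \code{frames} (list of coordinate matrices),
#'   \code{species}, \code{steps}, \code{box}.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list(); steps <- integer(); species <- NULL; box <- NULL
  i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    cm <- lines[i + 1L]
    step <- as.integer(sub(".*step=([0-9]+).*", "\\1", cm))
    box <- as.numeric(strsplit(sub(".*box=", "", cm), " ")[[1]])
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(block, " +")
    tags <- vapply(parts, `[`, "", 1L)
    coords <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))),
                     ncol = 3, byrow = TRUE)
    frames[[length(frames) + 1L]] <- coords
    steps <- c(steps, step)
    species <- as.integer(tags == "NP")
    i <- i + 2L + n
  }
  list(frames = frames, species = species, steps = steps, box = box)
}

#' Write a trajectory in the LAMMPS-dump text dialect
#'
#' Per snapshot: \code{ITEM: TIMESTEP}, \code{ITEM: NUMBER OF ATOMS},
#' \code{ITEM: BOX BOUNDS} (\code{pp pp ff} for the slab, \code{pp pp pp}
#' for the periodic cylinder box) and \code{ITEM: ATOMS id type x y z}
#' with type 1 = monomer, 2 = nanoparticle.
#'
#' @inheritParams write_xyz
#' @export
write_lammps_dump <- function(x, path) {
  tf <- traj_frames(x)
  bstyle <- if (all(tf$geometry$pbc)) "pp pp pp" else "pp pp ff"
  con <- file(path, "w")
  on.exit(close(con))
  ids <- seq_along(tf$species)
  for (k in seq_along(tf$frames)) {
    p <- tf$frames[[k]]
    writeLines(c(
      "ITEM: TIMESTEP", as.character(tf$steps[k]),
      "ITEM: NUMBER OF ATOMS", as.character(nrow(p)),
      paste("ITEM: BOX BOUNDS", bstyle),
      sprintf("%.17g %.17g", 0, tf$geometry$box[1]),
      sprintf("%.17g %.17g", 0, tf$geometry$box[2]),
      sprintf("%.17g %.17g", 0, tf$geometry$box[3]),
      "ITEM: ATOMS id type x y z",
      sprintf("%d %d %.17g %.17g %.17g", ids, tf$species + 1L,
              p[, 1], p[, 2], p[, 3])), con)
  }
  invisible(path)
}

#' Read a LAMMPS-dump dialect trajectory
#'
#' @param path dump file (\code{ITEM: ATOMS id type x y z} columns).
#' @return list with \code{frames}, \code{species}, \code{steps},
#'   \code{box}, \code{bounds_style}.
#' @export
read_lammps_dump <- function(path) {
  lines <- readLines(path)
  frames <- list(); steps <- integer(); species <- NULL
  box <- NULL; bstyle <- NULL
  i <- 1L
  while (i <= length(lines)) {
    stopifnot(startsWith(lines[i], "ITEM: TIMESTEP"))
    step <- as.integer(lines[i + 1L])
    n <- as.integer(lines[i + 3L])
    bstyle <- sub("ITEM: BOX BOUNDS ", "", lines[i + 4L])
    bounds <- do.call(rbind, lapply(lines[(i + 5L):(i + 7L)], function(l)
      as.numeric(strsplit(l, " +")[[1]])))
    box <- bounds[, 2] - bounds[, 1]
    block <- lines[(i + 9L):(i + 8L + n)]
    parts <- strsplit(block, " +")
    m <- matrix(as.numeric(unlist(parts)), ncol = 5, byrow = TRUE)
    ord <- order(m[, 1])
    m <- m[ord, , drop = FALSE]
    frames[[length(frames) + 1L]] <- m[, 3:5, drop = FALSE]
    species <- as.integer(m[, 2]) - 1L
    steps <- c(steps, step)
    i <- i + 9L + n
  }
  list(frames = frames, species = species, steps = steps, box = box,
       bounds_style = bstyle)
}

#' Rebuild an md_trajectory from read frames and a matching system
#'
#' Glues trajectory frames read from disk back onto the chain topology,
#' anchors and geometry of the system that produced them, so the analysis
#' operations can run on stored trajectories.
#'
#' @param frames_data output of \code{\link{read_lammps_dump}} or
#'   \code{\link{read_xyz}}.
#' @param sys the \code{particle_system} the frames belong to (same particle
#'   ordering).
#' @export
as_trajectory <- function(frames_data, sys) {
  stopifnot(identical(frames_data$species, sys$species))
  nf <- length(frames_data$frames)
  n <- length(sys$species)
  coords <- array(0, dim = c(n, 3, nf))
  for (k in seq_len(nf)) coords[, , k] <- frames_data$frames[[k]]
  structure(list(
    coords = coords, frame_steps = frames_data$steps,
    species = sys$species, chains = sys$chains, bonds = sys$bonds,
    anchors = sys$anchors, anchor_normals = sys$anchor_normals,
    geometry = sys$geometry, sigma_n = sys$sigma_n,
    log_equil = NULL, log_prod = NULL, params = NULL,
    final_system = NULL
  ), class = "md_trajectory")
}

#' Write a system as a LAMMPS-data-like structure block
#'
#' Plain text: counts header, \code{Atoms} section (id, species, x, y, z)
#' and \code{Bonds} section (id, type, i, j).
#'
#' @param sys a \code{particle_system}.
#' @param path output file.
#' @export
write_lammps_data <- function(sys, path) {
  n <- nrow(sys$positions)
  nb <- nrow(sys$bonds)
  lines <- c(
    "npbrush structure file",
    "",
    sprintf("%d atoms", n),
    sprintf("%d bonds", nb),
    sprintf("0 %.17g xlo xhi", sys$geometry$box[1]),
    sprintf("0 %.17g ylo yhi", sys$geometry$box[2]),
    sprintf("0 %.17g zlo zhi", sys$geometry$box[3]),
    "",
    "Atoms",
    "",
    sprintf("%d %d %.17g %.17g %.17g", seq_len(n), sys$species + 1L,
            sys$positions[, 1], sys$positions[, 2], sys$positions[, 3]),
    "",
    "Bonds",
    "",
    sprintf("%d 1 %d %d", seq_len(nb), sys$bonds[, 1], sys$bonds[, 2]))
  writeLines(lines, path)
  invisible(path)
}

#' Write the thermodynamic log of a trajectory as TSV
#'
#' @param traj an \code{md_trajectory}.
#' @param path output file.
#' @param stage \code{"prod"} or \code{"equil"}.
#' @export
write_thermo_log <- function(traj, path, stage = "prod") {
  log <- if (stage == "prod") traj$log_prod else traj$log_equil
  write.table(as.data.frame(log), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Write a density profile as TSV with header metadata
#'
#' @param profile a \code{density_profile}.
#' @param path output file.
#' @param meta named list echoed as \code{# key: value} header lines.
#' @export
write_profile <- function(profile, path, meta = list()) {
  hdr <- c(sprintf("# mode: %s", profile$mode),
           sprintf("# geometry: %s", profile$geometry_kind),
           sprintf("# target_integral: %.17g", profile$target_integral),
           vapply(names(meta), function(k)
             sprintf("# %s: %s", k, format(meta[[k]])), ""))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("coord\tvalue", con)
  writeLines(sprintf("%.17g\t%.17g", profile$mid, profile$values), con)
  invisible(path)
}
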