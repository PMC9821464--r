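# Configuration, presets and experiment orchestration: temperature /
# nanoparticle-count sweeps with replicate seeds, resumable state-point
# directories, and analysis aggregation.

#' Assemble a run configuration
#'
#' A structured description of one experiment: geometry, force field,
#' population, integrator, sweep lists and replicate seeds.  All parameters
#' are validated against the builder/integrator preconditions before a run
#' starts.
#'
#' @param geometry list: \code{kind} ("planar" or "cylinder"),
#'   \code{sigma_g}, and \code{Lz} (planar) or \code{R}, \code{box_pad}
#'   (cylinder).
#' @param force_field list: \code{sigma_n}, \code{eps_b}, \code{shift_nm}.
#' @param population list: \code{n_chains}, \code{N}, \code{n_np}.
#' @param integrator list: \code{temperature}, \code{dt}, \code{gamma},
#'   \code{n_steps_equil}, \code{n_steps_prod}, \code{snapshot_stride}.
#' @param sweep list of vectors \code{temperature} and/or \code{n_np};
#'   defaults to the single base value.
#' @param seeds integer vector of replicate seeds.
#' @param scale \code{"desk"} or \code{"paper"} (metadata label).
#' @return object of class \code{run_config}.
#' @export
run_config <- function(geometry, force_field, population, integrator,
                       sweep = list(), seeds = 1:5, scale = "desk") {
  cfg <- list(geometry = geometry, force_field = force_field,
              population = population, integrator = integrator,
              sweep = sweep, seeds = as.integer(seeds), scale = scale)
  class(cfg) <- "run_config"
  validate_config(cfg)
  cfg
}

#' Shipped configuration presets
#'
#' \code{"paper-flat"} and \code{"paper-cylinder"} encode the full-scale
#' protocol (100/400 chains of 100 beads at grafting density 0.0625, time
#' step 0.005, damping 1, 4e6 + 1e6 steps, 5 replicate seeds, 3000/30000
#' nanoparticles, cylinder radius 45); these are cluster-size jobs.
#' \code{"desk-flat"} and \code{"desk-cylinder"} are reduced versions sized
#' for a single CPU.
#'
#' @param name preset name.
#' @return a \code{run_config}.
#' @export
preset_config <- function(name = c("desk-flat", "desk-cylinder",
                                   "paper-flat", "paper-cylinder")) {
  name <- match.arg(name)
  switch(name,
    "paper-flat" = run_config(
      geometry = list(kind = "planar", sigma_g = 0.0625, Lz = 150),
      force_field = list(sigma_n = 1, eps_b = 1.0, shift_nm = FALSE),
      population = list(n_chains = 100, N = 100, n_np = 3000),
      integrator = list(temperature = 1, dt = 0.005, gamma = 1,
                        n_steps_equil = 4e6, n_steps_prod = 1e6,
                        snapshot_stride = 1000),
      seeds = 1:5, scale = "paper"),
    "paper-cylinder" = run_config(
      geometry = list(kind = "cylinder", sigma_g = 0.0625, R = 45,
                      box_pad = 10),
      force_field = list(sigma_n = 1, eps_b = 1.0, shift_nm = FALSE),
      population = list(n_chains = 400, N = 100, n_np = 30000),
      integrator = list(temperature = 1, dt = 0.005, gamma = 1,
                        n_steps_equil = 4e6, n_steps_prod = 1e6,
                        snapshot_stride = 1000),
      seeds = 1:5, scale = "paper"),
    "desk-flat" = run_config(
      geometry = list(kind = "planar", sigma_g = 0.0625, Lz = 60),
      force_field = list(sigma_n = 1, eps_b = 1.0, shift_nm = FALSE),
      population = list(n_chains = 16, N = 40, n_np = 192),
      integrator = list(temperature = 1, dt = 0.005, gamma = 1,
                        n_steps_equil = 6e4, n_steps_prod = 2e4,
                        snapshot_stride = 400),
      seeds = 1:5, scale = "desk"),
    "desk-cylinder" = run_config(
      geometry = list(kind = "cylinder", sigma_g = 0.0625, R = 12,
                      box_pad = 6),
      force_field = list(sigma_n = 1, eps_b = 1.0, shift_nm = FALSE),
      population = list(n_chains = 40, N = 25, n_np = 300),
      integrator = list(temperature = 1, dt = 0.005, gamma = 1,
                        n_steps_equil = 6e4, n_steps_prod = 2e4,
                        snapshot_stride = 400),
      seeds = 1:5, scale = "desk"))
}

#' Validate a run configuration
#'
#' Checks every referenced parameter against the module preconditions;
#' errors name the offending key.
#'
#' @param cfg a \code{run_config} (or plain list with the same blocks).
#' @export
validate_config <- function(cfg) {
  req <- function(block, key, test) {
    v <- cfg[[block]][[key]]
    if (is.null(v) || !test(v))
      stop(sprintf("config error in %s$%s", block, key), call. = FALSE)
    v
  }
  kind <- req("geometry", "kind",
              function(v) v %in% c("planar", "cylinder"))
  req("geometry", "sigma_g", function(v) is.numeric(v) && v > 0)
  if (kind == "cylinder") {
    req("geometry", "R", function(v) is.numeric(v) && v > 0)
    req("geometry", "box_pad", function(v) is.numeric(v) && v > 0)
  }
  req("force_field", "sigma_n", function(v) is.numeric(v) && v > 0)
  req("force_field", "eps_b", function(v) is.numeric(v) && v >= 0)
  req("population", "n_chains", function(v) v >= 1)
  req("population", "N", function(v) v >= 2)
  req("population", "n_np", function(v) v >= 0)
  req("integrator", "temperature", function(v) v > 0)
  req("integrator", "dt", function(v) v > 0)
  req("integrator", "gamma", function(v) v >= 0)
  req("integrator", "n_steps_equil", function(v) v >= 0)
  req("integrator", "n_steps_prod", function(v) v >= 0)
  if (is.null(cfg$seeds) || length(cfg$seeds) < 1)
    stop("config error in seeds", call. = FALSE)
  invisible(TRUE)
}

#' Read / write run configurations as YAML
#' @param path YAML file.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  class(cfg) <- "run_config"
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @param cfg a \code{run_config}.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

config_build <- function(cfg, temperature = NULL, n_np = NULL, seed = NULL) {
  g <- cfg$geometry; p <- cfg$population; f <- cfg$force_field
  temperature <- if (is.null(temperature)) cfg$integrator$temperature else temperature
  n_np <- if (is.null(n_np)) p$n_np else n_np
  seed <- if (is.null(seed)) cfg$seeds[1] else seed
  if (g$kind == "planar") {
    build_planar(p$n_chains, p$N, g$sigma_g, n_np, f$sigma_n,
                 Lz = g$Lz, temperature = temperature, seed = seed)
  } else {
    build_cylinder(p$n_chains, p$N, g$sigma_g, g$R, n_np, f$sigma_n,
                   box_pad = g$box_pad, temperature = temperature,
                   seed = seed)
  }
}

config_ff <- function(cfg) {
  force_field(sigma_n = cfg$force_field$sigma_n,
              eps_b = cfg$force_field$eps_b,
              shift_nm = isTRUE(cfg$force_field$shift_nm))
}

config_params <- function(cfg, temperature = NULL, seed = NULL) {
  it <- cfg$integrator
  md_params(temperature = if (is.null(temperature)) it$temperature else temperature,
            dt = it$dt, gamma = it$gamma,
            n_steps_equil = it$n_steps_equil,
            n_steps_prod = it$n_steps_prod,
            snapshot_stride = if (is.null(it$snapshot_stride)) 1000 else it$snapshot_stride,
            seed = if (is.null(seed)) cfg$seeds[1] else seed)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

state_point_dir <- function(temperature, n_np, seed) {
  sprintf("T%g_nnp%d_seed%d", temperature, as.integer(n_np), as.integer(seed))
}

#' Build initial configuration files from a config
#'
#' Writes the initial structure (XYZ and LAMMPS-data-like block) for the
#' base state point of a configuration, plus an echo of the resolved
#' parameters.
#'
#' @param cfg a \code{run_config} or path to a YAML config.
#' @param outdir output directory.
#' @return invisibly, the paths written.
#' @export
cmd_build <- function(cfg, outdir = ".") {
  if (is.character(cfg)) cfg <- read_config(cfg)
  validate_config(cfg)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sys <- config_build(cfg)
  paths <- c(xyz = file.path(outdir, "init.xyz"),
             data = file.path(outdir, "init.data"),
             config = file.path(outdir, "config.yml"))
  write_xyz(sys, paths["xyz"])
  write_lammps_data(sys, paths["data"])
  write_config(cfg, paths["config"])
  message(sprintf("built %d monomers + %d nanoparticles (%s)",
                  sum(sys$species == 0L), sum(sys$species == 1L),
                  sys$geometry$kind))
  invisible(paths)
}

#' Run every state point of a configuration sweep
#'
#' Loops over the sweep's temperatures, nanoparticle counts and replicate
#' seeds; each state point gets its own directory containing the production
#' trajectory (LAMMPS-dump dialect), thermodynamic logs, a metadata file
#' (resolved parameters, seed, config hash, package version) and a DONE
#' marker.  With \code{resume = TRUE}, completed points are skipped, so an
#' interrupted sweep restarts where it stopped.
#'
#' @inheritParams cmd_build
#' @param resume skip state points whose DONE marker exists.
#' @return data.frame of state points with their directories and status.
#' @export
cmd_run <- function(cfg, outdir = ".", resume = TRUE) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  validate_config(cfg)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  temps <- if (!is.null(cfg$sweep$temperature)) cfg$sweep$temperature
           else cfg$integrator$temperature
  nnps <- if (!is.null(cfg$sweep$n_np)) cfg$sweep$n_np
          else cfg$population$n_np
  hash <- config_hash(cfg)
  grid <- expand.grid(temperature = temps, n_np = nnps, seed = cfg$seeds)
  grid$dir <- NA_character_; grid$status <- NA_character_
  for (i in seq_len(nrow(grid))) {
    Tt <- grid$temperature[i]; nn <- grid$n_np[i]; sd_ <- grid$seed[i]
    d <- file.path(outdir, state_point_dir(Tt, nn, sd_))
    grid$dir[i] <- d
    if (resume && file.exists(file.path(d, "DONE"))) {
      grid$status[i] <- "skipped"
      next
    }
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    sys <- config_build(cfg, temperature = Tt, n_np = nn, seed = sd_)
    traj <- run_md(sys, config_ff(cfg), config_params(cfg, Tt, sd_))
    write_lammps_dump(traj, file.path(d, "traj.dump"))
    write_thermo_log(traj, file.path(d, "thermo.tsv"), "prod")
    yaml::write_yaml(list(
      temperature = Tt, n_np = nn, seed = sd_,
      eps_b = cfg$force_field$eps_b, sigma_n = cfg$force_field$sigma_n,
      geometry = cfg$geometry, population = cfg$population,
      integrator = cfg$integrator,
      config_hash = hash,
      package_version = as.character(utils::packageVersion("npbrush"))
    ), file.path(d, "meta.yml"))
    writeLines(hash, file.path(d, "DONE"))
    grid$status[i] <- "run"
  }
  grid
}

#' Analyze every completed state point under a results root
#'
#' Recomputes the density profile (planar psi or cylinder projection psi,
#' plus the nanoparticle profile where present), brush height and solution
#' concentration for each completed state point, writes per-point profile
#' TSVs, and aggregates an h-c table (and an eps_b/T collapse report when
#' several curves share a ratio) into machine-readable summaries.
#'
#' @param root directory containing state-point subdirectories from
#'   \code{\link{cmd_run}}.
#' @param bin_width profile bin width.
#' @return list with the state-point table, the \code{hc_diagram} and any
#'   collapse reports.
#' @export
cmd_analyze <- function(root, bin_width = 0.25) {
  dirs <- list.dirs(root, recursive = FALSE)
  dirs <- dirs[file.exists(file.path(dirs, "DONE"))]
  if (length(dirs) == 0) stop("nothing to analyze under ", root)
  rows <- list()
  for (d in dirs) {
    meta <- yaml::read_yaml(file.path(d, "meta.yml"))
    cfg <- list(geometry = meta$geometry,
                population = modifyList(meta$population,
                                        list(n_np = meta$n_np)),
                force_field = list(sigma_n = meta$sigma_n,
                                   eps_b = meta$eps_b),
                integrator = meta$integrator, seeds = meta$seed)
    sys <- config_build(cfg, temperature = meta$temperature,
                        n_np = meta$n_np, seed = meta$seed)
    dump <- tryCatch(read_lammps_dump(file.path(d, "traj.dump")),
                     error = function(e) NULL)
    if (is.null(dump)) {
      warning("missing or unreadable trajectory in ", d)
      next
    }
    traj <- as_trajectory(dump, sys)
    prof <- if (traj$geometry$kind == "planar_slab")
      profile_flat(traj, "monomer", bin_width)
    else profile_projection(traj, "monomer", bin_width)
    h <- brush_height(prof)
    write_profile(prof, file.path(d, "psi.tsv"),
                  meta = list(temperature = meta$temperature,
                              eps_b = meta$eps_b, sigma_n = meta$sigma_n,
                              seed = meta$seed,
                              config_hash = meta$config_hash))
    cc <- NA_real_
    if (meta$n_np > 0) {
      cc <- solution_concentration(traj, h = if (traj$geometry$kind ==
        "planar_slab") h else NULL, bin_width = bin_width)
      npprof <- profile_flat_or_radial_np(traj, bin_width)
      if (!is.null(npprof))
        write_profile(npprof, file.path(d, "phibar.tsv"),
                      meta = list(temperature = meta$temperature,
                                  seed = meta$seed))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      temperature = meta$temperature, eps_b = meta$eps_b,
      sigma_n = meta$sigma_n, n_np = meta$n_np, seed = meta$seed,
      h = h, c = cc, dir = d)
  }
  if (length(rows) == 0) stop("nothing to analyze under ", root)
  points <- do.call(rbind, rows)
  write.table(points, file.path(root, "state_points.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  out <- list(points = points)
  withc <- points[!is.na(points$c), , drop = FALSE]
  if (nrow(withc) > 0) {
    diag <- hc_diagram(withc)
    write.table(diag, file.path(root, "hc_table.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    out$hc <- diag
    ratios <- unique(round(diag$eps_b / diag$temperature, 9))
    reports <- list()
    for (r in ratios) {
      sub <- diag[abs(diag$eps_b / diag$temperature - r) < 1e-9, ]
      if (nrow(unique(sub[c("temperature", "eps_b")])) >= 2) {
        sc <- tryCatch(scaling_collapse(diag, ratio = r),
                       error = function(e) NULL)
        if (!is.null(sc)) reports[[sprintf("ratio_%g", r)]] <- sc
      }
    }
    if (length(reports) > 0) {
      yaml::write_yaml(reports, file.path(root, "collapse.yml"))
      out$collapse <- reports
    }
  }
  yaml::write_yaml(list(n_state_points = nrow(points),
                        root = root,
                        analyzed = format(Sys.time())),
                   file.path(root, "summary.yml"))
  out
}

profile_flat_or_radial_np <- function(traj, bin_width) {
  tryCatch({
    if (traj$geometry$kind == "planar_slab")
      profile_flat(traj, "nanoparticle", bin_width)
    else profile_radial(traj, "nanoparticle", bin_width)
  }, error = function(e) NULL)
}
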