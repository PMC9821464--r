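# Analysis layer: normalized density profiles, quantile brush height,
# solution nanoparticle concentration, h-c diagrams and eps_b/T collapse.

new_profile <- function(bin_edges, values, mode, norm_const, target,
                        geometry, extra = list()) {
  structure(c(list(
    bin_edges = bin_edges,
    mid = (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2,
    bin_width = diff(bin_edges)[1],
    values = values, mode = mode,
    normalization_constant = norm_const, target_integral = target,
    geometry_kind = geometry$kind
  ), extra), class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("density_profile (%s): %d bins of width %g, integral = %.6g\n",
              x$mode, length(x$values), x$bin_width, profile_integral(x)))
  invisible(x)
}

#' @export
plot.density_profile <- function(x, ...) {
  lab <- switch(x$mode, flat_psi = expression(psi(z)),
                np_phibar = expression(bar(phi)(z)),
                radial_psi = expression(psi(r)),
                projection_psi = expression(psi(s)))
  plot(x$mid, x$values, type = "l",
       xlab = if (x$mode == "projection_psi") "s" else
         if (x$mode == "radial_psi") "r (from wall)" else "z",
       ylab = lab, ...)
  invisible(x)
}

#' Defining integral of a density profile
#'
#' The quadrature under which each profile is normalized: piecewise-constant
#' bin densities, i.e. \code{sum(values * bin_width)} for flat, projection
#' and nanoparticle profiles, and the Jacobian-weighted sum
#' \code{2 pi L sum((R - r_mid) values) * bin_width} for radial profiles.
#'
#' @param profile a \code{density_profile}.
#' @export
profile_integral <- function(profile) {
  if (profile$mode == "radial_psi" || profile$mode == "radial_phibar") {
    2 * pi * profile$L_cyl *
      sum((profile$R - profile$mid) * profile$values) * profile$bin_width
  } else {
    sum(profile$values) * profile$bin_width
  }
}

traj_sel <- function(traj, species) {
  species <- match.arg(species, c("monomer", "nanoparticle"))
  sel <- which(traj$species == species_codes[[species]])
  if (length(sel) == 0) stop("no particles of species ", species)
  if (n_frames(traj) == 0) stop("empty trajectory")
  sel
}

#' Monomer / nanoparticle density profile of a planar brush
#'
#' Time-averaged histogram of z over production snapshots, divided by the
#' slab bin volume and rescaled so the profile integral equals the declared
#' normalization: \eqn{\int_0^{L_z} \psi(z) dz = \sigma_g N} for monomers, 1
#' for nanoparticles (the \eqn{\bar\phi} convention).
#'
#' @param traj an \code{md_trajectory} from a planar system.
#' @param species \code{"monomer"} or \code{"nanoparticle"}.
#' @param bin_width histogram bin width (default 0.25 sigma).
#' @return a \code{density_profile} (mode \code{flat_psi} or
#'   \code{np_phibar}).
#' @export
profile_flat <- function(traj, species = "monomer", bin_width = 0.25) {
  if (traj$geometry$kind != "planar_slab")
    stop("profile_flat requires a planar geometry")
  sel <- traj_sel(traj, species)
  nf <- n_frames(traj)
  box <- traj$geometry$box
  z <- as.vector(traj$coords[sel, 3, ])
  edges <- seq(0, by = bin_width, length.out = ceiling(box[3] / bin_width) + 1)
  cnt <- tabulate(pmin(pmax(floor(z / bin_width), 0) + 1, length(edges) - 1),
                  nbins = length(edges) - 1)
  vals <- cnt / (nf * box[1] * box[2] * bin_width)
  target <- if (startsWith(species, "mono")) {
    traj$geometry$sigma_g * length(traj$chains[[1]])
  } else 1
  mode <- if (startsWith(species, "mono")) "flat_psi" else "np_phibar"
  raw <- sum(vals) * bin_width
  if (raw <= 0) stop("empty profile")
  scale <- target / raw
  new_profile(edges, vals * scale, mode, scale, target, traj$geometry)
}

#' Radial density profile inside a cylindrical brush
#'
#' Histogram in the radial coordinate r measured from the grafting wall
#' (\code{r = R - } distance from the axis), each bin divided by its shell
#' volume \eqn{2\pi L (R - r_{mid}) \Delta r}, and rescaled so the identity
#' \eqn{2\pi L \int_0^R (R - r) \psi(r) dr = N n_{ch}} holds (monomers), or
#' the same weighted integral equals 1 (nanoparticles, counted inside the
#' cylinder only).  Meaningful only when chains do not reach the axis, where
#' the Jacobian vanishes; bins whose shell volume would be non-positive are
#' excluded with a warning.
#'
#' @inheritParams profile_flat
#' @export
profile_radial <- function(traj, species = "monomer", bin_width = 0.25) {
  g <- traj$geometry
  if (g$kind != "cylinder_in_box")
    stop("profile_radial requires a cylinder geometry")
  sel <- traj_sel(traj, species)
  nf <- n_frames(traj)
  rad <- sqrt((traj$coords[sel, 2, , drop = FALSE] - g$box[2] / 2)^2 +
              (traj$coords[sel, 3, , drop = FALSE] - g$box[3] / 2)^2)
  r <- g$R - as.vector(rad)
  r <- r[r >= 0]           # nanoparticles outside the cylinder are excluded
  nb <- ceiling(g$R / bin_width)
  edges <- seq(0, by = bin_width, length.out = nb + 1)
  mids <- (edges[-1] + edges[-(nb + 1)]) / 2
  keep <- (g$R - mids) > 0
  if (any(!keep))
    warning("excluding ", sum(!keep), " bins at the axis (vanishing Jacobian)")
  cnt <- tabulate(pmin(floor(r / bin_width) + 1, nb), nbins = nb)
  shell <- 2 * pi * g$L_cyl * (g$R - mids) * bin_width
  vals <- numeric(nb)
  vals[keep] <- cnt[keep] / (nf * shell[keep])
  target <- if (startsWith(species, "mono")) {
    length(traj$chains) * length(traj$chains[[1]])
  } else 1
  raw <- sum(vals[keep] * shell[keep])
  if (raw <= 0) stop("empty profile")
  scale <- target / raw
  mode <- if (startsWith(species, "mono")) "radial_psi" else "radial_phibar"
  new_profile(edges, vals * scale, mode, scale, target, g,
              extra = list(R = g$R, L_cyl = g$L_cyl))
}

#' Projection-method density profile of a cylindrical brush
#'
#' For each monomer, its projection \eqn{s} onto the inward surface normal
#' of its own chain's graft anchor is histogrammed over all chains and
#' snapshots; \eqn{s} may exceed the cylinder radius, which is what makes
#' this profile a sensible measure of brush height when chains pass the
#' axis.  Normalized like the planar profile with the grafting density:
#' \eqn{\int \psi(s) ds = \sigma_g N}.
#'
#' @inheritParams profile_flat
#' @export
profile_projection <- function(traj, species = "monomer", bin_width = 0.25) {
  g <- traj$geometry
  if (g$kind != "cylinder_in_box")
    stop("profile_projection requires a cylinder geometry")
  if (!startsWith(species, "mono"))
    stop("projection profile is defined for monomers (chain assignment required)")
  if (is.null(traj$chains) || length(traj$chains) == 0)
    stop("monomer without chain assignment: trajectory carries no chain topology")
  sel <- traj_sel(traj, species)
  nf <- n_frames(traj)
  nch <- length(traj$chains)
  N <- length(traj$chains[[1]])
  s_all <- vector("list", nch)
  for (c in seq_len(nch)) {
    idx <- traj$chains[[c]]
    a <- traj$anchors[c, ]
    nrm <- traj$anchor_normals[c, ]
    dy <- traj$coords[idx, 2, , drop = FALSE] - a[2]
    dz <- traj$coords[idx, 3, , drop = FALSE] - a[3]
    s_all[[c]] <- as.vector(dy * nrm[2] + dz * nrm[3])
  }
  s <- unlist(s_all)
  smax <- max(s, bin_width)
  nb <- ceiling(smax / bin_width) + 1
  edges <- seq(0, by = bin_width, length.out = nb + 1)
  cnt <- tabulate(pmin(pmax(floor(s / bin_width), 0) + 1, nb), nbins = nb)
  area <- 2 * pi * g$R * g$L_cyl
  vals <- cnt / (nf * area * bin_width)
  target <- g$sigma_g * N
  raw <- sum(vals) * bin_width
  if (raw <= 0) stop("empty profile")
  scale <- target / raw
  new_profile(edges, vals * scale, "projection_psi", scale, target, g,
              extra = list(R = g$R, L_cyl = g$L_cyl))
}

#' Brush height: quantile of the cumulative density profile
#'
#' The smallest h such that the cumulative fraction of the profile reaches
#' \code{fraction} (default 0.995), with linear interpolation inside the
#' straddling bin (ties broken toward smaller h).  The default fraction
#' follows the convention calibrated against classic bead-spring brush
#' simulations.  Invariant under profile rescaling; monotone non-decreasing
#' when mass is added above the current h.
#'
#' @param profile a \code{density_profile}.
#' @param fraction cumulative quantile defining the brush edge.
#' @return the brush height (same length units as the profile coordinate).
#' @export
brush_height <- function(profile, fraction = 0.995) {
  stopifnot(fraction > 0, fraction <= 1)
  w <- profile$bin_width
  mass <- if (profile$mode %in% c("radial_psi", "radial_phibar")) {
    2 * pi * profile$L_cyl * (profile$R - profile$mid) * profile$values * w
  } else {
    profile$values * w
  }
  total <- sum(mass)
  if (total <= 0) stop("all-zero profile")
  cum <- cumsum(mass)
  target <- fraction * total
  i <- which(cum >= target * (1 - 1e-12))[1]
  prev <- if (i > 1) cum[i - 1] else 0
  profile$bin_edges[i] + (target - prev) / mass[i] * w
}

#' Nanoparticle concentration in the solution phase
#'
#' Cylinder: time-averaged number of nanoparticles whose distance from the
#' axis exceeds R, divided by the solution volume (box volume minus cylinder
#' volume).  Planar: nanoparticles above the brush height h divided by
#' \eqn{L_x L_y (L_z - h)}; h defaults to the brush height of the monomer
#' profile of the same trajectory (solution region defined self-consistently
#' as z > h).
#'
#' @param traj an \code{md_trajectory} containing nanoparticles.
#' @param h brush height delimiting the planar solution region; computed
#'   from the trajectory when NULL.  Ignored for cylinders.
#' @param bin_width passed to the profile when h is computed internally.
#' @return number density of nanoparticles in the solution.
#' @export
solution_concentration <- function(traj, h = NULL, bin_width = 0.25) {
  g <- traj$geometry
  sel <- traj_sel(traj, "nanoparticle")
  nf <- n_frames(traj)
  if (g$kind == "cylinder_in_box") {
    rad <- sqrt((traj$coords[sel, 2, , drop = FALSE] - g$box[2] / 2)^2 +
                (traj$coords[sel, 3, , drop = FALSE] - g$box[3] / 2)^2)
    n_out <- sum(rad > g$R) / nf
    vol <- prod(g$box) - pi * g$R^2 * g$L_cyl
    n_out / vol
  } else {
    if (is.null(h))
      h <- brush_height(profile_flat(traj, "monomer", bin_width))
    if (h >= g$box[3]) stop("empty solution region: h >= Lz")
    z <- traj$coords[sel, 3, , drop = FALSE]
    n_out <- sum(z > h) / nf
    vol <- g$box[1] * g$box[2] * (g$box[3] - h)
    n_out / vol
  }
}

#' Aggregate brush state points into h-c curves
#'
#' Takes one row per replicate run (temperature, eps_b, sigma_n, n_np, h, c)
#' and aggregates replicates into means and standard deviations, ordering
#' each (temperature, eps_b, sigma_n) curve by solution concentration.
#'
#' @param points data.frame with columns \code{temperature}, \code{eps_b},
#'   \code{sigma_n}, \code{n_np}, \code{h}, \code{c}.
#' @return data.frame of class \code{hc_diagram} with replicate means and
#'   spreads.
#' @export
hc_diagram <- function(points) {
  need <- c("temperature", "eps_b", "sigma_n", "n_np", "h", "c")
  if (!all(need %in% names(points)))
    stop("points must have columns ", paste(need, collapse = ", "))
  key <- points[c("temperature", "eps_b", "sigma_n", "n_np")]
  agg <- aggregate(points[c("h", "c")], by = key, FUN = mean)
  names(agg)[names(agg) == "h"] <- "h_mean"
  names(agg)[names(agg) == "c"] <- "c_mean"
  sds <- aggregate(points[c("h", "c")], by = key, FUN = sd)
  ns <- aggregate(list(n_replicates = points$h), by = key, FUN = length)
  agg$h_sd <- sds$h
  agg$c_sd <- sds$c
  agg$n_replicates <- ns$n_replicates
  agg <- agg[order(agg$temperature, agg$eps_b, agg$sigma_n, agg$c_mean), ]
  rownames(agg) <- NULL
  class(agg) <- c("hc_diagram", "data.frame")
  agg
}

#' @export
plot.hc_diagram <- function(x, ...) {
  grp <- interaction(x$temperature, x$eps_b, x$sigma_n, drop = TRUE)
  plot(x$c_mean, x$h_mean, type = "n", xlab = "c", ylab = "h", ...)
  for (g in levels(grp)) {
    s <- x[grp == g, ]
    lines(s$c_mean, s$h_mean, type = "b", pch = 19,
          col = which(levels(grp) == g))
  }
  invisible(x)
}

#' Discrepancy score of an eps_b/T scaling collapse
#'
#' If equilibrium structure depends on the nanoparticle binding strength and
#' the temperature only through the Boltzmann ratio eps_b/T, then h-c curves
#' measured at different (eps_b, T) pairs with the same ratio should
#' coincide.  Curves sharing the requested ratio are interpolated onto a
#' common concentration grid over the overlap of their c ranges and the
#' maximum and mean absolute pairwise height discrepancies are returned;
#' small scores support the collapse.
#'
#' @param diagram an \code{\link{hc_diagram}}.
#' @param ratio the eps_b/T ratio selecting the curves; defaults to the most
#'   common ratio in the diagram.
#' @param n_grid number of grid points for the interpolation.
#' @param tol tolerance for matching the ratio.
#' @return list with \code{max}, \code{mean}, \code{ratio},
#'   \code{n_curves} and the c overlap range.
#' @export
scaling_collapse <- function(diagram, ratio = NULL, n_grid = 21,
                             tol = 1e-9) {
  r_all <- diagram$eps_b / diagram$temperature
  if (is.null(ratio)) {
    tab <- table(round(r_all, 9))
    ratio <- as.numeric(names(tab)[which.max(tab)])
  }
  d <- diagram[abs(r_all - ratio) < tol, , drop = FALSE]
  keys <- unique(d[c("temperature", "eps_b", "sigma_n")])
  if (nrow(keys) < 2)
    stop("need at least two (eps_b, T) curves with ratio ", ratio)
  curves <- lapply(seq_len(nrow(keys)), function(i) {
    s <- merge(d, keys[i, , drop = FALSE])
    s[order(s$c_mean), ]
  })
  lo <- max(vapply(curves, function(s) min(s$c_mean), 0))
  hi <- min(vapply(curves, function(s) max(s$c_mean), 0))
  if (lo > hi) stop("non-overlapping c ranges; no common grid")
  grid <- if (lo == hi) lo else seq(lo, hi, length.out = n_grid)
  hmat <- vapply(curves, function(s) {
    if (nrow(s) == 1) rep(s$h_mean, length(grid))
    else approx(s$c_mean, s$h_mean, xout = grid, rule = 2)$y
  }, numeric(length(grid)))
  dmax <- 0; dsum <- 0; npair <- 0
  for (i in seq_len(ncol(hmat) - 1))
    for (j in (i + 1):ncol(hmat)) {
      dd <- abs(hmat[, i] - hmat[, j])
      dmax <- max(dmax, max(dd))
      dsum <- dsum + mean(dd)
      npair <- npair + 1
    }
  list(max = dmax, mean = dsum / npair, ratio = ratio,
       n_curves = length(curves), c_range = c(lo, hi))
}
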