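#' Planar-slab geometry
#'
#' A rectangular box periodic in x and y, bounded by repulsive walls in the
#' x-y plane at z = 0 (the grafting surface) and z = Lz.  Both walls act on
#' monomers and nanoparticles.
#'
#' @param Lx,Ly,Lz box edge lengths.
#' @param sigma_g grafting density (chains per unit area of the z = 0 wall).
#' @param wall_spec wall interaction descriptor from \code{\link{build_wall}};
#'   built with defaults when NULL.
#' @return object of class \code{brush_geometry}.
#' @export
planar_geometry <- function(Lx, Ly, Lz, sigma_g = 0.0625, wall_spec = NULL) {
  stopifnot(Lx > 0, Ly > 0, Lz > 0, sigma_g > 0)
  g <- structure(list(
    kind = "planar_slab", box = c(Lx, Ly, Lz), pbc = c(TRUE, TRUE, FALSE),
    sigma_g = sigma_g, R = NULL, L_cyl = NULL, wall_spec = NULL
  ), class = "brush_geometry")
  g$wall_spec <- build_wall(g, wall_spec)
  g
}

#' Cylinder-in-box geometry
#'
#' A cylinder of radius R with its axis along x, centred in the y-z
#' cross-section of a fully periodic box.  Chains graft to the inner surface;
#' the smooth cylindrical wall potential repels monomers but is transparent
#' to nanoparticles (a permeable pore wall), so nanoparticles exchange freely
#' with the solution annulus outside the cylinder.
#'
#' @param R cylinder radius.
#' @param L_cyl cylinder (and box) length along x.
#' @param box_pad solution annulus thickness: the box cross-section is
#'   \code{2 R + 2 box_pad} in y and z.
#' @inheritParams planar_geometry
#' @export
cylinder_geometry <- function(R, L_cyl, box_pad = 10, sigma_g = 0.0625,
                              wall_spec = NULL) {
  stopifnot(R > 0, L_cyl > 0, box_pad > 0, sigma_g > 0)
  side <- 2 * R + 2 * box_pad
  g <- structure(list(
    kind = "cylinder_in_box", box = c(L_cyl, side, side),
    pbc = c(TRUE, TRUE, TRUE),
    sigma_g = sigma_g, R = R, L_cyl = L_cyl, wall_spec = NULL
  ), class = "brush_geometry")
  g$wall_spec <- build_wall(g, wall_spec)
  g
}

#' @export
print.brush_geometry <- function(x, ...) {
  cat(sprintf("%s geometry, box %.4g x %.4g x %.4g, sigma_g = %g\n",
              x$kind, x$box[1], x$box[2], x$box[3], x$sigma_g))
  if (!is.null(x$R))
    cat(sprintf("  cylinder R = %g, L = %g (axis along x)\n", x$R, x$L_cyl))
  invisible(x)
}

#' Build the wall interaction description for a geometry
#'
#' Walls are smooth surface potentials of the purely repulsive WCA form
#' acting on the particle's distance to the wall.  In the planar slab both
#' z-walls repel monomers and nanoparticles.  The cylinder wall repels
#' monomers (on R minus the distance from the axis) and exerts no force on
#' nanoparticles, emulating a pore wall permeable to nanoparticles.
#'
#' @param geometry a \code{brush_geometry}.
#' @param wall_spec optional overrides: list with \code{epsilon},
#'   \code{sigma_monomer}, \code{sigma_nanoparticle}.
#' @return wall descriptor list with fields \code{epsilon},
#'   \code{sigma_monomer}, \code{sigma_nanoparticle}, \code{acts_on_np}.
#' @export
build_wall <- function(geometry, wall_spec = NULL) {
  spec <- list(epsilon = 1, sigma_monomer = 1, sigma_nanoparticle = 1)
  if (!is.null(wall_spec)) spec <- modifyList(spec, wall_spec)
  spec$acts_on_np <- identical(geometry$kind, "planar_slab")
  spec$form <- "wca"
  spec
}

#' Wall energy of a single particle
#'
#' Evaluates the repulsive wall potential a particle feels in a geometry
#' (zero for a nanoparticle in the cylinder geometry, whose wall is
#' permeable).
#'
#' @param pos position 3-vector.
#' @param kind \code{"monomer"} or \code{"nanoparticle"}.
#' @param geometry a \code{brush_geometry}.
#' @export
wall_energy <- function(pos, kind, geometry) {
  kind <- match.arg(kind, c("monomer", "nanoparticle"))
  ws <- geometry$wall_spec
  sw <- if (kind == "monomer") ws$sigma_monomer else ws$sigma_nanoparticle
  wca <- function(d) {
    if (d <= 0) return(Inf)
    if (d >= 2^(1 / 6) * sw) return(0)
    q <- (sw / d)^6
    4 * ws$epsilon * (q^2 - q) + ws$epsilon
  }
  if (geometry$kind == "planar_slab") {
    wca(pos[3]) + wca(geometry$box[3] - pos[3])
  } else {
    if (kind == "nanoparticle") return(0)
    rad <- sqrt((pos[2] - geometry$box[2] / 2)^2 +
                (pos[3] - geometry$box[3] / 2)^2)
    wca(geometry$R - rad)
  }
}

# plain list for the C++ kernels
geom_to_cpp <- function(geometry) {
  ws <- geometry$wall_spec
  list(
    kind_code = if (geometry$kind == "planar_slab") 0L else 1L,
    box = geometry$box, pbc = geometry$pbc,
    R = geometry$R,
    wall_on_np = isTRUE(ws$acts_on_np),
    eps_w = ws$epsilon, sigw_m = ws$sigma_monomer,
    sigw_n = ws$sigma_nanoparticle
  )
}
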