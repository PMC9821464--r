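#' Define the bead-spring / nanoparticle force field
#'
#' Collects every interaction parameter of the coarse-grained model in reduced
#' Lennard-Jones units: a purely repulsive truncated-and-shifted LJ (WCA)
#' potential between monomers (and, with \code{sigma_m} replaced by
#' \code{sigma_n}, between nanoparticles), a FENE bond between adjacent
#' monomers of a chain, and a displaced LJ potential with an attractive tail
#' of depth \code{eps_b} between monomers and nanoparticles.
#'
#' Derived quantities are computed and validated here: the WCA cutoff
#' \code{rc_m = 2^(1/6) sigma_m}, the hard-core displacement
#' \code{delta = (sigma_n - sigma_m)/2} and the nanoparticle-nanoparticle
#' cutoff \code{rc_nn = 2^(1/6) sigma_n}.  The monomer-nanoparticle potential
#' is cut at \code{r_cut_nm = 3 sigma_m} regardless of \code{sigma_n} and is
#' by default \emph{not} energy-shifted at the cutoff (the discontinuity is
#' about \code{0.0055 eps_b}); set \code{shift_nm = TRUE} to shift it.
#'
#' @param sigma_n nanoparticle diameter (typically 1 or 3).
#' @param eps_b monomer-nanoparticle well depth (>= 0).
#' @param shift_nm logical; energy-shift the monomer-nanoparticle potential at
#'   its cutoff.
#' @param sigma_m monomer diameter (unit of length).
#' @param epsilon repulsive energy scale (unit of energy).
#' @param fene_k FENE spring constant (default 30 epsilon/sigma_m^2).
#' @param fene_r0 FENE maximum bond extension (default 1.5 sigma_m).
#' @return An object of class \code{force_field}.
#' @examples
#' ff <- force_field(sigma_n = 1, eps_b = 1)
#' u_mm(2^(1/6), ff)   # 0 at the cutoff
#' u_nm(2^(1/6), ff)   # -eps_b at the well minimum (delta = 0)
#' @export
force_field <- function(sigma_n = 1, eps_b = 1, shift_nm = FALSE,
                        sigma_m = 1, epsilon = 1,
                        fene_k = 30, fene_r0 = 1.5) {
  stopifnot(sigma_m > 0, sigma_n > 0, epsilon > 0, fene_k > 0, fene_r0 > 0)
  if (eps_b < 0) stop("eps_b must be >= 0")
  ff <- list(
    epsilon  = epsilon,
    sigma_m  = sigma_m,
    sigma_n  = sigma_n,
    eps_b    = eps_b,
    fene_k   = fene_k,
    fene_r0  = fene_r0,
    rc_m     = 2^(1 / 6) * sigma_m,
    r_cut_nm = 3 * sigma_m,
    delta    = (sigma_n - sigma_m) / 2,
    rc_nn    = 2^(1 / 6) * sigma_n,
    shift_nm = isTRUE(shift_nm)
  )
  class(ff) <- "force_field"
  ff
}

#' @export
print.force_field <- function(x, ...) {
  cat("Coarse-grained brush/nanoparticle force field (reduced LJ units)\n")
  cat(sprintf("  monomer:      sigma_m = %g, epsilon = %g, WCA cutoff rc_m = %.6f\n",
              x$sigma_m, x$epsilon, x$rc_m))
  cat(sprintf("  bonds:        FENE k = %g, r0 = %g\n", x$fene_k, x$fene_r0))
  cat(sprintf("  nanoparticle: sigma_n = %g (delta = %g), NN cutoff = %.6f\n",
              x$sigma_n, x$delta, x$rc_nn))
  cat(sprintf("  mon-NP:       eps_b = %g, cutoff = %g, shifted = %s\n",
              x$eps_b, x$r_cut_nm, x$shift_nm))
  invisible(x)
}

# energy shift applied to u_nm when shift_nm is on
unm_shift_value <- function(ff) {
  if (!ff$shift_nm) return(0)
  rs <- ff$r_cut_nm - ff$delta
  q <- (ff$sigma_m / rs)^6
  4 * ff$eps_b * (q^2 - q)
}

#' Monomer-monomer pair energy (WCA repulsion)
#'
#' Truncated-and-shifted Lennard-Jones potential:
#' \eqn{4\epsilon[(\sigma_m/r)^{12} - (\sigma_m/r)^6] + \epsilon} for
#' \eqn{r < 2^{1/6}\sigma_m}, zero beyond.  Purely repulsive and continuous
#' at the cutoff.
#'
#' @param r pair distance(s), > 0.
#' @param ff a \code{\link{force_field}}.
#' @return energy value(s), >= 0.
#' @export
u_mm <- function(r, ff = force_field()) {
  if (any(r <= 0)) stop("u_mm: pair distance must be positive")
  q <- (ff$sigma_m / r)^6
  u <- 4 * ff$epsilon * (q^2 - q) + ff$epsilon
  ifelse(r < ff$rc_m, u, 0)
}

#' FENE bond energy
#'
#' \eqn{-\frac{1}{2} k r_0^2 \ln[1 - (r/r_0)^2]}; finite extensibility:
#' diverges as \eqn{r \to r_0}.  Bond lengths at or beyond \code{r0} are a
#' hard error (an overstretched bond means the simulation must abort, never
#' silently clamp).
#'
#' @inheritParams u_mm
#' @export
u_fene <- function(r, ff = force_field()) {
  if (any(r < 0)) stop("u_fene: pair distance must be non-negative")
  if (any(r >= ff$fene_r0))
    stop(sprintf("FENE bond overstretched: r = %g >= r0 = %g",
                 max(r), ff$fene_r0))
  -0.5 * ff$fene_k * ff$fene_r0^2 * log(1 - (r / ff$fene_r0)^2)
}

#' Monomer-nanoparticle pair energy (displaced LJ with attractive tail)
#'
#' \eqn{4\epsilon_b[(\sigma_m/(r-\Delta))^{12} - (\sigma_m/(r-\Delta))^6]}
#' for \eqn{r < r_{cut}}, zero beyond, with
#' \eqn{\Delta = (\sigma_n - \sigma_m)/2}.  The well has depth
#' \eqn{-\epsilon_b}, attained exactly at \eqn{r = \Delta + 2^{1/6}\sigma_m}.
#' The region \eqn{r \le \Delta} is a hard core and a domain error.
#'
#' @inheritParams u_mm
#' @export
u_nm <- function(r, ff = force_field()) {
  if (any(r <= ff$delta))
    stop(sprintf("u_nm: distance inside the hard core (r <= delta = %g)",
                 ff$delta))
  rs <- r - ff$delta
  q <- (ff$sigma_m / rs)^6
  u <- 4 * ff$eps_b * (q^2 - q) - unm_shift_value(ff)
  ifelse(r < ff$r_cut_nm, u, 0)
}

#' Nanoparticle-nanoparticle pair energy (WCA repulsion at sigma_n)
#'
#' The monomer WCA form with \code{sigma_m} replaced by \code{sigma_n}
#' (cutoff \eqn{2^{1/6}\sigma_n}).
#'
#' @inheritParams u_mm
#' @export
u_nn <- function(r, ff = force_field()) {
  if (any(r <= 0)) stop("u_nn: pair distance must be positive")
  q <- (ff$sigma_n / r)^6
  u <- 4 * ff$epsilon * (q^2 - q) + ff$epsilon
  ifelse(r < ff$rc_nn, u, 0)
}

# analytic dU/dr for each non-bonded pair kind
du_dr <- function(r, kind, ff) {
  switch(kind,
    mm = {
      q <- (ff$sigma_m / r)^6
      ifelse(r < ff$rc_m, (24 * ff$epsilon / r) * (q - 2 * q^2), 0)
    },
    nn = {
      q <- (ff$sigma_n / r)^6
      ifelse(r < ff$rc_nn, (24 * ff$epsilon / r) * (q - 2 * q^2), 0)
    },
    nm = {
      rs <- r - ff$delta
      q <- (ff$sigma_m / rs)^6
      ifelse(r < ff$r_cut_nm, (24 * ff$eps_b / rs) * (q - 2 * q^2), 0)
    },
    stop("unknown pair kind"))
}

#' Analytic pair force between two particles
#'
#' Returns the force \eqn{-\nabla U} exerted on particle i by particle j for
#' the displacement \code{r_vec = x_i - x_j}, dispatching on the species
#' pair: monomer-monomer and nanoparticle-nanoparticle use the WCA repulsion
#' (at \code{sigma_m} and \code{sigma_n} respectively), monomer-nanoparticle
#' the displaced attractive LJ.  Antisymmetric under particle exchange.
#'
#' @param r_vec displacement 3-vector \code{x_i - x_j}.
#' @param kind_i,kind_j species, \code{"monomer"} or \code{"nanoparticle"}.
#' @param ff a \code{\link{force_field}}.
#' @return force 3-vector acting on particle i.
#' @export
pair_force <- function(r_vec, kind_i, kind_j, ff = force_field()) {
  stopifnot(length(r_vec) == 3)
  kinds <- sort(c(match.arg(kind_i, c("monomer", "nanoparticle")),
                  match.arg(kind_j, c("monomer", "nanoparticle"))))
  kind <- if (identical(kinds, c("monomer", "monomer"))) "mm"
          else if (identical(kinds, c("nanoparticle", "nanoparticle"))) "nn"
          else "nm"
  r <- sqrt(sum(r_vec^2))
  if (kind == "nm") {
    if (r <= ff$delta) stop("pair_force: distance inside the hard core")
  } else if (r <= 0) stop("pair_force: zero distance")
  -du_dr(r, kind, ff) * r_vec / r
}

# plain list for the C++ kernels
ff_to_cpp <- function(ff) {
  unclass(ff)
}
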