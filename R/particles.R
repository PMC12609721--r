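#' @include AllClasses.R energetics.R
NULL

#' Release ideal-gas particles into a chamber compartment
#'
#' Places `n` particles uniformly in an axis-aligned region and draws
#' Maxwell-like initial velocities: each component is Gaussian with
#' standard deviation `speedScale / sqrt(mass)` (um/us), so that with
#' `speedScale = 1` the mean kinetic energy per particle is 3/2 in kT
#' units regardless of mass. Directions are isotropic.
#'
#' The piston scenario re-samples velocities from the same distribution
#' each iteration, giving diffusive long-time behaviour with
#' well-defined per-collision momenta.
#'
#' @param n particle count (`>= 0`).
#' @param region 2 x 3 matrix of region bounds (um); must lie inside
#'   `chamber`.
#' @param mass particle mass (> 0, arbitrary mass units).
#' @param speedScale velocity scale: the per-axis standard deviation is
#'   `speedScale / sqrt(mass)` um/us.
#' @param compartment label, `"top"` or `"bottom"`.
#' @param chamber optional 2 x 3 chamber bounds; region must fit inside.
#' @param seed optional integer; when given, positions and velocities
#'   are drawn under this seed without disturbing the caller's RNG.
#' @return a [ParticleEnsemble-class].
#' @export
releaseParticles <- function(n, region, mass, speedScale = 1,
                             compartment = "bottom", chamber = NULL,
                             seed = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("n must be >= 0")
  region <- rbind(region)
  if (!all(dim(region) == c(2L, 3L))) stop("region must be a 2 x 3 matrix")
  if (!is.null(chamber)) {
    chamber <- rbind(chamber)
    if (any(region[1L, ] < chamber[1L, ]) || any(region[2L, ] > chamber[2L, ]))
      stop("release region lies outside the chamber")
  }
  if (mass <= 0) stop("mass must be > 0")
  draw <- function() {
    pos <- cbind(stats::runif(n, region[1L, 1L], region[2L, 1L]),
                 stats::runif(n, region[1L, 2L], region[2L, 2L]),
                 stats::runif(n, region[1L, 3L], region[2L, 3L]))
    vel <- matrix(stats::rnorm(3L * n, sd = speedScale / sqrt(mass)),
                  ncol = 3L)
    list(pos = pos, vel = vel)
  }
  d <- if (is.null(seed)) draw() else withSeed(seed, draw())
  new("ParticleEnsemble", positions = d$pos,
      masses = rep(as.numeric(mass), n), velocities = d$vel,
      compartment = rep(compartment, n))
}

#' Advance particles ballistically and tally piston collisions
#'
#' Each particle flies `v * dt` with specular reflection off the chamber
#' walls and the piston plane. Every piston hit is counted on the
#' particle's side and contributes `2 m |v_z|` to that side's impulse
#' (elastic reflection off the massless plane). Speeds are preserved and
#' no particle changes compartment.
#'
#' @param ensemble a [ParticleEnsemble-class].
#' @param chamberSide chamber cube side length L (um); walls at 0 and L.
#' @param pistonZ piston plane height (um), strictly inside (0, L).
#' @param dt timestep (us).
#' @return list with the advanced `ensemble` and a `tally` list
#'   (`collTop`, `collBottom`, `impulseTop`, `impulseBottom`).
#' @export
advanceAndCollide <- function(ensemble, chamberSide, pistonZ, dt = 1) {
  stopifnot(is(ensemble, "ParticleEnsemble"))
  L <- chamberSide
  if (pistonZ <= 0 || pistonZ >= L)
    stop("piston must lie strictly inside the chamber")
  p <- ensemble@positions
  top <- ensemble@compartment == "top"
  if (any(p < 0) || any(p > L) ||
      any(p[top, 3L] < pistonZ) || any(p[!top, 3L] > pistonZ))
    stop("a particle lies outside its compartment")
  res <- cpp_advance_particles(p, ensemble@velocities, ensemble@masses,
                               as.integer(top), L, pistonZ, dt)
  ensemble@positions <- res$positions
  ensemble@velocities <- res$velocities
  list(ensemble = ensemble,
       tally = list(collTop = res$collTop, collBottom = res$collBottom,
                    impulseTop = res$impulseTop,
                    impulseBottom = res$impulseBottom))
}

#' Move the piston by the net collision impulse
#'
#' The piston is massless and overdamped: it translates along z by
#' `mobility * (impulseBottom - impulseTop)` (bottom hits push up),
#' clamped so that it stays strictly inside the chamber by `margin`.
#'
#' @param pistonZ current piston height (um).
#' @param tally collision tally from [advanceAndCollide()].
#' @param mobility displacement per unit impulse (um per mass*um/us).
#' @param chamberSide chamber side length (um).
#' @param margin minimal piston-wall clearance (um).
#' @return the new piston height (um).
#' @export
applyMomentumKick <- function(pistonZ, tally, mobility, chamberSide,
                              margin = 0.01 * chamberSide) {
  dz <- mobility * (tally$impulseBottom - tally$impulseTop)
  min(max(pistonZ + dz, margin), chamberSide - margin)
}
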