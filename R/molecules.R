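#' @include AllClasses.R mesh-geometry.R
NULL

#' Define a bimolecular binding rule
#'
#' @param speciesA,speciesB reactant species (mobile and static side).
#' @param rate binding rate constant (1/s), applied to candidate pairs
#'   within the pairing distance.
#' @param pairingDistance capture radius (um).
#' @param offRate unbinding rate (1/s); 0 (the default) makes bonds
#'   permanent.
#' @return a [ReactionRule-class].
#' @export
reactionRule <- function(speciesA, speciesB, rate, pairingDistance,
                         offRate = 0) {
  new("ReactionRule", speciesA = as.character(speciesA),
      speciesB = as.character(speciesB), rate = as.numeric(rate),
      pairingDistance = as.numeric(pairingDistance),
      offRate = as.numeric(offRate))
}

#' Place molecules uniformly by area on a mesh
#'
#' Each molecule's host face is chosen with probability proportional to
#' face area, and its position within the face is uniform (barycentric
#' sampling via the square-root trick).
#'
#' @param mesh host [TriMesh-class] (must have faces).
#' @param n molecule count (`>= 0`).
#' @param species species name.
#' @param diffusion 2D diffusion constant (um^2/s).
#' @param seed optional integer; when given, sampling happens under this
#'   seed without disturbing the caller's RNG.
#' @return a [SurfaceMoleculeSet-class] with all molecules unbound.
#' @export
placeMolecules <- function(mesh, n, species = "A", diffusion = 0,
                           seed = NULL) {
  stopifnot(is(mesh, "TriMesh"))
  if (nFaces(mesh) == 0L) stop("cannot place molecules on an empty mesh")
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("n must be >= 0")
  draw <- function() {
    areas <- faceAreas(mesh)
    face <- sample.int(nFaces(mesh), n, replace = TRUE, prob = areas)
    r1 <- sqrt(stats::runif(n))
    r2 <- stats::runif(n)
    bary <- cbind(1 - r1, r1 * (1 - r2), r1 * r2)
    list(face = face, bary = bary)
  }
  d <- if (is.null(seed)) draw() else withSeed(seed, draw())
  if (n == 0L) d <- list(face = integer(0), bary = matrix(0, 0L, 3L))
  new("SurfaceMoleculeSet", species = rep(species, n),
      face = as.integer(d$face), bary = d$bary,
      diffusion = rep(as.numeric(diffusion), n),
      bond = rep(NA_integer_, n))
}

#' 3D embedded positions of surface molecules
#'
#' @param set a [SurfaceMoleculeSet-class].
#' @param mesh its host [TriMesh-class].
#' @return n x 3 matrix of Cartesian positions (um).
#' @export
moleculePositions <- function(set, mesh) {
  stopifnot(is(set, "SurfaceMoleculeSet"), is(mesh, "TriMesh"))
  n <- length(set@species)
  if (n == 0L) return(matrix(0, 0L, 3L))
  fv <- mesh@faces[set@face, , drop = FALSE]
  v <- mesh@vertices
  set@bary[, 1L] * v[fv[, 1L], , drop = FALSE] +
    set@bary[, 2L] * v[fv[, 2L], , drop = FALSE] +
    set@bary[, 3L] * v[fv[, 3L], , drop = FALSE]
}

#' Diffuse unbound molecules on the mesh surface
#'
#' Each unbound molecule takes an in-plane Gaussian step with per-axis
#' variance `2 D dt` in its face's tangent plane; a step that crosses an
#' edge continues into the adjacent face by unfolding the step across
#' the shared edge (rotation about the edge axis), so molecules never
#' leave the surface. At an open boundary the step reflects specularly.
#' Bound molecules do not move.
#'
#' @param set a [SurfaceMoleculeSet-class].
#' @param mesh host [TriMesh-class].
#' @param dt timestep (us). Diffusion constants are in um^2/s, so the
#'   step variance is `2 * D * dt * 1e-6` um^2 per tangent axis.
#' @param adjacency optional precomputed face adjacency (from an earlier
#'   call), to avoid rebuilding it every iteration.
#' @return the updated [SurfaceMoleculeSet-class].
#' @export
diffuseOnSurface <- function(set, mesh, dt = 1, adjacency = NULL) {
  stopifnot(is(set, "SurfaceMoleculeSet"), is(mesh, "TriMesh"))
  if (dt <= 0) stop("dt must be > 0")
  if (!length(set@species)) return(set)
  if (is.null(adjacency)) adjacency <- faceAdjacency(mesh)
  stepSD <- sqrt(2 * set@diffusion * dt * 1e-6)  # um
  frozen <- !is.na(set@bond)
  res <- cpp_diffuse_on_surface(mesh@vertices, mesh@faces, adjacency,
                                set@face, set@bary, frozen, stepSD)
  set@face <- res$face
  set@bary <- res$bary
  set
}

#' Distance-gated candidate pairs between mobile and static molecules
#'
#' Finds all (mobile, static) pairs of currently unbound molecules whose
#' Euclidean embedded distance is at most `pairingDistance` (uniform-grid
#' neighbour search, equivalent to an exact fixed-radius query), then
#' reduces them to a one-to-one matching greedily by increasing
#' distance, ties broken by lower mobile then lower static molecule id.
#'
#' @param mobilePos n x 3 positions of the mobile set (um), e.g. from
#'   [moleculePositions()].
#' @param staticPos k x 3 positions of the static set (um).
#' @param pairingDistance capture radius (um).
#' @param mobileFree,staticFree logical vectors: which molecules are
#'   unbound and eligible (default all).
#' @return a data.frame with columns `mobile`, `static`, `distance`,
#'   one row per matched pair (possibly zero rows).
#' @export
pairCandidates <- function(mobilePos, staticPos, pairingDistance,
                           mobileFree = NULL, staticFree = NULL) {
  mobilePos <- rbind(mobilePos); staticPos <- rbind(staticPos)
  nm <- nrow(mobilePos); ns <- nrow(staticPos)
  if (is.null(mobileFree)) mobileFree <- rep(TRUE, nm)
  if (is.null(staticFree)) staticFree <- rep(TRUE, ns)
  mi <- which(mobileFree); si <- which(staticFree)
  if (!length(mi) || !length(si) || pairingDistance <= 0)
    return(data.frame(mobile = integer(0), static = integer(0),
                      distance = numeric(0)))
  cand <- cpp_pair_candidates(mobilePos[mi, , drop = FALSE],
                              staticPos[si, , drop = FALSE],
                              pairingDistance)
  if (!length(cand$i))
    return(data.frame(mobile = integer(0), static = integer(0),
                      distance = numeric(0)))
  i <- mi[cand$i]; j <- si[cand$j]; d <- cand$d
  ord <- order(d, i, j)
  i <- i[ord]; j <- j[ord]; d <- d[ord]
  usedM <- logical(nm); usedS <- logical(ns)
  keep <- logical(length(i))
  for (t in seq_along(i)) {
    if (!usedM[i[t]] && !usedS[j[t]]) {
      keep[t] <- TRUE
      usedM[i[t]] <- TRUE
      usedS[j[t]] <- TRUE
    }
  }
  data.frame(mobile = i[keep], static = j[keep], distance = d[keep])
}

#' All candidate pairs within the pairing distance (pre-matching)
#'
#' The raw fixed-radius candidate set, before one-to-one matching;
#' mostly useful for verification against a brute-force distance
#' computation.
#'
#' @inheritParams pairCandidates
#' @return data.frame with columns `mobile`, `static`, `distance`.
#' @export
allCandidatePairs <- function(mobilePos, staticPos, pairingDistance) {
  mobilePos <- rbind(mobilePos); staticPos <- rbind(staticPos)
  cand <- cpp_pair_candidates(mobilePos, staticPos, pairingDistance)
  ord <- order(cand$i, cand$j)
  data.frame(mobile = cand$i[ord], static = cand$j[ord],
             distance = cand$d[ord])
}

#' Stochastically bind matched candidate pairs
#'
#' Each matched pair binds with probability `1 - exp(-k dt)` (rate k in
#' 1/s, dt in us). Bound partners are flagged with each other's index
#' and immobilised; they are excluded from future pairing. With
#' `offRate = 0` bonds are permanent and the cumulative bond count is
#' non-decreasing.
#'
#' @param mobile,static the two [SurfaceMoleculeSet-class] objects.
#' @param pairs matched pairs from [pairCandidates()].
#' @param rule the [ReactionRule-class] (uses `rate`).
#' @param dt timestep (us).
#' @return list with updated `mobile`, `static` and `newBonds` (count).
#' @export
applyBinding <- function(mobile, static, pairs, rule, dt = 1) {
  stopifnot(is(mobile, "SurfaceMoleculeSet"),
            is(static, "SurfaceMoleculeSet"), is(rule, "ReactionRule"))
  if (rule@rate < 0) stop("negative rate")
  if (!nrow(pairs))
    return(list(mobile = mobile, static = static, newBonds = 0L))
  p <- 1 - exp(-rule@rate * dt * 1e-6)  # rate 1/s, dt us
  hit <- stats::runif(nrow(pairs)) < p
  if (any(hit)) {
    mi <- pairs$mobile[hit]; si <- pairs$static[hit]
    mobile@bond[mi] <- as.integer(si)
    static@bond[si] <- as.integer(mi)
  }
  list(mobile = mobile, static = static, newBonds = sum(hit))
}

#' Adhesion energy of receptor-ligand bonds
#'
#' Each bond is a quadratic tether: energy
#' `0.5 * kBond * (d - restLength)^2` with `d` the current
#' anchor-to-anchor distance. The stiffness is derived from a per-bond
#' energy scale at a reference extension: `kBond = 2 * perBondEnergy /
#' refExtension^2`, i.e. stretching a bond by `refExtension` beyond rest
#' costs `perBondEnergy` kT. The total enters the Metropolis energy of
#' node moves, so membrane moves that stretch bonds are penalised and
#' moves toward the surface are favoured.
#'
#' @param bondDistances numeric vector of anchor-anchor distances (um).
#' @param perBondEnergy energy at the reference extension (kT).
#' @param restLength bond rest length (um).
#' @param refExtension reference extension (um).
#' @return total adhesion energy (kT).
#' @export
adhesionEnergy <- function(bondDistances, perBondEnergy = 5,
                           restLength = 0.01, refExtension = 0.05) {
  k <- bondStiffness(perBondEnergy, refExtension)
  sum(0.5 * k * (bondDistances - restLength)^2)
}

bondStiffness <- function(perBondEnergy, refExtension) {
  2 * perBondEnergy / refExtension^2
}

#' Export molecule snapshots as CSV
#'
#' One row per molecule: id, species, x, y, z, bond partner id (NA when
#' unbound).
#'
#' @param set a [SurfaceMoleculeSet-class].
#' @param mesh its host mesh.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
exportMolecules <- function(set, mesh, path) {
  pos <- moleculePositions(set, mesh)
  df <- data.frame(id = seq_len(nMolecules(set)), species = set@species,
                   x = pos[, 1L], y = pos[, 2L], z = pos[, 3L],
                   bond = set@bond)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
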