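#' @include AllClasses.R energetics.R
NULL

#' Metropolis acceptance rule
#'
#' Accepts an energy-lowering move always and an energy-raising move
#' with probability `exp(-dE)` (energies in kT, beta = 1). `dE = 0` is
#' accepted, the common limit of both branches.
#'
#' @param deltaE energy change of the proposed move (kT); must be
#'   finite.
#' @return logical: accept the move?
#' @examples
#' metropolisAccept(-1)  # TRUE always
#' @export
metropolisAccept <- function(deltaE) {
  if (length(deltaE) != 1L || is.na(deltaE) || !is.finite(deltaE))
    stop("deltaE must be a single finite number")
  if (deltaE <= 0) return(TRUE)
  stats::runif(1L) < exp(-deltaE)
}

## elastic (+ adhesion) energy restricted to the faces incident to a vertex,
## evaluated with that vertex at `pos`
localVertexEnergy <- function(mesh, vertexId, pos, kappa, incident,
                              bonds = NULL) {
  v <- mesh@vertices
  v[vertexId, ] <- pos
  f <- mesh@faces[incident, , drop = FALSE]
  areas <- triangleAreas(v, f)
  rest <- mesh@restAreas[incident]
  E <- sum(kappa / (2 * rest^2) * (areas - rest)^2)
  if (!is.null(bonds) && length(bonds$face)) {
    sel <- bonds$face %in% incident
    if (any(sel)) {
      bf <- bonds$face[sel]
      bb <- bonds$bary[sel, , drop = FALSE]
      bs <- bonds$static[sel, , drop = FALSE]
      fv <- mesh@faces[bf, , drop = FALSE]
      anchor <- bb[, 1L] * v[fv[, 1L], , drop = FALSE] +
                bb[, 2L] * v[fv[, 2L], , drop = FALSE] +
                bb[, 3L] * v[fv[, 3L], , drop = FALSE]
      d <- sqrt(rowSums((anchor - bs)^2)) - bonds$restLength
      E <- E + sum(0.5 * bonds$kBond * d^2)
    }
  }
  E
}

#' Propose a Metropolis node move
#'
#' Draws an isotropic Gaussian displacement (standard deviation `sigma`
#' per axis) for one mesh vertex and computes the resulting energy
#' change over exactly the faces incident to that vertex (locality: no
#' other face area changes). Clamped boundary vertices yield a no-op
#' proposal; rigid meshes are rejected outright.
#'
#' @param mesh a deformable [TriMesh-class].
#' @param vertexId 1-based vertex index.
#' @param sigma proposal standard deviation per axis (um).
#' @param elastic an [ElasticParams-class].
#' @param bonds optional adhesion-bond description: a list with `face`,
#'   `bary` (b x 3), `static` (b x 3 anchor positions), `kBond`,
#'   `restLength`, as produced by the spreading engine.
#' @return a list of class `MoveProposal` with `vertexId`,
#'   `displacement` and `deltaE` (kT); a clamped vertex gives zero
#'   displacement and `deltaE = 0`.
#' @export
proposeNodeMove <- function(mesh, vertexId, sigma, elastic, bonds = NULL) {
  stopifnot(is(mesh, "TriMesh"))
  if (mesh@rigid)
    stop("cannot propose a node move on a rigid mesh")
  vertexId <- as.integer(vertexId)
  if (vertexId < 1L || vertexId > nVertices(mesh))
    stop("vertexId out of range")
  if (mesh@boundary[vertexId]) {
    return(structure(list(vertexId = vertexId,
                          displacement = c(0, 0, 0), deltaE = 0),
                     class = "MoveProposal"))
  }
  disp <- stats::rnorm(3L, sd = sigma)
  incident <- which(mesh@faces[, 1L] == vertexId |
                    mesh@faces[, 2L] == vertexId |
                    mesh@faces[, 3L] == vertexId)
  kappa <- kappaEff(elastic)
  old <- mesh@vertices[vertexId, ]
  e0 <- localVertexEnergy(mesh, vertexId, old, kappa, incident, bonds)
  e1 <- localVertexEnergy(mesh, vertexId, old + disp, kappa, incident, bonds)
  structure(list(vertexId = vertexId, displacement = disp,
                 deltaE = e1 - e0),
            class = "MoveProposal")
}

#' Check a node move against the movement-space constraints
#'
#' Returns `FALSE` when the moved vertex would leave the movement-space
#' box, when any incident face would become degenerate (area below
#' `areaTol`), or when any incident face would intersect a face of
#' another mesh. Mesh-crossing uses exact segment-triangle tests against
#' nearby faces of the other meshes, pruned by axis-aligned bounding
#' boxes.
#'
#' @param mesh the mesh being moved.
#' @param proposal a `MoveProposal` from [proposeNodeMove()].
#' @param box 2 x 3 matrix of movement-space bounds (um).
#' @param otherMeshes list of [TriMesh-class] objects to test crossings
#'   against (may be empty).
#' @param areaTol degenerate-face threshold (um^2).
#' @return logical: is the move admissible?
#' @export
constraintCheck <- function(mesh, proposal, box,
                            otherMeshes = list(), areaTol = 1e-9) {
  stopifnot(is(mesh, "TriMesh"), inherits(proposal, "MoveProposal"))
  vid <- proposal$vertexId
  newPos <- mesh@vertices[vid, ] + proposal$displacement
  if (any(newPos < box[1L, ]) || any(newPos > box[2L, ])) return(FALSE)
  incident <- which(mesh@faces[, 1L] == vid | mesh@faces[, 2L] == vid |
                    mesh@faces[, 3L] == vid)
  v2 <- mesh@vertices
  v2[vid, ] <- newPos
  movedF <- mesh@faces[incident, , drop = FALSE]
  if (any(triangleAreas(v2, movedF) < areaTol)) return(FALSE)
  if (length(otherMeshes)) {
    ## bounding box of the moved fan, for pruning
    fanV <- v2[unique(as.vector(movedF)), , drop = FALSE]
    lo <- apply(fanV, 2L, min); hi <- apply(fanV, 2L, max)
    for (other in otherMeshes) {
      ov <- other@vertices; of <- other@faces
      fx <- cbind(ov[of[, 1L], 1L], ov[of[, 2L], 1L], ov[of[, 3L], 1L])
      fy <- cbind(ov[of[, 1L], 2L], ov[of[, 2L], 2L], ov[of[, 3L], 2L])
      fz <- cbind(ov[of[, 1L], 3L], ov[of[, 2L], 3L], ov[of[, 3L], 3L])
      near <- which(
        apply(fx, 1L, max) >= lo[1L] & apply(fx, 1L, min) <= hi[1L] &
        apply(fy, 1L, max) >= lo[2L] & apply(fy, 1L, min) <= hi[2L] &
        apply(fz, 1L, max) >= lo[3L] & apply(fz, 1L, min) <= hi[3L])
      if (length(near) &&
          cpp_tris_intersect(v2, movedF, ov, of[near, , drop = FALSE]))
        return(FALSE)
    }
  }
  TRUE
}

## CSR vertex -> incident-face structure used by the C++ sweep
meshIncidenceCSR <- function(mesh) {
  vf <- vertexFaceIncidence(mesh)
  list(ptr = as.integer(c(0L, cumsum(lengths(vf)))),
       idx = as.integer(unlist(vf, use.names = FALSE)) - 1L)
}

## internal: one Metropolis sweep over the free vertices (C++ core),
## with optional adhesion bonds and rigid-sphere obstacle.
sweepMesh <- function(mesh, config, bonds = NULL, sphere = c(0, 0, 0, -1),
                      nSweeps = 1L, traceVertex = -1L, incidence = NULL) {
  if (is.null(incidence)) incidence <- meshIncidenceCSR(mesh)
  vfPtr <- incidence$ptr
  vfIdx <- incidence$idx
  if (is.null(bonds) || !length(bonds$face)) {
    bondFace <- integer(0)
    bondBary <- matrix(0, 0L, 3L)
    bondStatic <- matrix(0, 0L, 3L)
    kBond <- 0; restLength <- 0
  } else {
    bondFace <- as.integer(bonds$face) - 1L
    bondBary <- bonds$bary
    bondStatic <- bonds$static
    kBond <- bonds$kBond
    restLength <- bonds$restLength
  }
  res <- cpp_sweep_vertices(
    mesh@vertices, mesh@faces, mesh@restAreas, mesh@boundary,
    as.integer(vfPtr), vfIdx,
    kappaEff(config@elastic), config@sigma,
    config@box[1L, ], config@box[2L, ],
    config@areaTol, as.numeric(sphere), config@crossTol,
    bondFace, bondBary, bondStatic, kBond, restLength,
    as.integer(nSweeps), as.integer(traceVertex) - 1L)
  mesh@vertices <- res$vertices
  list(mesh = mesh, accepted = res$accepted, attempted = res$attempted,
       trace = res$trace)
}

## internal: apply the pressure-restoring displacement along vertex normals
applyPressure <- function(mesh, pressure) {
  if (is.null(pressure) || pressure@c <= 0) return(mesh)
  V <- enclosedVolume(mesh, allowOpen = TRUE)
  dV <- V - pressure@vInt
  if (dV == 0) return(mesh)
  mag <- pressureDisplacement(dV, pressure)
  ## inward when the volume grew, outward when it shrank
  dir <- if (dV > 0) -1 else 1
  vn <- vertexNormals(mesh)
  free <- !mesh@boundary
  mesh@vertices[free, ] <- mesh@vertices[free, , drop = FALSE] +
    dir * mag * vn[free, , drop = FALSE]
  mesh
}
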