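#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib MembraneMC, .registration = TRUE
NULL

## ---------------------------------------------------------------------------
## TriMesh
## ---------------------------------------------------------------------------

#' Triangulated membrane mesh
#'
#' `TriMesh` is the central geometric container: a triangulated surface
#' with per-face relaxed reference ("rest") areas that anchor the elastic
#' stretching energy. Rest areas are frozen at construction and are never
#' mutated by the dynamics; the elastic energy of a deformed mesh is
#' measured against them. Piston membranes are flagged `rigid`: they
#' translate as a unit along z and carry no elastic energy.
#'
#' Units are micrometres throughout (areas in um^2, volumes in um^3).
#'
#' @slot vertices numeric matrix (n x 3) of vertex coordinates (um).
#' @slot faces integer matrix (m x 3) of 1-based vertex indices with
#'   consistent counterclockwise winding (outward normals for closed
#'   meshes).
#' @slot restAreas numeric vector (length m) of per-face reference areas
#'   (um^2), set once at construction.
#' @slot boundary logical vector (length n); `TRUE` for perimeter
#'   vertices of open meshes (these are clamped by the dynamics).
#' @slot rigid logical scalar; rigid meshes translate as a unit and are
#'   excluded from elastic energy.
#'
#' @seealso [generateIcosphere()], [generateFlatGrid()], [faceAreas()],
#'   [enclosedVolume()], [elasticEnergy()]
#' @export
setClass("TriMesh",
  representation(
    vertices  = "matrix",
    faces     = "matrix",
    restAreas = "numeric",
    boundary  = "logical",
    rigid     = "logical"
  )
)

setValidity("TriMesh", function(object) {
  v <- object@vertices; f <- object@faces
  msgs <- character(0)
  if (ncol(v) != 3L) msgs <- c(msgs, "vertices must be an n x 3 matrix")
  if (ncol(f) != 3L) msgs <- c(msgs, "faces must be an m x 3 matrix")
  if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)))
    msgs <- c(msgs, "vertex coordinates must be finite numbers")
  if (nrow(f) > 0L) {
    if (min(f) < 1L || max(f) > nrow(v))
      msgs <- c(msgs, "face indices must lie in 1..nVertices")
    if (any(f[, 1L] == f[, 2L] | f[, 1L] == f[, 3L] | f[, 2L] == f[, 3L]))
      msgs <- c(msgs, "a face may not repeat a vertex")
  }
  if (length(object@restAreas) != nrow(f))
    msgs <- c(msgs, "restAreas must have one entry per face")
  if (length(object@restAreas) && any(object@restAreas <= 0))
    msgs <- c(msgs, "all rest areas must be strictly positive")
  if (length(object@boundary) != nrow(v))
    msgs <- c(msgs, "boundary flags must have one entry per vertex")
  if (length(object@rigid) != 1L)
    msgs <- c(msgs, "rigid must be a single logical")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## ParticleEnsemble
## ---------------------------------------------------------------------------

#' Ensemble of freely diffusing particles
#'
#' Non-interacting point particles of an ideal gas, used by the piston
#' scenario. Each particle carries a position (um), a mass (arbitrary
#' mass units) and a velocity (um/us), and is labelled with the chamber
#' compartment (`"top"` or `"bottom"`) it was released into. Compartments
#' are impermeable: specular reflection off the piston plane keeps each
#' particle on its own side.
#'
#' @slot positions numeric matrix (n x 3), um.
#' @slot masses numeric vector (length n), > 0.
#' @slot velocities numeric matrix (n x 3), um/us.
#' @slot compartment character vector, `"top"` or `"bottom"`.
#'
#' @seealso [releaseParticles()], [advanceAndCollide()], [kineticEnergy()]
#' @export
setClass("ParticleEnsemble",
  representation(
    positions   = "matrix",
    masses      = "numeric",
    velocities  = "matrix",
    compartment = "character"
  )
)

setValidity("ParticleEnsemble", function(object) {
  n <- nrow(object@positions)
  msgs <- character(0)
  if (ncol(object@positions) != 3L || ncol(object@velocities) != 3L)
    msgs <- c(msgs, "positions and velocities must be n x 3 matrices")
  if (nrow(object@velocities) != n || length(object@masses) != n ||
      length(object@compartment) != n)
    msgs <- c(msgs, "positions, velocities, masses and compartment must agree in length")
  if (length(object@masses) && any(object@masses <= 0))
    msgs <- c(msgs, "all particle masses must be > 0")
  if (length(object@compartment) &&
      !all(object@compartment %in% c("top", "bottom")))
    msgs <- c(msgs, "compartment labels must be 'top' or 'bottom'")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## SurfaceMoleculeSet
## ---------------------------------------------------------------------------

#' Surface-bound molecules on a mesh
#'
#' Species-labelled molecules anchored to mesh faces by barycentric
#' coordinates. Unbound molecules diffuse in the surface (2D diffusion
#' with edge unfolding); molecules bound to a partner are immobilised.
#' Bond partners are indices into a partner `SurfaceMoleculeSet`
#' (e.g. mobile receptors on a cell vs static ligands on a coverslip);
#' the bond relation is symmetric and one-to-one.
#'
#' @slot species character vector of species names (e.g. `"TCR"`,
#'   `"pMHC"`).
#' @slot face integer vector of host face indices (1-based).
#' @slot bary numeric matrix (n x 3) of barycentric coordinates
#'   (non-negative, rows sum to 1).
#' @slot diffusion numeric vector of 2D diffusion constants (um^2/s).
#' @slot bond integer vector; index of the bound partner in the opposing
#'   set, or `NA` when unbound.
#'
#' @seealso [placeMolecules()], [diffuseOnSurface()], [pairCandidates()],
#'   [applyBinding()]
#' @export
setClass("SurfaceMoleculeSet",
  representation(
    species   = "character",
    face      = "integer",
    bary      = "matrix",
    diffusion = "numeric",
    bond      = "integer"
  )
)

setValidity("SurfaceMoleculeSet", function(object) {
  n <- length(object@species)
  msgs <- character(0)
  if (length(object@face) != n || nrow(object@bary) != n ||
      length(object@diffusion) != n || length(object@bond) != n)
    msgs <- c(msgs, "all per-molecule slots must agree in length")
  if (n && ncol(object@bary) != 3L)
    msgs <- c(msgs, "bary must be an n x 3 matrix")
  if (n) {
    if (any(object@bary < -1e-9))
      msgs <- c(msgs, "barycentric coordinates must be non-negative")
    if (any(abs(rowSums(object@bary) - 1) > 1e-6))
      msgs <- c(msgs, "barycentric coordinates must sum to 1")
    if (any(object@diffusion < 0))
      msgs <- c(msgs, "diffusion constants must be >= 0")
  }
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## Parameter blocks
## ---------------------------------------------------------------------------

#' Elastic membrane parameters
#'
#' Rigidities of the two apposed membranes, in kT units. The effective
#' rigidity of the pair is the harmonic-style combination
#' `kappa1 * kappa2 / (kappa1 + kappa2)`; when one membrane is much
#' stiffer than the other the effective rigidity approaches the softer
#' one. See [effectiveRigidity()].
#'
#' @slot kappa1,kappa2 non-negative rigidities (kT).
#' @export
setClass("ElasticParams",
  representation(kappa1 = "numeric", kappa2 = "numeric"))

setValidity("ElasticParams", function(object) {
  if (length(object@kappa1) != 1L || length(object@kappa2) != 1L)
    return("kappa1 and kappa2 must be scalars")
  if (object@kappa1 < 0 || object@kappa2 < 0)
    return("rigidities must be >= 0")
  if (object@kappa1 + object@kappa2 <= 0)
    return("at least one rigidity must be > 0")
  TRUE
})

#' Helfrich bending parameters
#'
#' Bending elastic constant (kT) and an enable flag. Bending is disabled
#' by default: the membrane dynamics use only stretching elasticity, and
#' [bendingEnergy()] refuses to evaluate unless explicitly enabled.
#'
#' @slot kappaB non-negative bending constant (kT).
#' @slot enabled logical scalar.
#' @export
setClass("BendingParams",
  representation(kappaB = "numeric", enabled = "logical"))

setValidity("BendingParams", function(object) {
  if (length(object@kappaB) != 1L || object@kappaB < 0)
    return("kappaB must be a non-negative scalar")
  if (length(object@enabled) != 1L) return("enabled must be a single logical")
  TRUE
})

#' Pressure-displacement parameters
#'
#' The membrane responds to volume change by a deterministic displacement
#' along vertex normals, restoring the enclosed volume toward its initial
#' value `vInt`: magnitude `c * (dV)^2 / vInt` (um), applied inward when
#' the volume grew and outward when it shrank.
#'
#' @slot c non-negative displacement constant.
#' @slot vInt initial enclosed volume (um^3), > 0.
#' @export
setClass("PressureParams",
  representation(c = "numeric", vInt = "numeric"))

setValidity("PressureParams", function(object) {
  if (length(object@c) != 1L || object@c < 0)
    return("displacement constant c must be a non-negative scalar")
  if (length(object@vInt) != 1L || object@vInt <= 0)
    return("initial volume vInt must be > 0")
  TRUE
})

#' Isothermal-work parameters
#'
#' Lumped `nRT` prefactor for the isothermal work `W = nRT log(V2/V1)`
#' done by a compartment of gas whose volume changes from `V1` to `V2`
#' at constant temperature.
#'
#' @slot nRT positive prefactor (energy units).
#' @export
setClass("ThermoParams", representation(nRT = "numeric"))

setValidity("ThermoParams", function(object) {
  if (length(object@nRT) != 1L || object@nRT <= 0)
    return("nRT must be a positive scalar")
  TRUE
})

#' Bimolecular surface binding rule
#'
#' Minimal reaction grammar `A + B -> A.B` with a rate constant that is
#' conditional on the pair being within the pairing distance, plus an
#' optional unbinding rate (default 0; bonds are permanent).
#'
#' @slot speciesA,speciesB reactant species names.
#' @slot rate binding rate constant (1/s) applied to paired candidates.
#' @slot pairingDistance capture radius (um).
#' @slot offRate unbinding rate (1/s), default 0.
#' @export
setClass("ReactionRule",
  representation(speciesA = "character", speciesB = "character",
                 rate = "numeric", pairingDistance = "numeric",
                 offRate = "numeric"))

setValidity("ReactionRule", function(object) {
  if (object@rate < 0) return("rate must be >= 0")
  if (object@pairingDistance <= 0) return("pairing distance must be > 0")
  if (object@offRate < 0) return("offRate must be >= 0")
  TRUE
})

## ---------------------------------------------------------------------------
## SimConfig / SimState / TrajectoryLog
## ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' Scenario-agnostic configuration: timestep (us), iteration count,
#' axis-aligned movement-space box (um), random seed, Gaussian node-move
#' proposal width `sigma` (um), numerical tolerances, the energy
#' parameter blocks, reaction rules, per-bond adhesion stiffness, and
#' scenario-specific parameters in `params`.
#'
#' @slot scenario one of `"piston"`, `"membrane"`, `"spread"`,
#'   `"cellcell"` or `"custom"`.
#' @slot timestep iteration duration (us), default 1.
#' @slot iterations number of iterations.
#' @slot box numeric 2 x 3 matrix: rows are lower/upper bounds (um).
#' @slot seed integer random seed.
#' @slot sigma node proposal standard deviation per axis (um).
#' @slot crossTol mesh-crossing tolerance (um).
#' @slot areaTol degenerate-face rejection threshold (um^2).
#' @slot elastic,bending,pressure,thermo parameter blocks.
#' @slot rules list of [ReactionRule-class] objects.
#' @slot adhesion list with `perBondEnergy` (kT), `restLength` (um) and
#'   `refExtension` (um) defining the quadratic bond tether.
#' @slot outputCadence snapshot cadence (iterations).
#' @slot params named list of scenario-specific parameters.
#' @seealso [simConfig()], [readSimConfig()]
#' @export
setClass("SimConfig",
  representation(
    scenario = "character", timestep = "numeric", iterations = "numeric",
    box = "matrix", seed = "numeric", sigma = "numeric",
    crossTol = "numeric", areaTol = "numeric",
    elastic = "ElasticParams", bending = "BendingParams",
    pressure = "ANY", thermo = "ThermoParams",
    rules = "list", adhesion = "list",
    outputCadence = "numeric", params = "list"
  )
)

setValidity("SimConfig", function(object) {
  msgs <- character(0)
  if (object@timestep <= 0) msgs <- c(msgs, "timestep must be > 0")
  if (object@sigma < 0) msgs <- c(msgs, "sigma must be >= 0")
  if (!all(dim(object@box) == c(2L, 3L)))
    msgs <- c(msgs, "box must be a 2 x 3 matrix of bounds")
  else if (any(object@box[2L, ] <= object@box[1L, ]))
    msgs <- c(msgs, "box must have positive extent in each axis")
  if (object@iterations < 0) msgs <- c(msgs, "iterations must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Live simulation state
#'
#' Mutable-by-replacement container threaded through [stepIteration()]:
#' the named meshes, the optional particle ensemble and piston, the
#' optional mobile/static molecule sets with their host meshes, the
#' configuration, and the accumulating per-iteration records.
#'
#' @slot meshes named list of [TriMesh-class] objects.
#' @slot particles [ParticleEnsemble-class] or `NULL`.
#' @slot pistonMesh name of the rigid piston mesh in `meshes`, or `NA`.
#' @slot mobile,static [SurfaceMoleculeSet-class] or `NULL`.
#' @slot mobileMesh,staticMesh names of the host meshes.
#' @slot config [SimConfig-class].
#' @slot iteration completed-iteration counter.
#' @slot records list of per-iteration observable rows.
#' @slot snapshots list of mesh snapshots keyed by iteration.
#' @slot cache precomputed topology (incidence, adjacency) and
#'   scenario-internal quantities; rebuilt by the runners, never saved.
#' @export
setClass("SimState",
  representation(
    meshes = "list", particles = "ANY", pistonMesh = "character",
    mobile = "ANY", static = "ANY",
    mobileMesh = "character", staticMesh = "character",
    config = "SimConfig", iteration = "numeric",
    records = "list", snapshots = "list", cache = "list"
  )
)

#' Trajectory log
#'
#' Per-iteration observables of a finished run (piston height, collision
#' counts, compartment volumes and work, peak membrane height, contact
#' area, bond counts — whichever the scenario produces) together with
#' mesh snapshots at the configured cadence and run metadata.
#'
#' @slot data data.frame with one row per iteration, first column
#'   `iteration` (strictly increasing).
#' @slot snapshots named list of [TriMesh-class] snapshots, names are
#'   iteration indices.
#' @slot meta list: resolved config, seed, scenario.
#' @seealso [observables()], [exportObservables()], [exportMeshFrames()]
#' @export
setClass("TrajectoryLog",
  representation(data = "data.frame", snapshots = "list", meta = "list"))

setValidity("TrajectoryLog", function(object) {
  d <- object@data
  if (nrow(d) && !"iteration" %in% names(d))
    return("log data must contain an 'iteration' column")
  if (nrow(d) > 1L && any(diff(d$iteration) <= 0))
    return("iteration indices must be strictly increasing")
  if (nrow(d)) {
    num <- vapply(d, is.numeric, logical(1))
    if (any(vapply(d[num], function(col) any(!is.finite(col)), logical(1))))
      return("log contains non-finite observable values")
  }
  TRUE
})
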