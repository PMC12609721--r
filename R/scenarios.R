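#' @include mc-engine.R particles.R molecules.R config.R observables.R
NULL

## ---------------------------------------------------------------------------
## state initialisation per scenario
## ---------------------------------------------------------------------------

initPistonState <- function(config) {
  p <- config@params
  L <- p$chamberSide
  z0 <- p$pistonZ0
  if (z0 <= 0 || z0 >= L)
    stop("piston initial position outside the chamber")
  chamber <- rbind(c(0, 0, 0), rep(L, 3))
  bottom <- releaseParticles(p$nBottom, rbind(c(0, 0, 0), c(L, L, z0)),
                             p$massBottom,
                             speedScale = p$speedBottom * sqrt(p$massBottom),
                             compartment = "bottom", chamber = chamber)
  top <- releaseParticles(p$nTop, rbind(c(0, 0, z0), c(L, L, L)),
                          p$massTop,
                          speedScale = p$speedTop * sqrt(p$massTop),
                          compartment = "top", chamber = chamber)
  ens <- new("ParticleEnsemble",
             positions = rbind(bottom@positions, top@positions),
             masses = c(bottom@masses, top@masses),
             velocities = rbind(bottom@velocities, top@velocities),
             compartment = c(bottom@compartment, top@compartment))
  piston <- generatePistonPlane(L, z0)
  new("SimState", meshes = list(piston = piston), particles = ens,
      pistonMesh = "piston", mobile = NULL, static = NULL,
      mobileMesh = NA_character_, staticMesh = NA_character_,
      config = config, iteration = 0,
      records = list(), snapshots = list(),
      cache = list(pistonZ = z0, L = L,
                   sigmaV = c(rep(p$speedBottom, p$nBottom),
                              rep(p$speedTop, p$nTop)),
                   vBottom0 = L^2 * z0, vTop0 = L^2 * (L - z0)))
}

initMembraneState <- function(config) {
  p <- config@params
  mesh <- generateFlatGrid(p$nx, p$ny, p$side)
  spike <- p$spikeVertex
  if (is.null(spike)) {
    ## vertex closest to the sheet centre
    ctr <- c(p$side / 2, p$side / 2)
    d2 <- (mesh@vertices[, 1L] - ctr[1L])^2 +
          (mesh@vertices[, 2L] - ctr[2L])^2
    d2[mesh@boundary] <- Inf
    spike <- which.min(d2)
  }
  if (mesh@boundary[spike])
    stop("spike vertex lies on the clamped boundary")
  mesh@vertices[spike, 3L] <- mesh@vertices[spike, 3L] + p$spikeHeight
  new("SimState", meshes = list(membrane = mesh), particles = NULL,
      pistonMesh = NA_character_, mobile = NULL, static = NULL,
      mobileMesh = NA_character_, staticMesh = NA_character_,
      config = config, iteration = 0, records = list(), snapshots = list(),
      cache = list(incidence = list(membrane = meshIncidenceCSR(mesh)),
                   spikeVertex = spike))
}

initSpreadingState <- function(config, withLigands = TRUE) {
  p <- config@params
  cell <- generateIcosphere(p$subdivisions, p$radius, p$ruffleAmplitude,
                            seed = config@seed)
  lift <- p$gap - min(cell@vertices[, 3L])
  cell <- translateMesh(cell, c(0, 0, lift))
  if (min(cell@vertices[, 3L]) < 0)
    stop("cell initially intersects the activating surface")
  ## activating surface: square patch at z = 0 centred under the cell
  nsGrid <- max(2L, ceiling(p$surfaceSide / 0.2) + 1L)
  surf <- generateFlatGrid(nsGrid, nsGrid, p$surfaceSide)
  surf <- translateMesh(surf, c(-p$surfaceSide / 2, -p$surfaceSide / 2, 0))
  rule <- config@rules[[1L]]
  mobile <- placeMolecules(cell, p$nMolecules, rule@speciesA,
                           diffusion = p$diffusion)
  nStatic <- if (withLigands) p$nMolecules else 0L
  static <- placeMolecules(surf, nStatic, rule@speciesB, diffusion = 0)
  pressure <- if (p$pressureC > 0)
    pressureParams(p$pressureC, enclosedVolume(cell)) else NULL
  cfg <- config
  cfg@pressure <- pressure
  new("SimState", meshes = list(cell = cell, surface = surf),
      particles = NULL, pistonMesh = NA_character_,
      mobile = mobile, static = static,
      mobileMesh = "cell", staticMesh = "surface",
      config = cfg, iteration = 0, records = list(), snapshots = list(),
      cache = list(incidence = list(cell = meshIncidenceCSR(cell)),
                   adjacency = list(cell = faceAdjacency(cell)),
                   staticPos = moleculePositions(static, surf),
                   cumBonds = 0,
                   kBond = bondStiffness(config@adhesion$perBondEnergy,
                                         config@adhesion$refExtension)))
}

initCellCellState <- function(config) {
  p <- config@params
  cell <- generateIcosphere(p$subdivisions, p$radius, 0, seed = config@seed)
  apc <- generateIcosphere(p$subdivisions, p$radius, 0, seed = config@seed)
  apc@rigid <- TRUE
  apcCenter <- c(0, 0, 2 * p$radius + p$gap)
  apc <- translateMesh(apc, apcCenter)
  if (p$gap <= 0) stop("cells initially overlap")
  pressure <- if (p$pressureC > 0)
    pressureParams(p$pressureC, enclosedVolume(cell)) else NULL
  cfg <- config
  cfg@pressure <- pressure
  nApproach <- max(1L, floor(config@iterations / 2))
  new("SimState", meshes = list(cell = cell, apc = apc),
      particles = NULL, pistonMesh = NA_character_,
      mobile = NULL, static = NULL,
      mobileMesh = NA_character_, staticMesh = NA_character_,
      config = cfg, iteration = 0, records = list(), snapshots = list(),
      cache = list(incidence = list(cell = meshIncidenceCSR(cell)),
                   apcCenter = apcCenter, radius = p$radius,
                   approachStep = p$approach / nApproach,
                   nApproach = nApproach))
}

## ---------------------------------------------------------------------------
## the per-iteration engine
## ---------------------------------------------------------------------------

#' Advance a simulation state by one iteration
#'
#' One full sweep in fixed order: (1) particle flight with
#' collision/impulse accumulation and the piston momentum kick, (2)
#' surface-molecule diffusion, (3) distance-gated pairing and binding,
#' (4) one attempted Metropolis move per non-clamped vertex of every
#' deformable mesh, in a seeded random order, (5) the pressure
#' displacement, (6) observable recording. Particle and molecule counts
#' are conserved; the iteration counter advances by one. Identical
#' states stepped under identical RNG states produce identical results.
#'
#' @param state a [SimState-class] produced by one of the scenario
#'   initialisers (via the `run*` functions).
#' @return the advanced [SimState-class].
#' @export
stepIteration <- function(state) {
  if (!is(state, "SimState") || !length(state@meshes))
    stop("uninitialized simulation state")
  config <- state@config
  p <- config@params
  dt <- config@timestep
  rec <- list(iteration = state@iteration + 1)

  ## (0) scenario pre-step: rigid APC approach (cell-cell contact)
  if (config@scenario == "cellcell" &&
      state@iteration < state@cache$nApproach) {
    ctr <- state@cache$apcCenter
    ctr[3L] <- ctr[3L] - state@cache$approachStep
    state@meshes$apc <- translateMesh(state@meshes$apc,
                                      c(0, 0, -state@cache$approachStep))
    state@cache$apcCenter <- ctr
    ## plastic deformation: push dented vertices out of the rigid sphere
    state@meshes$cell <- pushOutOfSphere(state@meshes$cell, ctr,
                                         state@cache$radius,
                                         config@crossTol)
  }

  ## (1) particles + piston
  if (!is.null(state@particles)) {
    ens <- state@particles
    n <- nrow(ens@positions)
    ens@velocities <- matrix(stats::rnorm(3L * n, sd = state@cache$sigmaV),
                             ncol = 3L)
    adv <- advanceAndCollide(ens, state@cache$L, state@cache$pistonZ, dt)
    ens <- adv$ensemble
    tally <- adv$tally
    zOld <- state@cache$pistonZ
    zNew <- applyMomentumKick(zOld, tally, p$mobility, state@cache$L)
    state@meshes[[state@pistonMesh]] <-
      translateMesh(state@meshes[[state@pistonMesh]], c(0, 0, zNew - zOld))
    ## keep particles on their side of the moved piston
    top <- ens@compartment == "top"
    zc <- ens@positions[, 3L]
    bad <- (!top & zc > zNew) | (top & zc < zNew)
    if (any(bad)) {
      zc[bad] <- 2 * zNew - zc[bad]
      zc <- pmin(pmax(zc, 0), state@cache$L)
      ens@positions[, 3L] <- zc
    }
    state@particles <- ens
    state@cache$pistonZ <- zNew
    L <- state@cache$L
    vB <- L^2 * zNew; vT <- L^2 * (L - zNew)
    rec <- c(rec, list(
      pistonZ = zNew, collTop = tally$collTop,
      collBottom = tally$collBottom,
      impulseTop = tally$impulseTop, impulseBottom = tally$impulseBottom,
      vBottom = vB, vTop = vT,
      workBottom = isothermalWork(config@thermo, state@cache$vBottom0, vB),
      workTop = isothermalWork(config@thermo, state@cache$vTop0, vT)))
  }

  ## (2) surface-molecule diffusion
  if (!is.null(state@mobile) && nMolecules(state@mobile) > 0) {
    state@mobile <- diffuseOnSurface(
      state@mobile, state@meshes[[state@mobileMesh]], dt,
      adjacency = state@cache$adjacency[[state@mobileMesh]])
  }

  ## (3) pairing + binding
  newBonds <- 0L
  if (!is.null(state@mobile) && !is.null(state@static) &&
      length(config@rules)) {
    rule <- config@rules[[1L]]
    if (nMolecules(state@mobile) > 0 && nMolecules(state@static) > 0) {
      mpos <- moleculePositions(state@mobile,
                                state@meshes[[state@mobileMesh]])
      pairs <- pairCandidates(mpos, state@cache$staticPos,
                              rule@pairingDistance,
                              mobileFree = is.na(state@mobile@bond),
                              staticFree = is.na(state@static@bond))
      if (nrow(pairs)) {
        bound <- applyBinding(state@mobile, state@static, pairs, rule, dt)
        state@mobile <- bound$mobile
        state@static <- bound$static
        newBonds <- bound$newBonds
      }
    }
    state@cache$cumBonds <- state@cache$cumBonds + newBonds
    rec <- c(rec, list(newBonds = newBonds,
                       cumBonds = state@cache$cumBonds))
  }

  ## (4) Metropolis vertex sweep over deformable meshes
  sphere <- c(0, 0, 0, -1)
  if (config@scenario == "cellcell")
    sphere <- c(state@cache$apcCenter, state@cache$radius)
  accepted <- 0
  for (nm in names(state@meshes)) {
    mesh <- state@meshes[[nm]]
    if (mesh@rigid) next
    if (config@scenario == "spread" && nm == "surface") next  # static floor
    bonds <- NULL
    if (!is.null(state@mobile) && identical(nm, state@mobileMesh)) {
      bi <- which(!is.na(state@mobile@bond))
      if (length(bi)) {
        bonds <- list(face = state@mobile@face[bi],
                      bary = state@mobile@bary[bi, , drop = FALSE],
                      static = state@cache$staticPos[state@mobile@bond[bi],
                                                     , drop = FALSE],
                      kBond = state@cache$kBond,
                      restLength = config@adhesion$restLength)
      }
    }
    sw <- sweepMesh(mesh, config, bonds = bonds, sphere = sphere,
                    incidence = state@cache$incidence[[nm]])
    state@meshes[[nm]] <- sw$mesh
    accepted <- accepted + sw$accepted
  }
  if (!is.null(state@cache$incidence))
    rec <- c(rec, list(acceptedMoves = accepted))

  ## (5) pressure displacement
  if (!is.null(config@pressure)) {
    nmP <- if ("cell" %in% names(state@meshes)) "cell"
           else names(state@meshes)[1L]
    mesh <- applyPressure(state@meshes[[nmP]], config@pressure)
    if (config@scenario == "cellcell")
      mesh <- pushOutOfSphere(mesh, state@cache$apcCenter,
                              state@cache$radius, config@crossTol)
    if (config@scenario == "spread")
      mesh@vertices[, 3L] <- pmax(mesh@vertices[, 3L], 0)
    state@meshes[[nmP]] <- mesh
  }

  ## (6) scenario observables
  if (config@scenario == "membrane") {
    rec <- c(rec, list(
      peakHeight = peakHeight(state@meshes$membrane, 0),
      elastic = elasticEnergy(state@meshes$membrane, config@elastic)))
  }
  if (config@scenario == "spread") {
    rec <- c(rec, list(contactArea = contactArea(state@meshes$cell, 0,
                                                 p$contactDelta)))
  }
  if (config@scenario == "cellcell") {
    dists <- sqrt(rowSums(sweep(state@meshes$cell@vertices, 2L,
                                state@cache$apcCenter)^2)) -
             state@cache$radius
    rec <- c(rec, list(contactArea = sphereContactArea(
                         state@meshes$cell, state@cache$apcCenter,
                         state@cache$radius, p$contactDelta),
                       minDistance = min(dists)))
  }

  state@iteration <- state@iteration + 1
  state@records[[length(state@records) + 1L]] <- rec
  if (config@outputCadence > 0 &&
      state@iteration %% config@outputCadence == 0) {
    nmS <- if ("cell" %in% names(state@meshes)) "cell"
           else names(state@meshes)[1L]
    state@snapshots[[as.character(state@iteration)]] <- state@meshes[[nmS]]
  }
  state
}

## project vertices that penetrated a rigid sphere back to its surface
pushOutOfSphere <- function(mesh, center, radius, tol) {
  d <- sweep(mesh@vertices, 2L, center)
  r <- sqrt(rowSums(d^2))
  inside <- r < radius + tol
  if (any(inside)) {
    scale <- (radius + tol) / pmax(r[inside], 1e-12)
    mesh@vertices[inside, ] <- sweep(d[inside, , drop = FALSE] * scale,
                                     2L, center, "+")
  }
  mesh
}

## area of faces whose vertices all lie within delta of a sphere surface
sphereContactArea <- function(mesh, center, radius, delta) {
  d <- abs(sqrt(rowSums(sweep(mesh@vertices, 2L, center)^2)) - radius)
  close_ <- d <= delta
  f <- mesh@faces
  sel <- close_[f[, 1L]] & close_[f[, 2L]] & close_[f[, 3L]]
  if (!any(sel)) return(0)
  sum(triangleAreas(mesh@vertices, f[sel, , drop = FALSE]))
}

## shared run loop
runLoop <- function(state) {
  config <- state@config
  iters <- as.integer(config@iterations)
  state@snapshots[["0"]] <-
    state@meshes[[if ("cell" %in% names(state@meshes)) "cell"
                  else names(state@meshes)[1L]]]
  for (i in seq_len(iters)) state <- stepIteration(state)
  makeTrajectoryLog(state@records, state@snapshots,
                    meta = list(scenario = config@scenario,
                                seed = config@seed, config = config))
}

## ---------------------------------------------------------------------------
## turn-key runners
## ---------------------------------------------------------------------------

#' Run the ideal-gas piston scenario
#'
#' Particles in the two compartments of a cubic chamber collide with a
#' rigid massless piston plane; the net collision impulse moves the
#' piston (overdamped). With equal per-axis speeds, a compartment of
#' heavier particles transfers more momentum per collision and the
#' piston drifts away from it; with equal masses and speeds the piston
#' performs an unbiased one-dimensional random walk.
#'
#' @param config a [SimConfig-class] from [pistonConfig()].
#' @return a [TrajectoryLog-class] with per-iteration piston height,
#'   collision counts, impulses, compartment volumes and isothermal
#'   work.
#' @export
runPiston <- function(config) {
  stopifnot(is(config, "SimConfig"), config@scenario == "piston")
  set.seed(as.integer(config@seed))
  runLoop(initPistonState(config))
}

#' Run the fluctuating-membrane (spike relaxation) scenario
#'
#' A flat square membrane with clamped perimeter, one interior vertex
#' displaced upward to a configured spike height, relaxes under the
#' stretching elasticity while fluctuating thermally. The logged peak
#' height decays to the thermal fluctuation band.
#'
#' @param config a [SimConfig-class] from [membraneConfig()].
#' @return a [TrajectoryLog-class] with per-iteration peak height and
#'   elastic energy.
#' @export
runFluctuatingMembrane <- function(config) {
  stopifnot(is(config, "SimConfig"), config@scenario == "membrane")
  set.seed(as.integer(config@seed))
  runLoop(initMembraneState(config))
}

#' Run the T cell spreading scenario
#'
#' A ruffled icosphere carrying mobile receptors hovers just above an
#' activating surface carrying static ligands. Receptors diffuse,
#' pair with ligands within the pairing distance and bind; bonds tether
#' the membrane to the surface and bias its Metropolis moves downward,
#' while internal pressure restores the enclosed volume. Contact area
#' and cumulative bonds grow as the cell spreads.
#'
#' @param config a [SimConfig-class] from [spreadingConfig()].
#' @param withLigands set `FALSE` for the ligand-free ablation control
#'   (no static molecules; everything else identical).
#' @return a [TrajectoryLog-class] with per-iteration contact area, new
#'   and cumulative bond counts, and mesh snapshots.
#' @export
runCellSpreading <- function(config, withLigands = TRUE) {
  stopifnot(is(config, "SimConfig"), config@scenario == "spread")
  set.seed(as.integer(config@seed))
  runLoop(initSpreadingState(config, withLigands = withLigands))
}

#' Run the reduced cell-cell contact scenario
#'
#' A rigid icosphere (the antigen-presenting cell) approaches a
#' deformable icosphere along z; the deformable cell dents plastically
#' around the contact (no interpenetration at any iteration), and
#' enabling internal pressure produces induced spreading around the
#' contact beyond the dent.
#'
#' @param config a [SimConfig-class] from [cellCellConfig()].
#' @return a [TrajectoryLog-class] with per-iteration contact area and
#'   minimum surface separation.
#' @export
runCellCell <- function(config) {
  stopifnot(is(config, "SimConfig"), config@scenario == "cellcell")
  set.seed(as.integer(config@seed))
  runLoop(initCellCellState(config))
}
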