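#' @include AllClasses.R energetics.R molecules.R
NULL

#' Build a simulation configuration
#'
#' Central constructor for [SimConfig-class]; the scenario helpers
#' ([pistonConfig()], [membraneConfig()], [spreadingConfig()],
#' [cellCellConfig()]) call this with scenario-appropriate defaults.
#'
#' @param scenario scenario tag.
#' @param timestep iteration duration (us).
#' @param iterations iteration count.
#' @param box 2 x 3 matrix of movement-space bounds (um).
#' @param seed integer random seed.
#' @param sigma node-move proposal standard deviation (um).
#' @param crossTol mesh-crossing tolerance (um).
#' @param areaTol degenerate-face threshold (um^2).
#' @param elastic,bending,pressure,thermo parameter blocks (see
#'   [elasticParams()] and friends); `pressure` may be `NULL`.
#' @param rules list of [ReactionRule-class] objects.
#' @param adhesion list with `perBondEnergy` (kT), `restLength` (um),
#'   `refExtension` (um).
#' @param outputCadence snapshot cadence in iterations.
#' @param params named list of scenario-specific parameters.
#' @return a [SimConfig-class].
#' @export
simConfig <- function(scenario = "custom", timestep = 1, iterations = 100,
                      box = rbind(c(-10, -10, -10), c(10, 10, 10)),
                      seed = 1L, sigma = 0.01, crossTol = 1e-9,
                      areaTol = 1e-9, elastic = elasticParams(),
                      bending = bendingParams(), pressure = NULL,
                      thermo = thermoParams(), rules = list(),
                      adhesion = list(perBondEnergy = 5, restLength = 0.01,
                                      refExtension = 0.05),
                      outputCadence = 100, params = list()) {
  new("SimConfig", scenario = scenario, timestep = timestep,
      iterations = iterations, box = box, seed = as.numeric(seed),
      sigma = sigma, crossTol = crossTol, areaTol = areaTol,
      elastic = elastic, bending = bending, pressure = pressure,
      thermo = thermo, rules = rules, adhesion = adhesion,
      outputCadence = outputCadence, params = params)
}

#' Piston scenario configuration
#'
#' An ideal-gas piston: a cube chamber of side `chamberSide` split by a
#' rigid massless piston plane, with particles released in each
#' compartment. Masses set the per-collision momentum transfer; the
#' per-axis RMS molecular speed is set per compartment (`speedBottom`,
#' `speedTop`, um/us) the way per-species diffusion speeds are assigned
#' in particle-based simulators, so compartments with equal speeds but
#' unequal masses exert unequal pressure and drive piston drift.
#'
#' @param nBottom,nTop particle counts per compartment.
#' @param massBottom,massTop particle masses (arbitrary mass units).
#' @param speedBottom,speedTop per-axis RMS speeds (um/us).
#' @param chamberSide chamber side (um), default 0.5.
#' @param mobility piston displacement per unit net impulse.
#' @param iterations iteration count.
#' @param seed integer seed.
#' @param nRT isothermal-work prefactor.
#' @param pistonZ0 initial piston height (default mid-chamber).
#' @return a [SimConfig-class] for [runPiston()].
#' @export
pistonConfig <- function(nBottom = 2000, nTop = 2000,
                         massBottom = 0.1, massTop = 0.01,
                         speedBottom = 0.02, speedTop = 0.02,
                         chamberSide = 0.5, mobility = 5e-6,
                         iterations = 5000, seed = 1L, nRT = 1,
                         pistonZ0 = chamberSide / 2) {
  simConfig(scenario = "piston", iterations = iterations, seed = seed,
            box = rbind(c(0, 0, 0), rep(chamberSide, 3)),
            thermo = thermoParams(nRT),
            params = list(nBottom = nBottom, nTop = nTop,
                          massBottom = massBottom, massTop = massTop,
                          speedBottom = speedBottom, speedTop = speedTop,
                          chamberSide = chamberSide, mobility = mobility,
                          pistonZ0 = pistonZ0))
}

#' Fluctuating-membrane scenario configuration
#'
#' A flat square membrane with clamped perimeter; one interior vertex is
#' displaced to `spikeHeight` and released, then relaxes under the
#' stretching elasticity while fluctuating thermally.
#'
#' @param nx,ny grid vertex counts.
#' @param side membrane side (um).
#' @param spikeHeight initial spike height (um).
#' @param spikeVertex 1-based index of the spiked vertex; default the
#'   central vertex.
#' @param kappa1,kappa2 membrane rigidities (kT).
#' @param sigma node proposal width (um).
#' @param iterations iteration count.
#' @param seed integer seed.
#' @return a [SimConfig-class] for [runFluctuatingMembrane()].
#' @export
membraneConfig <- function(nx = 20, ny = 20, side = 1, spikeHeight = 0.3,
                           spikeVertex = NULL, kappa1 = 40, kappa2 = 1e6,
                           sigma = 0.006, iterations = 2000, seed = 1L) {
  simConfig(scenario = "membrane", iterations = iterations, seed = seed,
            sigma = sigma,
            box = rbind(c(-side, -side, -2 * side),
                        c(2 * side, 2 * side, 2 * side)),
            elastic = elasticParams(kappa1, kappa2),
            params = list(nx = nx, ny = ny, side = side,
                          spikeHeight = spikeHeight,
                          spikeVertex = spikeVertex))
}

#' T cell spreading scenario configuration
#'
#' A ruffled icosphere ("cell") carrying mobile surface molecules,
#' hovering just above the activating plane z = 0 that carries an equal
#' number of static binding partners. Receptor-ligand bonds form within
#' the pairing distance and tether the membrane to the surface; the
#' feedback between binding and membrane moves produces spreading.
#'
#' @param subdivisions icosphere subdivision depth (4 gives 2562
#'   vertices, the default desk scale).
#' @param radius cell radius (um).
#' @param ruffleAmplitude ruffle amplitude (um). Keep it comparable to
#'   the pairing distance: much larger ruffles reduce the initial
#'   contact to a single spike whose area is too small to ever seed a
#'   bond, and spreading cannot nucleate.
#' @param gap initial clearance between the lowest ruffle and the plane
#'   (um).
#' @param nMolecules molecules per surface.
#' @param diffusion receptor diffusion constant (um^2/s).
#' @param rate binding rate (1/s within pairing distance).
#' @param pairingDistance capture radius (um).
#' @param perBondEnergy adhesion energy scale per bond (kT).
#' @param kappa1,kappa2 membrane rigidities (kT).
#' @param pressureC pressure displacement constant (0 disables).
#' @param sigma node proposal width (um).
#' @param iterations iteration count (default 1000).
#' @param seed integer seed.
#' @param contactDelta proximity threshold defining contact (um).
#' @param outputCadence snapshot cadence.
#' @param surfaceSide side of the square patch of activating surface
#'   carrying static molecules (um), centred under the cell.
#' @return a [SimConfig-class] for [runCellSpreading()].
#' @export
spreadingConfig <- function(subdivisions = 4, radius = 2,
                            ruffleAmplitude = 0.05, gap = 0.02,
                            nMolecules = 5000, diffusion = 5,
                            rate = 2e6, pairingDistance = 0.05,
                            perBondEnergy = 5, kappa1 = 20, kappa2 = 1e6,
                            pressureC = 0.002, sigma = 0.012,
                            iterations = 1000, seed = 1L,
                            contactDelta = 0.05, outputCadence = 250,
                            surfaceSide = 3 * radius) {
  rule <- reactionRule("TCR", "pMHC", rate = rate,
                       pairingDistance = pairingDistance)
  simConfig(scenario = "spread", iterations = iterations, seed = seed,
            sigma = sigma,
            box = rbind(c(-4 * radius, -4 * radius, 0),
                        c(4 * radius, 4 * radius, 8 * radius)),
            elastic = elasticParams(kappa1, kappa2),
            rules = list(rule),
            adhesion = list(perBondEnergy = perBondEnergy,
                            restLength = 0.01, refExtension = 0.05),
            outputCadence = outputCadence,
            params = list(subdivisions = subdivisions, radius = radius,
                          ruffleAmplitude = ruffleAmplitude, gap = gap,
                          nMolecules = nMolecules, diffusion = diffusion,
                          pressureC = pressureC,
                          contactDelta = contactDelta,
                          surfaceSide = surfaceSide))
}

#' Cell-cell contact scenario configuration
#'
#' A deformable icosphere is approached by a rigid icosphere (the
#' "APC") along a configured axis; the rigid sphere plastically dents
#' the deformable one, and enabling internal pressure in the deformable
#' cell produces induced spreading around the contact beyond the dent.
#'
#' @param subdivisions icosphere subdivision depth.
#' @param radius sphere radius (um), both cells.
#' @param gap initial surface-to-surface clearance (um).
#' @param approach total rigid-sphere travel (um) applied in equal
#'   per-iteration steps over the first half of the run.
#' @param pressureC pressure displacement constant for the deformable
#'   cell (0 disables).
#' @param kappa1,kappa2 membrane rigidities (kT).
#' @param sigma node proposal width (um).
#' @param iterations iteration count.
#' @param seed integer seed.
#' @param contactDelta proximity threshold defining contact (um).
#' @return a [SimConfig-class] for [runCellCell()].
#' @export
cellCellConfig <- function(subdivisions = 3, radius = 2, gap = 0.05,
                           approach = 0.8, pressureC = 0.02,
                           kappa1 = 20, kappa2 = 1e6, sigma = 0.012,
                           iterations = 400, seed = 1L,
                           contactDelta = 0.05) {
  simConfig(scenario = "cellcell", iterations = iterations, seed = seed,
            sigma = sigma,
            box = rbind(c(-6 * radius, -6 * radius, -6 * radius),
                        c(6 * radius, 6 * radius, 6 * radius)),
            elastic = elasticParams(kappa1, kappa2),
            params = list(subdivisions = subdivisions, radius = radius,
                          gap = gap, approach = approach,
                          pressureC = pressureC,
                          contactDelta = contactDelta))
}

#' Read a scenario configuration from YAML or JSON
#'
#' The file must contain a top-level `scenario` field naming one of
#' `piston`, `membrane`, `spread` or `cellcell`; the remaining fields
#' override that scenario's constructor defaults (unknown fields are an
#' error). The seed may be overridden from the CLI.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a [SimConfig-class].
#' @export
readSimConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::fromJSON(path, simplifyVector = TRUE)
         else stop("unsupported config format: .", ext)
  if (is.null(raw$scenario)) stop("config must name a 'scenario'")
  scenario <- raw$scenario
  raw$scenario <- NULL
  ctor <- switch(scenario,
                 piston = pistonConfig, membrane = membraneConfig,
                 spread = spreadingConfig, cellcell = cellCellConfig,
                 stop("unknown scenario: ", scenario))
  known <- names(formals(ctor))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config fields for scenario '", scenario, "': ",
         paste(bad, collapse = ", "))
  do.call(ctor, raw)
}
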