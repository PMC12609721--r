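smallPiston <- function(seed = 1, iterations = 40)
  pistonConfig(nBottom = 300, nTop = 300, iterations = iterations,
               seed = seed)

smallSpread <- function(seed = 1, iterations = 30)
  spreadingConfig(subdivisions = 2, radius = 1, nMolecules = 600,
                  iterations = iterations, seed = seed,
                  surfaceSide = 3, outputCadence = 10)

test_that("piston runs conserve particles and partition the chamber", {
  cfg <- smallPiston()
  log <- runPiston(cfg)
  df <- observables(log)
  expect_equal(nrow(df), 40L)
  L <- cfg@params$chamberSide
  ## compartment volumes always sum to the chamber volume
  expect_equal(df$vBottom + df$vTop, rep(L^3, 40), tolerance = 1e-12)
  ## piston never leaves the chamber
  expect_true(all(df$pistonZ > 0 & df$pistonZ < L))
  ## collision counts are non-negative integers
  expect_true(all(df$collTop >= 0 & df$collBottom >= 0))
  ## work starts near zero and is finite throughout
  expect_true(all(is.finite(df$workBottom) & is.finite(df$workTop)))
  ## final state retains every particle
  st <- MembraneMC:::initPistonState(cfg)
  expect_equal(nrow(st@particles@positions),
               cfg@params$nBottom + cfg@params$nTop)
})

test_that("scenario runs are bitwise reproducible under the seed", {
  a <- observables(runPiston(smallPiston(seed = 7)))
  b <- observables(runPiston(smallPiston(seed = 7)))
  expect_identical(a, b)
  cc <- observables(runPiston(smallPiston(seed = 8)))
  expect_false(identical(a, cc))

  m1 <- runFluctuatingMembrane(membraneConfig(nx = 7, ny = 7,
                                              iterations = 25, seed = 5))
  m2 <- runFluctuatingMembrane(membraneConfig(nx = 7, ny = 7,
                                              iterations = 25, seed = 5))
  expect_identical(observables(m1), observables(m2))
  expect_identical(vertices(snapshots(m1)[["0"]]),
                   vertices(snapshots(m2)[["0"]]))

  s1 <- observables(runCellSpreading(smallSpread(seed = 4)))
  s2 <- observables(runCellSpreading(smallSpread(seed = 4)))
  expect_identical(s1, s2)

  c1 <- observables(runCellCell(cellCellConfig(subdivisions = 2,
                                               iterations = 20, seed = 3)))
  c2 <- observables(runCellCell(cellCellConfig(subdivisions = 2,
                                               iterations = 20, seed = 3)))
  expect_identical(c1, c2)
})

test_that("membrane scenario clamps its perimeter and logs the spike", {
  cfg <- membraneConfig(nx = 8, ny = 8, iterations = 30, seed = 2)
  st0 <- MembraneMC:::initMembraneState(cfg)
  expect_equal(peakHeight(st0@meshes$membrane), cfg@params$spikeHeight)
  log <- runFluctuatingMembrane(cfg)
  df <- observables(log)
  expect_equal(nrow(df), 30L)
  expect_true(all(c("peakHeight", "elastic", "acceptedMoves") %in%
                  names(df)))
  ## the clamped perimeter never moves
  final <- snapshots(log)[[length(snapshots(log))]]
  clamped <- boundaryVertices(final)
  expect_identical(vertices(final)[clamped, ],
                   vertices(st0@meshes$membrane)[clamped, ])
})

test_that("spreading conserves molecules and caps bonds", {
  cfg <- smallSpread(seed = 6)
  st <- MembraneMC:::initSpreadingState(cfg)
  nM <- nMolecules(st@mobile)
  nS <- nMolecules(st@static)
  expect_equal(nM, cfg@params$nMolecules)
  expect_equal(nS, cfg@params$nMolecules)
  for (i in 1:25) st <- stepIteration(st)
  ## counts unchanged; bond tables stay mutually consistent
  expect_equal(nMolecules(st@mobile), nM)
  expect_equal(nMolecules(st@static), nS)
  bm <- bondPartners(st@mobile)
  bs <- bondPartners(st@static)
  expect_lte(sum(!is.na(bm)), min(nM, nS))
  expect_equal(sum(!is.na(bm)), sum(!is.na(bs)))
  bound <- which(!is.na(bm))
  expect_equal(bs[bm[bound]], bound)
  ## cumulative bond count in the log matches the state
  df <- do.call(rbind, lapply(st@records, as.data.frame))
  expect_equal(df$cumBonds[nrow(df)], sum(!is.na(bm)))
  expect_true(all(diff(df$cumBonds) >= 0))
  ## the cell never sinks below the activating surface
  expect_gte(min(vertices(st@meshes$cell)[, 3]), 0)
})

test_that("ligand ablation removes the static molecule population", {
  st <- MembraneMC:::initSpreadingState(smallSpread(seed = 2),
                                        withLigands = FALSE)
  expect_equal(nMolecules(st@static), 0L)
  log <- runCellSpreading(smallSpread(seed = 2), withLigands = FALSE)
  df <- observables(log)
  expect_true(all(df$cumBonds == 0))
})

test_that("cell-cell contact dents the deformable cell", {
  cfg <- cellCellConfig(subdivisions = 2, iterations = 60, seed = 11)
  set.seed(cfg@seed)
  st <- MembraneMC:::initCellCellState(cfg)
  for (i in seq_len(cfg@iterations)) st <- stepIteration(st)
  df <- do.call(rbind, lapply(st@records, as.data.frame))
  n <- nrow(df)
  ## the rigid sphere approaches and the gap closes
  expect_lt(df$minDistance[n], df$minDistance[1])
  ## a contact dent appears
  expect_gt(df$contactArea[n], 0)
  expect_equal(df$contactArea[1], 0)
  ## the deformable cell is never inside the rigid sphere
  d <- sqrt(rowSums(sweep(vertices(st@meshes$cell), 2,
                          st@cache$apcCenter)^2))
  expect_gte(min(d), cfg@params$radius - 1e-6)
})

test_that("stepIteration rejects an uninitialised state", {
  st <- MembraneMC:::initMembraneState(membraneConfig(nx = 4, ny = 4,
                                                      iterations = 1))
  st@meshes <- list()
  expect_error(stepIteration(st), "uninitial")
})
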