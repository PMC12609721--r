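test_that("molecule placement is uniform by area with valid barycentrics", {
  ## two faces with a 1:3 area ratio
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(-3, 0, 0))
  m <- triMesh(v, rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
  expect_equal(restAreas(m), c(0.5, 1.5))
  set.seed(21)
  n <- 20000
  mol <- placeMolecules(m, n, species = "TCR", diffusion = 5)
  expect_equal(nMolecules(mol), n)
  expect_true(all(species(mol) == "TCR"))
  expect_true(all(is.na(bondPartners(mol))))
  b <- mol@bary
  expect_true(all(b >= 0 & b <= 1))
  expect_equal(rowSums(b), rep(1, n), tolerance = 1e-12)
  ## face occupancy proportional to area (chi-square)
  counts <- tabulate(mol@face, 2)
  p <- stats::chisq.test(counts, p = c(0.25, 0.75))$p.value
  expect_gt(p, 0.001)
  ## embedded positions lie in the mesh plane
  expect_true(all(abs(moleculePositions(mol, m)[, 3]) < 1e-12))
  ## within-face uniformity: mean barycentric weight is 1/3 each
  expect_true(all(abs(colMeans(b[mol@face == 1L, ]) - 1 / 3) < 0.01))
})

test_that("surface diffusion stays on the surface with MSD ~ 4 D t", {
  sph <- generateIcosphere(3, 2)
  set.seed(6)
  mol <- placeMolecules(sph, 400, diffusion = 5)
  p0 <- moleculePositions(mol, sph)
  dt <- 1
  steps <- 200
  adj <- faceAdjacency(sph)
  cur <- mol
  for (s in seq_len(steps))
    cur <- diffuseOnSurface(cur, sph, dt, adjacency = adj)
  p1 <- moleculePositions(cur, sph)
  ## never leaves the faceted surface: radii stay between the mesh
  ## inradius and the circumradius
  r <- sqrt(rowSums(p1^2))
  expect_true(all(r <= 2 + 1e-9))
  expect_true(all(r >= 2 * 0.98))
  ## 2D MSD = 4 D t for t much shorter than the curvature time R^2/D
  msd <- mean(rowSums((p1 - p0)^2))
  expected <- 4 * 5 * steps * dt * 1e-6
  expect_equal(msd, expected, tolerance = 0.15)
  ## molecule count and species conserved
  expect_equal(nMolecules(cur), 400L)
  expect_true(all(cur@face >= 1L & cur@face <= nFaces(sph)))
})

test_that("bound molecules do not diffuse; unbound stream is unchanged", {
  g <- generateFlatGrid(6, 6, 2)
  set.seed(9)
  mol <- placeMolecules(g, 50, diffusion = 10)
  bound <- mol
  bound@bond[1:25] <- 1L   # freeze half
  set.seed(33); freeRun <- diffuseOnSurface(mol, g, 1)
  set.seed(33); mixRun <- diffuseOnSurface(bound, g, 1)
  pf <- moleculePositions(freeRun, g)
  pm <- moleculePositions(mixRun, g)
  p0 <- moleculePositions(mol, g)
  ## frozen molecules exactly in place
  expect_equal(pm[1:25, ], p0[1:25, ], tolerance = 1e-15)
  ## the unbound molecules take the same steps whether or not others are
  ## bound (per-molecule RNG draws are position-independent)
  expect_equal(pm[26:50, ], pf[26:50, ], tolerance = 1e-15)
  expect_false(isTRUE(all.equal(pm[26:50, ], p0[26:50, ])))
})

test_that("candidate pair search equals brute force exactly", {
  for (seed in 1:3) {
    set.seed(seed)
    a <- matrix(runif(300 * 3), ncol = 3)
    b <- matrix(runif(200 * 3), ncol = 3)
    cutoff <- 0.12
    got <- allCandidatePairs(a, b, cutoff)
    want <- bruteForcePairs(a, b, cutoff)
    expect_identical(pairKey(got), pairKey(want))
    ## reported distances are the true Euclidean distances
    d <- sqrt(rowSums((a[got$mobile, , drop = FALSE] -
                       b[got$static, , drop = FALSE])^2))
    expect_equal(got$distance, d, tolerance = 1e-12)
  }
})

test_that("matching is one-to-one, nearest-first, and respects bonds", {
  ## hand-built instance: one static molecule contested by two mobiles
  mob <- rbind(c(0, 0, 0), c(0.03, 0, 0))
  sta <- rbind(c(0.01, 0, 0), c(1, 1, 1))
  pairs <- pairCandidates(mob, sta, 0.05)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$mobile, 1L)        # the closer mobile wins
  expect_equal(pairs$static, 1L)
  ## excluding the winner lets the other mobile match
  p2 <- pairCandidates(mob, sta, 0.05, mobileFree = c(FALSE, TRUE))
  expect_equal(p2$mobile, 2L)
  ## already-bound static molecules are skipped
  p3 <- pairCandidates(mob, sta, 0.05, staticFree = c(FALSE, TRUE))
  expect_equal(nrow(p3), 0L)
  ## larger random instance: matching is injective both ways
  set.seed(14)
  a <- matrix(runif(600), ncol = 3)
  b <- matrix(runif(600), ncol = 3)
  m <- pairCandidates(a, b, 0.2)
  expect_false(any(duplicated(m$mobile)))
  expect_false(any(duplicated(m$static)))
  expect_true(all(m$distance <= 0.2))
})

test_that("binding probability follows 1 - exp(-k dt)", {
  rule0 <- reactionRule("A", "B", rate = 0, pairingDistance = 1)
  ruleFast <- reactionRule("A", "B", rate = 1e9, pairingDistance = 1)
  ruleMid <- reactionRule("A", "B", rate = 5e5, pairingDistance = 1)
  g <- generateFlatGrid(3, 3, 1)
  n <- 4000
  mkSet <- function() new("SurfaceMoleculeSet",
                          species = rep("A", n), face = rep(1L, n),
                          bary = matrix(1 / 3, n, 3),
                          diffusion = rep(0, n),
                          bond = rep(NA_integer_, n))
  pairs <- data.frame(mobile = seq_len(n), static = seq_len(n),
                      distance = 0)
  set.seed(10)
  none <- applyBinding(mkSet(), mkSet(), pairs, rule0)
  expect_equal(none$newBonds, 0L)
  all_ <- applyBinding(mkSet(), mkSet(), pairs, ruleFast)
  expect_equal(all_$newBonds, n)
  ## symmetric bond bookkeeping
  expect_equal(bondPartners(all_$mobile), seq_len(n))
  expect_equal(bondPartners(all_$static), seq_len(n))
  ## rate 5e5 /s over 1 us: p = 1 - exp(-0.5)
  mid <- applyBinding(mkSet(), mkSet(), pairs, ruleMid, dt = 1)
  p <- 1 - exp(-0.5)
  expect_lt(abs(mid$newBonds / n - p), 4 * sqrt(p * (1 - p) / n))
  expect_error(reactionRule("A", "B", -1, 1), ">= 0")
})
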