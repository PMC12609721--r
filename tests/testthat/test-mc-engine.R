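test_that("Metropolis rule: analytic acceptance and guards", {
  ## dE <= 0 accepts deterministically
  expect_true(all(replicate(50, metropolisAccept(-1))))
  expect_true(all(replicate(50, metropolisAccept(0))))
  ## dE = ln 2 accepts with probability exactly 1/2
  set.seed(42)
  n <- 20000
  acc <- mean(replicate(n, metropolisAccept(log(2))))
  expect_lt(abs(acc - 0.5), 4 * sqrt(0.25 / n))
  ## dE very large essentially never accepts
  set.seed(42)
  expect_false(any(replicate(200, metropolisAccept(50))))
  expect_error(metropolisAccept(NaN), "finite")
  expect_error(metropolisAccept(Inf), "finite")
  expect_error(metropolisAccept(c(1, 2)), "single")
})

test_that("acceptance frequencies satisfy detailed balance analytically", {
  ## For Metropolis, P(x->y)/P(y->x) must equal exp(-dE) for dE > 0.
  set.seed(7)
  n <- 40000
  dE <- 1.2
  fwd <- mean(replicate(n, metropolisAccept(dE)))   # uphill
  bwd <- 1                                          # downhill, certain
  expect_lt(abs(fwd / bwd - exp(-dE)), 4 * sqrt(exp(-dE) / n))
})

test_that("proposed node move reports the exact local energy change", {
  set.seed(3)
  g <- generateFlatGrid(4, 4, 1)
  g@vertices <- g@vertices + matrix(rnorm(length(g@vertices), sd = 0.02),
                                    ncol = 3)
  el <- elasticParams(5, 20)
  free <- which(!boundaryVertices(g))
  for (vid in free) {
    e0 <- elasticEnergy(g, el)
    prop <- proposeNodeMove(g, vid, sigma = 0.05, elastic = el)
    g2 <- g
    g2@vertices[vid, ] <- g2@vertices[vid, ] + prop$displacement
    ## locality: the reported dE equals the full-mesh energy difference
    expect_equal(prop$deltaE, elasticEnergy(g2, el) - e0,
                 tolerance = 1e-10)
  }
})

test_that("clamped vertices do not move; rigid meshes refuse moves", {
  g <- generateFlatGrid(4, 4, 1)
  el <- elasticParams(1, 1)
  bid <- which(boundaryVertices(g))[1]
  prop <- proposeNodeMove(g, bid, 0.1, el)
  expect_equal(prop$displacement, c(0, 0, 0))
  expect_equal(prop$deltaE, 0)
  r <- generatePistonPlane(1, 0.5)
  expect_true(isRigid(r))
  expect_error(proposeNodeMove(r, 1, 0.1, el), "rigid")
})

test_that("constraint check enforces box, degeneracy and mesh crossing", {
  g <- generateFlatGrid(3, 3, 1)
  el <- elasticParams(1, 1)
  vid <- which(!boundaryVertices(g))[1]
  mk <- function(disp) structure(list(vertexId = vid, displacement = disp,
                                      deltaE = 0), class = "MoveProposal")
  box <- rbind(c(-1, -1, -1), c(2, 2, 1))
  ## admissible small move
  expect_true(constraintCheck(g, mk(c(0, 0, 0.1)), box))
  ## box violation
  expect_false(constraintCheck(g, mk(c(0, 0, 5)), box))
  ## collapse onto a neighbour makes incident faces degenerate
  nb <- setdiff(unique(as.vector(
    faces(g)[rowSums(faces(g) == vid) > 0, ])), vid)[1]
  disp <- vertices(g)[nb, ] - vertices(g)[vid, ]
  expect_false(constraintCheck(g, mk(disp), box, areaTol = 1e-6))
  ## crossing another mesh: a plane hovering right above the vertex
  other <- translateMesh(generateFlatGrid(3, 3, 1), c(0, 0, 0.25))
  expect_false(constraintCheck(g, mk(c(0, 0, 0.5)), box,
                               otherMeshes = list(other)))
  expect_true(constraintCheck(g, mk(c(0, 0, 0.1)), box,
                              otherMeshes = list(other)))
})

test_that("single free vertex samples its Boltzmann distribution", {
  ## One interior vertex under stretching elasticity; compare sampled
  ## per-axis variances at 1e5 sweeps against deterministic quadrature
  ## of exp(-E) on a 3D grid.
  g <- generateFlatGrid(3, 3, 0.3)
  vid <- which(!boundaryVertices(g))
  expect_length(vid, 1L)
  kap <- effectiveRigidity(40, 1e6)
  rest <- vertices(g)[vid, ]
  h <- 0.15
  gr <- seq(-h, h, length.out = 81)
  pts <- as.matrix(expand.grid(x = gr + rest[1], y = gr + rest[2],
                               z = gr + rest[3]))
  w <- exp(-kap * vertexEnergyProfile(g, vid, pts))
  ## the quadrature box captures all the mass
  edge <- abs(pts[, 1] - rest[1]) > 0.9 * h |
          abs(pts[, 3] - rest[3]) > 0.9 * h
  expect_lt(max(w[edge]) / max(w), 1e-10)
  oracleVar <- vapply(1:3, function(ax) {
    mu <- sum(w * pts[, ax]) / sum(w)
    sum(w * (pts[, ax] - mu)^2) / sum(w)
  }, numeric(1))

  cfg <- simConfig(sigma = 0.02, elastic = elasticParams(40, 1e6),
                   box = rbind(c(-1, -1, -1), c(1, 1, 1)))
  set.seed(99)
  sw <- MembraneMC:::sweepMesh(g, cfg, nSweeps = 1e5L, traceVertex = vid)
  samp <- sw$trace[-seq_len(1000), ]     # discard burn-in
  ratio <- apply(samp, 2, var) / oracleVar
  expect_true(all(abs(ratio - 1) < 0.10))
  ## healthy acceptance rate, neither frozen nor trivial
  expect_gt(sw$accepted / sw$attempted, 0.1)
  expect_lt(sw$accepted / sw$attempted, 0.9)
})

test_that("sweeps are deterministic under a seed and clamp the boundary", {
  g <- generateFlatGrid(5, 5, 1)
  g@vertices[13, 3] <- 0.2
  cfg <- simConfig(sigma = 0.01, elastic = elasticParams(10, 1e6),
                   box = rbind(c(-2, -2, -2), c(3, 3, 3)))
  set.seed(4); a <- MembraneMC:::sweepMesh(g, cfg, nSweeps = 20L)
  set.seed(4); b <- MembraneMC:::sweepMesh(g, cfg, nSweeps = 20L)
  expect_identical(a$mesh@vertices, b$mesh@vertices)
  expect_identical(a$accepted, b$accepted)
  ## boundary never moves
  clamped <- boundaryVertices(g)
  expect_identical(a$mesh@vertices[clamped, ], g@vertices[clamped, ])
  ## free vertices did move
  expect_false(identical(a$mesh@vertices[!clamped, ],
                         g@vertices[!clamped, ]))
})

test_that("zero-width proposals leave the mesh untouched", {
  g <- generateFlatGrid(4, 4, 1)
  cfg <- simConfig(sigma = 0, elastic = elasticParams(1, 1),
                   box = rbind(c(-2, -2, -2), c(3, 3, 3)))
  set.seed(1)
  sw <- MembraneMC:::sweepMesh(g, cfg, nSweeps = 5L)
  expect_equal(sw$mesh@vertices, g@vertices)
})
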