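test_that("triMesh validates its combinatorics", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  m <- triMesh(v, rbind(c(1L, 2L, 3L)))
  expect_s4_class(m, "TriMesh")
  expect_equal(nVertices(m), 3L)
  expect_equal(nFaces(m), 1L)
  expect_equal(restAreas(m), 0.5)
  ## a single open triangle: every vertex is on the boundary
  expect_true(all(boundaryVertices(m)))
  expect_error(triMesh(v, rbind(c(1L, 2L, 4L))), "range|index")
  expect_error(triMesh(v, rbind(c(1L, 2L, 2L))), "repeat|degenerate")
})

test_that("icosphere counts, radius, closure and Euler characteristic", {
  for (s in 0:3) {
    m <- generateIcosphere(s, 1)
    expect_equal(nVertices(m), 2L + 10L * 4L^s)
    expect_equal(nFaces(m), 20L * 4L^s)
    expect_true(isClosed(m))
    expect_equal(eulerCharacteristic(m), 2L)
    expect_equal(max(abs(sqrt(rowSums(vertices(m)^2)) - 1)), 0,
                 tolerance = 1e-12)
    expect_false(any(boundaryVertices(m)))
  }
})

test_that("icosphere volume and area converge to the smooth sphere", {
  m <- generateIcosphere(4, 1)
  expect_equal(enclosedVolume(m), 4 * pi / 3, tolerance = 0.01)
  expect_equal(sum(faceAreas(m)), 4 * pi, tolerance = 0.01)
  ## radius scaling
  m2 <- generateIcosphere(2, 3)
  expect_equal(enclosedVolume(m2),
               27 * enclosedVolume(generateIcosphere(2, 1)),
               tolerance = 1e-12)
})

test_that("ruffled icosphere is reproducible and stays near the sphere", {
  a <- generateIcosphere(2, 1, ruffleAmplitude = 0.1, seed = 7)
  b <- generateIcosphere(2, 1, ruffleAmplitude = 0.1, seed = 7)
  cc <- generateIcosphere(2, 1, ruffleAmplitude = 0.1, seed = 8)
  expect_identical(vertices(a), vertices(b))
  expect_false(identical(vertices(a), vertices(cc)))
  r <- sqrt(rowSums(vertices(a)^2))
  expect_true(all(r >= 0.9 - 1e-12 & r <= 1.1 + 1e-12))
  ## ruffling must not touch the caller's RNG stream
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(generateIcosphere(1, 1, 0.1, seed = 3))
  x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("flat grid combinatorics, areas and clamped perimeter", {
  g <- generateFlatGrid(4, 5, 2)
  expect_equal(nVertices(g), 20L)
  expect_equal(nFaces(g), 2L * 3L * 4L)
  expect_equal(sum(faceAreas(g)), 4, tolerance = 1e-12)
  expect_false(isClosed(g))
  ## V - E + F = 1 for a disc
  expect_equal(eulerCharacteristic(g), 1L)
  v <- vertices(g)
  onEdge <- v[, 1] %in% range(v[, 1]) | v[, 2] %in% range(v[, 2])
  expect_equal(boundaryVertices(g), onEdge)
  ## faces wound consistently towards +z
  expect_true(all(faceNormals(g)[, 3] > 0))
})

test_that("box mesh is closed with exact volume and outward normals", {
  b <- generateBox(2)
  expect_true(isClosed(b))
  expect_equal(enclosedVolume(b), 8, tolerance = 1e-12)
  ctr <- colMeans(vertices(b))
  fn <- faceNormals(b)
  f <- faces(b)
  cent <- (vertices(b)[f[, 1], ] + vertices(b)[f[, 2], ] +
           vertices(b)[f[, 3], ]) / 3
  expect_true(all(rowSums(fn * sweep(cent, 2, ctr)) > 0))
})

test_that("faceAdjacency is symmetric and marks boundary edges", {
  g <- generateFlatGrid(3, 3, 1)
  adj <- faceAdjacency(g)
  f <- faces(g)
  for (t in seq_len(nrow(f))) {
    for (k in 1:3) {
      nb <- adj[t, k]
      if (nb == 0L) next
      ## the neighbour must list t back across some edge
      expect_true(t %in% adj[nb, ])
      ## and share exactly the two vertices of that edge
      shared <- intersect(f[t, ], f[nb, ])
      expect_length(shared, 2L)
    }
  }
  ## a closed mesh has no boundary edges
  expect_true(all(faceAdjacency(generateIcosphere(1, 1)) > 0L))
})

test_that("vertexFaceIncidence inverts the face table", {
  m <- generateIcosphere(1, 1)
  vf <- vertexFaceIncidence(m)
  f <- faces(m)
  for (vtx in c(1L, 5L, nVertices(m))) {
    expect_setequal(vf[[vtx]],
                    which(f[, 1] == vtx | f[, 2] == vtx | f[, 3] == vtx))
  }
})

test_that("translateMesh moves vertices only and preserves volume", {
  m <- generateIcosphere(2, 1)
  t1 <- translateMesh(m, c(1, -2, 0.5))
  expect_equal(vertices(t1), sweep(vertices(m), 2, c(1, -2, 0.5), "+"))
  expect_identical(faces(t1), faces(m))
  expect_equal(enclosedVolume(t1), enclosedVolume(m), tolerance = 1e-9)
})

test_that("degenerate faces are rejected by faceAreas via validity", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_error(triMesh(v, rbind(c(1L, 2L, 3L))), "degenerate|positive")
})

test_that("enclosedVolume refuses open meshes unless told otherwise", {
  g <- generateFlatGrid(3, 3, 1)
  expect_error(enclosedVolume(g), "closed")
  expect_silent(enclosedVolume(g, allowOpen = TRUE))
})
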