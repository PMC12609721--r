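test_that("kinetic energy and momentum closed forms", {
  expect_equal(kineticEnergy(2, matrix(c(0, 0, 3), 1)), 9)
  expect_equal(kineticEnergy(c(1, 4), rbind(c(1, 0, 0), c(0, 0.5, 0))),
               0.5 + 0.5)
  expect_equal(particleMomentum(c(1, 1), rbind(c(0, 0, 1), c(0, 0, -1))),
               c(0, 0, 0))
  expect_error(kineticEnergy(c(1, -1), rbind(c(0, 0, 1), c(0, 0, 1))),
               "> 0")
  expect_error(kineticEnergy(1, rbind(c(0, 0, 1), c(0, 0, 1))), "equal")
})

test_that("effective rigidity: symmetric value, soft-membrane limit, guards", {
  expect_equal(effectiveRigidity(2, 2), 1)
  expect_equal(effectiveRigidity(1, 1e6), 1, tolerance = 1e-5)
  expect_equal(effectiveRigidity(3, 6), 2)
  expect_equal(effectiveRigidity(5, 7), effectiveRigidity(7, 5))
  expect_error(effectiveRigidity(-1, 2), ">= 0")
  expect_error(effectiveRigidity(0, 0), "> 0")
})

test_that("elastic stretching energy matches hand computation on one face", {
  ## rest: right triangle of area 1/2; stretch one vertex so area doubles
  m <- oneFaceMesh()
  m@vertices[2, ] <- c(2, 0, 0)          # area becomes 1
  kap <- effectiveRigidity(3, 6)         # 2
  hand <- kap / (2 * 0.5^2) * (1 - 0.5)^2
  expect_equal(elasticEnergy(m, elasticParams(3, 6)), hand)
  ## undeformed mesh has zero energy
  expect_equal(elasticEnergy(oneFaceMesh(), elasticParams(3, 6)), 0)
  ## rigid-body motion costs nothing
  g <- translateMesh(generateFlatGrid(4, 4, 1), c(3, -1, 2))
  expect_equal(elasticEnergy(g, elasticParams(1, 1)), 0)
})

test_that("elastic energy agrees with the face-by-face oracle", {
  set.seed(11)
  g <- generateFlatGrid(5, 5, 1)
  g@vertices <- g@vertices + matrix(rnorm(length(g@vertices), sd = 0.02),
                                    ncol = 3)
  expect_equal(elasticEnergy(g, elasticParams(4, 12)),
               oracleElasticEnergy(g, 4, 12), tolerance = 1e-12)
})

test_that("bending energy matches an independent cotangent oracle", {
  set.seed(5)
  m <- generateIcosphere(1, 1, ruffleAmplitude = 0.05, seed = 9)
  expect_equal(bendingEnergy(m, bendingParams(2, TRUE)),
               oracleBendingEnergy(m, 2), tolerance = 1e-10)
  g <- generateFlatGrid(5, 5, 1)
  g@vertices[, 3] <- g@vertices[, 3] + rnorm(25, sd = 0.03)
  expect_equal(bendingEnergy(g, bendingParams(1, TRUE)),
               oracleBendingEnergy(g, 1), tolerance = 1e-10)
})

test_that("bending energy of refining spheres approaches 8 pi kappaB", {
  vals <- vapply(1:4, function(s)
    bendingEnergy(generateIcosphere(s, 1), bendingParams(1, TRUE)),
    numeric(1))
  err <- abs(vals - 8 * pi)
  expect_true(all(diff(err) < 0))          # monotone refinement
  expect_lt(err[4], 0.05)
  ## radius invariance of the Helfrich value
  expect_equal(bendingEnergy(generateIcosphere(3, 2), bendingParams(1, TRUE)),
               bendingEnergy(generateIcosphere(3, 1), bendingParams(1, TRUE)),
               tolerance = 1e-9)
  ## kappaB linearity
  expect_equal(bendingEnergy(generateIcosphere(2, 1), bendingParams(3, TRUE)),
               3 * bendingEnergy(generateIcosphere(2, 1),
                                 bendingParams(1, TRUE)),
               tolerance = 1e-12)
})

test_that("flat sheets carry zero bending energy; disabled term errors", {
  expect_equal(bendingEnergy(generateFlatGrid(6, 6, 1),
                             bendingParams(1, TRUE)), 0)
  expect_error(bendingEnergy(generateFlatGrid(3, 3, 1), bendingParams(1)),
               "disabled")
})

test_that("pressure displacement substitution and guards", {
  expect_equal(pressureDisplacement(2, pressureParams(c = 1, vInt = 4)), 1)
  expect_equal(pressureDisplacement(-2, pressureParams(c = 1, vInt = 4)), 1)
  expect_equal(pressureDisplacement(0.3, pressureParams(c = 0.5, vInt = 2)),
               0.5 * 0.09 / 2)
  expect_error(pressureDisplacement(1, pressureParams(c = 1, vInt = 0)),
               "> 0")
})

test_that("isothermal work at volume ratios 1, 2, 1/2", {
  th <- thermoParams(2.5)
  expect_equal(isothermalWork(th, 3, 3), 0)
  expect_equal(isothermalWork(th, 1, 2), 2.5 * log(2))
  expect_equal(isothermalWork(th, 2, 1), -2.5 * log(2))
  ## antisymmetry
  expect_equal(isothermalWork(th, 1.3, 0.7), -isothermalWork(th, 0.7, 1.3))
  expect_error(isothermalWork(th, 0, 1), "> 0")
})

test_that("adhesion energy is the quadratic tether sum", {
  k <- 2 * 5 / 0.05^2
  expect_equal(adhesionEnergy(0.01, perBondEnergy = 5, restLength = 0.01,
                              refExtension = 0.05), 0)
  expect_equal(adhesionEnergy(0.06, perBondEnergy = 5, restLength = 0.01,
                              refExtension = 0.05), 5)
  expect_equal(adhesionEnergy(c(0.02, 0.03), 5, 0.01, 0.05),
               0.5 * k * (0.01^2 + 0.02^2))
})
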