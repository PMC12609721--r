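test_that("particle release: bounds, counts, Maxwell-like velocities", {
  region <- rbind(c(0, 0, 0), c(0.5, 0.5, 0.25))
  ens <- releaseParticles(4000, region, mass = 0.1, speedScale = 0.02,
                          compartment = "bottom", seed = 8)
  expect_equal(nrow(ens@positions), 4000L)
  expect_true(all(ens@positions >= 0))
  expect_true(all(sweep(ens@positions, 2, region[2, ]) <= 0))
  expect_true(all(ens@compartment == "bottom"))
  ## per-axis velocity sd = speedScale / sqrt(mass)
  sdTarget <- 0.02 / sqrt(0.1)
  sds <- apply(ens@velocities, 2, sd)
  expect_true(all(abs(sds / sdTarget - 1) < 0.05))
  ## isotropy: mean velocity near zero
  expect_true(all(abs(colMeans(ens@velocities)) < 4 * sdTarget / sqrt(4000)))
  ## with speedScale = 1, mean kinetic energy per particle is 3/2 kT
  ens2 <- releaseParticles(20000, region, mass = 2.5, speedScale = 1,
                           seed = 9)
  expect_equal(kineticEnergy(ens2) / 20000, 1.5, tolerance = 0.05)
  ## reproducible under seed without touching caller's RNG
  set.seed(3); x1 <- runif(1)
  set.seed(3)
  invisible(releaseParticles(10, region, 1, seed = 5))
  expect_identical(runif(1), x1)
  expect_equal(releaseParticles(10, region, 1, seed = 5)@positions,
               releaseParticles(10, region, 1, seed = 5)@positions)
  expect_error(releaseParticles(-1, region, 1), ">= 0")
  expect_error(releaseParticles(5, region, 0), "> 0")
  expect_error(releaseParticles(5, rbind(c(0, 0, 0), c(2, 2, 2)), 1,
                                chamber = rbind(c(0, 0, 0), c(1, 1, 1))),
               "outside")
})

test_that("ballistic flight reflects off walls and preserves speed", {
  L <- 0.5
  ## free flight, no reflection
  ens <- new("ParticleEnsemble",
             positions = rbind(c(0.25, 0.25, 0.1)),
             masses = 1, velocities = rbind(c(0.01, -0.02, 0.05)),
             compartment = "bottom")
  adv <- advanceAndCollide(ens, L, pistonZ = 0.4, dt = 1)
  expect_equal(adv$ensemble@positions[1, ], c(0.26, 0.23, 0.15),
               tolerance = 1e-12)
  expect_equal(adv$tally$collBottom, 0L)
  expect_equal(adv$tally$impulseBottom, 0)
  ## hit the piston: z = 0.38, v_z = 0.05, piston at 0.4 -> fold back
  ens@positions[1, 3] <- 0.38
  adv2 <- advanceAndCollide(ens, L, pistonZ = 0.4, dt = 1)
  expect_equal(adv2$ensemble@positions[1, 3], 0.37, tolerance = 1e-12)
  expect_equal(adv2$tally$collBottom, 1L)
  expect_equal(adv2$tally$impulseBottom, 2 * 1 * 0.05)
  expect_equal(adv2$tally$collTop, 0L)
  ## velocity z flipped, speed preserved
  expect_equal(adv2$ensemble@velocities[1, ], c(0.01, -0.02, -0.05),
               tolerance = 1e-12)
  ## top particle hits the piston from above
  top <- new("ParticleEnsemble",
             positions = rbind(c(0.25, 0.25, 0.42)),
             masses = 0.5, velocities = rbind(c(0, 0, -0.05)),
             compartment = "top")
  adv3 <- advanceAndCollide(top, L, pistonZ = 0.4, dt = 1)
  expect_equal(adv3$tally$collTop, 1L)
  expect_equal(adv3$tally$impulseTop, 2 * 0.5 * 0.05)
  ## side-wall reflection
  wall <- new("ParticleEnsemble",
              positions = rbind(c(0.49, 0.25, 0.1)),
              masses = 1, velocities = rbind(c(0.05, 0, 0)),
              compartment = "bottom")
  adv4 <- advanceAndCollide(wall, L, pistonZ = 0.4, dt = 1)
  expect_equal(adv4$ensemble@positions[1, 1], 0.46, tolerance = 1e-12)
  expect_equal(adv4$ensemble@velocities[1, 1], -0.05)
  ## a bottom particle above the piston plane is a state violation
  expect_error(advanceAndCollide(wall, L, pistonZ = 0.05, dt = 1),
               "compartment")
  expect_error(advanceAndCollide(wall, L, pistonZ = 0), "inside")
})

test_that("flight conserves energy, counts and compartments in bulk", {
  L <- 0.5
  set.seed(12)
  bot <- releaseParticles(1500, rbind(c(0, 0, 0), c(L, L, 0.25)), 0.1,
                          speedScale = 0.02 * sqrt(0.1))
  top <- releaseParticles(1500, rbind(c(0, 0, 0.25), c(L, L, L)), 0.01,
                          speedScale = 0.02 * sqrt(0.01),
                          compartment = "top")
  ens <- new("ParticleEnsemble",
             positions = rbind(bot@positions, top@positions),
             masses = c(bot@masses, top@masses),
             velocities = rbind(bot@velocities, top@velocities),
             compartment = c(bot@compartment, top@compartment))
  e0 <- kineticEnergy(ens)
  adv <- advanceAndCollide(ens, L, 0.25, dt = 1)
  out <- adv$ensemble
  expect_equal(nrow(out@positions), 3000L)
  expect_identical(out@compartment, ens@compartment)
  ## specular reflections preserve kinetic energy exactly
  expect_equal(kineticEnergy(out), e0, tolerance = 1e-12)
  ## all particles stay inside their compartment
  isTop <- out@compartment == "top"
  expect_true(all(out@positions >= 0 & out@positions <= L))
  expect_true(all(out@positions[isTop, 3] >= 0.25))
  expect_true(all(out@positions[!isTop, 3] <= 0.25))
  ## impulses are consistent with the collision counts and speeds
  expect_gte(adv$tally$collBottom, 0L)
  expect_gte(adv$tally$collTop, 0L)
  expect_gte(adv$tally$impulseBottom, 0)
})

test_that("momentum kick arithmetic and clamping", {
  t1 <- list(impulseBottom = 3, impulseTop = 1)
  expect_equal(applyMomentumKick(0.25, t1, mobility = 0.01,
                                 chamberSide = 0.5), 0.27)
  t2 <- list(impulseBottom = 0, impulseTop = 4)
  expect_equal(applyMomentumKick(0.25, t2, mobility = 0.01,
                                 chamberSide = 0.5), 0.21)
  ## clamped at the margins
  expect_equal(applyMomentumKick(0.49, t1, mobility = 1, chamberSide = 0.5),
               0.5 - 0.005)
  expect_equal(applyMomentumKick(0.01, t2, mobility = 1, chamberSide = 0.5),
               0.005)
})
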