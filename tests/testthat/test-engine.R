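quadraticProvider <- function(k) {
  function(positions, step = 0L)
    list(energy = k * sum(positions^2), forces = -2 * k * positions)
}

test_that("the minimizer is monotone and solves quadratic bowls", {
  ## start at the minimum: immediate return
  st <- simulationState(matrix(0, 2L, 3L))
  mn <- minimizeSystem(st, list(quadraticProvider(3)), maxSteps = 100L,
                       tol = 1e-8)
  expect_length(mn$energyTrace, 1L)
  expect_true(mn$converged)

  ## 1-D quadratic from x = 1 converges below 1e-6
  st <- simulationState(matrix(c(1, 0, 0), 1L, 3L))
  mn <- minimizeSystem(st, list(quadraticProvider(5)), maxSteps = 5000L,
                       tol = 1e-8)
  expect_lt(abs(mn$state@positions[1L, 1L]), 1e-6)
  expect_true(all(diff(mn$energyTrace) <= 0))
  expect_equal(max(abs(mn$state@velocities)), 0)

  ## NaN energies abort naming the provider
  bad <- function(positions, step = 0L)
    list(energy = NaN, forces = positions * 0)
  expect_error(
    minimizeSystem(st, list(okay = quadraticProvider(1), broken = bad),
                   maxSteps = 10L),
    "broken")
})

test_that("BAOAB limits: velocity decay, determinism, Verlet reduction", {
  free <- function(positions, step = 0L)
    list(energy = 0, forces = positions * 0)
  st <- simulationState(matrix(0, 1L, 3L),
                        matrix(c(1, 0, 0), 1L, 3L))
  s1 <- langevinStep(st, list(free), dt = 2, temperature = 0,
                     friction = 10, masses = 12)
  expect_equal(s1@velocities[1L, 1L],
               exp(-10 * 48.88821e-3 * 2 / 48.88821))

  ## same seed: bitwise-identical trajectories
  prov <- list(quadraticProvider(2))
  run <- function() {
    set.seed(123)
    langevinRun(simulationState(matrix(0, 4L, 3L)), prov, nSteps = 200L,
                dt = 1, temperature = 300, friction = 5,
                masses = rep(12, 4L))$state
  }
  a <- run(); b <- run()
  expect_identical(a@positions, b@positions)
  expect_identical(a@velocities, b@velocities)

  ## T = 0, friction = 0: harmonic energy conserved to < 1e-4 relative
  k <- 5; m <- 12
  ho <- quadraticProvider(k)
  st <- simulationState(matrix(c(1, 0, 0), 1L, 3L))
  r <- langevinRun(st, list(ho), nSteps = 100000L, dt = 1,
                   temperature = 0, friction = 0, masses = m)
  e0 <- k
  e1 <- k * sum(r$state@positions^2) + 0.5 * m * sum(r$state@velocities^2)
  expect_lt(abs(e1 - e0) / e0, 1e-4)
})

test_that("the thermostat samples equipartition within 5%", {
  k <- 10; m <- 12
  set.seed(5)
  st <- simulationState(matrix(0, 1L, 3L))
  r <- langevinRun(st, list(quadraticProvider(k)), nSteps = 200000L,
                   dt = 2, temperature = 300, friction = 20, masses = m,
                   recordEvery = 10L,
                   recordFun = function(pos, step) pos[1L, 1L])
  x2 <- mean(unlist(r$records)^2)
  expected <- 0.0019872041 * 300 / (2 * k)   # <x^2> = kB T / (2 k)
  expect_lt(abs(x2 - expected) / expected, 0.05)
})

test_that("refinement protocol contracts: zero stages, ramp-to-zero identity", {
  cd <- cdBridgeFixture()
  br <- metalBridgeRestraints("cd_bridge", cd$fragment, cd$system)
  r0 <- runRefinement(cd$system, list(cd$fragment), br, stages = list(),
                      includeNonbonded = FALSE)
  expect_identical(r0$state@positions, positions(cd$system))
  expect_equal(r0$state@step, 0L)

  ## undefined ramp id is a config error before execution
  brRamp <- metalBridgeRestraints("cd_bridge", cd$fragment, cd$system,
                                  rampId = "missing")
  expect_error(
    runRefinement(cd$system, list(cd$fragment), brRamp,
                  stages = list(list(mode = "minimize", nSteps = 1L))),
    "undefined ramp")

  ## restraints ramped to zero reproduce plain dynamics step for step
  iso <- cd$iso
  brIso <- metalBridgeRestraints("cd_bridge", iso$fragment, iso$system,
                                 rampId = "off")
  off <- rampSchedule(0L, 10L, 0, 0)
  stages <- list(list(mode = "dynamics", nSteps = 150L,
                      temperature = 200, dt = 1, friction = 5))
  set.seed(77)
  withR <- runRefinement(iso$system, list(iso$fragment), brIso, stages,
                         schedules = list(off = off),
                         includeNonbonded = FALSE)
  set.seed(77)
  plainProviders <- list(bonded = makeBondedProvider(iso$system))
  plain <- langevinRun(simulationState(positions(iso$system)),
                       plainProviders, nSteps = 150L, dt = 1,
                       temperature = 200, friction = 5,
                       masses = atoms(iso$system)$mass)
  expect_identical(withR$state@positions, plain$state@positions)
})

test_that("the bundle refinement closes the bridges below 9 A", {
  set.seed(2)
  hb <- makeHelixBundle(helixLength = 16L)
  s <- hb$system
  frags <- list()
  rsets <- list()
  for (m in c(1L, 3L)) {   # one Cd and one Mg bridge
    row <- hb$catalog[m, ]
    b <- buildBridgeFragment(s, fragmentSpec(row$kind,
                                             c(row$siteA, row$siteB)))
    s <- b$system
    frags[[length(frags) + 1L]] <- b$fragment
    rsets[[length(rsets) + 1L]] <-
      metalBridgeRestraints(row$kind, b$fragment, s, rampId = "bridge")
    rsets[[length(rsets) + 1L]] <- anchorRestraints(b$fragment, k = 50)
  }
  rsets[[length(rsets) + 1L]] <-
    secondaryStructureRestraints(s, hb$helixRanges, k = 5)
  restr <- do.call(combineRestraints, rsets)
  res <- runRefinement(
    s, frags, restr,
    stages = list(
      list(mode = "minimize", nSteps = 1000L, tol = 1e-4),
      list(mode = "dynamics", nSteps = 4000L, temperature = 300,
           dt = 1, friction = 5)),
    schedules = list(bridge = rampSchedule(800L, 3200L, 0, 1)))
  expect_true(all(res$report$cbCbDistance <= 9))
  expect_true(all(res$report$maxAnchorDev < 1))
  ## the report mirrors trajectory statistics: mean +- sd per bridge bond
  expect_true(all(c("mean", "sd") %in% names(res$bridgeStats)))
  expect_true(all(res$bridgeStats$sd >= 0))
  expect_true(all(abs(res$bridgeStats$mean - res$bridgeStats$x0) < 0.6))
})

test_that("reMD holds matched targets and converges dummy-label runs", {
  ## self-consistency: targets equal to the ensemble's own histogram
  set.seed(42)
  fp <- makeFreeProbes(nCopies = 10L, separation = 25, spread = 2,
                       seed = 6L)
  d <- ensembleDistanceMatrix(fp$ensembles[[1L]], fp$ensembles[[2L]],
                              positions(fp$system))
  self <- smoothedHistogram(as.numeric(d), sigma = 1.1)
  hr <- histogramRestraint(fp$ensembles[[1L]], fp$ensembles[[2L]], self)
  res <- runRestrainedEnsemble(fp$system, fp$ensembles, list(hr),
                               equilSteps = 0L, prodSteps = 2000L,
                               temperature = 10, dt = 1, friction = 20,
                               backboneK = 0, includeNonbonded = FALSE,
                               sampleEvery = 10L)
  expect_lt(res$report$uRE, 0.5)
  expect_lt(res$report$rmsDev, 5e-3)

  ## a histogram restraint referencing probes outside the labeled
  ## ensembles is a config error
  badHr <- new("HistogramRestraint", sitePair = c(1L, 3L),
               probesI = probeAtoms(fp$ensembles[[1L]]),
               probesJ = 999L, target = self, K = 500, sigma = 1.1)
  expect_error(
    runRestrainedEnsemble(fp$system, fp$ensembles, list(badHr),
                          equilSteps = 0L, prodSteps = 1L,
                          includeNonbonded = FALSE),
    "unlabeled site")

  ## dummy spin-labels on a host: tethered probes still reach the
  ## bimodal target
  set.seed(4)
  lh <- makeLabelHost(nSites = 2L, nRes = 40L, fold = "extended",
                      minSiteSep = 18)
  s <- lh$system
  ens <- list()
  for (site in lh$sites) {
    r <- buildLabelFragment(s, fragmentSpec("dummy_label", site,
                                            nCopies = 25L), seed = 7L)
    s <- r$system
    ens[[length(ens) + 1L]] <- r$ensemble
  }
  ca <- vapply(lh$sites, function(ss)
    which(atoms(s)$resid == ss & atoms(s)$name == "CA" &
            atoms(s)$fragmentId == 0L)[1L], 1L)
  dca <- measureDistance(positions(s), ca[1L], ca[2L])
  tgt <- makeTargetHistogram(list(c(dca - 4, 0.5), c(dca + 4, 0.5)),
                             sigmaGen = 2, siteDistance = dca,
                             reach = 12.4)
  hr2 <- histogramRestraint(ens[[1L]], ens[[2L]], tgt)
  res2 <- runRestrainedEnsemble(s, ens, list(hr2), equilSteps = 1000L,
                                prodSteps = 12000L, burnInSteps = 6000L,
                                temperature = 30, dt = 2, friction = 5,
                                backboneK = 100, anchorK = 10,
                                includeNonbonded = FALSE,
                                sampleEvery = 10L)
  expect_lt(res2$report$rmsDev, 0.01)
})
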