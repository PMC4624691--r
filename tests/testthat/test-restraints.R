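test_that("bridge restraint tables carry the published parameters", {
  cd <- cdBridgeFixture()
  br <- metalBridgeRestraints("cd_bridge", cd$fragment, cd$system)
  t <- restraintTerms(br)
  expect_equal(nrow(t), 3L)
  expect_equal(t$kind, c("bond", "bond", "angle"))
  expect_equal(t$kconst, c(10, 10, 10))
  expect_equal(t$x0, c(2.6, 2.6, 180))

  hb <- cd$bundle
  zrow <- hb$catalog[hb$catalog$kind == "zn_bridge", ][1L, ]
  zn <- buildBridgeFragment(hb$system,
                            fragmentSpec("zn_bridge",
                                         c(zrow$siteA, zrow$siteB)))
  zt <- restraintTerms(metalBridgeRestraints("zn_bridge", zn$fragment,
                                             zn$system))
  expect_equal(nrow(zt), 7L)
  expect_setequal(zt$kind[zt$kind == "angle"], "angle")
  expect_setequal(zt$x0[zt$kind == "angle"], c(127.0, 125.5))
  expect_equal(sum(zt$kind == "improper"), 2L)
  expect_equal(zt$x0[zt$kind == "dihedral"], 180)
  expect_equal(zt$x0[zt$kind == "bond"], c(2.1, 2.1))
  expect_true(all(zt$kconst == 10))

  srow <- hb$catalog[hb$catalog$kind == "salt_bridge", ][1L, ]
  sb <- buildBridgeFragment(hb$system,
                            fragmentSpec("salt_bridge",
                                         c(srow$siteA, srow$siteB)))
  st <- restraintTerms(metalBridgeRestraints("salt_bridge", sb$fragment,
                                             sb$system))
  expect_equal(nrow(st), 1L)
  expect_equal(st$x0, 3.5)

  expect_error(metalBridgeRestraints("mg_bridge", cd$fragment,
                                     cd$system), "built as cd_bridge")
})

test_that("restraint energies follow k(x - x0)^2 and vanish at equilibrium", {
  cd <- cdBridgeFixture()
  iso <- cd$iso
  br <- metalBridgeRestraints("cd_bridge", iso$fragment, iso$system)
  t <- restraintTerms(br)
  ion <- iso$fragment@bridgingIon

  ## place SG-Cd at exactly 2.6 / 2.6 and 180 degrees: E = 0, F = 0
  pos <- positions(iso$system)
  pos[t$i[1L], ] <- c(0, 0, 0)
  pos[ion, ] <- c(2.6, 0, 0)
  pos[t$i[2L], ] <- c(5.2, 0, 0)
  ev <- restraintEnergyForces(br, pos)
  expect_equal(ev$energy, 0, tolerance = 1e-12)
  expect_lt(max(abs(ev$forces)), 1e-9)

  ## S-Cd stretched to 3.6 A with k = 10 -> E = 10 kcal/mol
  one <- new("RestraintSet", terms = t[1L, , drop = FALSE])
  pos[t$i[1L], ] <- pos[ion, ] - c(3.6, 0, 0)
  expect_equal(restraintEnergyForces(one, pos)$energy, 10)
})

test_that("restraint forces match finite differences and sum to zero per term", {
  set.seed(21)
  pos <- randomPositions(4L, seed = 21, scale = 2)
  terms <- rbind(
    fragmentMD:::.restraintRow("bond", 1L, 2L, kconst = 10, x0 = 2.6),
    fragmentMD:::.restraintRow("anchor", 2L, 3L, kconst = 50, x0 = 0),
    fragmentMD:::.restraintRow("angle", 1L, 2L, 3L, kconst = 10,
                               x0 = 127),
    fragmentMD:::.restraintRow("dihedral", 1L, 2L, 3L, 4L, kconst = 10,
                               x0 = 180),
    fragmentMD:::.restraintRow("improper", 2L, 1L, 4L, 3L, kconst = 10,
                               x0 = 0))
  for (r in seq_len(nrow(terms))) {
    rs <- new("RestraintSet", terms = terms[r, , drop = FALSE])
    prov <- makeRestraintProvider(rs)
    cg <- checkGradients(prov, pos)
    expect_lt(cg$maxRelErr, 1e-6)
    expect_lt(max(abs(colSums(prov(pos)$forces))), 1e-10)
    expect_gte(prov(pos)$energy, 0)
  }
})

test_that("near-colinear angle terms stay finite (theta0 = 180 guard)", {
  terms <- fragmentMD:::.restraintRow("angle", 1L, 2L, 3L, kconst = 10,
                                      x0 = 180)
  rs <- new("RestraintSet", terms = terms)
  pos <- rbind(c(-2.6, 1e-10, 0), c(0, 0, 0), c(2.6, 0, 0))
  ev <- restraintEnergyForces(rs, pos)
  expect_true(all(is.finite(ev$forces)))
  expect_true(is.finite(ev$energy))
})

test_that("ramp schedules interpolate linearly and gate the forces", {
  rs <- rampSchedule(0L, 100L, 0, 1)
  expect_equal(ramp(rs, 50L), 0.5)
  expect_equal(ramp(rs, 1000L), 1)
  expect_equal(ramp(rs, 0L), 0)

  multi <- new("RampSchedule", stages = data.frame(
    startStep = c(0L, 200L), endStep = c(100L, 300L),
    scaleStart = c(0, 0.5), scaleEnd = c(0.5, 1)))
  vals <- ramp(multi, 0:350)
  expect_true(all(diff(vals) >= 0))        # monotone stages -> monotone
  expect_equal(ramp(multi, 150L), 0.5)     # holds between stages

  ## ramp scale 0: restraint forces vanish identically
  terms <- fragmentMD:::.restraintRow("bond", 1L, 2L, kconst = 10,
                                      x0 = 2.6, rampId = "up")
  set <- new("RestraintSet", terms = terms)
  pos <- rbind(c(0, 0, 0), c(5, 0, 0))
  ev <- restraintEnergyForces(set, pos, step = 0L,
                              schedules = list(up = rs))
  expect_equal(ev$energy, 0)
  expect_equal(max(abs(ev$forces)), 0)
  ev2 <- restraintEnergyForces(set, pos, step = 50L,
                               schedules = list(up = rs))
  expect_equal(ev2$energy, 0.5 * 10 * (5 - 2.6)^2)
  expect_error(restraintEnergyForces(set, pos, schedules = list()),
               "undefined ramp")
})

test_that("helix phi/psi restraints are at equilibrium on the ideal helix", {
  hb <- makeHelixBundle(helixLength = 12L)
  ss <- secondaryStructureRestraints(hb$system, hb$helixRanges, k = 10)
  ev <- restraintEnergyForces(ss, positions(hb$system))
  expect_lt(ev$energy, 1e-3)

  expect_length(restraintTerms(
    secondaryStructureRestraints(hb$system, list(), k = 10))$kind, 0L)
  expect_error(secondaryStructureRestraints(hb$system, list(1:3)),
               "at least 4")
})

test_that("an extended strand is penalized at every residue", {
  hb <- makeHelixBundle(helixLength = 12L)
  span <- hb$helixRanges[[1L]][3:8]
  ss <- secondaryStructureRestraints(hb$system, list(span), k = 10)
  ## stretch the span into a straight line (extended backbone)
  pos <- positions(hb$system)
  t <- restraintTerms(ss)
  atomsInSpan <- sort(unique(c(t$i, t$j, t$k_, t$l)))
  pos[atomsInSpan, ] <- cbind(seq_along(atomsInSpan) * 1.3, 0, 0)
  pos[atomsInSpan, 2L] <- rep_len(c(0, 0.8), length(atomsInSpan))
  perTerm <- vapply(seq_len(nrow(t)), function(r) {
    restraintEnergyForces(new("RestraintSet",
                              terms = t[r, , drop = FALSE]), pos)$energy
  }, 1)
  expect_true(all(perTerm > 0))
})

test_that("bridge restraints alone reach the target geometry", {
  cd <- cdBridgeFixture()
  iso <- cd$iso
  br <- metalBridgeRestraints("cd_bridge", iso$fragment, iso$system)
  mn <- minimizeSystem(simulationState(positions(iso$system)),
                       list(bridge = makeRestraintProvider(br)),
                       maxSteps = 30000L, tol = 1e-6)
  expect_true(mn$converged)
  expect_true(all(diff(mn$energyTrace) <= 0))
  t <- restraintTerms(br)
  p <- mn$state@positions
  expect_equal(measureDistance(p, t$i[1L], t$j[1L]), 2.6,
               tolerance = 1e-3 / 2.6)
  expect_equal(measureDistance(p, t$i[2L], t$j[2L]), 2.6,
               tolerance = 1e-3 / 2.6)
  expect_lt(abs(measureAngle(p, t$i[3L], t$j[3L], t$k_[3L]) - 180), 0.1)
})
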