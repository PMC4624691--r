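test_that("softcore distance has the right closed forms and limits", {
  expect_equal(softcoreDistance(5, 0), 5)     # delta = 0: plain distance
  expect_equal(softcoreDistance(0, 1), 1)
  expect_equal(softcoreDistance(3, 7), 4)     # sqrt(9 + 7)
  expect_error(softcoreDistance(-1, 0), ">= 0")
  expect_error(softcoreDistance(1, -1), ">= 0")

  ## monotone increasing in both arguments
  r <- seq(0, 15, by = 0.25)
  for (delta in c(0, 0.5, 2)) {
    expect_true(all(diff(softcoreDistance(r, delta)) > 0))
  }
  for (rr in c(0, 1, 7)) {
    expect_true(all(diff(softcoreDistance(rr, seq(0, 4, 0.5))) >= 0))
  }
})

test_that("excluded pairs have zero energy; overlap stays finite", {
  cd <- cdBridgeFixture()
  model <- buildExclusionModel(cd$system, list(cd$fragment))
  params <- softCoreParams(delta = 1)
  a <- atoms(cd$system)
  frag <- cd$fragment

  ## fragment atom vs its target host residue: scale 0, zero energy
  hostTarget <- which(a$fragmentId == 0L & a$resid == frag@sites[1L])[1L]
  fa <- frag@atomIndices[1L]
  expect_equal(pairScale(model, fa, hostTarget), 0)
  pe <- pairEnergy(cd$system, fa, hostTarget, model, params)
  expect_equal(pe$energy, 0)
  expect_equal(pe$forceI, c(0, 0, 0))

  ## fragment-host pair at r = 0: soft core keeps it finite
  farHost <- which(a$fragmentId == 0L &
                     !a$resid %in% c(frag@sites - 1L, frag@sites,
                                     frag@sites + 1L))[1L]
  pos <- positions(cd$system)
  pos[fa, ] <- pos[farHost, ]
  pe0 <- pairEnergy(cd$system, fa, farHost, model, params,
                    positions = pos)
  expect_true(is.finite(pe0$energy))
  expect_true(all(is.finite(pe0$forceI)))
  expect_equal(pe0$forceI, c(0, 0, 0))  # symmetric overlap: no direction

  ## symmetry of the pair scale
  set.seed(31)
  ii <- sample(nAtoms(cd$system), 40L, replace = TRUE)
  jj <- sample(nAtoms(cd$system), 40L, replace = TRUE)
  keep <- ii != jj
  expect_equal(pairScale(model, ii[keep], jj[keep]),
               pairScale(model, jj[keep], ii[keep]))
})

test_that("nonbonded forces are exact gradients and obey Newton's third law", {
  cd <- cdBridgeFixture()
  model <- buildExclusionModel(cd$system, list(cd$fragment))
  params <- softCoreParams(delta = 1)
  prov <- makeNonbondedProvider(cd$system, model, params)
  pos <- positions(cd$system)
  set.seed(7)
  probe <- c(sample(which(atoms(cd$system)$fragmentId == 0L), 3L),
             cd$fragment@atomIndices[c(2L, 7L)])
  cg <- checkGradients(prov, pos, atoms = probe)
  expect_lt(cg$maxRelErr, 1e-6)
  expect_lt(max(abs(colSums(prov(pos)$forces))), 1e-9)
})

test_that("energy is continuous and once-differentiable at the switch boundaries", {
  ## probe a single host-host pair across 10 A and 12 A
  a <- fragmentMD:::.atomRows(1:2, c("C1", "C2"), c("C", "C"), 1:2,
                              "LIG", "A", charge = c(0.3, -0.3))
  s <- fragmentMD:::.makeSystem(atoms = a, positions = rbind(
    c(0, 0, 0), c(9, 0, 0)))
  model <- buildExclusionModel(s, list())
  params <- softCoreParams(delta = 0)
  eAt <- function(r) {
    p <- rbind(c(0, 0, 0), c(r, 0, 0))
    pairEnergy(s, 1L, 2L, model, params, positions = p)
  }
  for (boundary in c(10, 12)) {
    rs <- boundary + seq(-5e-3, 5e-3, by = 1e-4)
    es <- vapply(rs, function(r) eAt(r)$energy, 1)
    fs <- vapply(rs, function(r) eAt(r)$forceI[1L], 1)
    ## a truncation discontinuity would show up as an O(|V|) jump in
    ## the energy or an O(|V'|) jump in the force between neighbouring
    ## grid points; smooth switching keeps both at the grid-spacing
    ## scale
    expect_lt(max(abs(diff(es))), 1e-4)
    expect_lt(max(abs(diff(fs))), 1e-3)
  }
  expect_equal(eAt(12.5)$energy, 0)  # truncated beyond the cutoff
})

test_that("energy decomposes exactly and fragments are mutually blind", {
  cd <- cdBridgeFixture()
  hb <- cd$bundle
  row <- hb$catalog[hb$catalog$kind == "mg_bridge", ][1L, ]
  b2 <- buildBridgeFragment(cd$system,
                            fragmentSpec("mg_bridge",
                                         c(row$siteA, row$siteB)))
  s <- b2$system
  frags <- list(cd$fragment, b2$fragment)
  model <- buildExclusionModel(s, frags)
  params <- softCoreParams(delta = 1)
  tn <- totalNonbonded(s, model, params)
  expect_lt(abs(tn$energy - (tn$components[["hostHost"]] +
                               tn$components[["intraFragment"]] +
                               tn$components[["crossScaled"]])), 1e-9)

  ## exclusion independence: perturbing fragment A leaves every force
  ## component on fragment B unchanged, exactly
  prov <- makeNonbondedProvider(s, model, params)
  pos <- positions(s)
  f0 <- prov(pos)$forces[b2$fragment@atomIndices, ]
  pos2 <- pos
  pos2[cd$fragment@atomIndices[3L], ] <-
    pos2[cd$fragment@atomIndices[3L], ] + c(0.7, -0.4, 0.2)
  f1 <- prov(pos2)$forces[b2$fragment@atomIndices, ]
  expect_identical(f0, f1)
})

test_that("with no fragments the evaluation matches a brute-force double loop", {
  hb <- makeHelixBundle(helixLength = 10L)  # 200 atoms
  model <- buildExclusionModel(hb$system, list())
  params <- softCoreParams(delta = 1)
  tn <- totalNonbonded(hb$system, model, params)
  oracle <- bruteForceNonbonded(hb$system, params)
  expect_lt(abs(tn$energy - oracle), 1e-8 * max(1, abs(oracle)))
  expect_equal(unname(tn$components[["crossScaled"]]), 0)
  expect_equal(unname(tn$components[["intraFragment"]]), 0)
})

test_that("fragment-environment energies scale exactly by 1/N", {
  hb <- cdBridgeFixture()$bundle
  site <- hb$catalog$siteA[2L]
  for (n in c(1L, 4L, 25L)) {
    r <- buildLabelFragment(hb$system,
                            fragmentSpec("mtssl_label", site,
                                         nCopies = n), seed = 3L)
    model <- buildExclusionModel(r$system, r$ensemble@copies)
    ratio <- scaledInteractionRatio(r$system, model, softCoreParams(),
                                    r$ensemble@copies[[1L]])
    expect_equal(ratio, 1 / n)
  }
})

test_that("the cell list agrees with the direct pair scan", {
  set.seed(12)
  pos <- matrix(runif(3 * 1500L, 0, 40), ncol = 3L)
  direct <- fragmentMD:::.pairsWithinCutoff(pos[1:900, ], 8)
  big <- fragmentMD:::.pairsWithinCutoff(pos, 8)    # cell-list path
  sub <- big$i <= 900L & big$j <= 900L
  keyA <- sort((pmin(big$i[sub], big$j[sub]) - 1) * 900 +
                 pmax(big$i[sub], big$j[sub]))
  keyB <- sort((pmin(direct$i, direct$j) - 1) * 900 +
                 pmax(direct$i, direct$j))
  expect_identical(keyA, keyB)
})
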