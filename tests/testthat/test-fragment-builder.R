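test_that("bridge fragments carry the right atoms and are neutral", {
  cd <- cdBridgeFixture()
  frag <- cd$fragment
  a <- atoms(cd$system)[frag@atomIndices, ]
  expect_equal(sum(a$name == "SG"), 2L)         # two cysteine thiolates
  expect_equal(sum(a$element == "CD"), 1L)      # one bridging ion
  expect_equal(sum(a$charge), 0)                # electrically neutral
  expect_equal(nrow(frag@anchorPairs), 8L)      # 4 per patched residue

  hb <- cd$bundle
  row <- hb$catalog[hb$catalog$kind == "mg_bridge", ][1L, ]
  mg <- buildBridgeFragment(hb$system,
                            fragmentSpec("mg_bridge",
                                         c(row$siteA, row$siteB)))
  am <- atoms(mg$system)[mg$fragment@atomIndices, ]
  expect_equal(sum(am$name == "OD2"), 2L)       # Mg coordinates O-delta2
  expect_equal(sum(am$element == "MG"), 1L)
  expect_equal(sum(am$charge), 0)
})

test_that("builders reject mismatched specs and degenerate sites", {
  hb <- cdBridgeFixture()$bundle
  expect_error(
    buildBridgeFragment(hb$system, fragmentSpec("mtssl_label", 17L)),
    "buildLabelFragment")
  expect_error(
    buildLabelFragment(hb$system, fragmentSpec("cd_bridge", c(7L, 59L))),
    "buildBridgeFragment")
  expect_error(fragmentSpec("cd_bridge", 7L), "2 host sites")
  expect_error(fragmentSpec("mtssl_label", c(7L, 59L)), "1 host site")
  expect_error(fragmentSpec("mtssl_label", 7L, nCopies = 0L), ">= 1")
  expect_error(
    buildBridgeFragment(hb$system, fragmentSpec("cd_bridge", c(7L, 7L))),
    "distinct")
})

test_that("copy expansion conserves composition and spreads dihedrals", {
  hb <- cdBridgeFixture()$bundle
  site <- hb$catalog$siteA[1L]
  r1 <- buildLabelFragment(hb$system,
                           fragmentSpec("mtssl_label", site,
                                        nCopies = 5L), seed = 1L)
  expect_length(r1$ensemble@copies, 5L)
  a <- atoms(r1$system)
  nameSets <- lapply(r1$ensemble@copies, function(f)
    a$name[f@atomIndices])
  for (k in 2:5) expect_identical(nameSets[[k]], nameSets[[1L]])
  chargeSets <- lapply(r1$ensemble@copies, function(f)
    a$charge[f@atomIndices])
  for (k in 2:5) expect_identical(chargeSets[[k]], chargeSets[[1L]])
  expect_equal(unique(vapply(r1$ensemble@copies, interactionScale, 1)),
               1 / 5)

  ## chi-1 differs across copies (spread), but composition matches
  chi1 <- function(sys, f) {
    idx <- function(nm) f@atomIndices[a$name[f@atomIndices] == nm]
    measureDihedral(positions(sys), idx("N"), idx("CA"), idx("CB"),
                    idx("SG"))
  }
  chis <- vapply(r1$ensemble@copies, function(f) chi1(r1$system, f), 1)
  expect_gt(max(abs(diff(chis))), 1)

  ## different seeds: same composition, different dihedrals
  r2 <- buildLabelFragment(hb$system,
                           fragmentSpec("mtssl_label", site,
                                        nCopies = 5L), seed = 2L)
  a2 <- atoms(r2$system)
  expect_identical(a2$name[r2$ensemble@copies[[1L]]@atomIndices],
                   nameSets[[1L]])
  chis2 <- vapply(r2$ensemble@copies, function(f) {
    idx <- function(nm)
      f@atomIndices[a2$name[f@atomIndices] == nm]
    measureDihedral(positions(r2$system), idx("N"), idx("CA"),
                    idx("CB"), idx("SG"))
  }, 1)
  expect_false(isTRUE(all.equal(chis, chis2)))

  ## single-copy expansion is the identity case
  r3 <- buildLabelFragment(hb$system,
                           fragmentSpec("dummy_label", site), seed = 1L)
  expect_length(r3$ensemble@copies, 1L)
  expect_equal(interactionScale(r3$ensemble@copies[[1L]]), 1)
})

test_that("anchor restraints follow the k(d - b0)^2 convention", {
  cd <- cdBridgeFixture()
  ar <- anchorRestraints(cd$fragment, k = 50)
  t <- restraintTerms(ar)
  expect_true(all(t$kind == "anchor"))
  expect_true(all(t$x0 == 0))
  expect_error(anchorRestraints(cd$fragment, k = -1), "> 0")

  ## coincident anchor atoms: zero energy, zero force
  pos <- positions(cd$system)
  pos[t$i, ] <- pos[t$j, ]
  ev <- restraintEnergyForces(ar, pos)
  expect_equal(ev$energy, 0)
  expect_equal(max(abs(ev$forces)), 0)

  ## k = 50, d = 1 A -> E = 50 kcal/mol
  one <- new("RestraintSet", terms = t[1L, , drop = FALSE])
  pos <- positions(cd$system)
  pos[t$i[1L], ] <- pos[t$j[1L], ] + c(1, 0, 0)
  expect_equal(restraintEnergyForces(one, pos)$energy, 50)
})

test_that("anchors alone restore the fragment backbone onto the host", {
  cd <- cdBridgeFixture()
  ar <- anchorRestraints(cd$fragment, k = 50)
  pos <- positions(cd$system)
  idx <- cd$fragment@atomIndices
  pos[idx, ] <- pos[idx, ] + rep(c(1.5, -0.8, 0.6), each = length(idx))
  mn <- minimizeSystem(simulationState(pos),
                       list(anchors = makeRestraintProvider(ar)),
                       maxSteps = 20000L, tol = 1e-8)
  t <- restraintTerms(ar)
  dev <- sqrt(rowSums((mn$state@positions[t$i, , drop = FALSE] -
                         mn$state@positions[t$j, , drop = FALSE])^2))
  expect_lt(max(dev), 1e-3)
})

test_that("greedy grouping separates same-site copies and packs far sites", {
  lh <- makeLabelHost(nSites = 2L, nRes = 40L, fold = "extended",
                      minSiteSep = 30)
  s <- lh$system
  ens <- list()
  for (site in lh$sites) {
    r <- buildLabelFragment(s, fragmentSpec("dummy_label", site,
                                            nCopies = 6L), seed = 5L)
    s <- r$system
    ens[[length(ens) + 1L]] <- r$ensemble
  }
  gr <- groupFragments(s, ens, cutoff = 12)
  ## copies at one site always conflict; far sites share groups
  expect_equal(gr$nGroups, 6L)
  byGroup <- split(gr$assignment$site, gr$assignment$group)
  for (g in byGroup) expect_equal(sort(g), sort(lh$sites))

  ## brute-force within-group distance verification
  pos <- positions(gr$system)
  copies <- do.call(c, lapply(gr$ensembles, copies))
  grp <- vapply(copies, exclusionGroup, 1L)
  for (g in unique(grp)) {
    mem <- which(grp == g)
    for (a in seq_along(mem)) {
      for (b in seq_len(a - 1L)) {
        pa <- pos[copies[[mem[a]]]@atomIndices, , drop = FALSE]
        pb <- pos[copies[[mem[b]]]@atomIndices, , drop = FALSE]
        d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") -
          2 * tcrossprod(pa, pb)
        expect_gt(sqrt(max(0, min(d2))), 12)
      }
    }
  }

  ## overflow reports the achieved group count
  expect_error(groupFragments(s, ens, cutoff = 12, maxGroups = 3L),
               "maxGroups = 3")
})
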