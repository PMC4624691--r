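## Shared fixtures, cached across test files (some are expensive to
## build).

.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(name, expr) {
  if (!exists(name, .fixtureCache))
    assign(name, force(expr), .fixtureCache)
  get(name, .fixtureCache)
}

## Small bundle + one Cd bridge fragment, isolated for restraint-only
## work.
cdBridgeFixture <- function() {
  cachedFixture("cdBridge", {
    hb <- makeHelixBundle(helixLength = 16L)
    row <- hb$catalog[hb$catalog$kind == "cd_bridge", ][1L, ]
    b <- buildBridgeFragment(hb$system,
                             fragmentSpec("cd_bridge",
                                          c(row$siteA, row$siteB)))
    list(bundle = hb, system = b$system, fragment = b$fragment,
         iso = isolateFragment(b$system, b$fragment))
  })
}

## Label host with 34 sites beyond twice the cutoff plus label reach,
## carrying 850 dummy-label copies (25 per site).
bigLabelFixture <- function() {
  cachedFixture("bigLabel", {
    lh <- makeLabelHost(nSites = 34L, fold = "extended",
                        minSiteSep = 37)
    s <- lh$system
    ensembles <- vector("list", length(lh$sites))
    for (k in seq_along(lh$sites)) {
      r <- buildLabelFragment(
        s, fragmentSpec("dummy_label", lh$sites[k], nCopies = 25L),
        seed = 11L)
      s <- r$system
      ensembles[[k]] <- r$ensemble
    }
    list(host = lh, system = s, ensembles = ensembles)
  })
}

## Independent brute-force nonbonded oracle: plain double loop with
## switched LJ + Coulomb and only the 1-2/1-3 exclusions, no fragment
## logic.  Deliberately written from scratch against the same physics.
bruteForceNonbonded <- function(system, params) {
  a <- atoms(system)
  pos <- positions(system)
  n <- nrow(pos)
  excl <- matrix(FALSE, n, n)
  b <- system@bonds
  for (r in seq_len(nrow(b))) excl[b$i[r], b$j[r]] <- excl[b$j[r], b$i[r]] <- TRUE
  an <- system@angles
  for (r in seq_len(nrow(an)))
    excl[an$i[r], an$k_[r]] <- excl[an$k_[r], an$i[r]] <- TRUE
  e <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (excl[i, j]) next
      r <- sqrt(sum((pos[i, ] - pos[j, ])^2))
      if (r >= params@cutoff) next
      eps <- sqrt(a$epsilon[i] * a$epsilon[j])
      rmin <- a$rminHalf[i] + a$rminHalf[j]
      sr6 <- (rmin / r)^6
      v <- eps * (sr6^2 - 2 * sr6) +
        332.0636 * a$charge[i] * a$charge[j] / (params@dielectric * r)
      sw <- if (r <= params@switchOn) 1 else {
        A <- params@cutoff^2 - r^2
        A^2 * (params@cutoff^2 + 2 * r^2 - 3 * params@switchOn^2) /
          (params@cutoff^2 - params@switchOn^2)^3
      }
      e <- e + v * sw
    }
  }
  e
}

## Deterministic random coordinates.
randomPositions <- function(n, seed, scale = 5) {
  set.seed(seed)
  matrix(stats::rnorm(3L * n, sd = scale), n, 3L)
}
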