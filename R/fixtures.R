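## Deterministic synthetic fixtures: every mechanism in the package can
## be exercised without downloading a structure.  Fixtures are reduced
## backbone + C-beta systems (side chains appear only where fragments
## are grafted), keeping atom counts at desk scale.

.idealPhi <- -57
.idealPsi <- -47

## Build one ideal alpha-helix (N, CA, C, O, CB per residue) of the
## given length via NeRF chain construction at exactly
## (phi, psi, omega) = (-57, -47, 180).  Returns a list of per-residue
## 5 x 3 coordinate blocks.
.buildIdealHelix <- function(nRes) {
  phi <- .idealPhi * pi / 180
  psi <- .idealPsi * pi / 180
  N <- c(0, 0, 0)
  CA <- c(1.458, 0, 0)
  u <- (N - CA) / 1.458
  C <- CA + 1.525 * (cos(111.2 * pi / 180) * u +
                       sin(111.2 * pi / 180) * c(0, 1, 0))
  res <- vector("list", nRes)
  for (i in seq_len(nRes)) {
    O <- .placeAtom(N, CA, C, 1.231, 120.5 * pi / 180, psi + pi)
    CB <- .placeAtom(N, C, CA, 1.530, 110.6 * pi / 180,
                     -122.6 * pi / 180)
    res[[i]] <- rbind(N = N, CA = CA, C = C, O = O, CB = CB)
    if (i < nRes) {
      Nn <- .placeAtom(N, CA, C, 1.329, 116.2 * pi / 180, psi)
      CAn <- .placeAtom(CA, C, Nn, 1.458, 121.7 * pi / 180, pi)
      Cn <- .placeAtom(C, Nn, CAn, 1.525, 111.2 * pi / 180, phi)
      N <- Nn; CA <- CAn; C <- Cn
    }
  }
  res
}

## Align a helix (list of residue blocks) so its CA axis runs along +z
## and its xy-centroid sits at the origin.
.alignHelixZ <- function(res) {
  pts <- do.call(rbind, res)
  ca <- pts[rownames(pts) == "CA", , drop = FALSE]
  axis <- ca[nrow(ca), ] - ca[1L, ]
  axis <- axis / .norm3(axis)
  z <- c(0, 0, 1)
  v <- .cross3(axis, z)
  sv <- .norm3(v)
  if (sv > 1e-12) {
    ang <- atan2(sv, sum(axis * z))
    pts <- .rotateAbout(pts, c(0, 0, 0), v, ang)
  } else if (sum(axis * z) < 0) {
    pts <- .rotateAbout(pts, c(0, 0, 0), c(1, 0, 0), pi)
  }
  ctr <- colMeans(pts[rownames(pts) == "CA", , drop = FALSE])
  pts <- sweep(pts, 2L, c(ctr[1L], ctr[2L], 0))
  lapply(seq_along(res), function(i) {
    out <- pts[(i - 1L) * 5L + 1:5, , drop = FALSE]
    rownames(out) <- c("N", "CA", "C", "O", "CB")
    out
  })
}

## Flip a z-aligned helix head-to-tail while keeping its z extent.
.flipHelixBlocks <- function(blocks) {
  pts <- do.call(rbind, blocks)
  zr <- range(pts[rownames(pts) == "CA", 3L])
  pts <- .rotateAbout(pts, c(0, 0, 0), c(1, 0, 0), pi)
  pts[, 3L] <- pts[, 3L] + zr[1L] + zr[2L]
  lapply(seq_along(blocks), function(i) {
    out <- pts[(i - 1L) * 5L + 1:5, , drop = FALSE]
    rownames(out) <- c("N", "CA", "C", "O", "CB")
    out
  })
}

.hostResidueAtoms <- function(block, resid, chain, serial0, resname = "ALA") {
  nm <- c("N", "CA", "C", "O", "CB")
  el <- c("N", "C", "C", "O", "C")
  .atomRows(serial = serial0 + 1:5, name = nm, element = el,
            resid = resid, resname = resname, chain = chain,
            charge = 0, fragmentId = 0L)
}

## Host backbone bonded terms for a run of consecutive residues.
.hostBondedTerms <- function(atomBase, nRes) {
  idx <- function(r, k) atomBase + (r - 1L) * 5L + k  # N CA C O CB
  bonds <- NULL; angles <- NULL
  for (r in seq_len(nRes)) {
    bonds <- rbind(bonds,
      data.frame(i = idx(r, 1L), j = idx(r, 2L), k = 300, b0 = 1.458),
      data.frame(i = idx(r, 2L), j = idx(r, 3L), k = 300, b0 = 1.525),
      data.frame(i = idx(r, 3L), j = idx(r, 4L), k = 500, b0 = 1.231),
      data.frame(i = idx(r, 2L), j = idx(r, 5L), k = 250, b0 = 1.530))
    angles <- rbind(angles,
      data.frame(i = idx(r, 1L), j = idx(r, 2L), k_ = idx(r, 3L),
                 ktheta = 50, theta0 = 111.2),
      data.frame(i = idx(r, 2L), j = idx(r, 3L), k_ = idx(r, 4L),
                 ktheta = 50, theta0 = 120.5),
      data.frame(i = idx(r, 1L), j = idx(r, 2L), k_ = idx(r, 5L),
                 ktheta = 50, theta0 = 110.5),
      data.frame(i = idx(r, 3L), j = idx(r, 2L), k_ = idx(r, 5L),
                 ktheta = 50, theta0 = 110.6))
    if (r < nRes) {
      bonds <- rbind(bonds, data.frame(i = idx(r, 3L),
                                       j = idx(r + 1L, 1L),
                                       k = 300, b0 = 1.329))
      angles <- rbind(angles,
        data.frame(i = idx(r, 2L), j = idx(r, 3L), k_ = idx(r + 1L, 1L),
                   ktheta = 50, theta0 = 116.2),
        data.frame(i = idx(r, 4L), j = idx(r, 3L), k_ = idx(r + 1L, 1L),
                   ktheta = 50, theta0 = 123.2),
        data.frame(i = idx(r, 3L), j = idx(r + 1L, 1L),
                   k_ = idx(r + 1L, 2L), ktheta = 50, theta0 = 121.7))
    }
  }
  list(bonds = bonds, angles = angles)
}

#' Four-helix bundle fixture with a bridge-site catalog
#'
#' Builds four ideal antiparallel alpha-helices (phi/psi exactly
#' -57/-47 degrees, backbone + C-beta) on a square lattice, emulating a
#' small transmembrane four-helix bundle (helices S1-S4 as chains
#' A-D).  Residue indices are globally unique across chains.  A catalog
#' maps seven bridge-style constraints (Cd/Cd/Mg/salt/Zn between the
#' S1/S4, S2/S4, S2/S3 and S3/S4 helix pairs) onto fixture residue
#' pairs whose initial C-beta--C-beta separations lie in the 8-16 A
#' range typical of bridgeable starting models.
#'
#' @param helixLength residues per helix (>= 10)
#' @param spacing lattice spacing, Angstrom (>= 5; default 10)
#' @return list with the [AtomicSystem] (`system`), the bridge-site
#'   `catalog` data.frame, `helixRanges` (residue spans per helix) and
#'   the chain ids
#' @export
makeHelixBundle <- function(helixLength = 24L, spacing = 10) {
  if (helixLength < 10L) stop("helixLength must be >= 10")
  if (spacing < 5) stop("lattice spacing < 5 A would clash the helices")
  helix <- .alignHelixZ(.buildIdealHelix(helixLength))
  offsets <- list(c(0, 0), c(spacing, 0), c(spacing, spacing),
                  c(0, spacing))
  chains <- c("A", "B", "C", "D")
  atoms <- NULL; posL <- list(); bonds <- NULL; angles <- NULL
  helixRanges <- list()
  for (h in 1:4) {
    blocks <- helix
    if (h %% 2L == 0L)  # antiparallel: flip every second helix in place
      blocks <- .flipHelixBlocks(blocks)
    atomBase <- 5L * helixLength * (h - 1L)
    resBase <- helixLength * (h - 1L)
    helixRanges[[h]] <- resBase + seq_len(helixLength)
    for (r in seq_len(helixLength)) {
      blk <- sweep(blocks[[r]], 2L, c(offsets[[h]], 0), "+")
      atoms <- rbind(atoms, .hostResidueAtoms(blk, resBase + r,
                                              chains[h],
                                              atomBase + (r - 1L) * 5L))
      posL[[length(posL) + 1L]] <- blk
    }
    bt <- .hostBondedTerms(atomBase, helixLength)
    bonds <- rbind(bonds, bt$bonds)
    angles <- rbind(angles, bt$angles)
  }
  pos <- do.call(rbind, posL)
  system <- .makeSystem(atoms = atoms, positions = unname(pos),
                        bonds = bonds, angles = angles)

  ## catalog: emulate the seven bridge constraints on helix pairs
  mfKinds <- c("cd_bridge", "cd_bridge", "mg_bridge", "salt_bridge",
               "zn_bridge", "cd_bridge", "cd_bridge")
  mfPairs <- list(c(1L, 4L), c(2L, 4L), c(2L, 3L), c(2L, 4L),
                  c(2L, 4L), c(3L, 4L), c(3L, 4L))
  cbIdx <- function(res) .atomIndex(system, res, "CB")
  used <- character(0)
  catalog <- NULL
  margin <- 3L  # keep sites away from helix termini
  for (m in seq_along(mfKinds)) {
    hp <- mfPairs[[m]]
    best <- NULL
    for (ra in helixRanges[[hp[1L]]][-c(seq_len(margin),
                                        helixLength - seq_len(margin) + 1L)]) {
      for (rb in helixRanges[[hp[2L]]][-c(seq_len(margin),
                                          helixLength - seq_len(margin) + 1L)]) {
        key <- paste(ra, rb)
        if (key %in% used) next
        d <- measureDistance(system, cbIdx(ra), cbIdx(rb))
        if (d >= 8 && d <= 16 &&
            (is.null(best) || abs(d - 11) < abs(best$d - 11)))
          best <- list(ra = ra, rb = rb, d = d, key = key)
      }
    }
    if (is.null(best))
      stop("no bridgeable residue pair found for helix pair ",
           paste(hp, collapse = "/"))
    used <- c(used, best$key)
    catalog <- rbind(catalog, data.frame(
      mf = sprintf("MF-%d", m), kind = mfKinds[m],
      helices = paste(chains[hp], collapse = "/"),
      siteA = best$ra, siteB = best$rb, cbCbDistance = best$d))
  }
  list(system = system, catalog = catalog, helixRanges = helixRanges,
       chains = chains)
}

#' Label-host fixture for multiple-copy spin-labeling
#'
#' A single-chain synthetic host with `nSites` labelable residues whose
#' pairwise C-alpha separations exceed a declared spread.  The
#' `"globular"` fold packs short helical segments on a compact grid
#' (~160 residues by default); the `"extended"` fold lays one long
#' ideal helix so that arbitrarily large site separations are available
#' (used for exclusion-group packing demonstrations where all sites
#' must be farther apart than the non-bonded cutoff plus label reach).
#'
#' @param nSites number of labelable sites (>= 2)
#' @param nRes minimum residue count (default 160)
#' @param fold `"globular"` or `"extended"`
#' @param minSiteSep required pairwise site separation, Angstrom
#'   (extended fold only; default 0 means as-compact-as-possible)
#' @return list with the [AtomicSystem] (`system`), the `sites`
#'   residue indices and the realized minimum pairwise C-alpha
#'   separation `minSeparation`
#' @export
makeLabelHost <- function(nSites = 34L, nRes = 160L,
                          fold = c("globular", "extended"),
                          minSiteSep = 0) {
  fold <- match.arg(fold)
  if (nSites < 2L) stop("nSites must be >= 2")
  atoms <- NULL; posL <- list(); bonds <- NULL; angles <- NULL
  if (fold == "extended") {
    resPerGap <- max(4L, as.integer(ceiling((minSiteSep + 6) / 1.5)))
    need <- nSites * resPerGap + 4L
    nRes <- max(nRes, need)
    helix <- .alignHelixZ(.buildIdealHelix(nRes))
    for (r in seq_len(nRes)) {
      atoms <- rbind(atoms, .hostResidueAtoms(helix[[r]], r, "A",
                                              (r - 1L) * 5L))
      posL[[r]] <- helix[[r]]
    }
    bt <- .hostBondedTerms(0L, nRes)
    bonds <- bt$bonds; angles <- bt$angles
    sites <- 3L + (seq_len(nSites) - 1L) * resPerGap
  } else {
    segLen <- 20L
    nSeg <- as.integer(ceiling(nRes / segLen))
    nRes <- nSeg * segLen
    if (nSites > nRes) stop("requested more sites than residues")
    helix <- .alignHelixZ(.buildIdealHelix(segLen))
    grid <- expand.grid(gx = 0:3, gy = 0:((nSeg - 1L) %/% 4L))
    for (sgm in seq_len(nSeg)) {
      off <- c(grid$gx[sgm] * 10, grid$gy[sgm] * 10, 0)
      blocks <- helix
      if (sgm %% 2L == 0L) blocks <- .flipHelixBlocks(blocks)
      atomBase <- 5L * segLen * (sgm - 1L)
      resBase <- segLen * (sgm - 1L)
      for (r in seq_len(segLen)) {
        blk <- sweep(blocks[[r]], 2L, off, "+")
        atoms <- rbind(atoms, .hostResidueAtoms(blk, resBase + r, "A",
                                                atomBase + (r - 1L) * 5L))
        posL[[length(posL) + 1L]] <- blk
      }
      bt <- .hostBondedTerms(atomBase, segLen)
      bonds <- rbind(bonds, bt$bonds)
      angles <- rbind(angles, bt$angles)
    }
    ## greedy farthest-point site selection on CA coordinates
    sites <- NULL
  }
  system <- .makeSystem(atoms = atoms,
                        positions = unname(do.call(rbind, posL)),
                        bonds = bonds, angles = angles)
  caIdx <- which(system@atoms$name == "CA")
  ca <- system@positions[caIdx, , drop = FALSE]
  resOfCa <- system@atoms$resid[caIdx]
  if (is.null(sites)) {
    if (nSites > length(resOfCa)) stop("requested more sites than residues")
    chosen <- which.max(ca[, 1L] + ca[, 2L] + ca[, 3L])
    while (length(chosen) < nSites) {
      dmin <- apply(ca, 1L, function(p)
        min(sqrt(colSums((t(ca[chosen, , drop = FALSE]) - p)^2))))
      chosen <- c(chosen, which.max(dmin))
    }
    sites <- sort(resOfCa[chosen])
  }
  sIdx <- match(sites, resOfCa)
  d <- as.matrix(stats::dist(ca[sIdx, , drop = FALSE]))
  minSep <- min(d[upper.tri(d)])
  if (fold == "extended" && minSiteSep > 0 && minSep <= minSiteSep)
    stop(sprintf("extended fixture failed the declared spread: %.1f A",
                 minSep))
  list(system = system, sites = sites, minSeparation = minSep)
}

#' Free-probe fixture for restrained-ensemble convergence experiments
#'
#' Two sites of `nCopies` free probe particles each (no host, no
#' bonded terms): the minimal system on which the histogram-restraint
#' energy can be exercised in isolation.  Initial positions are seeded
#' Gaussian clouds around the two site centres.
#'
#' @param nCopies copies per site (default 25)
#' @param separation distance between site centres, Angstrom
#' @param spread cloud standard deviation, Angstrom
#' @param seed integer seed
#' @return list with `system` and the two-element `ensembles` list
#' @export
makeFreeProbes <- function(nCopies = 25L, separation = 30, spread = 2,
                           seed = 1L) {
  nCopies <- as.integer(nCopies)
  rng <- .freshRNG(.subSeed(seed, 977L))
  centres <- rbind(c(0, 0, 0), c(0, 0, separation))
  atoms <- NULL
  pos <- NULL
  ensembles <- list()
  serial <- 0L
  for (s in 1:2) {
    idx <- serial + seq_len(nCopies)
    atoms <- rbind(atoms, .atomRows(
      serial = idx, name = "DU", element = "X", resid = s,
      resname = "DUM", chain = "P", charge = 0,
      fragmentId = seq_len(nCopies)))
    pos <- rbind(pos, sweep(matrix(rng$rnorm(3L * nCopies, sd = spread),
                                   nCopies, 3L), 2L, centres[s, ], "+"))
    copiesL <- lapply(seq_len(nCopies), function(cc)
      new("MolecularFragment", atomIndices = as.integer(idx[cc]),
          anchorPairs = matrix(integer(0), 0L, 2L,
                               dimnames = list(NULL, c("frag", "host"))),
          exclusionGroup = cc, scale = 1 / nCopies,
          bridgingIon = NA_integer_, probeAtom = as.integer(idx[cc]),
          sites = s, kind = "dummy_label"))
    ensembles[[s]] <- new("CopyEnsemble", site = s, copies = copiesL,
                          probeAtoms = idx, kind = "dummy_label")
    serial <- serial + nCopies
  }
  list(system = .makeSystem(atoms = atoms, positions = pos),
       ensembles = ensembles)
}

#' Gaussian-mixture target distance histogram
#'
#' Builds a normalized target distribution on the standard bin grid
#' from a list of (mean, weight) modes of generating width `sigmaGen`,
#' emulating experimentally determined multimodal distance
#' distributions.  If the site geometry is supplied, each mode is
#' checked against the geometrically reachable distance window
#' `[siteDistance - reach, siteDistance + reach]`; unachievable targets
#' error unless `override = TRUE`.
#'
#' @param modes list of `c(mean, weight)` pairs (weights sum to 1)
#' @param sigmaGen generating Gaussian width, Angstrom (default 2)
#' @param binWidth bin width, Angstrom (default 1)
#' @param nBins number of bins (default 60)
#' @param siteDistance optional anchor-point distance of the site pair
#' @param reach total tether reach of the two labels, Angstrom
#' @param override skip the achievability check
#' @return a [HistogramTable]
#' @export
makeTargetHistogram <- function(modes, sigmaGen = 2, binWidth = 1,
                                nBins = 60L, siteDistance = NULL,
                                reach = 0, override = FALSE) {
  means <- vapply(modes, `[`, 1, 1L)
  weights <- vapply(modes, `[`, 1, 2L)
  if (abs(sum(weights) - 1) > 1e-9) stop("mode weights must sum to 1")
  win <- nBins * binWidth
  if (any(means <= 0 | means >= win))
    stop("mode mean outside the histogram bin window (0, ",
         win, ")")
  if (!is.null(siteDistance) && !override) {
    lo <- max(binWidth, siteDistance - reach)
    hi <- min(win, siteDistance + reach)
    bad <- means < lo | means > hi
    if (any(bad))
      stop(sprintf(paste0(
        "target mode at %.1f A is geometrically unachievable ",
        "(reachable window %.1f-%.1f A); use override = TRUE to force"),
        means[bad][1L], lo, hi))
  }
  centers <- seq_len(nBins) * binWidth
  v <- rep(0, nBins)
  for (k in seq_along(means))
    v <- v + weights[k] * stats::dnorm(centers, means[k], sigmaGen)
  histogramTable(v, binWidth)
}
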