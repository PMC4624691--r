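#' Specify a molecular fragment
#'
#' A fragment specification names the constraint kind, the host
#' residue(s) it attaches to, optional residue-name mutations at those
#' sites, and (for spin-labels) the number of copies of the
#' multiple-copy expansion.
#'
#' @param kind one of `"cd_bridge"`, `"mg_bridge"`, `"zn_bridge"`,
#'   `"salt_bridge"`, `"mtssl_label"`, `"dummy_label"`
#' @param sites host residue indices: 2 for bridge kinds, 1 for labels
#' @param mutations optional residue names replacing the defaults
#'   (bridges: CYS/ASP/HIS pairs, salt bridge: LYS + GLU)
#' @param nCopies number of copies for label kinds (default 1)
#' @return a validated `fragmentSpec` list
#' @examples
#' fragmentSpec("cd_bridge", sites = c(17, 94))
#' fragmentSpec("mtssl_label", sites = 59, nCopies = 25)
#' @export
fragmentSpec <- function(kind = c("cd_bridge", "mg_bridge", "zn_bridge",
                                  "salt_bridge", "mtssl_label",
                                  "dummy_label"),
                         sites, mutations = NULL, nCopies = 1L) {
  kind <- match.arg(kind)
  isBridge <- kind %in% c("cd_bridge", "mg_bridge", "zn_bridge",
                          "salt_bridge")
  if (isBridge && length(sites) != 2L)
    stop("bridge kinds require exactly 2 host sites")
  if (!isBridge && length(sites) != 1L)
    stop("label kinds require exactly 1 host site")
  if (nCopies < 1L) stop("nCopies must be >= 1")
  structure(list(kind = kind, sites = as.integer(sites),
                 mutations = mutations, nCopies = as.integer(nCopies)),
            class = "fragmentSpec")
}

## Default mutated residue names per kind.
.defaultMutations <- function(kind) {
  switch(kind,
         cd_bridge = c("CYS", "CYS"),
         mg_bridge = c("ASP", "ASP"),
         zn_bridge = c("HIS", "HIS"),
         salt_bridge = c("LYS", "GLU"),
         mtssl_label = "MTSSL",
         dummy_label = "DUM")
}

.backboneNames <- c("N", "C", "O", "CA")

## Host backbone positions of one residue; errors if incomplete.
.hostBackbone <- function(system, site) {
  idx <- vapply(.backboneNames, function(nm) {
    i <- .atomIndex(system, site, nm, fragmentId = 0L)
    if (length(i) != 1L)
      stop("host residue ", site, " lacks a unique backbone atom ", nm)
    i
  }, 1L)
  idx
}

## Build one patched residue (backbone copy + template side chain) as
## atom rows / positions / named bonded terms.  Coordinates start from
## the host backbone; the side chain is grown from ideal internal
## geometry.
.buildPatchedResidue <- function(system, site, resname) {
  tpl <- .sideChainTemplates[[resname]]
  if (is.null(tpl)) stop("no side-chain template for residue ", resname)
  hostIdx <- .hostBackbone(system, site)
  hostPos <- system@positions[hostIdx, , drop = FALSE]
  rownames(hostPos) <- .backboneNames
  chain <- system@atoms$chain[hostIdx[1L]]

  names <- .backboneNames
  pos <- hostPos
  charges <- rep(0, 4L)
  elements <- c("N", "C", "O", "C")
  for (r in seq_len(nrow(tpl$atoms))) {
    row <- tpl$atoms[r, ]
    for (ref in c(row$refA, row$refB, row$refC))
      if (!ref %in% names)
        stop("template reference atom ", ref, " not yet placed")
    p <- .placeAtom(pos[row$refA, ], pos[row$refB, ], pos[row$refC, ],
                    row$bond, row$angle * pi / 180,
                    row$dihedral * pi / 180)
    pos <- rbind(pos, p)
    names <- c(names, row$name)
    rownames(pos) <- names
    charges <- c(charges, row$charge)
    elements <- c(elements, row$element)
  }
  list(names = names, elements = elements, charges = charges,
       positions = pos, chain = chain, site = site, resname = resname,
       hostIdx = hostIdx, template = tpl)
}

## Append a patched residue to the system under a fragment id; resolves
## the template's named bonded terms to atom indices.
.appendResidue <- function(system, res, fragmentId, resnameOut = NULL) {
  a <- system@atoms
  n0 <- nrow(a)
  serial0 <- if (n0) max(a$serial) else 0L
  rows <- .atomRows(serial = serial0 + seq_along(res$names),
                    name = res$names, element = res$elements,
                    resid = res$site,
                    resname = if (is.null(resnameOut)) res$resname
                              else resnameOut,
                    chain = res$chain, charge = res$charges,
                    fragmentId = fragmentId)
  idxOf <- function(nm) n0 + match(nm, res$names)
  tpl <- res$template
  bonds <- rbind(.backboneBonds, tpl$bonds)
  newBonds <- data.frame(i = idxOf(bonds$a), j = idxOf(bonds$b),
                         k = bonds$k, b0 = bonds$b0)
  angles <- rbind(.backboneAngles, tpl$angles)
  newAngles <- data.frame(i = idxOf(angles$a), j = idxOf(angles$b),
                          k_ = idxOf(angles$c), ktheta = angles$k,
                          theta0 = angles$theta0)
  newDih <- NULL
  if (!is.null(tpl$dihedrals) && nrow(tpl$dihedrals))
    newDih <- data.frame(i = idxOf(tpl$dihedrals$a),
                         j = idxOf(tpl$dihedrals$b),
                         k_ = idxOf(tpl$dihedrals$c),
                         l = idxOf(tpl$dihedrals$d),
                         kchi = tpl$dihedrals$k,
                         mult = as.integer(tpl$dihedrals$mult),
                         delta = tpl$dihedrals$delta)
  system@atoms <- rbind(a, rows)
  system@positions <- rbind(system@positions, unname(res$positions))
  system@bonds <- rbind(system@bonds, newBonds)
  system@angles <- rbind(system@angles, newAngles)
  if (!is.null(newDih)) system@dihedrals <- rbind(system@dihedrals, newDih)
  list(system = system, indices = n0 + seq_along(res$names))
}

.nextFragmentGroup <- function(system) {
  max(0L, system@atoms$fragmentId) + 1L
}

#' Build a metal-ion or salt-bridge fragment
#'
#' Constructs an atomically detailed bridge fragment: the two mutated
#' side chains grown from ideal internal geometry on copies of the host
#' backbone at the two sites, plus (for metal bridges) the bridging ion
#' placed at the midpoint of the two coordinating atoms.  The mutated
#' bridge residues carry the deprotonated charge state so that the
#' fragment is electrically neutral.  Anchor pairs tie the fragment
#' backbone atoms (N, C, O, C-alpha) to the host backbone.
#'
#' @param system an [AtomicSystem]; the fragment atoms are appended
#' @param spec a [fragmentSpec] of a bridge kind
#' @param exclusionGroup exclusion group id (default: next free)
#' @return list with the updated `system` and the [MolecularFragment]
#' @seealso [metalBridgeRestraints()], [anchorRestraints()]
#' @export
buildBridgeFragment <- function(system, spec,
                                exclusionGroup = .nextFragmentGroup(system)) {
  if (!inherits(spec, "fragmentSpec")) stop("spec must be a fragmentSpec")
  if (!spec$kind %in% c("cd_bridge", "mg_bridge", "zn_bridge",
                        "salt_bridge"))
    stop("buildBridgeFragment handles bridge kinds only; got ",
         spec$kind, " (use buildLabelFragment)")
  if (spec$sites[1L] == spec$sites[2L])
    stop("the two bridge sites must be distinct")
  resnames <- if (is.null(spec$mutations)) .defaultMutations(spec$kind)
              else spec$mutations
  group <- as.integer(exclusionGroup)

  allIdx <- integer(0)
  anchors <- NULL
  coordIdx <- integer(0)
  for (s in 1:2) {
    res <- .buildPatchedResidue(system, spec$sites[s], resnames[s])
    app <- .appendResidue(system, res, group)
    system <- app$system
    allIdx <- c(allIdx, app$indices)
    anchors <- rbind(anchors,
                     cbind(frag = app$indices[match(.backboneNames,
                                                    res$names)],
                           host = res$hostIdx))
    coordName <- .sideChainTemplates[[resnames[s]]]$coordAtom
    ci <- app$indices[match(coordName, res$names)]
    if (is.na(ci)) stop("coordinating atom ", coordName, " not found")
    coordIdx <- c(coordIdx, ci)
  }

  ionIdx <- NA_integer_
  if (spec$kind %in% names(.ionSpecs)) {
    ion <- .ionSpecs[[spec$kind]]
    mid <- colMeans(system@positions[coordIdx, , drop = FALSE])
    n0 <- nrow(system@atoms)
    rows <- .atomRows(serial = max(system@atoms$serial) + 1L,
                      name = ion$ion, element = ion$ion,
                      resid = max(system@atoms$resid) + 1L,
                      resname = ion$resname,
                      chain = system@atoms$chain[allIdx[1L]],
                      charge = ion$charge, fragmentId = group)
    system@atoms <- rbind(system@atoms, rows)
    system@positions <- rbind(system@positions, mid)
    ionIdx <- n0 + 1L
    allIdx <- c(allIdx, ionIdx)
  }

  netCharge <- sum(system@atoms$charge[allIdx])
  if (abs(netCharge) > 1e-9)
    stop(sprintf("bridge fragment is not electrically neutral (q = %+.2f)",
                 netCharge))

  frag <- new("MolecularFragment", atomIndices = allIdx,
              anchorPairs = anchors, exclusionGroup = group,
              scale = 1, bridgingIon = ionIdx,
              probeAtom = NA_integer_, sites = spec$sites,
              kind = spec$kind)
  validObject(frag)
  list(system = system, fragment = frag)
}

#' Build a multiple-copy spin-label ensemble
#'
#' Attaches `nCopies` identical spin-label fragments (full MTSSL arm or
#' a single-pseudo-atom dummy label) at one host site.  The side-chain
#' chi dihedrals of each copy are perturbed by uniformly random offsets
#' from a seeded generator so the copies start spread over rotamer
#' space; composition, bonds and charges are identical across copies.
#' Each copy's interaction with the environment is scaled by
#' `1/nCopies`.
#'
#' @param system an [AtomicSystem]; copies are appended
#' @param spec a [fragmentSpec] with kind `"mtssl_label"` or
#'   `"dummy_label"`
#' @param seed integer seed for the copy-spreading perturbations
#' @param firstGroup exclusion group id of the first copy; copy `c`
#'   gets `firstGroup + c - 1` until [groupFragments] reassigns groups
#' @return list with the updated `system` and the [CopyEnsemble]
#' @export
buildLabelFragment <- function(system, spec, seed = 1L,
                               firstGroup = .nextFragmentGroup(system)) {
  if (!inherits(spec, "fragmentSpec")) stop("spec must be a fragmentSpec")
  if (!spec$kind %in% c("mtssl_label", "dummy_label"))
    stop("buildLabelFragment handles label kinds only; got ", spec$kind,
         " (use buildBridgeFragment)")
  if (spec$nCopies < 1L) stop("nCopies must be >= 1")
  resname <- if (is.null(spec$mutations)) .defaultMutations(spec$kind)
             else spec$mutations
  tpl <- .sideChainTemplates[[resname]]
  probeName <- tpl$probeAtom
  if (is.null(probeName)) stop(resname, " has no probe atom")

  rng <- .freshRNG(.subSeed(seed, spec$sites[1L]))
  copies <- vector("list", spec$nCopies)
  probes <- integer(spec$nCopies)
  for (cc in seq_len(spec$nCopies)) {
    res <- .buildPatchedResidue(system, spec$sites[1L], resname)
    ## spread the copy over chi space: rotate everything downstream of
    ## each rotatable bond by a random offset
    for (chi in tpl$chiBonds) {
      offset <- rng$runif(1L, -pi, pi)
      down <- .downstreamAtoms(res, chi)
      if (length(down)) {
        axisA <- res$positions[chi[1L], ]
        axisB <- res$positions[chi[2L], ]
        res$positions[down, ] <- .rotateAbout(
          res$positions[down, , drop = FALSE], axisA, axisB - axisA,
          offset)
      }
    }
    group <- as.integer(firstGroup + cc - 1L)
    app <- .appendResidue(system, res, group)
    system <- app$system
    anchors <- cbind(frag = app$indices[match(.backboneNames, res$names)],
                     host = res$hostIdx)
    probes[cc] <- app$indices[match(probeName, res$names)]
    copies[[cc]] <- new("MolecularFragment",
                        atomIndices = app$indices, anchorPairs = anchors,
                        exclusionGroup = group,
                        scale = 1 / spec$nCopies,
                        bridgingIon = NA_integer_,
                        probeAtom = probes[cc],
                        sites = spec$sites, kind = spec$kind)
  }
  ens <- new("CopyEnsemble", site = spec$sites[1L], copies = copies,
             probeAtoms = probes, kind = spec$kind)
  validObject(ens)
  list(system = system, ensemble = ens)
}

## Atoms strictly downstream of the rotatable bond (a, b): the connected
## component of b once the a-b edge is removed, minus the backbone.
.downstreamAtoms <- function(res, chi) {
  tpl <- res$template
  bonds <- rbind(.backboneBonds[, c("a", "b")], tpl$bonds[, c("a", "b")])
  drop <- (bonds$a == chi[1L] & bonds$b == chi[2L]) |
          (bonds$a == chi[2L] & bonds$b == chi[1L])
  bonds <- bonds[!drop, , drop = FALSE]
  comp <- chi[2L]
  repeat {
    nb <- unique(c(bonds$b[bonds$a %in% comp], bonds$a[bonds$b %in% comp]))
    nb <- setdiff(nb, comp)
    if (!length(nb)) break
    comp <- c(comp, nb)
  }
  down <- setdiff(comp, c(.backboneNames, chi[2L]))
  match(down, res$names)
}

## A private RNG stream that does not disturb the global RNG state.
.freshRNG <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    s
  })
  draw <- function(fun, ...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- fun(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    out
  }
  list(runif = function(n, min = 0, max = 1) draw(stats::runif, n, min, max),
       rnorm = function(n, mean = 0, sd = 1) draw(stats::rnorm, n, mean, sd))
}

#' Extract a fragment as an isolated system
#'
#' Returns a small [AtomicSystem] holding only the fragment's atoms
#' (with its internal bonded terms, reindexed) together with the
#' reindexed [MolecularFragment].  Anchor pairs are dropped since the
#' host is absent.  Useful for restraint-only minimization of a single
#' bridge fragment.
#'
#' @param system the full [AtomicSystem]
#' @param fragment a [MolecularFragment] within it
#' @return list with the isolated `system`, the reindexed `fragment`
#'   and the `indexMap` (old atom index -> new)
#' @export
isolateFragment <- function(system, fragment) {
  idx <- sort(fragment@atomIndices)
  map <- integer(nAtoms(system))
  map[idx] <- seq_along(idx)
  keepTerm <- function(df, cols) {
    if (!nrow(df)) return(df)
    sel <- rowSums(matrix(as.matrix(df[, cols]) %in% idx,
                          nrow = nrow(df))) == length(cols)
    out <- df[sel, , drop = FALSE]
    for (cl in cols) out[[cl]] <- map[out[[cl]]]
    out
  }
  iso <- .makeSystem(
    atoms = system@atoms[idx, , drop = FALSE],
    positions = system@positions[idx, , drop = FALSE],
    bonds = keepTerm(system@bonds, c("i", "j")),
    angles = keepTerm(system@angles, c("i", "j", "k_")),
    dihedrals = keepTerm(system@dihedrals, c("i", "j", "k_", "l")))
  newFrag <- new("MolecularFragment",
                 atomIndices = map[fragment@atomIndices],
                 anchorPairs = matrix(integer(0), 0L, 2L,
                                      dimnames = list(NULL,
                                                      c("frag", "host"))),
                 exclusionGroup = 1L, scale = fragment@scale,
                 bridgingIon = if (is.na(fragment@bridgingIon))
                   NA_integer_ else map[fragment@bridgingIon],
                 probeAtom = if (is.na(fragment@probeAtom))
                   NA_integer_ else map[fragment@probeAtom],
                 sites = fragment@sites, kind = fragment@kind)
  list(system = iso, fragment = newFrag, indexMap = map)
}

#' Anchor restraints for a fragment
#'
#' One harmonic distance restraint per anchor pair,
#' \eqn{E = k (d - b_0)^2} with \eqn{b_0 = 0}, tying each fragment
#' backbone atom (N, C, O, C-alpha) on top of the matching host backbone
#' atom.
#'
#' @param fragment a [MolecularFragment] with populated anchor pairs
#' @param k force constant, kcal/mol/Angstrom^2 (50 for bridge
#'   refinement, 10 for the restrained-ensemble spin-labels)
#' @param b0 equilibrium distance, Angstrom (default 0)
#' @return a [RestraintSet] of `anchor` terms
#' @export
anchorRestraints <- function(fragment, k = 50, b0 = 0) {
  if (k <= 0) stop("anchor force constant must be > 0")
  ap <- fragment@anchorPairs
  if (nrow(ap) == 0L) stop("fragment has no anchor pairs")
  new("RestraintSet", terms = data.frame(
    kind = "anchor", i = as.integer(ap[, "frag"]),
    j = as.integer(ap[, "host"]), k_ = NA_integer_, l = NA_integer_,
    kconst = k, x0 = b0, rampId = NA_character_,
    stringsAsFactors = FALSE))
}

#' Group spin-label copies into a bounded number of exclusion groups
#'
#' MD engines with a hard cap on the number of non-interacting fragments
#' (255 in the reference engine) cannot give each of `nSites * nCopies`
#' label copies its own group.  Copies whose minimum inter-atomic
#' distance exceeds the non-bonded cutoff never interact, so they can
#' share one engine-level group.  A deterministic greedy first-fit pass
#' (copies sorted by site then copy index, ties to the lowest group
#' index) packs the copies; every within-group pair is guaranteed to be
#' beyond the cutoff.
#'
#' @param system the [AtomicSystem] holding the copies
#' @param ensembles list of [CopyEnsemble]
#' @param cutoff non-bonded cutoff, Angstrom
#' @param maxGroups maximum number of exclusion groups (default 255)
#' @return list with updated `system` (per-atom fragment ids), updated
#'   `ensembles`, the `assignment` data.frame (site, copy, group) and
#'   `nGroups`
#' @export
groupFragments <- function(system, ensembles, cutoff = 12,
                           maxGroups = 255L) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  copiesFlat <- list()
  meta <- NULL
  for (e in ensembles) {
    for (cc in seq_along(e@copies)) {
      copiesFlat[[length(copiesFlat) + 1L]] <- e@copies[[cc]]
      meta <- rbind(meta, data.frame(site = e@site, copy = cc))
    }
  }
  ## site-major, copy-index order (the construction order)
  coords <- lapply(copiesFlat, function(f)
    system@positions[f@atomIndices, , drop = FALSE])
  centroid <- t(vapply(coords, colMeans, numeric(3L)))
  radius <- vapply(seq_along(coords), function(i)
    sqrt(max(rowSums(sweep(coords[[i]], 2L, centroid[i, ])^2))), 1)

  minDistExceeds <- function(i, j, cut) {
    dc <- sqrt(sum((centroid[i, ] - centroid[j, ])^2))
    if (dc - radius[i] - radius[j] > cut) return(TRUE)
    if (dc + radius[i] + radius[j] <= cut) return(FALSE)
    a <- coords[[i]]; b <- coords[[j]]
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
    sqrt(max(0, min(d2))) > cut
  }

  members <- list()
  assignment <- integer(length(copiesFlat))
  for (i in seq_along(copiesFlat)) {
    placed <- FALSE
    for (g in seq_along(members)) {
      ok <- all(vapply(members[[g]], function(j)
        minDistExceeds(i, j, cutoff), TRUE))
      if (ok) {
        members[[g]] <- c(members[[g]], i)
        assignment[i] <- g
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      if (length(members) >= maxGroups)
        stop(sprintf(paste0(
          "greedy grouping needs more than maxGroups = %d exclusion ",
          "groups (%d achieved before overflow)"), maxGroups,
          length(members)))
      members[[length(members) + 1L]] <- i
      assignment[i] <- length(members)
    }
  }

  ## write groups back into atoms and fragment objects
  k <- 0L
  for (ei in seq_along(ensembles)) {
    e <- ensembles[[ei]]
    for (cc in seq_along(e@copies)) {
      k <- k + 1L
      g <- assignment[k]
      f <- e@copies[[cc]]
      f@exclusionGroup <- g
      e@copies[[cc]] <- f
      system@atoms$fragmentId[f@atomIndices] <- g
    }
    ensembles[[ei]] <- e
  }
  list(system = system, ensembles = ensembles,
       assignment = cbind(meta, group = assignment),
       nGroups = length(members))
}
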