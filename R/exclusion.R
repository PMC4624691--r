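#' Soft-core parameter constructor
#'
#' @param delta soft-core offset, Angstrom^2 (default 1)
#' @param switchOn start of the switching region, Angstrom (default 10)
#' @param cutoff truncation distance, Angstrom (default 12)
#' @param dielectric relative dielectric constant (default 1)
#' @return a [SoftCoreParams]
#' @export
softCoreParams <- function(delta = 1, switchOn = 10, cutoff = 12,
                           dielectric = 1) {
  new("SoftCoreParams", delta = delta, switchOn = switchOn,
      cutoff = cutoff, dielectric = dielectric)
}

#' Soft-core effective distance
#'
#' \eqn{r' = \sqrt{r^2 + \Delta}}.  Applied to atom pairs that involve a
#' molecular fragment, it lets unphysically small separations occur
#' (fragments may overlap each other's host environment) while keeping
#' the pair interaction and its forces finite and smooth at r = 0.
#'
#' @param r distance(s), Angstrom (>= 0)
#' @param delta soft-core offset, Angstrom^2 (>= 0)
#' @return effective distance(s), Angstrom
#' @examples
#' softcoreDistance(3, 7)   # 4
#' softcoreDistance(0, 1)   # 1
#' @export
softcoreDistance <- function(r, delta) {
  if (any(r < 0)) stop("r must be >= 0")
  if (any(delta < 0)) stop("delta must be >= 0")
  sqrt(r * r + delta)
}

#' Exclusion model for fragment-aware nonbonded evaluation
#'
#' Precomputes the pairwise interaction scale implied by the
#' non-interacting fragment scheme:
#' * atoms of different exclusion groups (both fragment atoms): scale 0;
#' * any fragment atom against any atom of the fragment's target host
#'   residue(s): scale 0;
#' * fragment backbone atoms against host backbone atoms of the
#'   flanking residues (i-1, i+1): scale 0;
#' * standard 1-2/1-3 bonded exclusions: scale 0;
#' * fragment-environment pairs: the fragment's copy scale (1/N);
#' * host-host and intra-fragment pairs: scale 1.
#'
#' @slot fragOfAtom integer per atom: index into the fragment list (0 =
#'   host).
#' @slot groupOfAtom integer per atom: exclusion group (0 = host).
#' @slot scaleOfFrag numeric per fragment.
#' @slot hostZero,list per fragment: host atoms of the target residue(s).
#' @slot hostBBZero list per fragment: host backbone atoms of residues
#'   i-1 and i+1.
#' @slot fragBB list per fragment: the fragment's backbone atoms.
#' @slot exclKeys sorted numeric pair keys of 1-2/1-3 exclusions.
#' @slot nAtomsModel number of atoms the model was built for.
#' @export
setClass("ExclusionModel",
  representation(fragOfAtom = "integer", groupOfAtom = "integer",
                 scaleOfFrag = "numeric", hostZero = "list",
                 hostBBZero = "list", fragBB = "list",
                 exclKeys = "numeric", nAtomsModel = "integer"))

setMethod("show", "ExclusionModel", function(object) {
  cat(sprintf(paste0(
    "ExclusionModel: %d atoms, %d fragments, %d exclusion groups, ",
    "%d bonded exclusions\n"),
    object@nAtomsModel, length(object@scaleOfFrag),
    length(unique(object@groupOfAtom[object@groupOfAtom > 0L])),
    length(object@exclKeys)))
  invisible(object)
})

.pairKey <- function(i, j, n) {
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  (lo - 1) * n + hi
}

#' Build the exclusion model for a system and its fragments
#'
#' @param system an [AtomicSystem]
#' @param fragments list of [MolecularFragment] (bridge fragments and/or
#'   all label copies, flattened)
#' @return an [ExclusionModel]
#' @export
buildExclusionModel <- function(system, fragments = list()) {
  n <- nAtoms(system)
  a <- system@atoms
  fragOf <- integer(n)
  groupOf <- integer(n)
  scaleOf <- numeric(length(fragments))
  hostZero <- vector("list", length(fragments))
  hostBBZero <- vector("list", length(fragments))
  fragBB <- vector("list", length(fragments))
  hostSel <- a$fragmentId == 0L
  for (fi in seq_along(fragments)) {
    f <- fragments[[fi]]
    fragOf[f@atomIndices] <- fi
    groupOf[f@atomIndices] <- f@exclusionGroup
    scaleOf[fi] <- f@scale
    hostZero[[fi]] <- which(hostSel & a$resid %in% f@sites)
    flank <- c(f@sites - 1L, f@sites + 1L)
    hostBBZero[[fi]] <- which(hostSel & a$resid %in% flank &
                                a$name %in% .backboneNames)
    fragBB[[fi]] <- f@atomIndices[a$name[f@atomIndices] %in%
                                    .backboneNames]
  }
  keys <- numeric(0)
  if (nrow(system@bonds))
    keys <- c(keys, .pairKey(system@bonds$i, system@bonds$j, n))
  if (nrow(system@angles))
    keys <- c(keys, .pairKey(system@angles$i, system@angles$k_, n))
  new("ExclusionModel", fragOfAtom = fragOf, groupOfAtom = groupOf,
      scaleOfFrag = scaleOf, hostZero = hostZero,
      hostBBZero = hostBBZero, fragBB = fragBB,
      exclKeys = sort(unique(keys)), nAtomsModel = as.integer(n))
}

#' Pairwise interaction scale
#'
#' @param model an [ExclusionModel]
#' @param i,j atom index vectors (recycled to equal length)
#' @return numeric scale(s) in `{0} U (0, 1]`
#' @export
pairScale <- function(model, i, j) {
  m <- max(length(i), length(j))
  i <- rep_len(as.integer(i), m)
  j <- rep_len(as.integer(j), m)
  if (any(i == j)) stop("pair scale undefined for i == j")
  s <- rep(1, m)
  n <- model@nAtomsModel
  excl <- .pairKey(i, j, n) %in% model@exclKeys
  s[excl] <- 0
  fi <- model@fragOfAtom[i]
  fj <- model@fragOfAtom[j]
  gi <- model@groupOfAtom[i]
  gj <- model@groupOfAtom[j]
  bothFrag <- fi > 0L & fj > 0L
  s[bothFrag & gi != gj] <- 0
  ## fragment-host pairs: loop over the fragments actually present
  for (swap in c(FALSE, TRUE)) {
    fa <- if (swap) fj else fi
    fb <- if (swap) fi else fj
    ia <- if (swap) j else i
    ib <- if (swap) i else j
    cross <- which(fa > 0L & fb == 0L & s > 0)
    for (f in unique(fa[cross])) {
      sel <- cross[fa[cross] == f]
      zero <- ib[sel] %in% model@hostZero[[f]] |
        (ia[sel] %in% model@fragBB[[f]] &
           ib[sel] %in% model@hostBBZero[[f]])
      s[sel[zero]] <- 0
      s[sel[!zero]] <- model@scaleOfFrag[f]
    }
  }
  s
}

## CHARMM-style switching function value and derivative at x.
.switchFn <- function(x, ron, rc) {
  S <- numeric(length(x))
  dS <- numeric(length(x))
  below <- x <= ron
  S[below] <- 1
  mid <- x > ron & x < rc
  if (any(mid)) {
    xm <- x[mid]
    A <- rc^2 - xm^2
    B <- rc^2 + 2 * xm^2 - 3 * ron^2
    C <- (rc^2 - ron^2)^3
    S[mid] <- A^2 * B / C
    dS[mid] <- 4 * xm * A * (A - B) / C
  }
  list(S = S, dS = dS)
}

.coulombConst <- 332.0636  # kcal/mol * A / e^2

## Vectorized pair kernel at effective distances x: returns energy per
## pair and dE/dx (before the soft-core chain rule).
.pairKernel <- function(x, eps, rmin, qq, params) {
  sw <- .switchFn(x, params@switchOn, params@cutoff)
  sr2 <- (rmin / x)^2
  sr6 <- sr2^3
  vlj <- eps * (sr6^2 - 2 * sr6)
  dvlj <- (12 * eps / x) * (sr6 - sr6^2)
  vc <- .coulombConst * qq / (params@dielectric * x)
  dvc <- -vc / x
  v <- vlj + vc
  list(e = v * sw$S, dedx = (dvlj + dvc) * sw$S + v * sw$dS)
}

## Candidate pairs with r < cutoff.  Full O(n^2) scan in blocks for
## small systems, cell list with edge = cutoff for larger ones.
.pairsWithinCutoff <- function(pos, cutoff) {
  n <- nrow(pos)
  if (n < 2L)
    return(list(i = integer(0), j = integer(0), r = numeric(0),
                dx = matrix(numeric(0), ncol = 3L)))
  if (n <= 1200L) {
    d2 <- outer(rowSums(pos^2), rowSums(pos^2), "+") - 2 * tcrossprod(pos)
    sel <- which(upper.tri(d2) & d2 < cutoff^2, arr.ind = TRUE)
    i <- sel[, 1L]; j <- sel[, 2L]
  } else {
    cell <- floor(sweep(pos, 2L, apply(pos, 2L, min)) / cutoff)
    dims <- apply(cell, 2L, max) + 1L
    lin <- cell[, 1L] + dims[1L] * (cell[, 2L] + dims[2L] * cell[, 3L])
    byCell <- split(seq_len(n), lin)
    ids <- as.numeric(names(byCell))
    off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    offLin <- off$dx + dims[1L] * (off$dy + dims[2L] * off$dz)
    iL <- list(); jL <- list(); k <- 0L
    for (ci in seq_along(byCell)) {
      A <- byCell[[ci]]
      for (o in offLin) {
        target <- ids[ci] + o
        if (o < 0) next         # handled from the other side
        if (o == 0) {
          if (length(A) > 1L) {
            cmb <- utils::combn(A, 2L)
            k <- k + 1L; iL[[k]] <- cmb[1L, ]; jL[[k]] <- cmb[2L, ]
          }
        } else {
          ti <- match(target, ids)
          if (!is.na(ti)) {
            B <- byCell[[ti]]
            g <- expand.grid(A, B)
            k <- k + 1L; iL[[k]] <- g[, 1L]; jL[[k]] <- g[, 2L]
          }
        }
      }
    }
    i <- unlist(iL); j <- unlist(jL)
    if (is.null(i)) i <- integer(0)
    if (is.null(j)) j <- integer(0)
    ## normalize and drop duplicates (small grids can alias cell ids)
    lo <- pmin(i, j); hi <- pmax(i, j)
    keep <- !duplicated((lo - 1) * n + hi)
    i <- lo[keep]; j <- hi[keep]
  }
  dx <- pos[i, , drop = FALSE] - pos[j, , drop = FALSE]
  r <- sqrt(rowSums(dx^2))
  keep <- r < cutoff
  list(i = i[keep], j = j[keep], r = r[keep],
       dx = dx[keep, , drop = FALSE])
}

## Core nonbonded evaluation shared by pairEnergy / totalNonbonded.
.nonbondedEval <- function(system, positions, model, params) {
  a <- system@atoms
  pl <- .pairsWithinCutoff(positions, params@cutoff)
  n <- nrow(positions)
  forces <- matrix(0, n, 3L)
  comp <- c(hostHost = 0, intraFragment = 0, crossScaled = 0,
            crossUnscaled = 0)
  if (!length(pl$i))
    return(list(energy = 0, forces = forces, components = comp))
  i <- pl$i; j <- pl$j
  s <- pairScale(model, i, j)
  fi <- model@fragOfAtom[i]
  fj <- model@fragOfAtom[j]
  soft <- (fi > 0L | fj > 0L) & fi != fj
  act <- which(s > 0)
  if (length(act)) {
    ia <- i[act]; ja <- j[act]
    r <- pl$r[act]
    x <- ifelse(soft[act], sqrt(r^2 + params@delta), r)
    eps <- sqrt(a$epsilon[ia] * a$epsilon[ja])
    rmin <- a$rminHalf[ia] + a$rminHalf[ja]
    qq <- a$charge[ia] * a$charge[ja]
    kr <- .pairKernel(x, eps, rmin, qq, params)
    e <- s[act] * kr$e
    ## dE/d(rvec): chain rule through the soft-core distance; the
    ## coefficient multiplies the displacement vector directly, so the
    ## r -> 0 soft-core limit is regular
    coefPerDx <- s[act] * kr$dedx / x
    hard <- !soft[act]
    if (any(hard))
      coefPerDx[hard] <- s[act][hard] * kr$dedx[hard] / pmax(r[hard], 1e-12)
    fvec <- -coefPerDx * pl$dx[act, , drop = FALSE]
    ## pairwise accumulation (Newton's third law)
    accI <- rowsum(fvec, ia)
    accJ <- rowsum(-fvec, ja)
    idxI <- as.integer(rownames(accI))
    idxJ <- as.integer(rownames(accJ))
    forces[idxI, ] <- forces[idxI, ] + accI
    forces[idxJ, ] <- forces[idxJ, ] + accJ

    bothHost <- fi[act] == 0L & fj[act] == 0L
    intra <- fi[act] > 0L & fj[act] > 0L
    cross <- !bothHost & !intra
    comp["hostHost"] <- sum(e[bothHost])
    comp["intraFragment"] <- sum(e[intra])
    comp["crossScaled"] <- sum(e[cross])
    comp["crossUnscaled"] <- sum(kr$e[cross])
    return(list(energy = sum(e), forces = forces, components = comp))
  }
  list(energy = 0, forces = forces, components = comp)
}

#' Nonbonded energy and forces of a single atom pair
#'
#' Evaluates the switched Lennard-Jones plus Coulomb interaction of one
#' atom pair under the exclusion model, using the soft-core effective
#' distance for pairs that involve a fragment atom.  Forces are the
#' exact gradients of the returned energy.
#'
#' @param system an [AtomicSystem]
#' @param i,j atom indices (i != j)
#' @param model an [ExclusionModel]
#' @param params a [SoftCoreParams]
#' @param positions optional coordinate override
#' @return list with `energy`, `forceI`, `forceJ`
#' @export
pairEnergy <- function(system, i, j, model, params,
                       positions = NULL) {
  if (i == j) stop("pair energy undefined for i == j")
  pos <- if (is.null(positions)) system@positions else positions
  a <- system@atoms
  dx <- pos[i, ] - pos[j, ]
  r <- .norm3(dx)
  s <- pairScale(model, i, j)
  fi <- model@fragOfAtom[i]
  fj <- model@fragOfAtom[j]
  soft <- (fi > 0L || fj > 0L) && fi != fj
  if (s == 0 || r >= params@cutoff)
    return(list(energy = 0, forceI = c(0, 0, 0), forceJ = c(0, 0, 0)))
  x <- if (soft) sqrt(r^2 + params@delta) else r
  kr <- .pairKernel(x, sqrt(a$epsilon[i] * a$epsilon[j]),
                    a$rminHalf[i] + a$rminHalf[j],
                    a$charge[i] * a$charge[j], params)
  coef <- if (soft) s * kr$dedx / x else s * kr$dedx / max(r, 1e-12)
  f <- -coef * dx
  list(energy = s * kr$e, forceI = f, forceJ = -f)
}

#' Total nonbonded energy and forces
#'
#' Sums [pairEnergy] over all pairs within the cutoff.  The result
#' decomposes exactly as
#' `E = E_hostHost + E_intraFragment + E_crossScaled`, returned in
#' `components` (with the unscaled cross energy alongside).
#'
#' @inheritParams pairEnergy
#' @return list with `energy`, `forces` (n x 3) and `components`
#' @export
totalNonbonded <- function(system, model, params, positions = NULL) {
  pos <- if (is.null(positions)) system@positions else positions
  .nonbondedEval(system, pos, model, params)
}

#' Fragment-environment interaction scaling ratio
#'
#' The interactions between an N-copy fragment and the rest of the
#' system are scaled by 1/N; this reports the realized ratio of the
#' scaled to the unscaled fragment-environment energy, which equals the
#' fragment's scale exactly.  When the unscaled cross energy is zero the
#' ratio is returned as the fragment's scale by construction.
#'
#' @param system an [AtomicSystem]
#' @param model an [ExclusionModel]
#' @param params a [SoftCoreParams]
#' @param fragment the [MolecularFragment] to probe
#' @return the scalar ratio
#' @export
scaledInteractionRatio <- function(system, model, params, fragment) {
  pos <- system@positions
  a <- system@atoms
  pl <- .pairsWithinCutoff(pos, params@cutoff)
  inFrag <- seq_len(nAtoms(system)) %in% fragment@atomIndices
  cross <- xor(inFrag[pl$i], inFrag[pl$j]) &
    (model@fragOfAtom[pl$i] == 0L | model@fragOfAtom[pl$j] == 0L)
  if (!any(cross)) return(fragment@scale)
  i <- pl$i[cross]; j <- pl$j[cross]
  s <- pairScale(model, i, j)
  act <- s > 0
  if (!any(act)) return(fragment@scale)
  i <- i[act]; j <- j[act]
  r <- pl$r[cross][act]
  x <- sqrt(r^2 + params@delta)
  kr <- .pairKernel(x, sqrt(a$epsilon[i] * a$epsilon[j]),
                    a$rminHalf[i] + a$rminHalf[j],
                    a$charge[i] * a$charge[j], params)
  unscaled <- sum(kr$e)
  if (abs(unscaled) < 1e-300) return(fragment@scale)
  sum(s[act] * kr$e) / unscaled
}

#' Force provider for the nonbonded interaction
#'
#' @inheritParams pairEnergy
#' @return a function `f(positions, step)` returning
#'   `list(energy=, forces=)`
#' @export
makeNonbondedProvider <- function(system, model, params) {
  force(system); force(model); force(params)
  function(positions, step = 0L) {
    res <- .nonbondedEval(system, positions, model, params)
    list(energy = res$energy, forces = res$forces,
         components = res$components)
  }
}
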