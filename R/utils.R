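## Shared constructors and measurement helpers.

.atomCols <- c("serial", "name", "element", "resid", "resname", "chain",
               "segid", "charge", "epsilon", "rminHalf", "mass",
               "fragmentId")

.emptyAtoms <- function() {
  data.frame(serial = integer(0), name = character(0),
             element = character(0), resid = integer(0),
             resname = character(0), chain = character(0),
             segid = character(0), charge = numeric(0),
             epsilon = numeric(0), rminHalf = numeric(0),
             mass = numeric(0), fragmentId = integer(0),
             stringsAsFactors = FALSE)
}

## Build atom rows, filling mass/LJ from the element table.
.atomRows <- function(serial, name, element, resid, resname, chain,
                      segid = "", charge = 0, fragmentId = 0L) {
  n <- length(name)
  props <- .elementProps(element)
  data.frame(serial = as.integer(serial), name = name, element = element,
             resid = as.integer(resid), resname = resname,
             chain = rep_len(chain, n), segid = rep_len(segid, n),
             charge = rep_len(charge, n),
             epsilon = props$epsilon, rminHalf = props$rminHalf,
             mass = props$mass,
             fragmentId = rep_len(as.integer(fragmentId), n),
             stringsAsFactors = FALSE)
}

.makeSystem <- function(atoms = .emptyAtoms(),
                        positions = matrix(numeric(0), ncol = 3L),
                        bonds = NULL, angles = NULL, dihedrals = NULL) {
  proto <- new("AtomicSystem")
  if (is.null(bonds)) bonds <- proto@bonds
  if (is.null(angles)) angles <- proto@angles
  if (is.null(dihedrals)) dihedrals <- proto@dihedrals
  new("AtomicSystem", atoms = atoms,
      positions = matrix(as.numeric(positions), ncol = 3L),
      bonds = bonds, angles = angles, dihedrals = dihedrals)
}

## Index of an atom by residue and atom name (chain optional).
.atomIndex <- function(system, resid, name, chain = NULL,
                       fragmentId = NULL) {
  a <- system@atoms
  sel <- a$resid == resid & a$name == name
  if (!is.null(chain)) sel <- sel & a$chain == chain
  if (!is.null(fragmentId)) sel <- sel & a$fragmentId == fragmentId
  which(sel)
}

#' Geometric measurements on a coordinate matrix
#'
#' Convenience helpers for distances (Angstrom), bond angles and
#' dihedral angles (degrees) between atom rows of a coordinate matrix or
#' [AtomicSystem].
#'
#' @param x an [AtomicSystem] or an n x 3 coordinate matrix
#' @param i,j,k,l atom indices
#' @return numeric scalar
#' @examples
#' p <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
#' measureDistance(p, 1, 2)
#' measureAngle(p, 1, 2, 3)
#' @export
measureDistance <- function(x, i, j) {
  p <- if (is(x, "AtomicSystem")) x@positions else x
  .norm3(p[i, ] - p[j, ])
}

#' @rdname measureDistance
#' @export
measureAngle <- function(x, i, j, k) {
  p <- if (is(x, "AtomicSystem")) x@positions else x
  .angleValue(p[i, ], p[j, ], p[k, ]) * 180 / pi
}

#' @rdname measureDistance
#' @export
measureDihedral <- function(x, i, j, k, l) {
  p <- if (is(x, "AtomicSystem")) x@positions else x
  .dihedralValue(p[i, ], p[j, ], p[k, ], p[l, ]) * 180 / pi
}

#' Finite-difference audit of a force provider
#'
#' Compares the analytic forces returned by a force provider against
#' central finite differences of its energy and returns the worst
#' relative deviation.  A force provider is a function
#' `f(positions, step)` returning `list(energy=, forces=)` with forces
#' the exact negative gradient of the energy.
#'
#' @param provider force provider function
#' @param positions n x 3 coordinate matrix
#' @param step integer step passed through to the provider
#' @param h finite-difference displacement (Angstrom)
#' @param atoms optional subset of atom indices to probe
#' @return list with `maxAbsErr`, `maxRelErr` (relative to the force
#'   scale) and the probed `forceScale`
#' @export
checkGradients <- function(provider, positions, step = 0L, h = 1e-5,
                           atoms = NULL) {
  if (is.null(atoms)) atoms <- seq_len(nrow(positions))
  res <- provider(positions, step)
  fAna <- res$forces
  maxAbs <- 0
  scale <- max(abs(fAna), 1e-8)
  for (ia in atoms) {
    for (d in 1:3) {
      pp <- positions; pp[ia, d] <- pp[ia, d] + h
      pm <- positions; pm[ia, d] <- pm[ia, d] - h
      fNum <- -(provider(pp, step)$energy - provider(pm, step)$energy) /
        (2 * h)
      maxAbs <- max(maxAbs, abs(fNum - fAna[ia, d]))
    }
  }
  list(maxAbsErr = maxAbs, maxRelErr = maxAbs / scale,
       forceScale = scale)
}

## Deterministic sub-seed derivation (kept below 2^31).
.subSeed <- function(seed, tag) {
  (as.integer(seed) * 69069L + as.integer(tag) * 101L) %% 2147483111L
}
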