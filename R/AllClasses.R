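#' @import methods
NULL

## Central S4 containers.  All coordinates are in Angstrom, energies in
## kcal/mol, charges in elementary charges, angles in degrees at the user
## surface (converted to radians internally), masses in amu.

#' Atomic system with a minimal internal force field
#'
#' `AtomicSystem` holds atoms (identity, position, charge, Lennard-Jones
#' parameters), a per-atom fragment id (0 = host protein, >0 = the
#' exclusion group of a molecular fragment), and the bonded terms of a
#' deliberately simple internal force field: harmonic bonds
#' \eqn{k_b (b-b_0)^2}, harmonic angles \eqn{k_\theta(\theta-\theta_0)^2}
#' and cosine dihedrals \eqn{k_\chi(1+\cos(n\chi-\delta))}.
#'
#' The refinement method implemented by this package is a restraint and
#' exclusion layer on top of whatever force field describes the system;
#' the internal force field is intentionally minimal so that every
#' mechanism can be exercised at desk scale.
#'
#' @slot atoms data.frame with columns `serial`, `name`, `element`,
#'   `resid` (1-based residue index), `resname`, `chain`, `segid`,
#'   `charge`, `epsilon` (kcal/mol), `rminHalf` (Angstrom), `mass` (amu)
#'   and `fragmentId` (integer, 0 for host atoms).
#' @slot positions numeric matrix, one row per atom, columns x/y/z in
#'   Angstrom.
#' @slot bonds data.frame `i`, `j`, `k`, `b0`.
#' @slot angles data.frame `i`, `j`, `k_`, `ktheta`, `theta0` (degrees).
#' @slot dihedrals data.frame `i`, `j`, `k_`, `l`, `kchi`, `mult`,
#'   `delta` (degrees).
#'
#' @examples
#' sys <- makeHelixBundle()$system
#' sys
#' nAtoms(sys)
#' @export
setClass("AtomicSystem",
  representation(
    atoms = "data.frame",
    positions = "matrix",
    bonds = "data.frame",
    angles = "data.frame",
    dihedrals = "data.frame"
  ),
  prototype(
    atoms = data.frame(),
    positions = matrix(numeric(0), ncol = 3L),
    bonds = data.frame(i = integer(0), j = integer(0),
                       k = numeric(0), b0 = numeric(0)),
    angles = data.frame(i = integer(0), j = integer(0), k_ = integer(0),
                        ktheta = numeric(0), theta0 = numeric(0)),
    dihedrals = data.frame(i = integer(0), j = integer(0), k_ = integer(0),
                           l = integer(0), kchi = numeric(0),
                           mult = integer(0), delta = numeric(0))
  )
)

setValidity("AtomicSystem", function(object) {
  a <- object@atoms
  n <- nrow(a)
  msgs <- character(0)
  if (nrow(object@positions) != n)
    msgs <- c(msgs, "positions and atoms disagree in length")
  if (ncol(object@positions) != 3L)
    msgs <- c(msgs, "positions must have 3 columns")
  if (n > 0L) {
    if (anyDuplicated(a$serial))
      msgs <- c(msgs, "atom serials must be unique")
    if (!all(is.finite(object@positions)))
      msgs <- c(msgs, "positions must be finite")
  }
  checkTerm <- function(df, cols, what) {
    if (nrow(df) == 0L) return(NULL)
    idx <- as.matrix(df[, cols, drop = FALSE])
    if (any(idx < 1L) || any(idx > n))
      return(sprintf("%s index out of range", what))
    fid <- matrix(a$fragmentId[idx], nrow = nrow(idx))
    if (any(apply(fid, 1L, function(x) length(unique(x)) > 1L)))
      return(sprintf("%s term spans host and fragment atoms", what))
    NULL
  }
  msgs <- c(msgs,
            checkTerm(object@bonds, c("i", "j"), "bond"),
            checkTerm(object@angles, c("i", "j", "k_"), "angle"),
            checkTerm(object@dihedrals, c("i", "j", "k_", "l"), "dihedral"))
  if (length(msgs)) msgs else TRUE
})

#' Molecular fragment anchored to a host protein
#'
#' A molecular fragment is an atomically detailed sub-molecule (a pair of
#' mutated bridge residues plus a bridging ion, or one copy of a
#' spin-label) overlaid on the host: its backbone atoms (N, C, O, C-alpha
#' of each patched residue) sit on top of the host backbone via harmonic
#' anchor restraints, and it is excluded from interacting with other
#' fragments.
#'
#' @slot atomIndices integer, atom rows of the fragment in its
#'   [AtomicSystem].
#' @slot anchorPairs integer matrix with columns `frag`, `host`: one row
#'   per anchored backbone atom (4 per patched residue).
#' @slot exclusionGroup positive integer exclusion group id.
#' @slot scale interaction scale against the environment, `1/nCopies`
#'   for copy-expanded labels, 1 for single bridges.
#' @slot bridgingIon atom index of the bridging ion, or `NA`.
#' @slot probeAtom atom index of the distance probe (nitroxide oxygen for
#'   MTSSL, the pseudo-atom for dummy labels), or `NA`.
#' @slot sites host residue indices the fragment is attached to.
#' @slot kind fragment kind string.
#' @export
setClass("MolecularFragment",
  representation(
    atomIndices = "integer",
    anchorPairs = "matrix",
    exclusionGroup = "integer",
    scale = "numeric",
    bridgingIon = "integer",
    probeAtom = "integer",
    sites = "integer",
    kind = "character"
  )
)

setValidity("MolecularFragment", function(object) {
  msgs <- character(0)
  if (length(object@scale) != 1L || object@scale <= 0 || object@scale > 1)
    msgs <- c(msgs, "scale must lie in (0, 1]")
  if (nrow(object@anchorPairs) %% 4L != 0L)
    msgs <- c(msgs, "anchorPairs must hold 4 rows (N, C, O, CA) per patched residue")
  if (!is.na(object@bridgingIon) &&
      !(object@bridgingIon %in% object@atomIndices))
    msgs <- c(msgs, "bridging ion must belong to the fragment's atom set")
  if (length(object@exclusionGroup) != 1L || object@exclusionGroup < 1L)
    msgs <- c(msgs, "exclusionGroup must be a positive integer")
  if (length(msgs)) msgs else TRUE
})

#' Ensemble of spin-label copies at one site
#'
#' Multiple-copy representation of a spin-label: `nCopies` fragments of
#' identical composition attached to the same host residue, each scaled
#' by `1/nCopies` against its environment.  The per-copy probe atoms are
#' the atoms whose pair distances enter the restrained-ensemble
#' histograms.
#'
#' @slot site host residue index.
#' @slot copies list of [MolecularFragment] of equal composition.
#' @slot probeAtoms integer, one probe atom index per copy.
#' @slot kind `"mtssl_label"` or `"dummy_label"`.
#' @export
setClass("CopyEnsemble",
  representation(
    site = "integer",
    copies = "list",
    probeAtoms = "integer",
    kind = "character"
  )
)

setValidity("CopyEnsemble", function(object) {
  msgs <- character(0)
  if (length(object@copies) < 1L)
    msgs <- c(msgs, "ensemble needs at least one copy")
  if (length(object@probeAtoms) != length(object@copies))
    msgs <- c(msgs, "one probe atom per copy required")
  if (length(object@copies) > 1L) {
    nAt <- vapply(object@copies, function(f) length(f@atomIndices), 1L)
    if (length(unique(nAt)) != 1L)
      msgs <- c(msgs, "all copies must share composition")
  }
  if (length(msgs)) msgs else TRUE
})

#' Soft-core nonbonded parameters
#'
#' `delta` (Angstrom^2) is the soft-core offset of the effective distance
#' \eqn{r' = \sqrt{r^2 + \Delta}} applied to pairs that involve a
#' fragment atom, bounding their interaction at atomic overlap.  The
#' Lennard-Jones and Coulomb terms are smoothly switched off between
#' `switchOn` and `cutoff`.
#'
#' @slot delta soft-core offset, Angstrom^2 (>= 0).
#' @slot switchOn switching start, Angstrom (default 10).
#' @slot cutoff truncation distance, Angstrom (default 12).
#' @slot dielectric relative dielectric constant (default 1).
#' @export
setClass("SoftCoreParams",
  representation(delta = "numeric", switchOn = "numeric",
                 cutoff = "numeric", dielectric = "numeric"),
  prototype(delta = 1, switchOn = 10, cutoff = 12, dielectric = 1)
)

setValidity("SoftCoreParams", function(object) {
  msgs <- character(0)
  if (object@delta < 0) msgs <- c(msgs, "delta must be >= 0")
  if (!(object@switchOn >= 0 && object@switchOn < object@cutoff))
    msgs <- c(msgs, "need 0 <= switchOn < cutoff")
  if (object@dielectric <= 0) msgs <- c(msgs, "dielectric must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' Normalized distance histogram on a regular bin grid
#'
#' Bin `n` (n = 1..nBins) is centred at `n * binWidth` Angstrom and
#' carries a density value in 1/Angstrom.  A valid table satisfies
#' \eqn{\sum_n h(n)\,\Delta r = 1}.
#'
#' @slot values numeric densities, one per bin (1/Angstrom, >= 0).
#' @slot binWidth bin width Delta-r in Angstrom.
#' @export
setClass("HistogramTable",
  representation(values = "numeric", binWidth = "numeric")
)

setValidity("HistogramTable", function(object) {
  msgs <- character(0)
  if (length(object@binWidth) != 1L || object@binWidth <= 0)
    msgs <- c(msgs, "binWidth must be a positive scalar")
  if (any(object@values < 0)) msgs <- c(msgs, "values must be >= 0")
  s <- sum(object@values) * object@binWidth
  if (abs(s - 1) > 1e-10)
    msgs <- c(msgs, sprintf("histogram not normalized: sum(value)*dr = %.12g", s))
  if (length(msgs)) msgs else TRUE
})

#' Restrained-ensemble histogram restraint for one site pair
#'
#' Couples the Gaussian-smoothed ensemble histogram of the N x N probe
#' distances between the label copies at two sites to a target
#' distribution `target` through the energy
#' \eqn{U = (K/2) \sum_n (\bar h(n) - H(n))^2}.
#'
#' @slot sitePair integer of length 2, the host residue indices.
#' @slot probesI,probesJ atom indices of the probe atoms of the copies at
#'   each site.
#' @slot target [HistogramTable] target distribution.
#' @slot K force constant, kcal/mol/Angstrom^2 (default 500).
#' @slot sigma Gaussian smoothing width, Angstrom (default 1.1).
#' @export
setClass("HistogramRestraint",
  representation(sitePair = "integer", probesI = "integer",
                 probesJ = "integer", target = "HistogramTable",
                 K = "numeric", sigma = "numeric"),
  prototype(K = 500, sigma = 1.1)
)

setValidity("HistogramRestraint", function(object) {
  msgs <- character(0)
  if (object@K <= 0) msgs <- c(msgs, "K must be > 0")
  if (object@sigma <= 0) msgs <- c(msgs, "sigma must be > 0")
  if (length(object@probesI) < 1L || length(object@probesJ) < 1L)
    msgs <- c(msgs, "both sites need at least one probe atom")
  if (length(object@sitePair) == 2L &&
      object@sitePair[1L] == object@sitePair[2L])
    msgs <- c(msgs, "self-pairs (i == j) are undefined")
  if (length(msgs)) msgs else TRUE
})

#' Set of harmonic restraint terms
#'
#' Wraps a data.frame of restraint terms of kinds `bond`, `angle`,
#' `dihedral`, `improper` and `anchor`, each evaluated as
#' \eqn{E = k_\mathrm{eff}(x - x_0)^2} with
#' \eqn{k_\mathrm{eff} = k \cdot \mathrm{ramp}(step)}.  The harmonic
#' convention carries no factor 1/2, matching the extra-bond convention
#' of common MD engines under which the tabulated bridge force constants
#' are defined.
#'
#' @slot terms data.frame with columns `kind`, `i`, `j`, `k_`, `l`
#'   (unused indices NA), `kconst`, `x0` (Angstrom for bond/anchor,
#'   degrees for angular kinds) and `rampId` (NA for unscheduled terms).
#' @export
setClass("RestraintSet", representation(terms = "data.frame"))

setValidity("RestraintSet", function(object) {
  t <- object@terms
  need <- c("kind", "i", "j", "k_", "l", "kconst", "x0", "rampId")
  if (!all(need %in% names(t)))
    return(sprintf("terms must have columns %s", paste(need, collapse = ", ")))
  if (nrow(t) == 0L) return(TRUE)
  msgs <- character(0)
  if (!all(t$kind %in% c("bond", "angle", "dihedral", "improper", "anchor")))
    msgs <- c(msgs, "unknown restraint kind")
  if (any(t$kconst <= 0)) msgs <- c(msgs, "force constants must be > 0")
  ang <- t$kind %in% c("angle", "dihedral", "improper")
  if (any(ang & (t$x0 < 0 | t$x0 >= 360)))
    msgs <- c(msgs, "angular equilibrium values must lie in [0, 360)")
  needs4 <- t$kind %in% c("dihedral", "improper")
  if (any(needs4 & (is.na(t$k_) | is.na(t$l))) ||
      any(t$kind == "angle" & is.na(t$k_)))
    msgs <- c(msgs, "term arity does not match kind")
  if (length(msgs)) msgs else TRUE
})

#' Piecewise-linear force-constant ramp schedule
#'
#' Restraint force constants are turned on (or off) gradually over the
#' course of a protocol stage to let the structure adjust smoothly.  The
#' scale at integer `step` is interpolated linearly inside each stage;
#' before the first stage it equals the first `scaleStart`, after the
#' last it holds the last `scaleEnd`.
#'
#' @slot stages data.frame `startStep`, `endStep`, `scaleStart`,
#'   `scaleEnd`, ordered, scales >= 0.
#' @export
setClass("RampSchedule", representation(stages = "data.frame"))

setValidity("RampSchedule", function(object) {
  s <- object@stages
  need <- c("startStep", "endStep", "scaleStart", "scaleEnd")
  if (!all(need %in% names(s)))
    return("stages needs startStep, endStep, scaleStart, scaleEnd")
  if (nrow(s) == 0L) return("at least one stage required")
  msgs <- character(0)
  if (any(s$endStep < s$startStep)) msgs <- c(msgs, "endStep < startStep")
  if (nrow(s) > 1L && any(diff(s$startStep) < 0))
    msgs <- c(msgs, "stages must be ordered by startStep")
  if (any(s$scaleStart < 0) || any(s$scaleEnd < 0))
    msgs <- c(msgs, "scales must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Simulation state
#'
#' @slot positions numeric n x 3 matrix, Angstrom.
#' @slot velocities numeric n x 3 matrix, Angstrom per AKMA time unit.
#' @slot step integer step counter.
#' @export
setClass("SimulationState",
  representation(positions = "matrix", velocities = "matrix",
                 step = "integer")
)

setValidity("SimulationState", function(object) {
  if (!all(is.finite(object@positions)) || !all(is.finite(object@velocities)))
    return("state must be finite")
  if (!identical(dim(object@positions), dim(object@velocities)))
    return("positions and velocities must share dimensions")
  TRUE
})
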