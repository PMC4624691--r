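#' Ramp schedule constructor and evaluation
#'
#' `rampSchedule` builds a piecewise-linear force-constant schedule;
#' `ramp` evaluates its scale at an integer step.  Between stages the
#' scale holds the previous stage's end value; before the first stage it
#' is the first `scaleStart`, after the last stage the last `scaleEnd`.
#'
#' @param startStep,endStep integer stage boundaries (inclusive)
#' @param scaleStart,scaleEnd scales at the stage boundaries (>= 0)
#' @return `rampSchedule`: a [RampSchedule]; `ramp`: numeric scale
#' @examples
#' rs <- rampSchedule(0, 100, 0, 1)
#' ramp(rs, 50)    # 0.5
#' ramp(rs, 1000)  # 1
#' @export
rampSchedule <- function(startStep, endStep, scaleStart, scaleEnd) {
  new("RampSchedule", stages = data.frame(
    startStep = as.integer(startStep), endStep = as.integer(endStep),
    scaleStart = scaleStart, scaleEnd = scaleEnd))
}

#' @rdname rampSchedule
#' @param schedule a [RampSchedule]
#' @param step integer step (>= 0)
#' @export
ramp <- function(schedule, step) {
  s <- schedule@stages
  vapply(step, function(st) {
    if (st <= s$startStep[1L]) return(s$scaleStart[1L])
    last <- nrow(s)
    if (st >= s$endStep[last]) return(s$scaleEnd[last])
    for (r in seq_len(last)) {
      if (st >= s$startStep[r] && st <= s$endStep[r]) {
        span <- s$endStep[r] - s$startStep[r]
        f <- if (span == 0L) 1 else (st - s$startStep[r]) / span
        return(s$scaleStart[r] + f * (s$scaleEnd[r] - s$scaleStart[r]))
      }
      if (r < last && st > s$endStep[r] && st < s$startStep[r + 1L])
        return(s$scaleEnd[r])
    }
    s$scaleEnd[last]
  }, numeric(1L))
}

.restraintRow <- function(kind, i, j, k_ = NA_integer_, l = NA_integer_,
                          kconst, x0, rampId = NA_character_) {
  data.frame(kind = kind, i = as.integer(i), j = as.integer(j),
             k_ = as.integer(k_), l = as.integer(l), kconst = kconst,
             x0 = x0, rampId = rampId, stringsAsFactors = FALSE)
}

#' Combine restraint sets
#' @param ... [RestraintSet] objects
#' @return a single [RestraintSet]
#' @export
combineRestraints <- function(...) {
  sets <- list(...)
  new("RestraintSet",
      terms = do.call(rbind, lapply(sets, function(s) s@terms)))
}

.fragAtomByName <- function(system, fragment, site, name) {
  a <- system@atoms
  idx <- fragment@atomIndices[a$resid[fragment@atomIndices] == site &
                                a$name[fragment@atomIndices] == name]
  if (length(idx) != 1L)
    stop("atom ", name, " not found in fragment at site ", site)
  idx
}

#' Harmonic restraint terms for a metal-ion or salt bridge
#'
#' Instantiates the bridge restraint parameter set for a fragment built
#' by [buildBridgeFragment]:
#' * Cd bridge: two S-gamma--Cd bond terms (k = 10 kcal/mol/A^2,
#'   b0 = 2.6 A) and one S-gamma--Cd--S-gamma angle
#'   (k = 10 kcal/mol/rad^2, 180 deg);
#' * Mg bridge: two O-delta2--Mg bonds (k = 10, b0 = 2.1 A) and the
#'   O-delta2--Mg--O-delta2 angle (k = 10, 180 deg);
#' * Zn bridge: two N-epsilon--Zn bonds (k = 10, b0 = 2.1 A), the
#'   C-epsilon1--N-epsilon--Zn (127.0 deg) and
#'   C-delta2--N-epsilon--Zn (125.5 deg) angles, the
#'   C-gamma--C-delta2--N-epsilon--Zn dihedral (180 deg) and both
#'   improper torsions (0 deg), all k = 10 -- the orientation terms keep
#'   the ion in the imidazole plane;
#' * salt bridge: one N-zeta--O-epsilon2 bond restraint at 3.5 A.
#'
#' All terms use the harmonic convention \eqn{E = k (x - x_0)^2}.
#'
#' @param kind bridge kind string (must match the fragment)
#' @param fragment a [MolecularFragment] from [buildBridgeFragment]
#' @param system the [AtomicSystem] holding the fragment
#' @param saltK force constant of the salt-bridge restraint,
#'   kcal/mol/Angstrom^2 (default 10, matching the metal-bridge terms)
#' @param rampId optional ramp schedule id applied to every term
#' @return a [RestraintSet]
#' @export
metalBridgeRestraints <- function(kind, fragment, system, saltK = 10,
                                  rampId = NA_character_) {
  if (!identical(kind, fragment@kind))
    stop("fragment was built as ", fragment@kind, ", not ", kind)
  s1 <- fragment@sites[1L]
  s2 <- fragment@sites[2L]
  ion <- fragment@bridgingIon
  at <- function(site, name) .fragAtomByName(system, fragment, site, name)
  terms <- switch(kind,
    cd_bridge = rbind(
      .restraintRow("bond", at(s1, "SG"), ion, kconst = 10, x0 = 2.6,
                    rampId = rampId),
      .restraintRow("bond", at(s2, "SG"), ion, kconst = 10, x0 = 2.6,
                    rampId = rampId),
      .restraintRow("angle", at(s1, "SG"), ion, at(s2, "SG"),
                    kconst = 10, x0 = 180, rampId = rampId)),
    mg_bridge = rbind(
      .restraintRow("bond", at(s1, "OD2"), ion, kconst = 10, x0 = 2.1,
                    rampId = rampId),
      .restraintRow("bond", at(s2, "OD2"), ion, kconst = 10, x0 = 2.1,
                    rampId = rampId),
      .restraintRow("angle", at(s1, "OD2"), ion, at(s2, "OD2"),
                    kconst = 10, x0 = 180, rampId = rampId)),
    zn_bridge = rbind(
      .restraintRow("bond", at(s1, "NE2"), ion, kconst = 10, x0 = 2.1,
                    rampId = rampId),
      .restraintRow("bond", at(s2, "NE2"), ion, kconst = 10, x0 = 2.1,
                    rampId = rampId),
      .restraintRow("angle", at(s1, "CE1"), at(s1, "NE2"), ion,
                    kconst = 10, x0 = 127.0, rampId = rampId),
      .restraintRow("angle", at(s1, "CD2"), at(s1, "NE2"), ion,
                    kconst = 10, x0 = 125.5, rampId = rampId),
      .restraintRow("dihedral", at(s1, "CG"), at(s1, "CD2"),
                    at(s1, "NE2"), ion, kconst = 10, x0 = 180,
                    rampId = rampId),
      .restraintRow("improper", at(s1, "NE2"), at(s1, "CD2"),
                    at(s1, "CE1"), ion, kconst = 10, x0 = 0,
                    rampId = rampId),
      .restraintRow("improper", at(s1, "NE2"), at(s1, "CE1"),
                    at(s1, "CD2"), ion, kconst = 10, x0 = 0,
                    rampId = rampId)),
    salt_bridge = .restraintRow("bond", at(s1, "NZ"), at(s2, "OE2"),
                                kconst = saltK, x0 = 3.5,
                                rampId = rampId),
    stop("unknown bridge kind: ", kind))
  new("RestraintSet", terms = terms)
}

#' Backbone phi/psi restraints for helical spans
#'
#' Harmonic dihedral restraints holding the backbone of the given
#' residue spans at canonical alpha-helical torsions
#' (phi, psi) = (-57, -47) degrees.  Used during early refinement stages
#' to avoid large distortions; the force constant is typically ramped
#' down.
#'
#' @param system an [AtomicSystem]
#' @param helixRanges list of integer residue-index vectors, each a
#'   helical span of at least 4 residues
#' @param k force constant, kcal/mol/rad^2
#' @param rampId optional ramp schedule id
#' @return a [RestraintSet] of dihedral terms
#' @export
secondaryStructureRestraints <- function(system, helixRanges, k = 10,
                                         rampId = NA_character_) {
  if (!length(helixRanges))
    return(new("RestraintSet", terms = .restraintRow(
      "bond", 1L, 1L, kconst = 1, x0 = 0)[0, ]))
  terms <- NULL
  for (span in helixRanges) {
    if (length(span) < 4L)
      stop("helical spans must contain at least 4 residues")
    bb <- function(res, name) {
      i <- .atomIndex(system, res, name, fragmentId = 0L)
      if (length(i) != 1L)
        stop("residue ", res, " in helix span lacks backbone atom ", name)
      i
    }
    for (res in span) {
      for (nm in .backboneNames) bb(res, nm)  # full backbone required
      if ((res - 1L) %in% span)               # phi needs C(i-1)
        terms <- rbind(terms, .restraintRow(
          "dihedral", bb(res - 1L, "C"), bb(res, "N"), bb(res, "CA"),
          bb(res, "C"), kconst = k, x0 = 303, rampId = rampId))
      if ((res + 1L) %in% span)               # psi needs N(i+1)
        terms <- rbind(terms, .restraintRow(
          "dihedral", bb(res, "N"), bb(res, "CA"), bb(res, "C"),
          bb(res + 1L, "N"), kconst = k, x0 = 313, rampId = rampId))
    }
  }
  new("RestraintSet", terms = terms)
}

#' Evaluate restraint energy and forces
#'
#' Every term contributes \eqn{E = k_\mathrm{eff} (x - x_0)^2} with
#' \eqn{k_\mathrm{eff} = k \cdot \mathrm{ramp}(step)}; `x` is a distance
#' (bond/anchor terms) or an angle in radians (angle, dihedral, improper
#' terms, with the deviation taken as the minimal periodic difference).
#' Forces are the exact gradients; angle terms near the colinear
#' singularity use a guarded force coefficient (the analytic limit of
#' \eqn{(\theta-\theta_0)/\sin\theta} is finite for the
#' \eqn{\theta_0 = 180^\circ} terms that operate there by design).
#'
#' @param restraints a [RestraintSet]
#' @param positions n x 3 coordinate matrix
#' @param step integer step for ramp evaluation
#' @param schedules named list of [RampSchedule] referenced by term
#'   `rampId`
#' @return list with `energy` and `forces` (n x 3)
#' @export
restraintEnergyForces <- function(restraints, positions, step = 0L,
                                  schedules = list()) {
  t <- restraints@terms
  n <- nrow(positions)
  forces <- matrix(0, n, 3L)
  energy <- 0
  if (nrow(t) == 0L) return(list(energy = 0, forces = forces))
  keff <- t$kconst
  if (!all(is.na(t$rampId))) {
    for (id in unique(stats::na.omit(t$rampId))) {
      sch <- schedules[[id]]
      if (is.null(sch)) stop("undefined ramp schedule: ", id)
      keff[!is.na(t$rampId) & t$rampId == id] <-
        keff[!is.na(t$rampId) & t$rampId == id] * ramp(sch, step)
    }
  }
  sel <- t$kind %in% c("bond", "anchor") & keff > 0
  if (any(sel)) {
    i <- t$i[sel]; j <- t$j[sel]
    dx <- positions[i, , drop = FALSE] - positions[j, , drop = FALSE]
    d <- .rowNorm(dx)
    dev <- d - t$x0[sel]
    energy <- energy + sum(keff[sel] * dev * dev)
    ## E = k (|r| - b0)^2 has a removable singularity at r = 0 when
    ## b0 = 0 (E = k |r|^2 is smooth there)
    coef <- ifelse(d < 1e-12,
                   ifelse(t$x0[sel] == 0, 2 * keff[sel], 0),
                   2 * keff[sel] * dev / d)
    g <- coef * dx
    forces <- .accumForces(forces, i, -g)
    forces <- .accumForces(forces, j, g)
  }
  sel <- t$kind == "angle" & keff > 0
  if (any(sel)) {
    ag <- .angleGradBatch(positions, t$i[sel], t$j[sel], t$k_[sel])
    dev <- .wrapAngle(ag$theta - t$x0[sel] * pi / 180)
    energy <- energy + sum(keff[sel] * dev * dev)
    coef <- 2 * keff[sel] * dev
    forces <- .accumForces(forces, t$i[sel], -coef * ag$gi)
    forces <- .accumForces(forces, t$j[sel], -coef * ag$gj)
    forces <- .accumForces(forces, t$k_[sel], -coef * ag$gk)
  }
  sel <- t$kind %in% c("dihedral", "improper") & keff > 0
  if (any(sel)) {
    dg <- .dihedralGradBatch(positions, t$i[sel], t$j[sel], t$k_[sel],
                             t$l[sel])
    dev <- .wrapAngle(dg$phi - t$x0[sel] * pi / 180)
    energy <- energy + sum(keff[sel] * dev * dev)
    coef <- 2 * keff[sel] * dev
    forces <- .accumForces(forces, t$i[sel], -coef * dg$gi)
    forces <- .accumForces(forces, t$j[sel], -coef * dg$gj)
    forces <- .accumForces(forces, t$k_[sel], -coef * dg$gk)
    forces <- .accumForces(forces, t$l[sel], -coef * dg$gl)
  }
  list(energy = energy, forces = forces)
}

#' Force provider for a restraint set
#'
#' @inheritParams restraintEnergyForces
#' @return a provider function `f(positions, step)`
#' @export
makeRestraintProvider <- function(restraints, schedules = list()) {
  force(restraints); force(schedules)
  function(positions, step = 0L)
    restraintEnergyForces(restraints, positions, step, schedules)
}

#' Harmonic positional restraint provider
#'
#' \eqn{E = k \sum_i |r_i - r_i^0|^2} over the selected atoms; used to
#' hold the host backbone during restrained-ensemble runs
#' (k = 100 kcal/mol/A^2 in the reference protocol).
#'
#' @param indices atom indices to restrain
#' @param refPositions reference coordinates (full n x 3 matrix)
#' @param k force constant, kcal/mol/Angstrom^2
#' @return a provider function `f(positions, step)`
#' @export
makePositionalRestraintProvider <- function(indices, refPositions, k) {
  force(indices); force(refPositions); force(k)
  function(positions, step = 0L) {
    d <- positions[indices, , drop = FALSE] -
      refPositions[indices, , drop = FALSE]
    forces <- matrix(0, nrow(positions), 3L)
    forces[indices, ] <- -2 * k * d
    list(energy = k * sum(d * d), forces = forces)
  }
}
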