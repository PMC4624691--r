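## AKMA-style units: lengths in Angstrom, energies in kcal/mol, masses
## in amu; the internal time unit is 48.88821 fs, chosen so that
## acceleration = force/mass without conversion factors.
.kBoltz <- 0.0019872041       # kcal/mol/K
.fsPerAkma <- 48.88821

#' Create a simulation state
#'
#' @param positions n x 3 coordinate matrix, Angstrom
#' @param velocities optional n x 3 velocity matrix (default zero)
#' @param step initial step counter
#' @return a [SimulationState]
#' @export
simulationState <- function(positions, velocities = NULL, step = 0L) {
  if (is.null(velocities))
    velocities <- matrix(0, nrow(positions), 3L)
  new("SimulationState", positions = positions,
      velocities = velocities, step = as.integer(step))
}

#' Maxwell-Boltzmann velocity initialization
#'
#' @param masses per-atom masses, amu
#' @param temperature kelvin
#' @return n x 3 velocity matrix (internal units)
#' @export
initVelocities <- function(masses, temperature) {
  n <- length(masses)
  sd <- sqrt(.kBoltz * temperature / masses)
  matrix(stats::rnorm(3L * n, sd = rep(sd, 3L)), n, 3L)
}

## Evaluate a (named) list of force providers; NaN/Inf energies or
## forces abort with a diagnostic naming the offending provider.
.evalProviders <- function(providers, positions, step = 0L) {
  energy <- 0
  forces <- matrix(0, nrow(positions), 3L)
  nms <- names(providers)
  for (p in seq_along(providers)) {
    res <- providers[[p]](positions, step)
    if (!is.finite(res$energy) || !all(is.finite(res$forces)))
      stop("non-finite energy/forces from force provider ",
           if (!is.null(nms) && nzchar(nms[p])) nms[p] else p)
    energy <- energy + res$energy
    forces <- forces + res$forces
  }
  list(energy = energy, forces = forces)
}

#' Force provider for the internal bonded force field
#'
#' Harmonic bonds \eqn{k(b-b_0)^2}, harmonic angles
#' \eqn{k(\theta-\theta_0)^2} and cosine dihedrals
#' \eqn{k(1+\cos(n\chi-\delta))} of an [AtomicSystem].
#'
#' @param system an [AtomicSystem]
#' @return a provider function `f(positions, step)`
#' @export
makeBondedProvider <- function(system) {
  bonds <- system@bonds
  angles <- system@angles
  dihedrals <- system@dihedrals
  force(bonds); force(angles); force(dihedrals)
  function(positions, step = 0L) {
    energy <- 0
    forces <- matrix(0, nrow(positions), 3L)
    if (nrow(bonds)) {
      dx <- positions[bonds$i, , drop = FALSE] -
        positions[bonds$j, , drop = FALSE]
      d <- sqrt(rowSums(dx^2))
      dev <- d - bonds$b0
      energy <- energy + sum(bonds$k * dev * dev)
      coef <- 2 * bonds$k * dev / pmax(d, 1e-12)
      fv <- -coef * dx
      fI <- rowsum(fv, bonds$i)
      fJ <- rowsum(-fv, bonds$j)
      forces[as.integer(rownames(fI)), ] <-
        forces[as.integer(rownames(fI)), ] + fI
      forces[as.integer(rownames(fJ)), ] <-
        forces[as.integer(rownames(fJ)), ] + fJ
    }
    if (nrow(angles)) {
      ag <- .angleGradBatch(positions, angles$i, angles$j, angles$k_)
      dev <- ag$theta - angles$theta0 * pi / 180
      energy <- energy + sum(angles$ktheta * dev * dev)
      coef <- 2 * angles$ktheta * dev
      forces <- .accumForces(forces, angles$i, -coef * ag$gi)
      forces <- .accumForces(forces, angles$j, -coef * ag$gj)
      forces <- .accumForces(forces, angles$k_, -coef * ag$gk)
    }
    if (nrow(dihedrals)) {
      dg <- .dihedralGradBatch(positions, dihedrals$i, dihedrals$j,
                               dihedrals$k_, dihedrals$l)
      arg <- dihedrals$mult * dg$phi - dihedrals$delta * pi / 180
      energy <- energy + sum(dihedrals$kchi * (1 + cos(arg)))
      coef <- -dihedrals$kchi * dihedrals$mult * sin(arg)
      forces <- .accumForces(forces, dihedrals$i, -coef * dg$gi)
      forces <- .accumForces(forces, dihedrals$j, -coef * dg$gj)
      forces <- .accumForces(forces, dihedrals$k_, -coef * dg$gk)
      forces <- .accumForces(forces, dihedrals$l, -coef * dg$gl)
    }
    list(energy = energy, forces = forces)
  }
}

#' Energy minimization by monotone adaptive steepest descent
#'
#' Accepted steps never increase the energy: a trial step along the
#' force direction is accepted only if the energy does not rise,
#' otherwise the step size is halved and retried.  Terminates when the
#' maximum force component falls below `tol` or after `maxSteps`
#' accepted steps.
#'
#' @param state a [SimulationState] (velocities are zeroed on return)
#' @param providers named list of force providers
#' @param maxSteps maximum accepted steps
#' @param tol force tolerance, kcal/mol/Angstrom
#' @param step protocol step passed to providers (for ramps)
#' @return list with the final `state`, the accepted `energyTrace`,
#'   `converged` flag and final `maxForce`
#' @export
minimizeSystem <- function(state, providers, maxSteps = 5000L,
                           tol = 1e-6, step = 0L) {
  pos <- state@positions
  ev <- .evalProviders(providers, pos, step)
  trace <- ev$energy
  gamma <- 1e-3
  accepted <- 0L
  maxF <- max(abs(ev$forces))
  prevPos <- NULL
  prevF <- NULL
  while (accepted < maxSteps && maxF > tol) {
    ## Barzilai-Borwein step length when history is available (large,
    ## curvature-adapted steps); monotone safeguard below rejects any
    ## energy increase
    g <- gamma
    if (!is.null(prevPos)) {
      s <- pos - prevPos
      y <- prevF - ev$forces       # gradient difference
      sy <- sum(s * y)
      yy <- sum(y * y)
      if (is.finite(sy) && sy > 0 && yy > 0) g <- sy / yy
    }
    repeat {
      trial <- pos + g * ev$forces
      evT <- .evalProviders(providers, trial, step)
      if (evT$energy <= ev$energy) break
      g <- g * 0.5
      if (g < 1e-14) break
    }
    if (evT$energy > ev$energy) break  # stuck at numerical floor
    prevPos <- pos
    prevF <- ev$forces
    pos <- trial
    ev <- evT
    gamma <- g * 1.2
    accepted <- accepted + 1L
    trace <- c(trace, ev$energy)
    maxF <- max(abs(ev$forces))
  }
  out <- simulationState(pos, step = state@step)
  list(state = out, energyTrace = trace, converged = maxF <= tol,
       maxForce = maxF)
}

#' BAOAB Langevin dynamics
#'
#' `langevinStep` advances one BAOAB step (half kick, half drift,
#' Ornstein-Uhlenbeck velocity update, half drift, half kick);
#' `langevinRun` iterates it.  At zero temperature with no forces,
#' velocities decay by `exp(-friction * dt)` per step; with zero
#' friction and temperature the scheme reduces to velocity Verlet.
#' Trajectories are deterministic for a fixed RNG state (use
#' `set.seed()` before the call).
#'
#' @param state a [SimulationState]
#' @param providers named list of force providers
#' @param dt timestep, fs (default 1)
#' @param temperature kelvin
#' @param friction Langevin friction, 1/ps (default 5)
#' @param masses per-atom masses, amu
#' @param nSteps number of steps
#' @param recordEvery if > 0, call `recordFun` every so many steps
#' @param recordFun function(positions, step) invoked for recording
#' @return `langevinStep`: the advanced [SimulationState];
#'   `langevinRun`: list with the final `state` and a `records` list of
#'   `recordFun` return values
#' @export
langevinRun <- function(state, providers, nSteps, dt = 1,
                        temperature = 300, friction = 5, masses,
                        recordEvery = 0L, recordFun = NULL) {
  h <- dt / .fsPerAkma
  gam <- friction * .fsPerAkma * 1e-3 / 1   # 1/ps -> 1/AKMA
  a <- exp(-gam * h)
  n <- length(masses)
  bSd <- sqrt(.kBoltz * temperature * (1 - a * a) / masses)
  invm <- 1 / masses
  pos <- state@positions
  vel <- state@velocities
  stepNow <- state@step
  ev <- .evalProviders(providers, pos, stepNow)
  records <- list()
  for (s in seq_len(nSteps)) {
    vel <- vel + (h / 2) * ev$forces * invm
    pos <- pos + (h / 2) * vel
    if (temperature > 0 && gam > 0) {
      vel <- a * vel + bSd * matrix(stats::rnorm(3L * n), n, 3L)
    } else {
      vel <- a * vel
    }
    pos <- pos + (h / 2) * vel
    stepNow <- stepNow + 1L
    ev <- .evalProviders(providers, pos, stepNow)
    vel <- vel + (h / 2) * ev$forces * invm
    if (recordEvery > 0L && s %% recordEvery == 0L && !is.null(recordFun))
      records[[length(records) + 1L]] <- recordFun(pos, stepNow)
  }
  list(state = new("SimulationState", positions = pos, velocities = vel,
                   step = stepNow),
       records = records)
}

#' @rdname langevinRun
#' @export
langevinStep <- function(state, providers, dt = 1, temperature = 300,
                         friction = 5, masses) {
  langevinRun(state, providers, nSteps = 1L, dt = dt,
              temperature = temperature, friction = friction,
              masses = masses)$state
}
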