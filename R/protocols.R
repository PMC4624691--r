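#' Staged bridge-refinement protocol
#'
#' Executes an ordered list of stages (energy minimization or Langevin
#' dynamics) with the internal force field, the fragment-aware
#' nonbonded interaction and a restraint set whose force constants may
#' follow ramp schedules, then reports restraint satisfaction: bridge
#' bond distances (mean and standard deviation over the recorded tail
#' of the trajectory), bridge angle values, C-beta--C-beta distances of
#' bridge fragments, and the maximum anchor deviation.
#'
#' Each stage is a list with `mode` (`"minimize"` or `"dynamics"`),
#' `nSteps`, and for dynamics `temperature` (K), `dt` (fs) and
#' `friction` (1/ps).  Ramp schedules are evaluated against the global
#' step counter accumulated across stages.  A stage list referencing an
#' undefined ramp id is a configuration error detected before any
#' execution.
#'
#' @param system an [AtomicSystem] holding host and fragment atoms
#' @param fragments list of [MolecularFragment]
#' @param restraints a [RestraintSet] (bridge + anchor + secondary
#'   structure terms)
#' @param stages list of stage lists; empty list returns the input
#'   state unchanged
#' @param schedules named list of [RampSchedule]
#' @param params a [SoftCoreParams]
#' @param includeNonbonded evaluate the nonbonded interaction (default
#'   TRUE)
#' @param recordEvery record trajectory statistics every so many
#'   dynamics steps (default: nSteps/50, at least 1)
#' @param outPdb optional path: write the final structure as PDB
#' @param logFile optional path: write the per-record energy log as TSV
#' @return list with final `state`, updated `system`, `report`
#'   (data.frame of restraint satisfaction), `bridgeStats` (mean/sd of
#'   bridge distances over the recorded tail) and `energyLog`
#' @export
runRefinement <- function(system, fragments, restraints, stages,
                          schedules = list(),
                          params = softCoreParams(),
                          includeNonbonded = TRUE, recordEvery = NULL,
                          outPdb = NULL, logFile = NULL) {
  rampIds <- stats::na.omit(unique(restraints@terms$rampId))
  missing <- setdiff(rampIds, names(schedules))
  if (length(missing))
    stop("restraints reference undefined ramp schedule(s): ",
         paste(missing, collapse = ", "))

  model <- buildExclusionModel(system, fragments)
  providers <- list(bonded = makeBondedProvider(system),
                    restraints = makeRestraintProvider(restraints,
                                                       schedules))
  if (includeNonbonded)
    providers$nonbonded <- makeNonbondedProvider(system, model, params)
  masses <- system@atoms$mass

  state <- simulationState(system@positions)
  bondTerms <- restraints@terms[restraints@terms$kind == "bond", ,
                                drop = FALSE]
  energyLog <- NULL
  tailRecords <- list()
  recordFun <- function(pos, st) {
    d <- if (nrow(bondTerms))
      sqrt(rowSums((pos[bondTerms$i, , drop = FALSE] -
                      pos[bondTerms$j, , drop = FALSE])^2))
    else numeric(0)
    e <- .evalProviders(providers, pos, st)$energy
    list(step = st, energy = e, bridgeDists = d)
  }

  for (stage in stages) {
    mode <- stage$mode
    if (mode == "minimize") {
      res <- minimizeSystem(state, providers,
                            maxSteps = stage$nSteps,
                            tol = if (is.null(stage$tol)) 1e-4
                                  else stage$tol,
                            step = state@step)
      state <- res$state
      energyLog <- rbind(energyLog,
                         data.frame(step = state@step,
                                    energy = res$energyTrace[
                                      length(res$energyTrace)],
                                    stage = "minimize"))
    } else if (mode == "dynamics") {
      re <- if (is.null(recordEvery))
        max(1L, stage$nSteps %/% 50L) else recordEvery
      run <- langevinRun(state, providers, nSteps = stage$nSteps,
                         dt = if (is.null(stage$dt)) 1 else stage$dt,
                         temperature = stage$temperature,
                         friction = if (is.null(stage$friction)) 5
                                    else stage$friction,
                         masses = masses, recordEvery = re,
                         recordFun = recordFun)
      state <- run$state
      tailRecords <- run$records
      if (length(run$records))
        energyLog <- rbind(energyLog, data.frame(
          step = vapply(run$records, `[[`, 1, "step"),
          energy = vapply(run$records, `[[`, 1, "energy"),
          stage = "dynamics"))
    } else stop("unknown stage mode: ", mode)
  }

  pos <- state@positions
  system@positions <- pos

  ## restraint-satisfaction report
  report <- NULL
  for (f in fragments) {
    if (!f@kind %in% c("cd_bridge", "mg_bridge", "zn_bridge",
                       "salt_bridge")) next
    cb <- vapply(f@sites, function(s) {
      i <- .atomIndex(system, s, "CB",
                      fragmentId = NULL)
      i[i %in% f@atomIndices][1L]
    }, 1L)
    cbd <- if (!anyNA(cb)) measureDistance(pos, cb[1L], cb[2L]) else NA
    anchorDev <- if (nrow(f@anchorPairs))
      max(sqrt(rowSums((pos[f@anchorPairs[, "frag"], , drop = FALSE] -
                          pos[f@anchorPairs[, "host"], ,
                              drop = FALSE])^2)))
    else NA_real_
    report <- rbind(report, data.frame(
      kind = f@kind, sites = paste(f@sites, collapse = "/"),
      cbCbDistance = cbd, maxAnchorDev = anchorDev))
  }

  ## mean +- sd of bridge restraint distances over the recorded tail
  bridgeStats <- NULL
  if (length(tailRecords) && nrow(bondTerms)) {
    tail <- tailRecords[seq(ceiling(length(tailRecords) / 2),
                            length(tailRecords))]
    dmat <- do.call(rbind, lapply(tail, `[[`, "bridgeDists"))
    bridgeStats <- data.frame(
      i = bondTerms$i, j = bondTerms$j, x0 = bondTerms$x0,
      mean = colMeans(dmat), sd = apply(dmat, 2L, stats::sd))
  } else if (nrow(bondTerms)) {
    d <- sqrt(rowSums((pos[bondTerms$i, , drop = FALSE] -
                         pos[bondTerms$j, , drop = FALSE])^2))
    bridgeStats <- data.frame(i = bondTerms$i, j = bondTerms$j,
                              x0 = bondTerms$x0, mean = d, sd = 0)
  }

  if (!is.null(outPdb)) writePDB(system, outPdb)
  if (!is.null(logFile) && !is.null(energyLog))
    utils::write.table(energyLog, logFile, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  list(state = state, system = system, report = report,
       bridgeStats = bridgeStats, energyLog = energyLog)
}

#' Restrained-ensemble (reMD) protocol
#'
#' Equilibrates the copy ensembles without the histogram energy
#' restraint, then runs a production phase with the restraint active.
#' The host backbone is held by a harmonic positional restraint and
#' every label copy is anchored to its host residue.  During production
#' the instantaneous smoothed histograms are sampled and time-averaged
#' per site pair; the per-pair RMS bin deviation from the target is
#' reported.
#'
#' @param system an [AtomicSystem] holding host and label atoms
#' @param ensembles list of [CopyEnsemble] (grouping already applied if
#'   the copy count exceeds the engine group limit)
#' @param histRestraints list of [HistogramRestraint]; every referenced
#'   probe atom must belong to one of the ensembles
#' @param equilSteps,prodSteps step counts of the two phases
#' @param burnInSteps production steps run with the restraint active
#'   before histogram sampling starts (discarded transient)
#' @param temperature kelvin (default 300)
#' @param dt timestep, fs (default 1)
#' @param friction 1/ps (default 5)
#' @param backboneK host-backbone positional restraint force constant,
#'   kcal/mol/Angstrom^2 (default 100)
#' @param anchorK label anchor force constant, kcal/mol/Angstrom^2
#'   (default 10)
#' @param params a [SoftCoreParams]
#' @param includeNonbonded evaluate the nonbonded interaction (default
#'   TRUE; turn off for free-probe toy systems)
#' @param sampleEvery histogram sampling stride during production
#' @return list with final `state`, per-pair `histograms` (each with
#'   the time-averaged `hbar`, the `target` and `rmsDev`), and a
#'   summary `report` data.frame
#' @export
runRestrainedEnsemble <- function(system, ensembles, histRestraints,
                                  equilSteps, prodSteps,
                                  burnInSteps = 0L,
                                  temperature = 300, dt = 1,
                                  friction = 5, backboneK = 100,
                                  anchorK = 10,
                                  params = softCoreParams(),
                                  includeNonbonded = TRUE,
                                  sampleEvery = 10L) {
  knownProbes <- unlist(lapply(ensembles, function(e) e@probeAtoms))
  for (hr in histRestraints)
    if (!all(c(hr@probesI, hr@probesJ) %in% knownProbes))
      stop("histogram restraint references a probe atom of an ",
           "unlabeled site")

  copies <- do.call(c, lapply(ensembles, function(e) e@copies))
  providers <- list(bonded = makeBondedProvider(system))
  if (includeNonbonded) {
    model <- buildExclusionModel(system, copies)
    providers$nonbonded <- makeNonbondedProvider(system, model, params)
  }
  anchored <- Filter(function(f) nrow(f@anchorPairs) > 0L, copies)
  if (length(anchored)) {
    anchors <- do.call(combineRestraints,
                       lapply(anchored, anchorRestraints, k = anchorK))
    providers$anchors <- makeRestraintProvider(anchors)
  }
  bbIdx <- which(system@atoms$fragmentId == 0L &
                   system@atoms$name %in% .backboneNames)
  if (length(bbIdx) && backboneK > 0)
    providers$backbone <- makePositionalRestraintProvider(
      bbIdx, system@positions, backboneK)

  masses <- system@atoms$mass
  state <- simulationState(system@positions)
  if (equilSteps > 0L)
    state <- langevinRun(state, providers, nSteps = equilSteps, dt = dt,
                         temperature = temperature, friction = friction,
                         masses = masses)$state

  providers$histogram <- makeHistogramRestraintProvider(histRestraints)
  if (burnInSteps > 0L)
    state <- langevinRun(state, providers, nSteps = burnInSteps,
                         dt = dt, temperature = temperature,
                         friction = friction, masses = masses)$state
  nPairs <- length(histRestraints)
  sums <- lapply(histRestraints, function(hr)
    numeric(length(hr@target@values)))
  nSamp <- 0L
  recordFun <- function(pos, st) {
    for (p in seq_len(nPairs)) {
      ev <- .histogramRestraintEval(histRestraints[[p]], pos)
      sums[[p]] <<- sums[[p]] + ev$hbar@values
    }
    nSamp <<- nSamp + 1L
    NULL
  }
  if (prodSteps > 0L)
    state <- langevinRun(state, providers, nSteps = prodSteps, dt = dt,
                         temperature = temperature, friction = friction,
                         masses = masses, recordEvery = sampleEvery,
                         recordFun = recordFun)$state

  histograms <- vector("list", nPairs)
  report <- NULL
  for (p in seq_len(nPairs)) {
    hr <- histRestraints[[p]]
    hbar <- if (nSamp > 0L)
      histogramTable(sums[[p]] / nSamp, hr@target@binWidth)
    else .histogramRestraintEval(hr, state@positions)$hbar
    rms <- sqrt(mean((hbar@values - hr@target@values)^2))
    histograms[[p]] <- list(sitePair = hr@sitePair, hbar = hbar,
                            target = hr@target, rmsDev = rms)
    report <- rbind(report, data.frame(
      siteI = hr@sitePair[1L], siteJ = hr@sitePair[2L],
      rmsDev = rms,
      uRE = histogramRestraintEnergy(hbar, hr@target, hr@K)))
  }
  list(state = state, histograms = histograms, report = report)
}
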