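test_that("smoothed histograms are discretized Gaussians, normalized", {
  ## one distance exactly at a bin centre: discretized unit-mass
  ## Gaussian centred there
  h <- smoothedHistogram(30, sigma = 1.1, binWidth = 1, nBins = 60L)
  expect_equal(sum(histValues(h)) * binWidth(h), 1)
  expect_equal(which.max(histValues(h)), 30L)
  raw <- stats::dnorm(1:60, 30, 1.1)
  expect_equal(histValues(h), raw / sum(raw), tolerance = 1e-12)

  ## duplicated distances: the mean over copies is averaging-invariant
  h1 <- smoothedHistogram(c(24.3, 31.7), sigma = 1.1)
  h2 <- smoothedHistogram(rep(c(24.3, 31.7), each = 4L), sigma = 1.1)
  expect_equal(histValues(h1), histValues(h2))

  ## random ensembles match an independent evaluation of the Gaussian
  ## mixture at the bin centres
  set.seed(14)
  for (rep in 1:5) {
    d <- runif(40L, 12, 48)
    h <- smoothedHistogram(d, sigma = 1.1)
    oracle <- vapply(1:60, function(n)
      sum(exp(-(n - d)^2 / (2 * 1.1^2))) / (length(d) *
                                              sqrt(2 * pi * 1.1^2)),
      1)
    oracle <- oracle / sum(oracle)
    expect_lt(max(abs(histValues(h) - oracle)), 1e-8)
    expect_lt(abs(sum(histValues(h)) * 1 - 1), 1e-10)
  }
  expect_error(smoothedHistogram(500, sigma = 1.1), "outside")
  expect_error(smoothedHistogram(-2), ">= 0")
})

test_that("the ensemble restraint energy is the half-K quadratic form", {
  tgt <- makeTargetHistogram(list(c(30, 1)), sigmaGen = 3)
  expect_equal(histogramRestraintEnergy(tgt, tgt, K = 500), 0)

  ## single-bin discrepancy of 0.1 1/A at K = 500 -> 2.5 kcal/mol
  h2 <- tgt
  h2@values[20L] <- h2@values[20L] + 0.1   # raw bin-wise perturbation
  expect_equal(histogramRestraintEnergy(h2, tgt, K = 500), 2.5)
  expect_equal(histogramRestraintEnergy(h2, tgt, K = 1000), 5)  # linear in K

  bad <- new("HistogramTable", values = histValues(tgt)[1:30] /
               sum(histValues(tgt)[1:30]), binWidth = 1)
  expect_error(histogramRestraintEnergy(bad, tgt, 500), "grids")
})

test_that("ensemble distance matrices count N^2 cross pairs", {
  fp <- makeFreeProbes(nCopies = 25L, separation = 30, seed = 4L)
  d <- ensembleDistanceMatrix(fp$ensembles[[1L]], fp$ensembles[[2L]],
                              positions(fp$system))
  expect_equal(dim(d), c(25L, 25L))
  expect_equal(length(d), 625L)
  dSwap <- ensembleDistanceMatrix(fp$ensembles[[2L]], fp$ensembles[[1L]],
                                  positions(fp$system))
  expect_equal(sort(as.numeric(d)), sort(as.numeric(dSwap)))
  expect_error(
    ensembleDistanceMatrix(fp$ensembles[[1L]], fp$ensembles[[1L]],
                           positions(fp$system)), "undefined")

  one <- makeFreeProbes(nCopies = 1L, separation = 17, seed = 4L)
  d1 <- ensembleDistanceMatrix(one$ensembles[[1L]], one$ensembles[[2L]],
                               positions(one$system))
  expect_equal(as.numeric(d1),
               measureDistance(positions(one$system),
                               probeAtoms(one$ensembles[[1L]]),
                               probeAtoms(one$ensembles[[2L]])))
})

test_that("histogram forces are exact gradients with the expected symmetries", {
  fp <- makeFreeProbes(nCopies = 6L, separation = 22, spread = 3,
                       seed = 9L)
  tgt <- makeTargetHistogram(list(c(20, 0.5), c(27, 0.5)), sigmaGen = 2)
  hr <- histogramRestraint(fp$ensembles[[1L]], fp$ensembles[[2L]], tgt)
  prov <- makeHistogramRestraintProvider(list(hr))
  pos <- positions(fp$system)

  cg <- checkGradients(prov, pos)
  expect_lt(cg$maxRelErr, 1e-6)

  ev <- histogramRestraintForces(hr, pos)
  expect_gte(ev$energy, 0)
  expect_equal(sum(histValues(ev$hbar)) * binWidth(ev$hbar), 1)
  ## rigid translation: energy unchanged, net force zero
  shifted <- pos + matrix(rep(c(3, -2, 5), each = nrow(pos)), ncol = 3L)
  expect_equal(prov(shifted)$energy, ev$energy)
  expect_lt(max(abs(colSums(ev$forces))), 1e-12)

  ## a matched target: zero energy, zero force
  d <- ensembleDistanceMatrix(fp$ensembles[[1L]], fp$ensembles[[2L]], pos)
  self <- smoothedHistogram(as.numeric(d), sigma = 1.1)
  hrSelf <- histogramRestraint(fp$ensembles[[1L]], fp$ensembles[[2L]],
                               self)
  evSelf <- histogramRestraintForces(hrSelf, pos)
  expect_lt(evSelf$energy, 1e-18)
  expect_lt(max(abs(evSelf$forces)), 1e-8)

  ## forces act on probe atoms only (here all atoms are probes, so
  ## check with a padded system instead)
  pos2 <- rbind(pos, c(100, 100, 100))
  ev2 <- .histEvalPadded <- histogramRestraintForces(hr, pos2)
  expect_equal(ev2$forces[nrow(pos2), ], c(0, 0, 0))
})

test_that("every computed histogram obeys the normalization identity", {
  set.seed(88)
  for (rep in 1:10) {
    n <- sample(3:30, 1L)
    d <- runif(n * n, 5, 55)
    h <- smoothedHistogram(d, sigma = runif(1, 0.6, 2),
                           binWidth = 1, nBins = 60L)
    expect_lt(abs(sum(histValues(h)) * binWidth(h) - 1), 1e-10)
  }
})
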