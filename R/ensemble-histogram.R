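#' Gaussian-smoothed ensemble distance histogram
#'
#' Builds the smooth, differentiable histogram of an ensemble of
#' distances: the raw density at bin n (centred at n * binWidth) is
#' \deqn{\bar h(n) = \frac{1}{N_d}\sum_{p}
#'   \frac{1}{\sqrt{2\pi\sigma^2}}
#'   e^{-(n\Delta r - d_p)^2 / 2\sigma^2}}
#' and the returned table is renormalized so that
#' \eqn{\sum_n \bar h(n)\,\Delta r = 1} over the bin window.
#'
#' @param distances numeric distances, Angstrom (for a site pair with N
#'   copies each, the N^2 cross distances)
#' @param sigma Gaussian smoothing width, Angstrom (default 1.1)
#' @param binWidth bin width Delta-r, Angstrom (default 1)
#' @param nBins number of bins (default 60; bins n = 1..nBins)
#' @return a [HistogramTable]
#' @examples
#' h <- smoothedHistogram(c(25.0, 31.2, 28.4))
#' sum(histValues(h)) * binWidth(h)  # 1 by construction
#' @export
smoothedHistogram <- function(distances, sigma = 1.1, binWidth = 1,
                              nBins = 60L) {
  if (any(distances < 0)) stop("distances must be >= 0")
  if (sigma <= 0 || binWidth <= 0) stop("sigma and binWidth must be > 0")
  centers <- seq_len(nBins) * binWidth
  raw <- rowMeans(exp(-outer(centers, distances, "-")^2 /
                        (2 * sigma^2))) / sqrt(2 * pi * sigma^2)
  if (sum(raw) * binWidth < 1e-12)
    stop("ensemble distances lie outside the histogram bin window")
  histogramTable(raw, binWidth)
}

#' Restrained-ensemble histogram energy
#'
#' \eqn{U = (K/2) \sum_n (\bar h(n) - H(n))^2} comparing the computed
#' ensemble histogram to the target on a matching bin grid.  Zero if and
#' only if the histograms agree bin-wise.
#'
#' @param hbar computed [HistogramTable]
#' @param target target [HistogramTable]
#' @param K force constant, kcal/mol/Angstrom^2 (default 500)
#' @return energy, kcal/mol
#' @export
histogramRestraintEnergy <- function(hbar, target, K = 500) {
  if (length(hbar@values) != length(target@values) ||
      abs(hbar@binWidth - target@binWidth) > 1e-12)
    stop("histogram bin grids do not match")
  (K / 2) * sum((hbar@values - target@values)^2)
}

#' All cross-site probe distances of two copy ensembles
#'
#' The N_i x N_j matrix of probe-atom distances between the copies of
#' two different sites (within-site pairs are not part of the scheme).
#'
#' @param ensembleI,ensembleJ [CopyEnsemble] objects at two sites
#' @param positions n x 3 coordinate matrix
#' @return numeric N_i x N_j distance matrix, Angstrom
#' @export
ensembleDistanceMatrix <- function(ensembleI, ensembleJ, positions) {
  if (ensembleI@site == ensembleJ@site)
    stop("self-pairs (i == j) are undefined for ensemble histograms")
  pi_ <- positions[ensembleI@probeAtoms, , drop = FALSE]
  pj <- positions[ensembleJ@probeAtoms, , drop = FALSE]
  d2 <- outer(rowSums(pi_^2), rowSums(pj^2), "+") - 2 * tcrossprod(pi_, pj)
  sqrt(pmax(d2, 0))
}

#' Create a histogram restraint for a site pair
#'
#' @param ensembleI,ensembleJ [CopyEnsemble] objects at the two sites
#' @param target target [HistogramTable]
#' @param K force constant, kcal/mol/Angstrom^2 (default 500)
#' @param sigma Gaussian width, Angstrom (default 1.1)
#' @return a [HistogramRestraint]
#' @export
histogramRestraint <- function(ensembleI, ensembleJ, target, K = 500,
                               sigma = 1.1) {
  new("HistogramRestraint",
      sitePair = c(ensembleI@site, ensembleJ@site),
      probesI = ensembleI@probeAtoms, probesJ = ensembleJ@probeAtoms,
      target = target, K = K, sigma = sigma)
}

## Energy + forces of one histogram restraint.  The gradient runs
## through the Gaussian smoothing *and* the renormalization of the
## ensemble histogram (quotient rule), so the forces are the exact
## gradient of what histogramRestraintEnergy evaluates.
.histogramRestraintEval <- function(restraint, positions) {
  tgt <- restraint@target
  dr <- tgt@binWidth
  nBins <- length(tgt@values)
  sigma <- restraint@sigma
  pi_ <- positions[restraint@probesI, , drop = FALSE]
  pj <- positions[restraint@probesJ, , drop = FALSE]
  ni <- nrow(pi_)
  nj <- nrow(pj)
  ## pair displacement vectors and distances, pairs in column-major
  ## (s, s') order
  ip <- rep(seq_len(ni), times = nj)
  jp <- rep(seq_len(nj), each = ni)
  dx <- pi_[ip, , drop = FALSE] - pj[jp, , drop = FALSE]
  d <- sqrt(rowSums(dx^2))
  centers <- seq_len(nBins) * dr
  G <- exp(-outer(centers, d, "-")^2 / (2 * sigma^2)) /
    sqrt(2 * pi * sigma^2)           # nBins x nPairs
  raw <- rowSums(G) / (ni * nj)
  S <- sum(raw)
  if (S * dr < 1e-12)
    stop("ensemble distances lie outside the histogram bin window")
  h <- raw / (S * dr)
  dev <- h - tgt@values
  energy <- (restraint@K / 2) * sum(dev * dev)
  ## dU/draw_m = (K/(S dr)) (dev_m - sum(dev * h) * dr)
  W <- (restraint@K / (S * dr)) * (dev - sum(dev * h) * dr)
  ## draw_m/dd_p = (1/(ni nj)) G_mp (m dr - d_p)/sigma^2
  M <- G * outer(centers, d, "-") / sigma^2 / (ni * nj)
  dUdd <- as.numeric(crossprod(M, W))   # nPairs
  ## force on each probe: -dU/dd * unit vector; zero direction at d = 0
  coef <- ifelse(d > 1e-12, dUdd / d, 0)
  fPair <- -coef * dx
  forces <- matrix(0, nrow(positions), 3L)
  fI <- rowsum(fPair, restraint@probesI[ip])
  fJ <- rowsum(-fPair, restraint@probesJ[jp])
  forces[as.integer(rownames(fI)), ] <-
    forces[as.integer(rownames(fI)), ] + fI
  forces[as.integer(rownames(fJ)), ] <-
    forces[as.integer(rownames(fJ)), ] + fJ
  list(energy = energy, forces = forces, hbar = histogramTable(raw, dr))
}

#' Forces of a histogram restraint
#'
#' Exact gradient of [histogramRestraintEnergy] composed with
#' [smoothedHistogram] with respect to the probe-atom coordinates,
#' including the renormalization quotient term.  Forces on non-probe
#' atoms are zero.
#'
#' @param restraint a [HistogramRestraint]
#' @param positions n x 3 coordinate matrix
#' @return list with `energy`, `forces` (n x 3) and the instantaneous
#'   normalized histogram `hbar`
#' @export
histogramRestraintForces <- function(restraint, positions) {
  .histogramRestraintEval(restraint, positions)
}

#' Force provider summing several histogram restraints
#'
#' Per-pair energies are summed into one scalar restraint energy over
#' all configured site pairs.
#'
#' @param restraints list of [HistogramRestraint]
#' @return a provider function `f(positions, step)`
#' @export
makeHistogramRestraintProvider <- function(restraints) {
  force(restraints)
  function(positions, step = 0L) {
    energy <- 0
    forces <- matrix(0, nrow(positions), 3L)
    for (r in restraints) {
      ev <- .histogramRestraintEval(r, positions)
      energy <- energy + ev$energy
      forces <- forces + ev$forces
    }
    list(energy = energy, forces = forces)
  }
}
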