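## Internal geometry helpers: distances, angles, dihedrals and their
## Cartesian gradients, plus NeRF-style atom placement from internal
## coordinates.  Angles handled in radians here; degrees only at the
## user surface.

.norm3 <- function(v) sqrt(sum(v * v))

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Measure a bond angle (radians)
#' @keywords internal
#' @noRd
.angleValue <- function(ri, rj, rk) {
  u <- ri - rj
  v <- rk - rj
  cu <- sum(u * v) / (.norm3(u) * .norm3(v))
  acos(max(-1, min(1, cu)))
}

## Gradient of the angle at j spanned by i-j-k with respect to the three
## atom positions; returns list(theta, gi, gj, gk).  Near-colinear
## geometries are guarded by flooring sin(theta): the harmonic force
## coefficient (theta - theta0)/sin(theta) stays finite in the
## theta -> pi limit so the guard only suppresses 0/0 noise.
.angleGrad <- function(ri, rj, rk) {
  u <- ri - rj
  v <- rk - rj
  lu <- .norm3(u)
  lv <- .norm3(v)
  uh <- u / lu
  vh <- v / lv
  ct <- max(-1, min(1, sum(uh * vh)))
  theta <- acos(ct)
  st <- max(sqrt(max(0, 1 - ct * ct)), 1e-8)
  gi <- (ct * uh - vh) / (lu * st)
  gk <- (ct * vh - uh) / (lv * st)
  list(theta = theta, gi = gi, gj = -(gi + gk), gk = gk)
}

## Dihedral angle i-j-k-l and gradients w.r.t. the four positions.
## Standard normal-vector formulation; phi in (-pi, pi].
.dihedralGrad <- function(ri, rj, rk, rl) {
  b1 <- rj - ri
  b2 <- rk - rj
  b3 <- rl - rk
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  lb2 <- .norm3(b2)
  phi <- atan2(sum(.cross3(n1, n2) * b2) / lb2, sum(n1 * n2))
  n1sq <- max(sum(n1 * n1), 1e-12)
  n2sq <- max(sum(n2 * n2), 1e-12)
  gi <- -lb2 / n1sq * n1
  gl <- lb2 / n2sq * n2
  f1 <- sum(b1 * b2) / (lb2 * lb2)
  f2 <- sum(b3 * b2) / (lb2 * lb2)
  gj <- -(1 + f1) * gi + f2 * gl
  gk <- f1 * gi - (1 + f2) * gl
  list(phi = phi, gi = gi, gj = gj, gk = gk, gl = gl)
}

.dihedralValue <- function(ri, rj, rk, rl) {
  .dihedralGrad(ri, rj, rk, rl)$phi
}

## Minimal periodic difference x - x0 mapped into (-pi, pi].
.wrapAngle <- function(dx) {
  dx - 2 * pi * round(dx / (2 * pi))
}

## Place an atom from internal coordinates: at distance `bond` from c,
## forming angle `theta` (radians) with b-c and dihedral `phi` with
## a-b-c (NeRF construction).
.placeAtom <- function(a, b, c, bond, theta, phi) {
  bc <- c - b
  bcn <- bc / .norm3(bc)
  ab <- b - a
  n <- .cross3(ab, bcn)
  ln <- .norm3(n)
  if (ln < 1e-10) {
    ## colinear reference frame: pick any perpendicular
    ref <- if (abs(bcn[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    n <- .cross3(ref, bcn)
    ln <- .norm3(n)
  }
  n <- n / ln
  m <- .cross3(n, bcn)
  d <- c(-bond * cos(theta),
         bond * sin(theta) * cos(phi),
         bond * sin(theta) * sin(phi))
  c + d[1L] * bcn + d[2L] * m + d[3L] * n
}

## Batch (row-wise) versions of the angle/dihedral gradients for
## vectorized force evaluation over many terms at once.
.rowNorm <- function(m) sqrt(rowSums(m * m))

.rowCross <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

.angleGradBatch <- function(P, i, j, k) {
  u <- P[i, , drop = FALSE] - P[j, , drop = FALSE]
  v <- P[k, , drop = FALSE] - P[j, , drop = FALSE]
  lu <- .rowNorm(u)
  lv <- .rowNorm(v)
  uh <- u / lu
  vh <- v / lv
  ct <- pmax(-1, pmin(1, rowSums(uh * vh)))
  theta <- acos(ct)
  st <- pmax(sqrt(pmax(0, 1 - ct * ct)), 1e-8)
  gi <- (ct * uh - vh) / (lu * st)
  gk <- (ct * vh - uh) / (lv * st)
  list(theta = theta, gi = gi, gj = -(gi + gk), gk = gk)
}

.dihedralGradBatch <- function(P, i, j, k, l) {
  b1 <- P[j, , drop = FALSE] - P[i, , drop = FALSE]
  b2 <- P[k, , drop = FALSE] - P[j, , drop = FALSE]
  b3 <- P[l, , drop = FALSE] - P[k, , drop = FALSE]
  n1 <- .rowCross(b1, b2)
  n2 <- .rowCross(b2, b3)
  lb2 <- .rowNorm(b2)
  phi <- atan2(rowSums(.rowCross(n1, n2) * b2) / lb2, rowSums(n1 * n2))
  n1sq <- pmax(rowSums(n1 * n1), 1e-12)
  n2sq <- pmax(rowSums(n2 * n2), 1e-12)
  gi <- -(lb2 / n1sq) * n1
  gl <- (lb2 / n2sq) * n2
  f1 <- rowSums(b1 * b2) / lb2^2
  f2 <- rowSums(b3 * b2) / lb2^2
  gj <- -(1 + f1) * gi + f2 * gl
  gk <- f1 * gi - (1 + f2) * gl
  list(phi = phi, gi = gi, gj = gj, gk = gk, gl = gl)
}

## Scatter-add per-term force contributions into an n x 3 matrix.
.accumForces <- function(forces, idx, contrib) {
  acc <- rowsum(contrib, idx)
  rows <- as.integer(rownames(acc))
  forces[rows, ] <- forces[rows, ] + acc
  forces
}

## Rotate points about the axis through `origin` along unit vector
## `axis` by `angle` radians (Rodrigues).
.rotateAbout <- function(pts, origin, axis, angle) {
  axis <- axis / .norm3(axis)
  shifted <- sweep(pts, 2L, origin)
  ca <- cos(angle)
  sa <- sin(angle)
  K <- matrix(c(0, -axis[3L], axis[2L],
                axis[3L], 0, -axis[1L],
                -axis[2L], axis[1L], 0), 3L, 3L, byrow = TRUE)
  R <- diag(3L) * ca + sa * K + (1 - ca) * (axis %o% axis)
  sweep(shifted %*% t(R), 2L, origin, "+")
}
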