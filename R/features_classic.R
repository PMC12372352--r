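# Classical trajectory descriptors: shape, confinement and heterogeneity
# features adopted from the diffusional-fingerprinting literature.
#
# Features that are undefined on a degenerate trajectory (all points
# coincident, zero step variance, ...) return NA; the fingerprint pipeline
# flags such rows and excludes them from classification by default.

#' Katz-George fractal dimension of a trajectory
#'
#' `Df = log(n) / (log(n) + log(d_max / L))` with `n` the number of steps,
#' `L` the total path length and `d_max` the largest pairwise distance
#' between positions. A straight ballistic path gives exactly 1; planar
#' Brownian paths give about 2; strongly confined or subdiffusive paths
#' exceed 2.
#'
#' @param traj An [trajectory()] with at least 3 positions.
#' @return Dimensionless fractal dimension, or `NA` when the path length is
#'   zero (all points coincident).
#' @export
fractal_dimension <- function(traj) {
  stopifnot(inherits(traj, "sptraj"))
  if (length(traj$x) < 3L) stop("need at least 3 positions")
  L <- sum(.step_lengths(traj))
  if (L <= 0) return(NA_real_)
  n <- length(traj$x) - 1L
  d_max <- .max_extent(traj)
  log(n) / (log(n) + log(d_max / L))
}

#' Straightness efficiency of a trajectory
#'
#' `E = |r_N - r_1|^2 / ((N - 1) * sum_i |r_{i+1} - r_i|^2)`: 1 for a
#' straight path of equal steps, 0 for a closed loop. By Cauchy-Schwarz
#' `E` lies in `[0, 1]`.
#'
#' @param traj An [trajectory()].
#' @return Efficiency in `[0, 1]`; 0 when the particle never moves.
#' @export
efficiency <- function(traj) {
  stopifnot(inherits(traj, "sptraj"))
  N <- length(traj$x)
  s <- .steps(traj)
  denom <- (N - 1L) * sum(s[, 1]^2 + s[, 2]^2)
  if (denom <= 0) return(0)
  net2 <- (traj$x[N] - traj$x[1L])^2 + (traj$y[N] - traj$y[1L])^2
  net2 / denom
}

#' Trappedness: probability-like confinement score
#'
#' `pt = 1 - exp(0.2048 - 0.25117 * (D_short * t_total) / r0^2)`, clamped to
#' `[0, 1]`. `D_short` comes from a through-origin linear fit of the first
#' two MSD lags (`MSD = 4 D tau`), `t_total` is the trajectory duration and
#' `r0` half the largest pairwise extent. Particles that could have
#' explored far beyond their observed extent score near 1 (trapped).
#'
#' @param traj An [trajectory()].
#' @param msd The matching [compute_tamsd()] curve (>= 2 lags).
#' @return Trappedness in `[0, 1]`. A zero-extent trajectory returns 1
#'   (fully trapped by convention).
#' @export
trappedness <- function(traj, msd) {
  stopifnot(inherits(traj, "sptraj"), inherits(msd, "msd_curve"))
  if (length(msd$lags_tau) < 2L) stop("msd curve needs at least 2 lags")
  r0 <- .max_extent(traj) / 2
  if (r0 <= 0) return(1)
  tau12 <- msd$lags_tau[1:2]; m12 <- msd$msd[1:2]
  D_short <- sum(m12 * tau12) / (4 * sum(tau12^2))
  t_total <- (length(traj$x) - 1L) * traj$dt
  pt <- 1 - exp(0.2048 - 0.25117 * (D_short * t_total) / r0^2)
  min(max(pt, 0), 1)
}

#' Gaussianity of the displacement distribution
#'
#' Per lag, `g(tau) = MQD(tau) / (2 * MSD(tau)^2) - 1` (planar convention:
#' `<r^4> = 2 <r^2>^2` for 2-D Gaussian displacements, so `g = 0` for ideal
#' Brownian motion). The feature is the mean of `g` over the lags of the
#' curve. Since `MQD >= MSD^2`, `g >= -0.5` always.
#'
#' @param msd An [compute_tamsd()] curve with MQD.
#' @return Mean Gaussianity, or `NA` when all MSD values are zero.
#' @export
gaussianity <- function(msd) {
  stopifnot(inherits(msd, "msd_curve"))
  keep <- msd$msd > 0
  if (!any(keep)) return(NA_real_)
  g <- msd$mqd[keep] / (2 * msd$msd[keep]^2) - 1
  mean(g)
}

#' Kurtosis of projected step displacements
#'
#' Step displacement vectors are projected onto the dominant eigenvector of
#' their covariance matrix and the sample Pearson kurtosis (normal
#' reference = 3) of the projections is returned. Heavy-tailed step
#' distributions -- a signature of heterogeneous environments -- push the
#' value above 3.
#'
#' @param traj An [trajectory()] with at least 4 positions.
#' @return Pearson kurtosis, or `NA` when the projected steps have zero
#'   variance.
#' @export
step_kurtosis <- function(traj) {
  stopifnot(inherits(traj, "sptraj"))
  if (length(traj$x) < 4L) stop("need at least 4 positions (3 steps)")
  s <- .steps(traj)
  cv <- stats::cov(s)
  ev <- eigen(cv, symmetric = TRUE)
  proj <- as.numeric(s %*% ev$vectors[, 1L])
  m2 <- mean((proj - mean(proj))^2)
  if (m2 <= 0) return(NA_real_)
  mean((proj - mean(proj))^4) / m2^2
}

#' Mean per-frame step length
#'
#' @param traj An [trajectory()].
#' @return Mean Euclidean step length in micrometers.
#' @export
mean_step_length <- function(traj) {
  stopifnot(inherits(traj, "sptraj"))
  mean(.step_lengths(traj))
}

#' Mean MSD over the fitted lag range
#'
#' @param msd An [compute_tamsd()] curve.
#' @return Mean of the MSD values in um^2.
#' @export
mean_msd <- function(msd) {
  stopifnot(inherits(msd, "msd_curve"))
  mean(msd$msd)
}
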