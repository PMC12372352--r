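# Time-averaged MSD and the power-law fit that anchors the fingerprint.

#' Time-averaged mean squared (and quartic) displacement
#'
#' For lag `n` the time-averaged MSD is the mean over all start frames `i`
#' of `|r_{i+n} - r_i|^2`; the quartic displacement (MQD) is the mean of
#' `|r_{i+n} - r_i|^4` and feeds the Gaussianity feature. Lags run from 1 to
#' `floor(N * max_lag_fraction)` frames.
#'
#' @param traj An [trajectory()] with at least 3 positions.
#' @param max_lag_fraction Fraction of the trajectory length used as the
#'   largest lag, in (0, 1). The default 0.25 keeps the per-lag averages
#'   well populated (lags 1-25 s for a 100-frame, 1 Hz track).
#' @return An object of class `msd_curve`: list with `lags_tau` (seconds),
#'   `msd` (um^2), `mqd` (um^4), `n_pairs`, `dt`, `n_obs`.
#' @export
compute_tamsd <- function(traj, max_lag_fraction = 0.25) {
  stopifnot(inherits(traj, "sptraj"))
  N <- length(traj$x)
  if (N < 3L) stop("need at least 3 positions to compute a time-averaged MSD")
  if (!is.numeric(max_lag_fraction) || max_lag_fraction <= 0 || max_lag_fraction >= 1) {
    stop("max_lag_fraction must be in (0, 1)")
  }
  max_lag <- max(1L, floor(N * max_lag_fraction))
  lags <- seq_len(max_lag)
  msd <- mqd <- numeric(max_lag)
  n_pairs <- integer(max_lag)
  for (n in lags) {
    dx <- traj$x[(n + 1L):N] - traj$x[1L:(N - n)]
    dy <- traj$y[(n + 1L):N] - traj$y[1L:(N - n)]
    r2 <- dx^2 + dy^2
    msd[n] <- mean(r2)
    mqd[n] <- mean(r2^2)
    n_pairs[n] <- N - n
  }
  structure(list(lags_tau = lags * traj$dt, msd = msd, mqd = mqd,
                 n_pairs = n_pairs, dt = traj$dt, n_obs = N),
            class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("<msd_curve> %d lags (%.3g - %.3g s), msd(1) = %.4g um^2\n",
              length(x$lags_tau), x$lags_tau[1L], x$lags_tau[length(x$lags_tau)],
              x$msd[1L]))
  invisible(x)
}

#' @export
plot.msd_curve <- function(x, log = "xy", ...) {
  keep <- x$msd > 0
  graphics::plot(x$lags_tau[keep], x$msd[keep], log = log,
                 xlab = expression(tau ~ "(s)"),
                 ylab = expression(MSD ~ (mu * m^2)), ...)
  invisible(x)
}

#' Power-law fit of an MSD curve
#'
#' Fits `MSD = D_gen * tau^alpha` by ordinary least squares on
#' `(log tau, log MSD)`; `alpha` is the slope of the log-log MSD curve and
#' `D_gen` the generalized diffusion coefficient (um^2 s^-alpha). Goodness
#' of fit is summarized by the upper-tail p-value of the chi-squared
#' statistic `sum((msd_obs - msd_fit)^2 / msd_fit)` on `n_lags - 2` degrees
#' of freedom, evaluated in linear MSD space.
#'
#' Lags with zero MSD are excluded. If fewer than 3 positive lags remain
#' (an immobile, noise-free track) the fit is degenerate: `alpha`, `D_gen`
#' and `pval_chi2` are reported as 0 with `degenerate = TRUE`.
#'
#' @param msd An [compute_tamsd()] curve.
#' @return An object of class `power_law_fit`: list with `D_gen`, `alpha`,
#'   `pval_chi2`, `degenerate`, `n_lags_fit`, `tau_range`.
#' @export
fit_power_law <- function(msd) {
  stopifnot(inherits(msd, "msd_curve"))
  keep <- msd$msd > 0
  if (sum(keep) < 3L) {
    return(structure(list(D_gen = 0, alpha = 0, pval_chi2 = 0,
                          degenerate = TRUE, n_lags_fit = sum(keep),
                          tau_range = range(msd$lags_tau)),
                     class = "power_law_fit"))
  }
  lt <- log(msd$lags_tau[keep]); lm_ <- log(msd$msd[keep])
  n <- length(lt)
  sxx <- sum((lt - mean(lt))^2)
  slope <- sum((lt - mean(lt)) * (lm_ - mean(lm_))) / sxx
  intercept <- mean(lm_) - slope * mean(lt)
  fit_lin <- exp(intercept) * msd$lags_tau[keep]^slope
  stat <- sum((msd$msd[keep] - fit_lin)^2 / fit_lin)
  dof <- n - 2L
  pval <- if (dof > 0L) stats::pchisq(stat, df = dof, lower.tail = FALSE) else NA_real_
  structure(list(D_gen = exp(intercept), alpha = slope, pval_chi2 = pval,
                 degenerate = FALSE, n_lags_fit = n,
                 tau_range = range(msd$lags_tau[keep])),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("<power_law_fit> degenerate (immobile / zero-MSD trajectory)\n")
  } else {
    cat(sprintf("<power_law_fit> MSD = %.4g * tau^%.3f (chi^2 p = %.3g, %d lags)\n",
                x$D_gen, x$alpha, x$pval_chi2, x$n_lags_fit))
  }
  invisible(x)
}

# local log-log slope of a measured MSD curve, evaluated at arbitrary times
# t0 (seconds); slopes are clamped to the measured lag range at the ends.
# Used by the per-frequency variant of the complex-modulus calculation.
.local_loglog <- function(msd) {
  keep <- msd$msd > 0
  lt <- log(msd$lags_tau[keep]); lm_ <- log(msd$msd[keep])
  if (sum(keep) < 3L) return(NULL)
  slopes <- diff(lm_) / diff(lt)
  mid <- (lt[-1L] + lt[-length(lt)]) / 2
  list(
    msd_at = function(t0) {
      v <- stats::approx(lt, lm_, xout = log(t0), rule = 2L)$y
      # linear extrapolation beyond the measured range using the end slopes
      lo <- log(t0) < lt[1L]; hi <- log(t0) > lt[length(lt)]
      v[lo] <- lm_[1L] + slopes[1L] * (log(t0[lo]) - lt[1L])
      v[hi] <- lm_[length(lm_)] + slopes[length(slopes)] * (log(t0[hi]) - lt[length(lt)])
      exp(v)
    },
    alpha_at = function(t0) stats::approx(mid, slopes, xout = log(t0), rule = 2L)$y
  )
}
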