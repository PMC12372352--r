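# Passive microrheology from single trajectories via the generalized
# Stokes-Einstein relation.
#
# Five features are derived per trajectory: creep compliance J(tau)
# (proportional to the MSD), the complex shear modulus |G*| evaluated on a
# Laplace-frequency grid from the power-law MSD fit, its storage (G') and
# loss (G'') projections, and the low-frequency viscosity G''/omega.
# Trajectory MSDs enter in um^2 and are converted to SI internally.

#' Laplace/angular frequency grid for microrheology
#'
#' Log-spaced grid of Laplace frequencies `s0` (also used as the angular
#' frequency grid omega), default 60 points over `[0.01, 100]` 1/s, so the
#' probed timescales `t0 = 1/s0` span 0.01-100 s.
#'
#' @param range Two-element frequency range in 1/s.
#' @param n Number of grid points.
#' @return Numeric vector of frequencies.
#' @export
rheology_grid <- function(range = c(0.01, 100), n = 60L) {
  stopifnot(length(range) == 2L, all(range > 0), range[2] > range[1], n >= 2L)
  exp(seq(log(range[1]), log(range[2]), length.out = n))
}

#' Creep compliance from a trajectory MSD
#'
#' `J(tau) = 3 pi a / (d kB T) * <dr^2(tau)>` with the tracer radius `a` in
#' meters and the MSD converted to m^2: the medium's strain per unit stress
#' at lag `tau`, directly proportional to the MSD. `mean_J` averages J over
#' all lags of the curve.
#'
#' @param msd An [compute_tamsd()] curve (um^2).
#' @param ctx A [particle_context()] providing `radius_a`, `temperature_T`,
#'   `dimensionality_d`.
#' @return List with `tau` (s), `J` (1/Pa) and `mean_J`.
#' @export
creep_compliance <- function(msd, ctx) {
  stopifnot(inherits(msd, "msd_curve"), inherits(ctx, "particle_context"))
  J <- 3 * pi * ctx$radius_a / (ctx$dimensionality_d * .kB * ctx$temperature_T) *
    (msd$msd * 1e-12)
  list(tau = msd$lags_tau, J = J, mean_J = mean(J))
}

#' Complex shear modulus over a frequency grid
#'
#' `G*(s0) = d kB T / (3 pi a <dr^2(t0)> Gamma(alpha + 1))` evaluated at
#' `t0 = 1/s0` on the grid. By default (`alpha_mode = "global"`) the MSD at
#' `t0` is the fitted power law `D_gen * t0^alpha`, which also extrapolates
#' below the first measured lag (needed for the `s0 > 1/dt` half of the
#' grid); `alpha_mode = "local"` instead uses the measured curve's local
#' log-log slope and log-log-interpolated MSD at each `t0`.
#'
#' `alpha` is clamped to `[1e-3, 2]` before the Gamma-function and MSD
#' evaluation so the result stays on the physical branch; clamping is
#' reported via the `alpha_clamped` field.
#'
#' @param fit A [fit_power_law()] result (um^2 s^-alpha scale).
#' @param ctx A [particle_context()].
#' @param s0 Frequency grid from [rheology_grid()].
#' @param alpha_mode `"global"` (default) or `"local"`.
#' @param msd Required for `alpha_mode = "local"`: the measured MSD curve.
#' @return List with `s0`, `t0`, `alpha_used` (per grid point), `Gstar`
#'   (Pa), `mean_Gstar`, `alpha_clamped`, `degenerate`.
#' @export
complex_modulus <- function(fit, ctx, s0 = rheology_grid(),
                            alpha_mode = c("global", "local"), msd = NULL) {
  stopifnot(inherits(fit, "power_law_fit"), inherits(ctx, "particle_context"))
  alpha_mode <- match.arg(alpha_mode)
  if (fit$degenerate) {
    return(list(s0 = s0, t0 = 1 / s0, alpha_used = rep(NA_real_, length(s0)),
                Gstar = rep(NA_real_, length(s0)), mean_Gstar = NA_real_,
                alpha_clamped = FALSE, degenerate = TRUE))
  }
  t0 <- 1 / s0
  if (alpha_mode == "global") {
    a_used <- rep(fit$alpha, length(s0))
    a_cl <- .clamp(a_used, 1e-3, 2)
    msd_t0 <- fit$D_gen * t0^a_cl * 1e-12          # m^2
  } else {
    if (is.null(msd)) stop("alpha_mode = \"local\" requires the msd curve")
    loc <- .local_loglog(msd)
    if (is.null(loc)) {
      return(complex_modulus(structure(list(degenerate = TRUE), class = "power_law_fit"),
                             ctx, s0))
    }
    a_used <- loc$alpha_at(t0)
    a_cl <- .clamp(a_used, 1e-3, 2)
    msd_t0 <- loc$msd_at(t0) * 1e-12
  }
  Gstar <- ctx$dimensionality_d * .kB * ctx$temperature_T /
    (3 * pi * ctx$radius_a * msd_t0 * gamma(a_cl + 1))
  list(s0 = s0, t0 = t0, alpha_used = a_cl, Gstar = Gstar,
       mean_Gstar = mean(Gstar),
       alpha_clamped = any(a_used != a_cl), degenerate = FALSE)
}

#' Storage and loss moduli from the complex modulus
#'
#' `G'(omega) = |G*| cos(pi alpha / 2)` and `G''(omega) = |G*| sin(pi alpha
#' / 2)`, with the same clamped `alpha` used for `G*` and `omega = s0`.
#' For `alpha > 1` the cosine is negative, so `G'` carries the sign of
#' `cos(pi alpha / 2)`: near-Newtonian tracks scatter around `G' = 0`.
#'
#' @param gm A [complex_modulus()] result.
#' @return List with `omega`, `Gprime`, `Gdoubleprime` (Pa) and their
#'   grid means `mean_Gprime`, `mean_Gdoubleprime`.
#' @export
storage_loss <- function(gm) {
  Gp <- gm$Gstar * cos(pi * gm$alpha_used / 2)
  Gpp <- gm$Gstar * sin(pi * gm$alpha_used / 2)
  list(omega = gm$s0, Gprime = Gp, Gdoubleprime = Gpp,
       mean_Gprime = mean(Gp), mean_Gdoubleprime = mean(Gpp))
}

#' Low-frequency viscosity
#'
#' `eta(omega) = G''(omega) / omega`, averaged over the low-frequency band
#' (default: the lowest decade of the grid, omega in `[0.01, 0.1]` 1/s).
#' For a Newtonian medium the result is frequency-independent and equals
#' the shear viscosity.
#'
#' @param sl A [storage_loss()] result.
#' @param band Two-element angular-frequency band in 1/s.
#' @return List with `omega`, `eta` (Pa s, full grid) and `mean_eta`
#'   (band average).
#' @export
trajectory_viscosity <- function(sl, band = c(0.01, 0.1)) {
  eta <- sl$Gdoubleprime / sl$omega
  in_band <- sl$omega >= band[1] & sl$omega <= band[2]
  if (!any(in_band)) stop("no grid points inside the low-frequency band")
  list(omega = sl$omega, eta = eta, mean_eta = mean(eta[in_band]))
}

#' Elastic-to-viscous modulus ratio
#'
#' `mean_Gprime / mean_Gdoubleprime`: > 1 indicates a locally solid-like
#' (elastic) response, < 1 liquid-like. For a pure power-law medium the
#' ratio is `cot(pi alpha / 2)`, so `alpha = 0.5` gives exactly 1.
#'
#' @param rheo A list or one-row data frame with `mean_Gprime` and
#'   `mean_Gdoubleprime` (e.g. a fingerprint row).
#' @return The ratio, or `NA` when the loss modulus is 0 or missing.
#' @export
elastic_viscous_ratio <- function(rheo) {
  gp <- rheo$mean_Gprime; gpp <- rheo$mean_Gdoubleprime
  if (is.null(gpp) || !is.finite(gpp) || gpp == 0) return(NA_real_)
  gp / gpp
}

#' Full rheology spectrum and features for one trajectory
#'
#' Convenience wrapper running [creep_compliance()], [complex_modulus()],
#' [storage_loss()] and [trajectory_viscosity()] and collecting the five
#' scalar fingerprint features.
#'
#' @param msd An [compute_tamsd()] curve.
#' @param fit The matching [fit_power_law()].
#' @param ctx A [particle_context()].
#' @param s0 Frequency grid.
#' @param alpha_mode `"global"` or `"local"` (see [complex_modulus()]).
#' @param eta_band Low-frequency band for the viscosity average.
#' @return An object of class `rheology_spectrum`: list of the per-grid
#'   curves plus `features`, a named vector `(mean_J, mean_Gstar,
#'   mean_Gprime, mean_Gdoubleprime, mean_eta)`, and `flagged` (TRUE when
#'   the power-law fit was degenerate, in which case the modulus features
#'   are NA).
#' @export
rheology_spectrum <- function(msd, fit, ctx, s0 = rheology_grid(),
                              alpha_mode = "global", eta_band = c(0.01, 0.1)) {
  cc <- creep_compliance(msd, ctx)
  gm <- complex_modulus(fit, ctx, s0 = s0, alpha_mode = alpha_mode, msd = msd)
  if (gm$degenerate) {
    feats <- c(mean_J = cc$mean_J, mean_Gstar = NA_real_, mean_Gprime = NA_real_,
               mean_Gdoubleprime = NA_real_, mean_eta = NA_real_)
    return(structure(list(J = cc, modulus = gm, storage_loss = NULL,
                          viscosity = NULL, features = feats, flagged = TRUE),
                     class = "rheology_spectrum"))
  }
  sl <- storage_loss(gm)
  vis <- trajectory_viscosity(sl, band = eta_band)
  feats <- c(mean_J = cc$mean_J, mean_Gstar = gm$mean_Gstar,
             mean_Gprime = sl$mean_Gprime, mean_Gdoubleprime = sl$mean_Gdoubleprime,
             mean_eta = vis$mean_eta)
  structure(list(J = cc, modulus = gm, storage_loss = sl, viscosity = vis,
                 features = feats, flagged = FALSE),
            class = "rheology_spectrum")
}

#' @export
print.rheology_spectrum <- function(x, ...) {
  cat("<rheology_spectrum>\n")
  print(signif(x$features, 4))
  invisible(x)
}
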