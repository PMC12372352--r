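# Labeled motion simulator.
#
# Generates planar trajectories with the statistical structure the
# fingerprint assumes: Brownian, fractional Brownian (exact circulant
# embedding), confined (reflecting circular boundary), directed (Brownian
# plus constant drift), immobile, and Markov state-switching motion.
# Independent Gaussian localization noise is added to every observed
# position. All generators are bit-reproducible given a seed.

#' Simulation configuration
#'
#' @param model One of `"brownian"`, `"fbm"`, `"confined"`, `"directed"`,
#'   `"immobile"`, `"switching"`.
#' @param n_trajectories Number of trajectories.
#' @param n_frames Positions per trajectory (default 100; 100-frame, 1 Hz
#'   acquisitions are the emulated scale).
#' @param dt Frame interval in seconds (default 1).
#' @param D Diffusion coefficient in um^2/s (per-axis increment variance
#'   `2 D dt`). For `"fbm"` this scales the motion so the planar MSD is
#'   `4 D tau^(2 hurst_H)` at `dt = 1`.
#' @param hurst_H Hurst exponent in (0, 1) for `"fbm"` (MSD exponent
#'   `alpha = 2 H`).
#' @param confinement_radius Reflecting-circle radius in um for
#'   `"confined"`.
#' @param drift_v Drift speed in um/s for `"directed"`.
#' @param drift_angle Drift direction in radians (default 0).
#' @param states For `"switching"`: list with `D` (per-state diffusivities,
#'   um^2/s) and `P` (row-stochastic transition matrix); the chain starts
#'   from its stationary distribution.
#' @param loc_noise_sigma Localization noise sd in um added independently
#'   to each observed coordinate (default 0.03, a typical localization
#'   precision; set 0 for noise-free truth).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(model = c("brownian", "fbm", "confined", "directed",
                                 "immobile", "switching"),
                       n_trajectories = 1L, n_frames = 100L, dt = 1,
                       D = 0.1, hurst_H = 0.5, confinement_radius = 0.5,
                       drift_v = 0.1, drift_angle = 0,
                       states = list(D = c(0.01, 1),
                                     P = matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2,
                                                byrow = TRUE)),
                       loc_noise_sigma = 0.03) {
  model <- match.arg(model)
  if (n_trajectories < 1L || n_frames < 2L) stop("need >= 1 trajectory of >= 2 frames")
  if (dt <= 0) stop("dt must be positive")
  if (D < 0) stop("D must be >= 0")
  if (loc_noise_sigma < 0) stop("loc_noise_sigma must be >= 0")
  if (model == "fbm" && (hurst_H <= 0 || hurst_H >= 1)) {
    stop("hurst_H must be in (0, 1)")
  }
  if (model == "confined" && confinement_radius <= 0) {
    stop("confinement_radius must be > 0")
  }
  if (model == "switching") {
    if (any(states$D < 0)) stop("state diffusivities must be >= 0")
    P <- states$P
    if (!is.matrix(P) || nrow(P) != length(states$D) || ncol(P) != nrow(P)) {
      stop("states$P must be a square matrix matching states$D")
    }
    if (any(abs(rowSums(P) - 1) > 1e-8) || any(P < 0)) {
      stop("states$P rows must be nonnegative and sum to 1")
    }
  }
  structure(list(model = model, n_trajectories = as.integer(n_trajectories),
                 n_frames = as.integer(n_frames), dt = dt, D = D,
                 hurst_H = hurst_H, confinement_radius = confinement_radius,
                 drift_v = drift_v, drift_angle = drift_angle, states = states,
                 loc_noise_sigma = loc_noise_sigma),
            class = "sim_config")
}

#' Simulate labeled trajectories
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param id_prefix Prefix for particle ids.
#' @return A list of [trajectory()] objects with attribute `labels`, a data
#'   frame with the generating `model` per trajectory. For the switching
#'   model each trajectory additionally carries its per-frame ground-truth
#'   state sequence as attribute `states` (length `n_frames - 1`, the state
#'   generating each step).
#' @export
simulate_trajectories <- function(config, seed = 1L, id_prefix = config$model) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(as.integer(seed))
  out <- vector("list", config$n_trajectories)
  for (i in seq_len(config$n_trajectories)) {
    pos <- switch(config$model,
      brownian  = .sim_brownian(config),
      fbm       = .sim_fbm(config),
      confined  = .sim_confined(config),
      directed  = .sim_directed(config),
      immobile  = .sim_immobile(config),
      switching = .sim_switching(config))
    x <- pos$x; y <- pos$y
    if (config$loc_noise_sigma > 0) {
      x <- x + stats::rnorm(length(x), 0, config$loc_noise_sigma)
      y <- y + stats::rnorm(length(y), 0, config$loc_noise_sigma)
    }
    tr <- trajectory(x, y, dt = config$dt, particle_id = sprintf("%s_%04d", id_prefix, i))
    if (!is.null(pos$states)) attr(tr, "states") <- pos$states
    out[[i]] <- tr
  }
  names(out) <- vapply(out, function(t) t$particle_id, character(1L))
  attr(out, "labels") <- data.frame(particle = names(out),
                                    model = config$model,
                                    stringsAsFactors = FALSE)
  out
}

.sim_brownian <- function(cfg) {
  sd_ax <- sqrt(2 * cfg$D * cfg$dt)
  n <- cfg$n_frames - 1L
  list(x = cumsum(c(0, stats::rnorm(n, 0, sd_ax))),
       y = cumsum(c(0, stats::rnorm(n, 0, sd_ax))))
}

.sim_immobile <- function(cfg) {
  list(x = rep(0, cfg$n_frames), y = rep(0, cfg$n_frames))
}

.sim_directed <- function(cfg) {
  b <- .sim_brownian(cfg)
  tvec <- (seq_len(cfg$n_frames) - 1L) * cfg$dt
  list(x = b$x + cfg$drift_v * cos(cfg$drift_angle) * tvec,
       y = b$y + cfg$drift_v * sin(cfg$drift_angle) * tvec)
}

.sim_confined <- function(cfg) {
  # Brownian steps with radial reflection at a circle centred on the start
  sd_ax <- sqrt(2 * cfg$D * cfg$dt)
  R <- cfg$confinement_radius
  n <- cfg$n_frames
  x <- y <- numeric(n)
  dx <- stats::rnorm(n - 1L, 0, sd_ax)
  dy <- stats::rnorm(n - 1L, 0, sd_ax)
  for (i in 2L:n) {
    xi <- x[i - 1L] + dx[i - 1L]
    yi <- y[i - 1L] + dy[i - 1L]
    r <- sqrt(xi^2 + yi^2)
    while (r > R) {
      # reflect the radial overshoot back inside
      xi <- xi * (2 * R - r) / r
      yi <- yi * (2 * R - r) / r
      r <- sqrt(xi^2 + yi^2)
      if (!is.finite(r)) { xi <- 0; yi <- 0; r <- 0 }
    }
    x[i] <- xi; y[i] <- yi
  }
  list(x = x, y = y)
}

.sim_switching <- function(cfg) {
  Dk <- cfg$states$D; P <- cfg$states$P
  K <- length(Dk)
  # stationary distribution of the chain (left eigenvector of P)
  ev <- eigen(t(P))
  st <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  st <- st / sum(st)
  n <- cfg$n_frames - 1L
  states <- integer(n)
  states[1L] <- sample.int(K, 1L, prob = st)
  if (n > 1L) for (t in 2L:n) {
    states[t] <- sample.int(K, 1L, prob = P[states[t - 1L], ])
  }
  sd_ax <- sqrt(2 * Dk[states] * cfg$dt)
  list(x = cumsum(c(0, stats::rnorm(n, 0, sd_ax))),
       y = cumsum(c(0, stats::rnorm(n, 0, sd_ax))),
       states = states)
}

# Exact fractional Gaussian noise by circulant embedding (Davies-Harte):
# the covariance of fGn is embedded in a circulant matrix whose
# eigenvalues are obtained by FFT, giving an exact-covariance sample.
.fgn <- function(n, H) {
  g <- function(k) 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  r <- g(0:(n - 1L))
  circ <- c(r, 0, rev(r[-1L]))
  lam <- Re(stats::fft(circ))
  if (any(lam < -1e-8 * max(lam))) stop("circulant embedding failed for H = ", H)
  lam[lam < 0] <- 0
  m <- length(circ)
  z <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m))
  w <- stats::fft(sqrt(lam / (2 * m)) * z)
  Re(w)[seq_len(n)]
}

.sim_fbm <- function(cfg) {
  n <- cfg$n_frames - 1L
  # per-axis fBm scaled so that the planar MSD is 4 D (tau/1s)^{2H} * dt^{2H}
  scale <- sqrt(2 * cfg$D) * cfg$dt^cfg$hurst_H
  list(x = cumsum(c(0, scale * .fgn(n, cfg$hurst_H))),
       y = cumsum(c(0, scale * .fgn(n, cfg$hurst_H))))
}
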