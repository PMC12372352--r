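# Deterministic fixture trajectories built in code.

# straight line along x with unit steps, n positions
line_traj <- function(n = 101L, step = 1, dt = 1) {
  trajectory(x = (seq_len(n) - 1L) * step, y = rep(0, n), dt = dt)
}

# trajectory from a given sequence of step lengths with random headings
steps_traj <- function(steps, seed = 1L, dt = 1) {
  set.seed(seed)
  ang <- stats::runif(length(steps), 0, 2 * pi)
  trajectory(cumsum(c(0, steps * cos(ang))), cumsum(c(0, steps * sin(ang))), dt = dt)
}

# rotate + translate a trajectory (rigid motion)
rigid_transform <- function(traj, theta = 0, dx = 0, dy = 0) {
  x <- traj$x * cos(theta) - traj$y * sin(theta) + dx
  y <- traj$x * sin(theta) + traj$y * cos(theta) + dy
  trajectory(x, y, dt = traj$dt, frames = traj$frames, particle_id = traj$particle_id)
}

scale_traj <- function(traj, c) {
  trajectory(traj$x * c, traj$y * c, dt = traj$dt, frames = traj$frames,
             particle_id = traj$particle_id)
}

# default test context: 1000 nm negative tracer in PNCM at 37 C
test_ctx <- function(medium = "PNCM", size_nm = 1000, charge = "negative") {
  particle_context(radius_a = size_nm / 2 * 1e-9, charge = charge,
                   nominal_diameter = size_nm, medium = medium)
}

# independent trapezoid rule for density checks
.trapz_test <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

# small labeled feature table for classifier tests: 3 classes, `shift`
# controls separation of the informative features
toy_feature_table <- function(n_per_class = 40L, shift = 0, seed = 1L,
                              n_features = 6L) {
  set.seed(seed)
  classes <- c("PNCM", "PACM-HEC", "PACM-PAA")
  rows <- lapply(seq_along(classes), function(k) {
    X <- matrix(rnorm(n_per_class * n_features), n_per_class, n_features)
    X[, 1] <- X[, 1] + (k - 1) * shift
    X[, 2] <- X[, 2] - (k - 1) * shift
    df <- as.data.frame(X)
    names(df) <- paste0("f", seq_len(n_features))
    df$medium <- classes[k]
    df
  })
  as_fingerprint_table(do.call(rbind, rows))
}
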