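test_that("zero diffusivity and zero noise give a fixed point", {
  cfg <- sim_config("brownian", n_trajectories = 2, D = 0, loc_noise_sigma = 0)
  trs <- simulate_trajectories(cfg, seed = 1)
  for (tr in trs) {
    expect_true(all(tr$x == tr$x[1]))
    expect_true(all(tr$y == tr$y[1]))
  }
})

test_that("Brownian ensemble MSD matches 4*D*tau within 5%", {
  D <- 1
  cfg <- sim_config("brownian", n_trajectories = 2000, n_frames = 40, dt = 1,
                    D = D, loc_noise_sigma = 0)
  trs <- simulate_trajectories(cfg, seed = 11)
  msd <- rowMeans(vapply(trs, function(tr) compute_tamsd(tr)$msd, numeric(10)))
  expect_equal(msd, 4 * D * (1:10), tolerance = 0.05)
})

test_that("fBm MSD scaling exponent recovers 2H across H values", {
  for (H in c(0.25, 0.5, 0.75)) {
    cfg <- sim_config("fbm", n_trajectories = 150, hurst_H = H, D = 0.1,
                      loc_noise_sigma = 0)
    trs <- simulate_trajectories(cfg, seed = round(100 * H))
    alphas <- vapply(trs, function(tr) fit_power_law(compute_tamsd(tr))$alpha,
                     numeric(1))
    expect_equal(mean(alphas), 2 * H, tolerance = 0.1 / (2 * H))
  }
})

test_that("confined trajectories plateau and respect the boundary", {
  R <- 0.4; sig <- 0.02
  cfg <- sim_config("confined", n_trajectories = 50, D = 0.5,
                    confinement_radius = R, loc_noise_sigma = sig)
  trs <- simulate_trajectories(cfg, seed = 5)
  for (tr in trs) {
    d_max <- max(dist(cbind(tr$x, tr$y)))
    expect_lte(d_max, 2 * R + 6 * sig)
  }
  # plateau: late-lag ensemble MSD grows much slower than linearly
  msd <- rowMeans(vapply(trs, function(tr) compute_tamsd(tr)$msd, numeric(25)))
  expect_lt(msd[25] / msd[5], 5 / 1.5)
})

test_that("directed motion adds the configured drift", {
  cfg <- sim_config("directed", n_trajectories = 200, D = 0.01, drift_v = 0.3,
                    drift_angle = 0, loc_noise_sigma = 0)
  trs <- simulate_trajectories(cfg, seed = 9)
  net_x <- mean(vapply(trs, function(tr) tr$x[100] - tr$x[1], numeric(1)))
  expect_equal(net_x, 0.3 * 99, tolerance = 0.05)
})

test_that("switching model carries ground-truth states and valid chains", {
  cfg <- sim_config("switching", n_trajectories = 5,
                    states = list(D = c(0.01, 1),
                                  P = matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE)))
  trs <- simulate_trajectories(cfg, seed = 2)
  for (tr in trs) {
    st <- attr(tr, "states")
    expect_length(st, length(tr$x) - 1L)
    expect_true(all(st %in% 1:2))
  }
  expect_error(sim_config("switching",
                          states = list(D = c(0.1, 1),
                                        P = matrix(c(0.9, 0.2, 0.1, 0.9), 2, 2))),
               "sum to 1")
})

test_that("identical seeds give bit-identical trajectories", {
  cfg <- sim_config("fbm", n_trajectories = 4, hurst_H = 0.3)
  a <- simulate_trajectories(cfg, seed = 123)
  b <- simulate_trajectories(cfg, seed = 123)
  expect_identical(a, b)
  c2 <- simulate_trajectories(cfg, seed = 124)
  expect_false(identical(a, c2))
})

test_that("invalid simulator configs are rejected", {
  expect_error(sim_config("fbm", hurst_H = 1.2), "hurst_H")
  expect_error(sim_config("brownian", D = -1), "D must be")
  expect_error(sim_config("confined", confinement_radius = 0), "confinement_radius")
  expect_error(sim_config("brownian", loc_noise_sigma = -0.1), "loc_noise_sigma")
})

test_that("synthetic study matches its design grid and counts", {
  des <- study_design(n_per_cell = 5)
  st <- build_synthetic_study(des, seed = 3)
  expect_equal(nrow(st$labels), 3 * 2 * 3 * 5)
  counts <- table(st$labels$medium, st$labels$charge, st$labels$nominal_diameter)
  expect_true(all(counts == 5))
  expect_setequal(unique(st$labels$medium), c("PNCM", "PACM-HEC", "PACM-PAA"))
  # contexts align with labels
  expect_identical(names(st$contexts), st$labels$particle)
  expect_equal(st$contexts[[1]]$radius_a,
               st$labels$nominal_diameter[1] / 2 * 1e-9)
  # reproducibility of the full study
  st2 <- build_synthetic_study(des, seed = 3)
  expect_identical(st$trajectories, st2$trajectories)
})

test_that("study designs can be read from YAML config files", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "name: mini",
    "n_frames: 50",
    "dt: 1",
    "loc_noise_sigma: 0.02",
    "cells:",
    "  - medium: PNCM",
    "    charge: negative",
    "    size_nm: 200",
    "    n_trajectories: 4",
    "    mixture:",
    "      - {model: brownian, weight: 0.5, D: 0.2}",
    "      - {model: immobile, weight: 0.5}"
  ), path)
  des <- read_study_config(path)
  expect_s3_class(des, "study_design")
  expect_equal(des$n_frames, 50L)
  st <- build_synthetic_study(des, seed = 1)
  expect_equal(nrow(st$labels), 4L)
  expect_setequal(unique(st$labels$model), c("brownian", "immobile"))
})
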