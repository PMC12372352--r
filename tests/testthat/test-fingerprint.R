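test_that("fingerprint rows have the 20 canonical features and are deterministic", {
  set.seed(2)
  tr <- simulate_trajectories(sim_config("brownian", n_trajectories = 1, D = 0.4),
                              seed = 2)[[1]]
  ctx <- test_ctx()
  row <- fingerprint(tr, ctx, seed = 5)
  feats <- fingerprint_features()
  expect_length(feats, 20L)
  expect_true(all(feats %in% names(row)))
  expect_false(row$flagged)
  expect_identical(row$medium, "PNCM")
  # identical trajectories -> identical rows
  row2 <- fingerprint(tr, ctx, seed = 5)
  expect_identical(row, row2)
})

test_that("a simulated Newtonian study has feature medians near closed forms", {
  cfg <- sim_config("brownian", n_trajectories = 60, D = 0.5, loc_noise_sigma = 0)
  trs <- simulate_trajectories(cfg, seed = 19)
  fp <- fingerprint_table(trs, test_ctx(), seed = 19)
  expect_equal(median(fp$alpha), 1, tolerance = 0.15)
  expect_equal(median(fp$gaussianity), 0, tolerance = 0.15)
  expect_equal(median(fp$fractal_dimension), 2, tolerance = 0.2)
  expect_true(all(fp$efficiency >= 0 & fp$efficiency <= 1))
  expect_true(all(fp$trappedness >= 0 & fp$trappedness <= 1))
  expect_true(all(fp$gaussianity >= -0.5))
})

test_that("all 20 features are invariant under rigid motions", {
  set.seed(23)
  tr <- simulate_trajectories(sim_config("brownian", n_trajectories = 1, D = 0.3),
                              seed = 23)[[1]]
  ctx <- test_ctx()
  base <- fingerprint(tr, ctx, seed = 7)
  rot <- fingerprint(rigid_transform(tr, theta = 2.1, dx = 40, dy = -7), ctx, seed = 7)
  for (f in fingerprint_features()) {
    expect_equal(rot[[f]], base[[f]], tolerance = 1e-6, label = f)
  }
})

test_that("scaling positions rescales D_gen, step length and MSD quadratically", {
  set.seed(29)
  tr <- simulate_trajectories(sim_config("brownian", n_trajectories = 1, D = 0.3),
                              seed = 29)[[1]]
  ctx <- test_ctx()
  c <- 2.5
  base <- fingerprint(tr, ctx, seed = 7)
  scaled <- fingerprint(scale_traj(tr, c), ctx, seed = 7)
  expect_equal(scaled$mean_step_length, c * base$mean_step_length, tolerance = 1e-9)
  expect_equal(scaled$mean_msd, c^2 * base$mean_msd, tolerance = 1e-9)
  expect_equal(scaled$D_gen, c^2 * base$D_gen, tolerance = 1e-7)
  for (f in c("alpha", "fractal_dimension", "efficiency", "gaussianity",
              "kurtosis", "T0", "T1", "T2", "T3", "mean_dwell")) {
    expect_equal(scaled[[f]], base[[f]], tolerance = 1e-7, label = f)
  }
})

test_that("categorize reproduces the nine canonical datasets", {
  tab <- toy_feature_table(n_per_class = 4, shift = 0)
  n <- nrow(tab)
  tab$charge <- rep(c("positive", "negative"), length.out = n)
  tab$nominal_diameter <- rep(c(100, 200, 1000), length.out = n)
  cats <- categorize(tab)
  expect_length(cats, 9L)
  expect_named(cats, c("All Data", "Positively charged",
                       "Positively charged 100 nm", "Positively charged 200 nm",
                       "Positively charged 1000 nm", "Negatively charged",
                       "Negatively charged 100 nm", "Negatively charged 200 nm",
                       "Negatively charged 1000 nm"),
               ignore.order = TRUE)
  expect_equal(nrow(cats[["All Data"]]), n)
  # a (positive, 100) row appears in exactly All Data + charge + charge x size
  hits <- vapply(cats, function(ct) {
    any(ct$charge == "positive" & ct$nominal_diameter == 100 &
          rownames(ct) == rownames(tab)[1])
  }, logical(1))
  expect_equal(sum(hits), 3L)
  # charge x size cells partition All Data
  cell_n <- sum(vapply(cats[grep("nm$", names(cats))], nrow, integer(1)))
  expect_equal(cell_n, n)
  # empty cells are allowed
  tab2 <- tab[tab$nominal_diameter != 1000, ]
  cats2 <- categorize(tab2)
  expect_equal(nrow(cats2[["Positively charged 1000 nm"]]), 0L)
  # unknown labels are not
  tab$charge[1] <- "neutral"
  expect_error(categorize(tab), "unknown charge")
})

test_that("diffusion modes follow the alpha boundaries", {
  alphas <- c(-0.2, 0, 0.5, 0.999, 1, 1.5, 2, 2.001)
  expect_equal(as.character(classify_mode(alphas)),
               c("immobile", "subdiffusive", "subdiffusive", "subdiffusive",
                 "diffusive", "diffusive", "diffusive", "active"))
})

test_that("mode fractions sum to 100 per group and report exclusions", {
  tab <- data.frame(alpha = c(-0.5, 0.5, 1.5, 2.5, NA, 0.7),
                    medium = "PNCM", charge = "negative",
                    nominal_diameter = 100,
                    flagged = c(rep(FALSE, 5), TRUE))
  mf <- mode_fractions(as_fingerprint_table(tab))
  expect_equal(sum(mf$percent), 100, tolerance = 1e-9)
  expect_equal(unique(mf$n_excluded), 2L)  # the NA and the flagged row
  expect_equal(mf$percent[mf$mode == "immobile"], 25)
})

test_that("standardization gives mean 0 / variance 1 and handles degenerate input", {
  tab <- toy_feature_table(n_per_class = 10, shift = 2)
  std <- standardize_features(tab, features = paste0("f", 1:6))
  for (f in paste0("f", 1:6)) {
    expect_lt(abs(mean(std[[f]])), 1e-10)
    expect_equal(var(std[[f]]), 1, tolerance = 1e-10)
  }
  # scaler reusable on held-out rows
  sc <- attr(std, "scaler")
  held <- apply_scaler(sc, tab[1:5, ])
  expect_equal(held$f1, (tab$f1[1:5] - sc$center[["f1"]]) / sc$scale[["f1"]])
  # applying the scaler twice is not the identity
  twice <- apply_scaler(sc, std)
  expect_false(isTRUE(all.equal(twice$f1, std$f1)))
  # constant features are dropped with a warning
  tab$f1 <- 1
  expect_warning(std2 <- standardize_features(tab, features = paste0("f", 1:6)),
                 "zero-variance.*f1")
  expect_false("f1" %in% names(std2))
  # single-row tables are rejected
  expect_error(fit_scaler(tab[1, ]), "at least 2")
})
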