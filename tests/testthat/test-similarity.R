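test_that("KDE density integrates to 1 and matches the normal pdf at 0", {
  set.seed(1)
  x <- rnorm(5000)
  kd <- kde_density(x)
  expect_equal(.trapz_test(kd$grid, kd$density), 1, tolerance = 1e-3)
  at0 <- kd$density[which.min(abs(kd$grid))]
  expect_equal(at0, 1 / sqrt(2 * pi), tolerance = 0.02 / 0.3989)
  # too-narrow grid is rejected
  expect_error(kde_density(x, grid = seq(-1, 1, length.out = 64)),
               "does not span")
  # zero-variance sample yields a flagged delta-like density
  kd0 <- kde_density(rep(2, 10), grid = seq(1, 3, length.out = 512))
  expect_true(kd0$flagged)
  expect_error(kde_density(c(1, 2)), "at least 5")
})

test_that("area overlap matches the equal-variance Gaussian closed form", {
  set.seed(2)
  a <- rnorm(4000, 0, 1)
  b <- rnorm(4000, 1, 1)
  grid <- seq(min(c(a, b)) - 1, max(c(a, b)) + 1, length.out = 512)
  fa <- kde_density(a, grid = grid)$density
  fb <- kde_density(b, grid = grid)$density
  # overlap of N(0,1) vs N(1,1) = 2 * Phi(-1/2) ~ 0.617
  expect_equal(area_overlap(fa, fb, grid), 2 * pnorm(-0.5), tolerance = 0.02 / 0.617)
  # identity and disjointness limits
  expect_equal(area_overlap(fa, fa, grid), 1, tolerance = 2e-3)
  c2 <- rnorm(4000, 50, 1)
  grid2 <- seq(-5, 55, length.out = 2048)
  f1 <- kde_density(a, grid = grid2)$density
  f2 <- kde_density(c2, grid = grid2)$density
  expect_lt(area_overlap(f1, f2, grid2), 1e-6)
})

test_that("overlap decreases monotonically with Gaussian mean separation", {
  set.seed(3)
  base <- rnorm(3000)
  ov <- vapply(c(0, 0.5, 1, 2, 4), function(sh) {
    b <- base + sh
    grid <- seq(min(c(base, b)) - 1, max(c(base, b)) + 1, length.out = 512)
    area_overlap(kde_density(base, grid = grid)$density,
                 kde_density(b, grid = grid)$density, grid)
  }, numeric(1))
  expect_true(all(diff(ov) < 0))
})

test_that("histogram divergences match hand-computed values", {
  # oracle: direct summation for P = (.5, .5), Q = (.9, .1)
  p <- c(0.5, 0.5); q <- c(0.9, 0.1)
  kl_oracle <- 0.5 * (sum(p * log(p / q)) + sum(q * log(q / p)))
  hd <- histogram_divergences(p, q)
  expect_equal(unname(hd["kl_divergence"]), kl_oracle, tolerance = 1e-6)
  expect_equal(unname(hd["cosine_similarity"]),
               sum(p * q) / sqrt(sum(p^2) * sum(q^2)), tolerance = 1e-12)
  expect_equal(unname(hd["euclidean_distance"]), sqrt(sum((p - q)^2)),
               tolerance = 1e-12)
  # identity
  hd0 <- histogram_divergences(p, p)
  expect_equal(unname(hd0), c(0, 1, 0), tolerance = 1e-9)
  # orthogonal histograms
  expect_equal(unname(histogram_divergences(c(1, 0), c(0, 1))["cosine_similarity"]),
               0, tolerance = 1e-9)
})

test_that("histogram metrics on samples behave at the identity and reject empties", {
  set.seed(4)
  x <- rnorm(500)
  hm <- histogram_metrics(x, x)
  expect_equal(unname(hm), c(0, 1, 0), tolerance = 1e-9)
  expect_error(histogram_metrics(numeric(0), x), "empty")
  # symmetry of all three metrics
  y <- rnorm(500, 1)
  expect_equal(histogram_metrics(x, y), histogram_metrics(y, x), tolerance = 1e-12)
})

test_that("similarity matrix has sane self-pairs and symmetric pairs", {
  set.seed(5)
  tab <- toy_feature_table(n_per_class = 60, shift = 1.5)
  sim <- similarity_matrix(tab, features = paste0("f", 1:4))
  self <- sim[sim$class_a == sim$class_b, ]
  expect_true(all(abs(self$area_overlap - 1) < 5e-3))
  expect_true(all(self$kl_divergence < 1e-9))
  expect_true(all(abs(self$cosine_similarity - 1) < 1e-9))
  expect_true(all(self$euclidean_distance < 1e-9))
  # aggregation: means per pair over features
  agg <- aggregate_similarity(sim)
  expect_equal(nrow(agg), 3L)
  expect_equal(agg$n_features, rep(4L, 3))
  one_pair <- sim[sim$class_a == "PACM-HEC" & sim$class_b == "PACM-PAA", ]
  expect_equal(agg$area_overlap[agg$pair == "PACM-HEC vs PACM-PAA"],
               mean(one_pair$area_overlap))
})

test_that("identical classes give overlap ~1 and zero divergences everywhere", {
  # finite-sample histogram KL is biased upward: ~bins/(2n) in populated
  # bins plus O(log(1/eps)/n) from zero-count tail bins under smoothing
  set.seed(6)
  tab <- toy_feature_table(n_per_class = 600, shift = 0)
  sim <- similarity_matrix(tab, features = paste0("f", 1:3))
  pairs <- sim[sim$class_a != sim$class_b, ]
  expect_true(all(pairs$area_overlap > 0.9))
  expect_true(all(pairs$kl_divergence < 0.3))
  expect_true(all(pairs$cosine_similarity > 0.9))
  expect_true(all(pairs$euclidean_distance < 0.1))
})

test_that("overlap-difference ranking recovers a planted discriminative feature", {
  set.seed(7)
  n <- 120
  mk <- function(medium, planted_shift) {
    data.frame(plant = rnorm(n, planted_shift), other1 = rnorm(n),
               other2 = rnorm(n), medium = medium)
  }
  # 'plant' identical for PNCM/PACM-HEC but shifted for PACM-PAA
  tab <- as_fingerprint_table(rbind(mk("PNCM", 0), mk("PACM-HEC", 0),
                                    mk("PACM-PAA", 4)))
  sim <- similarity_matrix(tab, features = c("plant", "other1", "other2"))
  rk <- overlap_difference_ranking(sim, top_k = 2)
  expect_identical(rk$feature[1], "plant")
  expect_gt(rk$delta[1], 0.5)
})
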