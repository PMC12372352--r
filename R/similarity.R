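# Feature-wise class-similarity analysis: kernel-density area overlap,
# symmetrized Kullback-Leibler divergence, cosine similarity and Euclidean
# distance between per-class feature distributions.

#' Gaussian kernel density on an explicit grid
#'
#' Scott's-rule bandwidth (`sd * n^(-1/5)`); the density is evaluated
#' exactly (mean of Gaussian kernels) on the supplied grid and integrates
#' to 1 up to grid truncation. A zero-variance sample yields a delta-like
#' density (tiny fallback bandwidth) and is flagged.
#'
#' @param values Numeric sample (>= 5 values).
#' @param grid Evaluation grid; default: sample range padded by 3
#'   bandwidths, 512 points.
#' @param bw Bandwidth override.
#' @param n_grid Grid size when `grid` is NULL.
#' @return List with `grid`, `density`, `bw`, `flagged`.
#' @export
kde_density <- function(values, grid = NULL, bw = NULL, n_grid = 512L) {
  values <- values[is.finite(values)]
  if (length(values) < 5L) stop("need at least 5 finite values for a KDE")
  flagged <- FALSE
  if (is.null(bw)) {
    s <- stats::sd(values)
    if (s <= 0) {
      bw <- max(abs(mean(values)), 1) * 1e-6
      flagged <- TRUE
    } else {
      bw <- s * length(values)^(-1 / 5)
    }
  }
  if (is.null(grid)) {
    grid <- seq(min(values) - 3 * bw, max(values) + 3 * bw, length.out = n_grid)
  }
  if (min(grid) > min(values) || max(grid) < max(values)) {
    stop("grid does not span the sample range")
  }
  dens <- numeric(length(grid))
  # chunk over sample to bound the outer-product size
  chunk <- max(1L, floor(5e6 / length(grid)))
  for (i in seq(1L, length(values), by = chunk)) {
    v <- values[i:min(i + chunk - 1L, length(values))]
    dens <- dens + rowSums(stats::dnorm(outer(grid, v, "-"), sd = bw))
  }
  list(grid = grid, density = dens / length(values), bw = bw, flagged = flagged)
}

# shared grid for a set of samples: pooled range padded by pad_bw pooled
# Scott bandwidths
.shared_grid <- function(values_list, n_grid = 512L, pad_bw = 3) {
  pooled <- unlist(values_list, use.names = FALSE)
  pooled <- pooled[is.finite(pooled)]
  bw <- max(stats::sd(pooled) * length(pooled)^(-1 / 5), 1e-12)
  seq(min(pooled) - pad_bw * bw, max(pooled) + pad_bw * bw, length.out = n_grid)
}

#' Area overlap of two densities on a shared grid
#'
#' Trapezoidal integral of the pointwise minimum: 1 for identical
#' distributions, near 0 for disjoint supports.
#'
#' @param f1,f2 Density vectors on the same grid.
#' @param grid The shared grid.
#' @return Overlap in `[0, 1]` (up to grid error).
#' @export
area_overlap <- function(f1, f2, grid) {
  stopifnot(length(f1) == length(grid), length(f2) == length(grid))
  .trapz(grid, pmin(f1, f2))
}

#' Histogram divergences between two probability vectors
#'
#' Low-level metric kernel: symmetrized (Jeffreys) Kullback-Leibler
#' divergence with epsilon smoothing, cosine similarity, and Euclidean
#' distance between two probability-normalized histogram vectors.
#'
#' @param p,q Nonnegative vectors of equal length (normalized internally).
#' @param eps Smoothing constant added before renormalizing for the KL term.
#' @return Named vector `(kl_divergence, cosine_similarity,
#'   euclidean_distance)`.
#' @export
histogram_divergences <- function(p, q, eps = 1e-10) {
  stopifnot(length(p) == length(q), all(p >= 0), all(q >= 0))
  p <- p / sum(p); q <- q / sum(q)
  ps <- (p + eps) / sum(p + eps); qs <- (q + eps) / sum(q + eps)
  kl <- 0.5 * (sum(ps * log(ps / qs)) + sum(qs * log(qs / ps)))
  cosine <- sum(p * q) / sqrt(sum(p^2) * sum(q^2))
  c(kl_divergence = kl, cosine_similarity = cosine,
    euclidean_distance = sqrt(sum((p - q)^2)))
}

#' Histogram metrics between two samples
#'
#' Bins both samples on shared bin edges over the pooled range (default 50
#' bins), normalizes counts to probabilities, and returns the symmetrized
#' KL divergence, cosine similarity and Euclidean distance.
#'
#' @param values1,values2 Numeric samples.
#' @param bins Number of shared bins.
#' @return Named vector as in [histogram_divergences()].
#' @export
histogram_metrics <- function(values1, values2, bins = 50L) {
  values1 <- values1[is.finite(values1)]
  values2 <- values2[is.finite(values2)]
  if (length(values1) == 0L || length(values2) == 0L) stop("empty sample")
  rng <- range(c(values1, values2))
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  h1 <- .bin_counts(values1, edges) / length(values1)
  h2 <- .bin_counts(values2, edges) / length(values2)
  histogram_divergences(h1, h2)
}

.bin_counts <- function(x, edges) {
  idx <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  tabulate(idx, nbins = length(edges) - 1L)
}

#' Feature-wise class-similarity matrix
#'
#' For every feature and every unordered class pair (self-pairs included as
#' internal controls) computes: KDE area overlap on a shared grid, and the
#' three histogram metrics. Features with fewer than `min_n` finite values
#' in a class are skipped.
#'
#' @param table A `fingerprint_table` with a class label column.
#' @param class_col Class label column (default `"medium"`).
#' @param features Feature columns.
#' @param bins Histogram bins (shared edges per feature).
#' @param n_grid,pad_bw KDE grid resolution and padding (in pooled
#'   bandwidths).
#' @param include_self Include self-pairs as sanity controls.
#' @param min_n Minimum finite values per class per feature.
#' @return An object of class `fp_similarity`: long data frame with
#'   columns `feature`, `class_a`, `class_b`, `area_overlap`,
#'   `kl_divergence`, `cosine_similarity`, `euclidean_distance`.
#' @export
similarity_matrix <- function(table, class_col = "medium",
                              features = .feature_cols(table), bins = 50L,
                              n_grid = 512L, pad_bw = 3, include_self = TRUE,
                              min_n = 5L) {
  df <- as.data.frame(table)[!table$flagged, , drop = FALSE]
  y <- factor(df[[class_col]])
  classes <- levels(y)
  pairs <- utils::combn(classes, 2L, simplify = FALSE)
  if (include_self) pairs <- c(lapply(classes, function(cl) c(cl, cl)), pairs)
  rows <- list()
  skipped <- 0L
  for (feat in features) {
    by_class <- split(df[[feat]], y)
    by_class <- lapply(by_class, function(v) v[is.finite(v)])
    grid <- .shared_grid(by_class, n_grid = n_grid, pad_bw = pad_bw)
    dens <- lapply(by_class, function(v) {
      if (length(v) >= min_n) kde_density(v, grid = grid)$density else NULL
    })
    for (pr in pairs) {
      v1 <- by_class[[pr[1]]]; v2 <- by_class[[pr[2]]]
      if (length(v1) < min_n || length(v2) < min_n) { skipped <- skipped + 1L; next }
      ov <- area_overlap(dens[[pr[1]]], dens[[pr[2]]], grid)
      hm <- histogram_metrics(v1, v2, bins = bins)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = feat, class_a = pr[1], class_b = pr[2],
        area_overlap = ov, kl_divergence = unname(hm["kl_divergence"]),
        cosine_similarity = unname(hm["cosine_similarity"]),
        euclidean_distance = unname(hm["euclidean_distance"]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- skipped
  class(out) <- unique(c("fp_similarity", class(out)))
  out
}

#' @export
print.fp_similarity <- function(x, ...) {
  cat(sprintf("<fp_similarity> %d feature x pair rows (%d skipped)\n",
              nrow(x), attr(x, "skipped") %||% 0L))
  print(aggregate_similarity(x))
  invisible(x)
}

#' Mean similarity per class pair across features
#'
#' @param sim An [similarity_matrix()] result.
#' @param include_self Keep self-pair control rows.
#' @return Data frame: one row per class pair with the mean of each metric
#'   across features (missing feature cells excluded).
#' @export
aggregate_similarity <- function(sim, include_self = FALSE) {
  d <- as.data.frame(sim)
  if (!include_self) d <- d[d$class_a != d$class_b, , drop = FALSE]
  key <- paste(d$class_a, d$class_b, sep = " vs ")
  out <- do.call(rbind, lapply(split(d, key), function(g) {
    data.frame(pair = paste(g$class_a[1], g$class_b[1], sep = " vs "),
               area_overlap = mean(g$area_overlap, na.rm = TRUE),
               kl_divergence = mean(g$kl_divergence, na.rm = TRUE),
               cosine_similarity = mean(g$cosine_similarity, na.rm = TRUE),
               euclidean_distance = mean(g$euclidean_distance, na.rm = TRUE),
               n_features = nrow(g))
  }))
  rownames(out) <- NULL
  out
}

#' Overlap-difference feature ranking
#'
#' For each feature, `delta = overlap(ref, class_a) - overlap(ref,
#' class_b)`: a large positive value marks a feature whose distribution in
#' `class_a` matches the reference class much better than in `class_b`.
#' The default contrasts the two artificial media against native mucus.
#'
#' @param sim An [similarity_matrix()] result.
#' @param ref Reference class (default `"PNCM"`).
#' @param class_a,class_b The two comparison classes.
#' @param top_k Number of top features (default 5); only positive
#'   differences are reported.
#' @return Data frame `feature`, `overlap_ref_a`, `overlap_ref_b`, `delta`,
#'   sorted by decreasing `delta`, at most `top_k` rows.
#' @export
overlap_difference_ranking <- function(sim, ref = "PNCM", class_a = "PACM-HEC",
                                       class_b = "PACM-PAA", top_k = 5L) {
  d <- as.data.frame(sim)
  get_pair <- function(c1, c2) {
    sel <- (d$class_a == c1 & d$class_b == c2) | (d$class_a == c2 & d$class_b == c1)
    stats::setNames(d$area_overlap[sel], d$feature[sel])
  }
  oa <- get_pair(ref, class_a)
  ob <- get_pair(ref, class_b)
  feats <- intersect(names(oa), names(ob))
  if (length(feats) == 0L) stop("no shared features for the requested pairs")
  delta <- oa[feats] - ob[feats]
  out <- data.frame(feature = feats, overlap_ref_a = unname(oa[feats]),
                    overlap_ref_b = unname(ob[feats]), delta = unname(delta))
  out <- out[order(-out$delta), , drop = FALSE]
  out <- out[out$delta > 0, , drop = FALSE]
  utils::head(out, top_k)
}
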