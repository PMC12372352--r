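# Assembly of the 20-feature diffusional fingerprint, dataset
# categorization, diffusion-mode classification and feature
# standardization.

#' Canonical fingerprint feature names
#'
#' The 20 features, in canonical column order: 10 classical descriptors,
#' 5 hidden-Markov features (K = 4 occupancies + mean dwell), 5
#' trajectory-microrheology features.
#'
#' @param hmm_K Number of HMM states (default 4; other values change the
#'   number of occupancy columns and hence the total feature count).
#' @return Character vector of feature names.
#' @export
fingerprint_features <- function(hmm_K = 4L) {
  c("D_gen", "alpha", "pval_chi2", "fractal_dimension", "efficiency",
    "trappedness", "gaussianity", "kurtosis", "mean_step_length", "mean_msd",
    paste0("T", seq_len(hmm_K) - 1L), "mean_dwell",
    "mean_J", "mean_Gstar", "mean_Gprime", "mean_Gdoubleprime", "mean_eta")
}

#' Fingerprint configuration
#'
#' @param max_lag_fraction MSD lag range as a fraction of trajectory length
#'   (default 0.25).
#' @param hmm_K,hmm_restarts HMM states and EM restarts.
#' @param s0_range,s0_points Microrheology frequency grid.
#' @param alpha_mode `"global"` or `"local"` scaling exponent for the
#'   complex modulus (see [complex_modulus()]).
#' @param eta_band Low-frequency band for the viscosity average (1/s).
#' @return A list of class `fp_config`.
#' @export
fp_config <- function(max_lag_fraction = 0.25, hmm_K = 4L, hmm_restarts = 3L,
                      s0_range = c(0.01, 100), s0_points = 60L,
                      alpha_mode = "global", eta_band = c(0.01, 0.1)) {
  structure(list(max_lag_fraction = max_lag_fraction, hmm_K = as.integer(hmm_K),
                 hmm_restarts = as.integer(hmm_restarts), s0_range = s0_range,
                 s0_points = as.integer(s0_points), alpha_mode = alpha_mode,
                 eta_band = eta_band),
            class = "fp_config")
}

#' Compute the diffusional fingerprint of one trajectory
#'
#' Runs the full feature stack -- time-averaged MSD, power-law fit,
#' classical shape/heterogeneity descriptors, HMM state features and
#' trajectory microrheology -- and returns one row of the fingerprint
#' table. Rows containing any undefined feature (degenerate power-law fit,
#' zero-extent path, non-converged HMM) are marked `flagged = TRUE` and are
#' excluded from classification by default.
#'
#' @param traj An [trajectory()].
#' @param ctx A [particle_context()] (radius, labels, temperature).
#' @param config An [fp_config()].
#' @param seed Integer seed for the HMM restarts.
#' @return A one-row data frame: 20 feature columns (see
#'   [fingerprint_features()]), label columns `medium`, `charge`,
#'   `nominal_diameter`, plus `particle` and `flagged`.
#' @export
fingerprint <- function(traj, ctx, config = fp_config(), seed = 1L) {
  stopifnot(inherits(traj, "sptraj"), inherits(ctx, "particle_context"))
  msd <- compute_tamsd(traj, max_lag_fraction = config$max_lag_fraction)
  fit <- fit_power_law(msd)
  hmm <- fit_hmm(traj, K = config$hmm_K, n_restarts = config$hmm_restarts,
                 seed = seed)
  s0 <- rheology_grid(config$s0_range, config$s0_points)
  rheo <- rheology_spectrum(msd, fit, ctx, s0 = s0,
                            alpha_mode = config$alpha_mode,
                            eta_band = config$eta_band)
  classic <- c(D_gen = fit$D_gen, alpha = fit$alpha, pval_chi2 = fit$pval_chi2,
               fractal_dimension = fractal_dimension(traj),
               efficiency = efficiency(traj),
               trappedness = trappedness(traj, msd),
               gaussianity = gaussianity(msd),
               kurtosis = if (length(traj$x) >= 4L) step_kurtosis(traj) else NA_real_,
               mean_step_length = mean_step_length(traj),
               mean_msd = mean_msd(msd))
  feats <- c(classic, hmm_fingerprint(hmm), rheo$features)
  flagged <- any(!is.finite(feats)) || fit$degenerate || hmm$flagged || rheo$flagged
  row <- as.data.frame(as.list(feats), check.names = FALSE)
  row$medium <- ctx$medium
  row$charge <- ctx$charge
  row$nominal_diameter <- ctx$nominal_diameter
  row$particle <- as.character(traj$particle_id)
  row$flagged <- flagged
  as_fingerprint_table(row)
}

#' Fingerprint a collection of trajectories
#'
#' @param trajs List of [trajectory()] objects.
#' @param contexts A single [particle_context()] recycled for all
#'   trajectories, or a list of contexts matching `trajs`.
#' @param config An [fp_config()].
#' @param seed Base seed; per-trajectory HMM seeds are derived from it.
#' @return A `fingerprint_table` data frame, one row per trajectory.
#' @export
fingerprint_table <- function(trajs, contexts, config = fp_config(), seed = 1L) {
  if (inherits(contexts, "particle_context")) {
    contexts <- rep(list(contexts), length(trajs))
  }
  if (length(contexts) != length(trajs)) {
    stop("contexts must be a single particle_context or match trajs in length")
  }
  rows <- lapply(seq_along(trajs), function(i) {
    fingerprint(trajs[[i]], contexts[[i]], config = config,
                seed = .sub_seed(seed, i))
  })
  as_fingerprint_table(do.call(rbind, rows))
}

#' Fingerprint a synthetic study
#'
#' @param study A [build_synthetic_study()] result.
#' @inheritParams fingerprint_table
#' @return A `fingerprint_table` with the study's labels attached.
#' @export
fingerprint_study <- function(study, config = fp_config(), seed = 1L) {
  stopifnot(inherits(study, "synthetic_study"))
  fingerprint_table(study$trajectories, study$contexts[names(study$trajectories)],
                    config = config, seed = seed)
}

#' Coerce a data frame to a fingerprint table
#'
#' @param df A data frame with feature columns and a `medium` label column.
#' @return The data frame with class `fingerprint_table`.
#' @export
as_fingerprint_table <- function(df) {
  stopifnot(is.data.frame(df))
  if (!"flagged" %in% names(df)) df$flagged <- FALSE
  class(df) <- unique(c("fingerprint_table", class(df)))
  df
}

#' @export
print.fingerprint_table <- function(x, ...) {
  cat(sprintf("<fingerprint_table> %d trajectories x %d columns (%d flagged)\n",
              nrow(x), ncol(x), sum(x$flagged)))
  if ("medium" %in% names(x)) print(table(x$medium))
  invisible(x)
}

# feature columns present in a table, in canonical order; tables without
# canonical columns (e.g. external feature sets) fall back to all numeric
# non-label columns
.feature_cols <- function(table) {
  K <- sum(grepl("^T[0-9]+$", names(table)))
  canon <- intersect(fingerprint_features(hmm_K = max(K, 1L)), names(table))
  if (length(canon) > 0L) return(canon)
  labels <- c("medium", "charge", "nominal_diameter", "particle", "flagged",
              "model", "category")
  num <- vapply(table, is.numeric, logical(1L))
  setdiff(names(table)[num], labels)
}

#' Categorize a fingerprint table into the nine canonical datasets
#'
#' Splits by particle charge and nominal size: the union ("All Data"), one
#' subset per charge, and one per charge x size combination -- so each
#' charge x size row appears in exactly three categories.
#'
#' @param table A `fingerprint_table` with `charge` and `nominal_diameter`
#'   labels.
#' @param sizes Nominal diameters of the grid (default 100, 200, 1000 nm).
#' @return Named list of nine `fingerprint_table`s.
#' @export
categorize <- function(table, sizes = c(100, 200, 1000)) {
  stopifnot(is.data.frame(table))
  if (!all(c("charge", "nominal_diameter") %in% names(table))) {
    stop("table must carry 'charge' and 'nominal_diameter' labels")
  }
  bad <- setdiff(unique(table$charge), c("positive", "negative"))
  if (length(bad) > 0L) stop("unknown charge label(s): ", paste(bad, collapse = ", "))
  out <- list("All Data" = table)
  for (ch in c("Positively", "Negatively")) {
    chv <- if (ch == "Positively") "positive" else "negative"
    out[[paste(ch, "charged")]] <- table[table$charge == chv, , drop = FALSE]
    for (sz in sizes) {
      out[[sprintf("%s charged %d nm", ch, sz)]] <-
        table[table$charge == chv & table$nominal_diameter == sz, , drop = FALSE]
    }
  }
  lapply(out, as_fingerprint_table)
}

#' Classify diffusion mode from the MSD scaling exponent
#'
#' `alpha < 0`: immobile; `0 <= alpha < 1`: subdiffusive; `1 <= alpha <=
#' 2`: diffusive; `alpha > 2`: active.
#'
#' @param alpha Numeric vector of fitted scaling exponents.
#' @return Factor with levels immobile, subdiffusive, diffusive, active.
#' @export
classify_mode <- function(alpha) {
  lv <- c("immobile", "subdiffusive", "diffusive", "active")
  out <- rep(NA_character_, length(alpha))
  out[alpha < 0] <- "immobile"
  out[alpha >= 0 & alpha < 1] <- "subdiffusive"
  out[alpha >= 1 & alpha <= 2] <- "diffusive"
  out[alpha > 2] <- "active"
  factor(out, levels = lv)
}

#' Diffusion-mode percentages per group
#'
#' Groups the table (default: by medium, charge and size), classifies each
#' row's `alpha`, and reports the percentage of each mode per group.
#' Flagged rows are excluded; the number excluded is reported per group.
#'
#' @param table A `fingerprint_table` with an `alpha` column.
#' @param by Label columns to group by.
#' @return Data frame with the grouping columns, `mode`, `percent`
#'   (summing to 100 within each group) and `n_excluded`.
#' @export
mode_fractions <- function(table, by = c("medium", "charge", "nominal_diameter")) {
  stopifnot(is.data.frame(table), "alpha" %in% names(table))
  by <- intersect(by, names(table))
  key <- interaction(table[by], drop = TRUE, sep = " / ")
  out <- lapply(split(seq_len(nrow(table)), key), function(idx) {
    sub <- table[idx, , drop = FALSE]
    excl <- sub$flagged | !is.finite(sub$alpha)
    modes <- classify_mode(sub$alpha[!excl])
    pct <- 100 * table(modes) / max(length(modes), 1L)
    cbind(sub[rep(1L, nlevels(modes)), by, drop = FALSE],
          data.frame(mode = factor(levels(modes), levels = levels(modes)),
                     percent = as.numeric(pct),
                     n = length(modes), n_excluded = sum(excl)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fit a feature scaler (z-score)
#'
#' Computes per-feature mean and standard deviation on the fitting set.
#' Zero-variance features are dropped with a warning. Use
#' [apply_scaler()] to transform held-out rows with the same parameters
#' ("fit on train"); fitting the scaler on the full table before splitting
#' reproduces the alternative "global" standardization order.
#'
#' @param table A `fingerprint_table` (flagged rows excluded automatically).
#' @param features Feature columns (default: all canonical features
#'   present).
#' @return An object of class `fp_scaler`: list with `center`, `scale`,
#'   `features`, `dropped`.
#' @export
fit_scaler <- function(table, features = .feature_cols(table)) {
  x <- as.data.frame(table)[!table$flagged, features, drop = FALSE]
  if (nrow(x) < 2L) stop("need at least 2 unflagged rows to fit a scaler")
  ctr <- vapply(x, mean, numeric(1L))
  scl <- vapply(x, stats::sd, numeric(1L))
  dropped <- features[scl == 0 | !is.finite(scl)]
  if (length(dropped) > 0L) {
    warning("dropping zero-variance feature(s): ", paste(dropped, collapse = ", "))
  }
  keep <- setdiff(features, dropped)
  structure(list(center = ctr[keep], scale = scl[keep], features = keep,
                 dropped = dropped),
            class = "fp_scaler")
}

#' Apply a fitted scaler
#'
#' Note that z-scoring is not idempotent: applying a scaler to already
#' standardized data rescales it again.
#'
#' @param scaler An [fit_scaler()] object.
#' @param table A `fingerprint_table` (or data frame) with the scaler's
#'   feature columns.
#' @return The table with the scaler's features standardized and dropped
#'   features removed.
#' @export
apply_scaler <- function(scaler, table) {
  stopifnot(inherits(scaler, "fp_scaler"))
  out <- as.data.frame(table)
  for (f in scaler$features) {
    out[[f]] <- (out[[f]] - scaler$center[[f]]) / scaler$scale[[f]]
  }
  out[setdiff(names(out), scaler$dropped)]
}

#' Standardize a fingerprint table feature-wise
#'
#' Convenience wrapper: fits a scaler on the table and applies it, so each
#' retained feature has mean 0 and variance 1.
#'
#' @inheritParams fit_scaler
#' @return The standardized table with the scaler attached as attribute
#'   `scaler`.
#' @export
standardize_features <- function(table, features = .feature_cols(table)) {
  sc <- fit_scaler(table, features = features)
  out <- apply_scaler(sc, table)
  out <- as_fingerprint_table(out)
  attr(out, "scaler") <- sc
  out
}
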