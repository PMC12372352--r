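# Hidden-Markov state decomposition of step-length sequences.
#
# Emissions are Gaussian on the 1-D per-frame step length (sign-free), so
# states are mobility regimes. Fitted by Baum-Welch EM with random
# restarts; the decoded (Viterbi) path yields occupancy fractions and the
# mean dwell time. No pre-installed R package provides a sequential HMM
# with Gaussian emissions, so EM/Viterbi are implemented here.

#' Fit a Gaussian hidden Markov model to a trajectory's step lengths
#'
#' Runs EM (`n_restarts` random initializations, best log-likelihood kept)
#' on the step-length sequence, relabels states ascending by emission mean
#' (ties broken by variance), and Viterbi-decodes the state path.
#'
#' If EM fails to converge in every restart, or the step lengths have zero
#' variance, a flagged single-state solution is returned (all frames in
#' state 1, occupancy `(1, 0, ...)`).
#'
#' @param traj An [trajectory()] with at least `K + 2` steps.
#' @param K Number of hidden states (default 4, matching the T0..T3
#'   occupancy features of the fingerprint).
#' @param n_restarts Random EM restarts (default 3).
#' @param seed Integer seed; the fit is deterministic given (data, seed).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param merge_states Collapse statistically indistinguishable states
#'   after decoding (default TRUE). An unpenalized `K`-state fit always
#'   splits even single-regime data into overlapping states; adjacent
#'   (by emission mean) decoded states are therefore merged whenever a
#'   moment-matched single Gaussian explains their pooled steps as well as
#'   the two-component mixture under a BIC penalty (3 extra parameters).
#'   Well-separated genuine regimes (mean separation of a few pooled sd)
#'   are never merged; single-regime trajectories collapse to one state.
#' @return An object of class `hmm_fit`: list with `K`, `mean`, `var`
#'   (per-state emission parameters, ascending by mean), `transition`
#'   (K x K row-stochastic), `initial`, `path` (decoded states, 1-based),
#'   `occupancy` (fractions summing to 1), `mean_dwell` (frames),
#'   `loglik`, `converged`, `flagged`.
#' @export
fit_hmm <- function(traj, K = 4L, n_restarts = 3L, seed = 1L,
                    max_iter = 500L, tol = 1e-6, merge_states = TRUE) {
  stopifnot(inherits(traj, "sptraj"))
  s <- .step_lengths(traj)
  Tn <- length(s)
  if (Tn < K + 2L) stop("need at least K + 2 steps to fit a ", K, "-state HMM")
  if (stats::sd(s) < 1e-12 * (1 + mean(s))) {
    return(.hmm_single_state(s, K, flagged = FALSE))
  }
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- .hmm_init(s, K)
    fit <- .hmm_em(s, K, init, max_iter = max_iter, tol = tol)
    if (!is.null(fit) && fit$converged &&
        (is.null(best) || fit$loglik > best$loglik)) best <- fit
  }
  if (is.null(best)) return(.hmm_single_state(s, K, flagged = TRUE))
  # canonical state order: ascending emission mean, then variance
  ord <- order(best$mean, best$var)
  mu <- best$mean[ord]; v <- best$var[ord]
  A <- best$transition[ord, ord, drop = FALSE]
  p0 <- best$initial[ord]
  path <- .hmm_viterbi(s, mu, v, A, p0)
  if (merge_states) {
    mg <- .hmm_merge(s, mu, v, path, K)
    mu <- mg$mean; v <- mg$var; path <- mg$path
    A <- .empirical_transition(path, K)
  }
  occ <- tabulate(path, nbins = K) / Tn
  structure(list(K = K, mean = mu, var = v, transition = A, initial = p0,
                 path = path, occupancy = occ,
                 mean_dwell = mean(rle(path)$lengths),
                 loglik = best$loglik, converged = TRUE, flagged = FALSE),
            class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("<hmm_fit> K = %d, occupancy = (%s), mean dwell = %.2f frames%s\n",
              x$K, paste(sprintf("%.3f", x$occupancy), collapse = ", "),
              x$mean_dwell, if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' HMM fingerprint features
#'
#' Occupancy fractions of the `K` ordered states (`T0` slowest ...
#' `T(K-1)` fastest) plus the mean dwell time of the decoded path, in
#' frames. States never decoded have occupancy 0.
#'
#' @param fit An [fit_hmm()] result.
#' @return Named numeric vector `T0..T(K-1), mean_dwell`.
#' @export
hmm_fingerprint <- function(fit) {
  stopifnot(inherits(fit, "hmm_fit"))
  out <- c(fit$occupancy, fit$mean_dwell)
  names(out) <- c(paste0("T", seq_len(fit$K) - 1L), "mean_dwell")
  out
}

.hmm_single_state <- function(s, K, flagged) {
  Tn <- length(s)
  occ <- c(1, rep(0, K - 1L))
  A <- diag(K)
  structure(list(K = K, mean = c(mean(s), rep(mean(s), K - 1L)),
                 var = rep(max(stats::var(s), 0), K),
                 transition = A, initial = occ,
                 path = rep(1L, Tn), occupancy = occ, mean_dwell = Tn,
                 loglik = NA_real_, converged = FALSE, flagged = flagged),
            class = "hmm_fit")
}

# Iteratively merge adjacent decoded states when a single moment-matched
# Gaussian explains their pooled steps as well as the two-state mixture
# (BIC, 3 extra parameters). Surviving states are compacted to 1..K'
# preserving ascending emission-mean order.
.hmm_merge <- function(s, mu, v, path, K) {
  repeat {
    ks <- sort(unique(path))
    if (length(ks) < 2L) break
    ord <- ks[order(mu[ks])]
    best <- NULL
    for (a in seq_len(length(ord) - 1L)) {
      i <- ord[a]; j <- ord[a + 1L]
      sel <- path == i | path == j
      m <- sum(sel); ss <- s[sel]
      wi <- sum(path == i) / m
      ll_split <- sum(log(wi * stats::dnorm(ss, mu[i], sqrt(v[i])) +
                          (1 - wi) * stats::dnorm(ss, mu[j], sqrt(v[j])) + 1e-300))
      mm <- mean(ss)
      vv <- max(mean((ss - mm)^2), 1e-30)
      ll_merged <- sum(stats::dnorm(ss, mm, sqrt(vv), log = TRUE))
      score <- 2 * (ll_split - ll_merged) - 3 * log(m)
      if (is.null(best) || score < best$score) {
        best <- list(score = score, i = i, j = j, mm = mm, vv = vv)
      }
    }
    if (best$score >= 0) break
    path[path == best$j] <- best$i
    mu[best$i] <- best$mm
    v[best$i] <- best$vv
  }
  # compact surviving state labels to 1..K' in ascending-mean order
  ks <- sort(unique(path))
  ord <- ks[order(mu[ks], v[ks])]
  relabel <- integer(K); relabel[ord] <- seq_along(ord)
  mu_out <- rep(NA_real_, K); v_out <- rep(NA_real_, K)
  mu_out[seq_along(ord)] <- mu[ord]
  v_out[seq_along(ord)] <- v[ord]
  list(mean = mu_out, var = v_out, path = relabel[path])
}

# row-stochastic empirical transition matrix of a decoded path; states
# never visited get an identity row
.empirical_transition <- function(path, K) {
  A <- matrix(0, K, K)
  if (length(path) > 1L) {
    for (t in seq_len(length(path) - 1L)) {
      A[path[t], path[t + 1L]] <- A[path[t], path[t + 1L]] + 1
    }
  }
  rs <- rowSums(A)
  for (k in seq_len(K)) {
    if (rs[k] > 0) A[k, ] <- A[k, ] / rs[k] else A[k, k] <- 1
  }
  A
}

.hmm_init <- function(s, K) {
  qs <- stats::quantile(s, probs = (seq_len(K) - 0.5) / K, names = FALSE)
  mu <- qs + stats::rnorm(K, 0, 0.1 * stats::sd(s))
  v <- rep(stats::var(s) / K, K)
  A <- matrix(0.2 / (K - 1L), K, K); diag(A) <- 0.8
  list(mean = mu, var = v, transition = A, initial = rep(1 / K, K))
}

# scaled forward-backward EM for Gaussian emissions on a 1-D sequence
.hmm_em <- function(s, K, init, max_iter, tol) {
  Tn <- length(s)
  mu <- init$mean; v <- init$var; A <- init$transition; p0 <- init$initial
  vfloor <- max(stats::var(s) * 1e-6, 1e-30)
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    B <- vapply(seq_len(K), function(k) stats::dnorm(s, mu[k], sqrt(v[k])),
                numeric(Tn))
    B <- pmax(B, 1e-300)
    # forward (scaled)
    alpha <- matrix(0, Tn, K); cvec <- numeric(Tn)
    a <- p0 * B[1L, ]
    cvec[1L] <- sum(a); alpha[1L, ] <- a / cvec[1L]
    for (t in 2L:Tn) {
      a <- (alpha[t - 1L, ] %*% A) * B[t, ]
      cvec[t] <- sum(a); alpha[t, ] <- a / cvec[t]
    }
    ll <- sum(log(cvec))
    # backward (scaled)
    beta <- matrix(0, Tn, K)
    beta[Tn, ] <- 1
    for (t in (Tn - 1L):1L) {
      beta[t, ] <- (A %*% (B[t + 1L, ] * beta[t + 1L, ])) / cvec[t + 1L]
    }
    gam <- alpha * beta
    gam <- gam / rowSums(gam)
    # transition expectations, summed over time in one matrix product
    w <- (B[-1L, , drop = FALSE] * beta[-1L, , drop = FALSE]) / cvec[-1L]
    xi_sum <- A * crossprod(alpha[-Tn, , drop = FALSE], w)
    # M-step
    p0 <- gam[1L, ]
    A <- xi_sum / pmax(rowSums(xi_sum), 1e-300)
    wk <- colSums(gam)
    mu <- colSums(gam * s) / wk
    v <- pmax(colSums(gam * (outer(s, mu, "-")^2)) / wk, vfloor)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (1 + abs(ll))) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  if (!is.finite(ll_old)) return(NULL)
  list(mean = mu, var = v, transition = A, initial = p0,
       loglik = ll_old, converged = converged)
}

.hmm_viterbi <- function(s, mu, v, A, p0) {
  Tn <- length(s); K <- length(mu)
  logB <- vapply(seq_len(K), function(k) stats::dnorm(s, mu[k], sqrt(v[k]), log = TRUE),
                 numeric(Tn))
  logA <- log(pmax(A, 1e-300))
  delta <- matrix(-Inf, Tn, K); psi <- matrix(0L, Tn, K)
  delta[1L, ] <- log(pmax(p0, 1e-300)) + logB[1L, ]
  for (t in 2L:Tn) {
    for (k in seq_len(K)) {
      cand <- delta[t - 1L, ] + logA[, k]
      psi[t, k] <- which.max(cand)
      delta[t, k] <- cand[psi[t, k]] + logB[t, k]
    }
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta[Tn, ])
  for (t in (Tn - 1L):1L) path[t] <- psi[t + 1L, path[t + 1L]]
  path
}
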