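# Classifier panel, evaluation protocol, embeddings and tree-SHAP
# feature attributions.
#
# The panel spans the three families used in trajectory-fingerprint
# studies: linear models (multinomial logistic regression, Fisher's linear
# discriminant), instance-based learners (kNN, RBF-kernel SVM) and
# tree/ensemble methods (decision tree, random forest, histogram-based
# gradient boosting). Hyperparameters are the defaults of the underlying
# reference implementations and are recorded in the report.

#' The classifier panel
#'
#' @return Named list of classifier functions
#'   `function(Xtr, ytr, Xte, seed)` returning predicted class labels.
#' @export
panel_classifiers <- function() {
  list(
    svm_rbf = function(Xtr, ytr, Xte, seed) {
      set.seed(seed)
      fit <- e1071::svm(Xtr, ytr, kernel = "radial")
      stats::predict(fit, Xte)
    },
    knn = function(Xtr, ytr, Xte, seed) {
      set.seed(seed)
      class::knn(Xtr, Xte, ytr, k = 5L)
    },
    # histogram-mode boosting with the reference defaults: learning rate
    # 0.1, 100 rounds, leaf-wise growth capped at 31 leaves, and a ~20
    # samples-per-leaf floor (hessian mass ~ 0.22/sample for 3 classes)
    hist_gradient_boosting = function(Xtr, ytr, Xte, seed) {
      nc <- nlevels(ytr)
      dtr <- xgboost::xgb.DMatrix(Xtr, label = as.integer(ytr) - 1L)
      bst <- xgboost::xgb.train(
        params = list(objective = "multi:softprob", num_class = nc,
                      tree_method = "hist", grow_policy = "lossguide",
                      max_depth = 0L, max_leaves = 31L, eta = 0.1,
                      min_child_weight = 4, nthread = 1L, seed = seed),
        data = dtr, nrounds = 100L, verbose = 0L)
      prob <- stats::predict(bst, xgboost::xgb.DMatrix(Xte))
      factor(levels(ytr)[max.col(prob, ties.method = "first")], levels = levels(ytr))
    },
    # fully grown tree (reference default: no pruning / no complexity CV)
    decision_tree = function(Xtr, ytr, Xte, seed) {
      set.seed(seed)
      df <- data.frame(Xtr, check.names = TRUE); df$.y <- ytr
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          control = rpart::rpart.control(cp = 0, minsplit = 2L,
                                                         minbucket = 1L, xval = 0L))
      stats::predict(fit, data.frame(Xte, check.names = TRUE), type = "class")
    },
    logistic_regression = function(Xtr, ytr, Xte, seed) {
      set.seed(seed)
      df <- data.frame(Xtr, check.names = TRUE); df$.y <- ytr
      fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE, maxit = 300L,
                            MaxNWts = 10000L)
      pred <- stats::predict(fit, data.frame(Xte, check.names = TRUE))
      factor(as.character(pred), levels = levels(ytr))
    },
    random_forest = function(Xtr, ytr, Xte, seed) {
      set.seed(seed)
      fit <- randomForest::randomForest(Xtr, ytr)
      stats::predict(fit, Xte)
    },
    fisher_lda = function(Xtr, ytr, Xte, seed) {
      # lda handles near-collinear directions via its internal tolerance;
      # the repeated per-fold collinearity warning is suppressed
      fit <- suppressWarnings(MASS::lda(Xtr, grouping = ytr))
      stats::predict(fit, Xte)$class
    }
  )
}

# stratified fold assignment: within each class, indices are shuffled and
# dealt out cyclically, so every fold has (near-)proportional class counts
.stratified_folds <- function(y, k, seed) {
  old_seed <- .save_rng(); on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(as.integer(seed))
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.macro_metrics <- function(truth, pred, lv) {
  cm <- table(factor(truth, levels = lv), factor(pred, levels = lv))
  diagv <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, diagv / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, diagv / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  c(accuracy = sum(diagv) / sum(cm), precision = mean(prec),
    recall = mean(rec), f1 = mean(f1))
}

#' Train and evaluate the classifier panel
#'
#' Evaluates the seven-classifier panel on a fingerprint table with
#' stratified fivefold cross-validation (default) or a stratified 70/30
#' holdout split. Features are z-scored; by default the scaler is fitted on
#' each training fold only (`standardize = "fit_on_train"`, avoiding
#' leakage into the held-out rows); `"global"` standardizes the full table
#' before splitting. Flagged rows are excluded.
#'
#' @param table A `fingerprint_table` with a class label column.
#' @param protocol `"cv_5fold"` (default) or `"holdout_70_30"`.
#' @param seed Integer seed; the full report is reproducible from
#'   (table, protocol, seed).
#' @param class_col Label column to predict (default `"medium"`).
#' @param classifiers Named list from [panel_classifiers()] (subsettable).
#' @param standardize `"fit_on_train"` or `"global"`.
#' @param features Feature columns (default: canonical features present).
#' @return An object of class `fp_panel`: list with `metrics` (long data
#'   frame: classifier, fold, accuracy, precision, recall, f1), `summary`
#'   (mean and sd per classifier and metric), `confusion` (per-classifier
#'   aggregated count matrices, rows = truth), `best` (classifier with the
#'   highest mean F1), `classes`, `protocol`, `seed`, `standardize`, `n`.
#' @export
train_panel <- function(table, protocol = c("cv_5fold", "holdout_70_30"),
                        seed = 1L, class_col = "medium",
                        classifiers = panel_classifiers(),
                        standardize = c("fit_on_train", "global"),
                        features = .feature_cols(table)) {
  protocol <- match.arg(protocol)
  standardize <- match.arg(standardize)
  df <- as.data.frame(table)[!table$flagged, , drop = FALSE]
  y <- factor(df[[class_col]])
  if (nlevels(y) < 2L) stop("need at least 2 classes to classify")
  if (any(tabulate(y) < 10L)) {
    warning("fewer than 10 rows in some class(es); metrics will be noisy")
  }
  k <- if (protocol == "cv_5fold") 5L else NA_integer_
  if (protocol == "cv_5fold") {
    fold <- .stratified_folds(y, 5L, seed)
    splits <- lapply(1:5, function(f) list(train = which(fold != f), test = which(fold == f)))
  } else {
    fold <- .stratified_folds(y, 10L, seed)     # 10 strata dealt 7/3
    test <- which(fold %in% 1:3)
    splits <- list(list(train = setdiff(seq_along(y), test), test = test))
  }
  if (standardize == "global") {
    sc_glob <- fit_scaler(as_fingerprint_table(df), features = features)
    df_global <- apply_scaler(sc_glob, df)
  }
  lv <- levels(y)
  metrics <- list()
  confusion <- lapply(classifiers, function(...) {
    matrix(0L, nlevels(y), nlevels(y), dimnames = list(truth = lv, predicted = lv))
  })
  for (f in seq_along(splits)) {
    tr_idx <- splits[[f]]$train; te_idx <- splits[[f]]$test
    if (any(table(y[tr_idx]) == 0L)) {
      stop("class absent from a training fold; more data or fewer folds needed")
    }
    if (standardize == "fit_on_train") {
      # per-fold refit: silence the repeated zero-variance warnings
      sc <- suppressWarnings(
        fit_scaler(as_fingerprint_table(df[tr_idx, , drop = FALSE]),
                   features = features))
      feats_f <- sc$features
      Xall <- as.matrix(apply_scaler(sc, df)[feats_f])
    } else {
      Xall <- as.matrix(df_global[sc_glob$features])
    }
    for (cn in names(classifiers)) {
      pred <- classifiers[[cn]](Xall[tr_idx, , drop = FALSE], y[tr_idx],
                                Xall[te_idx, , drop = FALSE],
                                seed = .sub_seed(seed, f))
      m <- .macro_metrics(y[te_idx], pred, lv)
      metrics[[length(metrics) + 1L]] <-
        data.frame(classifier = cn, fold = f, t(m))
      confusion[[cn]] <- confusion[[cn]] +
        unclass(table(factor(y[te_idx], levels = lv), factor(pred, levels = lv)))
    }
  }
  metrics <- do.call(rbind, metrics)
  summ <- do.call(rbind, lapply(split(metrics, metrics$classifier), function(d) {
    data.frame(classifier = d$classifier[1L],
               accuracy = mean(d$accuracy), accuracy_sd = stats::sd(d$accuracy),
               precision = mean(d$precision), recall = mean(d$recall),
               f1 = mean(d$f1), f1_sd = stats::sd(d$f1))
  }))
  summ <- summ[order(-summ$f1), ]
  rownames(summ) <- NULL
  structure(list(metrics = metrics, summary = summ,
                 confusion = confusion, best = summ$classifier[1L],
                 classes = lv, protocol = protocol, seed = seed,
                 standardize = standardize, n = nrow(df),
                 features = features),
            class = "fp_panel")
}

#' @export
print.fp_panel <- function(x, digits = 3, ...) {
  cat(sprintf("<fp_panel> %s on %d rows, %d classes (%s); standardization: %s\n",
              x$protocol, x$n, length(x$classes),
              paste(x$classes, collapse = ", "), x$standardize))
  s <- x$summary
  s[-1] <- lapply(s[-1], round, digits)
  print(s, row.names = FALSE)
  cat("best by mean F1:", x$best, "\n")
  invisible(x)
}

#' @export
summary.fp_panel <- function(object, ...) object$summary

#' Row-normalized confusion matrix (per-class recall)
#'
#' Aggregated over folds; the diagonal holds per-class recall and each row
#' sums to 1.
#'
#' @param report An [train_panel()] result.
#' @param classifier Classifier name (default: the report's best).
#' @return Row-stochastic matrix, rows = true class.
#' @export
confusion <- function(report, classifier = report$best) {
  stopifnot(inherits(report, "fp_panel"))
  cm <- report$confusion[[classifier]]
  if (is.null(cm)) stop("unknown classifier: ", classifier)
  sweep(cm, 1L, pmax(rowSums(cm), 1L), "/")
}

#' Low-dimensional embeddings of a fingerprint table
#'
#' `"lda_1d"` projects standardized features onto the first Fisher linear
#' discriminant (supervised; at most `n_classes - 1` components exist).
#' `"tsne_2d"` runs exact t-SNE (perplexity-calibrated Gaussian affinities,
#' Kullback-Leibler gradient descent with early exaggeration) on the
#' standardized features.
#'
#' @param table A `fingerprint_table` with labels.
#' @param method `"lda_1d"` or `"tsne_2d"`.
#' @param seed Integer seed (t-SNE initialization; identical seeds give
#'   identical layouts).
#' @param class_col Label column for LDA.
#' @param perplexity t-SNE perplexity (reduced automatically for small n).
#' @return Data frame with the embedding coordinate(s) and the class label.
#' @export
embed_fingerprints <- function(table, method = c("lda_1d", "tsne_2d"), seed = 1L,
                               class_col = "medium", perplexity = 30) {
  method <- match.arg(method)
  df <- as.data.frame(table)[!table$flagged, , drop = FALSE]
  std <- standardize_features(as_fingerprint_table(df))
  X <- as.matrix(std[attr(std, "scaler")$features])
  y <- factor(df[[class_col]])
  if (method == "lda_1d") {
    fit <- MASS::lda(X, grouping = y)
    scores <- as.matrix(X %*% fit$scaling[, 1L, drop = FALSE])
    out <- data.frame(ld1 = scores[, 1L])
  } else {
    coords <- .tsne(X, perplexity = perplexity, seed = seed)
    out <- data.frame(tsne1 = coords[, 1L], tsne2 = coords[, 2L])
  }
  out[[class_col]] <- y
  out
}

# Exact (O(n^2)) t-SNE; adequate for fingerprint tables of a few thousand
# rows. Gaussian bandwidths are calibrated per point to the target
# perplexity by bisection; the map is optimized by momentum gradient
# descent with early exaggeration.
.tsne <- function(X, dims = 2L, perplexity = 30, max_iter = 400L, seed = 1L,
                  eta = 100) {
  old_seed <- .save_rng(); on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(as.integer(seed))
  n <- nrow(X)
  perplexity <- max(2, min(perplexity, floor((n - 1) / 3)))
  D2 <- as.matrix(stats::dist(X))^2
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    Di <- D2[i, -i]
    for (it in 1:50) {
      p <- exp(-Di * beta)
      sump <- sum(p)
      H <- log(sump) + beta * sum(Di * p) / sump
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p / sum(p)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  Y <- matrix(stats::rnorm(n * dims, 0, 1e-4), n, dims)
  G <- matrix(0, n, dims)
  gains <- matrix(1, n, dims)
  momentum <- 0.5
  for (iter in seq_len(max_iter)) {
    Pe <- if (iter <= 100L) P * 4 else P
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8)
    gains <- pmax(gains, 0.01)
    G <- momentum * G - eta * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2L, colMeans(Y))
    if (iter == 100L) momentum <- 0.8
  }
  Y
}

#' Tree-SHAP feature importance per class
#'
#' Trains a histogram-mode gradient-boosting model (the panel member) on
#' the standardized table and computes exact tree-SHAP attributions per
#' class; feature importance is the mean absolute attribution across
#' samples, reported per class and ranked by the total across classes.
#'
#' @param table A `fingerprint_table`.
#' @param seed Integer seed.
#' @param top_k Number of top-ranked features to report (default 5).
#' @param class_col Label column.
#' @return An object of class `fp_shap`: list with `importance` (feature x
#'   class matrix of mean absolute attributions, ranking order), `total`,
#'   `top` (the `top_k` feature names), `top_k`.
#' @export
shap_importance <- function(table, seed = 1L, top_k = 5L, class_col = "medium") {
  df <- as.data.frame(table)[!table$flagged, , drop = FALSE]
  std <- standardize_features(as_fingerprint_table(df))
  feats <- attr(std, "scaler")$features
  X <- as.matrix(std[feats])
  y <- factor(df[[class_col]])
  nc <- nlevels(y)
  dtr <- xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L)
  bst <- xgboost::xgb.train(
    params = list(objective = "multi:softprob", num_class = nc,
                  tree_method = "hist", grow_policy = "lossguide",
                  max_depth = 0L, max_leaves = 31L, eta = 0.1,
                  nthread = 1L, seed = as.integer(seed)),
    data = dtr, nrounds = 100L, verbose = 0L)
  contrib <- stats::predict(bst, dtr, predcontrib = TRUE)
  # [n, class, feature + bias] array; drop the bias column
  imp <- t(vapply(seq_len(nc), function(k) {
    colMeans(abs(contrib[, k, seq_along(feats), drop = FALSE])[, 1L, ])
  }, numeric(length(feats))))
  dimnames(imp) <- list(class = levels(y), feature = feats)
  imp <- t(imp)                                   # feature x class
  total <- rowSums(imp)
  ord <- order(total, decreasing = TRUE)
  imp <- imp[ord, , drop = FALSE]
  total <- total[ord]
  structure(list(importance = imp, total = total,
                 top = utils::head(rownames(imp), top_k), top_k = top_k),
            class = "fp_shap")
}

#' @export
print.fp_shap <- function(x, digits = 4, ...) {
  cat(sprintf("<fp_shap> top %d features by total mean |SHAP|:\n", x$top_k))
  print(round(x$importance[x$top, , drop = FALSE], digits))
  invisible(x)
}
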