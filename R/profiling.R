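# Untargeted profiling: SNV normalization, PCA, six-fold cross-validated
# classification, and loading-based marker ranking.

#' Drop uninformative m/z columns
#'
#' Removes grid columns whose intensity is below `threshold` (relative to
#' the base peak, i.e. on base-peak-normalized profiles) in every sample,
#' keeping matrices at desk scale before PCA.
#'
#' @param m Sample-by-m/z matrix.
#' @param threshold Relative intensity floor (default 1e-4).
#' @return The reduced matrix.
#' @export
drop_low_columns <- function(m, threshold = 1e-4) {
  keep <- apply(m, 2, max) >= threshold
  m[, keep, drop = FALSE]
}

#' Standard normal variate (SNV) normalization
#'
#' Transforms each row (sample spectrum) to zero mean and unit standard
#' deviation, the standard spectroscopy row-wise convention; removes
#' per-sample offset and scale before PCA.
#'
#' @param m Sample-by-m/z matrix with non-constant rows.
#' @return Matrix of the same shape with row means 0 and row sds 1.
#' @export
snv_normalize <- function(m) {
  m <- as.matrix(m)
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  zero <- sd == 0 | !is.finite(sd)
  if (any(zero)) {
    who <- rownames(m)[zero] %||% which(zero)
    stop("SNV undefined for zero-variance row(s): ",
         paste(who, collapse = ", "), call. = FALSE)
  }
  (m - mu) / sd
}

#' Principal component analysis of a profile matrix
#'
#' Column-mean-centered PCA by singular value decomposition (no column
#' scaling). The sign of each component is fixed so its largest-magnitude
#' loading is positive, making reports reproducible under the inherent
#' sign indeterminacy.
#'
#' @param m Sample-by-m/z matrix (typically SNV-normalized).
#' @param n_components Number of components to keep; default (and upper
#'   limit, enforced with a warning) is `min(nrow - 1, ncol)`.
#' @return A `pca_model` with `loadings` (m/z-by-component, orthonormal),
#'   `scores` (sample-by-component), `variance_explained` (fraction per
#'   component, non-increasing), `n_components`, `center`.
#' @export
fit_pca <- function(m, n_components = NULL) {
  m <- as.matrix(m)
  stopifnot(nrow(m) >= 2L)
  max_rank <- min(nrow(m) - 1L, ncol(m))
  if (is.null(n_components)) n_components <- max_rank
  if (n_components > max_rank) {
    warning("n_components clipped to ", max_rank, call. = FALSE)
    n_components <- max_rank
  }
  ctr <- colMeans(m)
  x <- sweep(m, 2, ctr)
  sv <- svd(x, nu = max_rank, nv = max_rank)
  k <- seq_len(n_components)
  loadings <- sv$v[, k, drop = FALSE]
  scores <- sv$u[, k, drop = FALSE] %*% diag(sv$d[k], nrow = length(k))
  # sign convention: largest-magnitude loading positive
  for (j in k) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- sv$d^2 / sum(sv$d^2)
  rownames(loadings) <- colnames(m)
  rownames(scores) <- rownames(m)
  colnames(loadings) <- colnames(scores) <- paste0("PC", k)
  structure(list(loadings = loadings, scores = scores,
                 variance_explained = ev[k], n_components = n_components,
                 center = ctr),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("PCA: %d component(s); variance explained: %s\n",
              x$n_components,
              paste(sprintf("%.1f%%", 100 * x$variance_explained),
                    collapse = ", ")))
  invisible(x)
}

.stratified_folds <- function(labels, k) {
  labels <- as.factor(labels)
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    if (length(idx) < k) {
      warning("class '", cl, "' has fewer samples (", length(idx),
              ") than folds (", k, "); best-effort stratification",
              call. = FALSE)
    }
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.fit_predict <- function(algorithm, xtr, ytr, xte) {
  ytr <- droplevels(ytr)
  lev <- levels(ytr)
  if (length(lev) == 1L) {
    prob <- matrix(1, nrow(xte), 1, dimnames = list(NULL, lev))
    return(list(class = factor(rep(lev, nrow(xte)), levels = lev), prob = prob))
  }
  if (algorithm == "bagged_trees") {
    fit <- randomForest::randomForest(x = xtr, y = ytr, ntree = 100,
                                      mtry = ncol(xtr))
    prob <- stats::predict(fit, xte, type = "prob")
  } else if (algorithm == "boosted_trees") {
    dtr <- xgboost::xgb.DMatrix(xtr, label = as.integer(ytr) - 1L)
    fit <- xgboost::xgb.train(
      params = list(objective = "multi:softprob", num_class = length(lev),
                    max_depth = 3, eta = 0.3, nthread = 1, verbosity = 0),
      data = dtr, nrounds = 100)
    prob <- matrix(stats::predict(fit, xgboost::xgb.DMatrix(xte)),
                   ncol = length(lev), byrow = TRUE,
                   dimnames = list(NULL, lev))
  } else {  # linear_svm
    fit <- e1071::svm(x = xtr, y = ytr, kernel = "linear", cost = 1,
                      probability = TRUE)
    pr <- stats::predict(fit, xte, probability = TRUE)
    prob <- attr(pr, "probabilities")[, lev, drop = FALSE]
  }
  cls <- factor(colnames(prob)[max.col(prob, ties.method = "first")],
                levels = lev)
  list(class = cls, prob = prob)
}

#' Cross-validated classification of PCA scores
#'
#' Stratified k-fold cross-validation (default six-fold, suited to small
#' cohorts) of one of three classifiers with fixed, sensible
#' hyperparameters: bagged trees (100 trees, all features per split),
#' boosted trees (100 rounds, depth 3) or a soft-margin linear SVM
#' (C = 1). Deterministic given `seed`.
#'
#' @param scores Sample-by-feature matrix (e.g. `pca$scores`).
#' @param labels Class labels, one per row.
#' @param algorithm `"bagged_trees"`, `"boosted_trees"` or `"linear_svm"`.
#' @param k Number of folds (default 6).
#' @param seed Integer seed controlling fold assignment and classifier
#'   randomness.
#' @return A `cv_report`: `algorithm`, `k_folds`, `accuracy`,
#'   `confusion_matrix` (rows = truth), `per_class_auc` (one-vs-rest),
#'   `predictions` data frame, `seed`.
#' @export
crossval_classify <- function(scores, labels,
                              algorithm = c("bagged_trees", "boosted_trees",
                                            "linear_svm"),
                              k = 6, seed = 1L) {
  algorithm <- match.arg(algorithm)
  scores <- as.matrix(scores)
  labels <- as.factor(labels)
  stopifnot(nrow(scores) == length(labels), nrow(scores) >= k,
            nlevels(labels) >= 2L)
  colnames(scores) <- colnames(scores) %||% paste0("F", seq_len(ncol(scores)))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  fold <- .stratified_folds(labels, k)
  pred <- factor(rep(NA_character_, length(labels)), levels = levels(labels))
  prob <- matrix(NA_real_, length(labels), nlevels(labels),
                 dimnames = list(NULL, levels(labels)))
  for (f in seq_len(k)) {
    te <- which(fold == f)
    tr <- which(fold != f)
    if (!length(te)) next
    out <- .fit_predict(algorithm, scores[tr, , drop = FALSE], labels[tr],
                        scores[te, , drop = FALSE])
    pred[te] <- as.character(out$class)
    prob[te, colnames(out$prob)] <- out$prob
  }
  cm <- table(truth = labels, predicted = pred)
  acc <- sum(diag(cm)) / sum(cm)
  auc <- vapply(levels(labels), function(cl) {
    y <- as.integer(labels == cl)
    if (length(unique(y)) < 2L || all(is.na(prob[, cl]))) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(y, prob[, cl], quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  }, numeric(1))
  structure(list(algorithm = algorithm, k_folds = k, accuracy = acc,
                 confusion_matrix = cm, per_class_auc = auc,
                 predictions = data.frame(truth = labels, predicted = pred,
                                          fold = fold),
                 seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold CV, %s: accuracy %.1f%%\n", x$k_folds, x$algorithm,
              100 * x$accuracy))
  print(x$confusion_matrix)
  invisible(x)
}

# save/restore the global RNG state so seeded CV does not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Rank m/z markers by PCA loading coefficients
#'
#' Orders the m/z variables of one component by signed coefficient and
#' reports both extremes: large positive loadings characterize samples at
#' the positive end of the component, large negative ones the opposite
#' end. Because of PCA sign indeterminacy (fixed here by the largest-
#' loading convention) both ends are always reported.
#'
#' @param pca A `pca_model` from [fit_pca()].
#' @param component Component index (default 1).
#' @param top_n Markers to keep from each extreme (default 10).
#' @return Data frame `mz` (numeric if parseable, else the column name),
#'   `coefficient`, `direction` (`positive`/`negative`), sorted by
#'   descending coefficient.
#' @export
rank_markers <- function(pca, component = 1L, top_n = 10L) {
  stopifnot(component >= 1L, component <= pca$n_components)
  coefs <- pca$loadings[, component]
  o <- order(coefs, decreasing = TRUE)
  n <- length(coefs)
  top_n <- min(top_n, ceiling(n / 2))
  sel <- unique(c(o[seq_len(top_n)], o[seq(n - top_n + 1L, n)]))
  mz_chr <- names(coefs)[sel]
  mz_num <- suppressWarnings(as.numeric(mz_chr))
  data.frame(
    mz = if (anyNA(mz_num)) mz_chr else mz_num,
    coefficient = unname(coefs[sel]),
    direction = ifelse(coefs[sel] >= 0, "positive", "negative"),
    stringsAsFactors = FALSE
  )
}
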