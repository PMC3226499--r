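#' Fisher linear discriminant fit for two classes
#'
#' Computes the Fisher direction `w = S_pooled^-1 (mu1 - mu0)` with a small
#' ridge added to the pooled within-class covariance diagonal, and an
#' intercept placing the decision boundary at the midpoint of the projected
#' class means (equal priors). Deterministic.
#'
#' @param X Numeric matrix, samples x features.
#' @param y Binary labels (logical, 0/1, or two-level factor); `TRUE`/1 is
#'   the positive class.
#' @param ridge Ridge added to the pooled covariance diagonal (default 1e-6).
#' @return An `lda_model` list with `coefficients`, `intercept` and class
#'   means; use [predict.lda_model()] for scores and classes.
#' @export
lda_fit <- function(X, y, ridge = 1e-6) {
  X <- as.matrix(X)
  y <- as_binary(y)
  if (length(unique(y)) < 2)
    stop("both classes must be present", call. = FALSE)
  if (nrow(X) <= ncol(X) + 1)
    stop("need more samples than features + 1", call. = FALSE)
  X0 <- X[y == 0, , drop = FALSE]
  X1 <- X[y == 1, , drop = FALSE]
  mu0 <- colMeans(X0)
  mu1 <- colMeans(X1)
  n0 <- nrow(X0); n1 <- nrow(X1)
  pool <- ((n0 - 1) * cov(X0) + (n1 - 1) * cov(X1)) / (n0 + n1 - 2)
  pool <- pool + diag(ridge, ncol(X))
  w <- tryCatch(solve(pool, mu1 - mu0), error = function(e)
    stop("pooled covariance is singular for this feature subset",
         call. = FALSE))
  structure(list(coefficients = setNames(as.numeric(w), colnames(X)),
                 intercept = -sum(w * (mu0 + mu1) / 2),
                 mu0 = mu0, mu1 = mu1, ridge = ridge),
            class = "lda_model")
}

#' Predict from a Fisher LDA fit
#'
#' @param object An `lda_model` from [lda_fit()].
#' @param newdata Numeric matrix with the same features.
#' @param type `"score"` for the signed discriminant score (positive means
#'   class 1) or `"class"` for 0/1 labels.
#' @param ... Unused.
#' @return Numeric scores or integer classes.
#' @export
predict.lda_model <- function(object, newdata, type = c("score", "class"),
                              ...) {
  type <- match.arg(type)
  s <- as.numeric(as.matrix(newdata) %*% object$coefficients +
                    object$intercept)
  if (type == "score") s else as.integer(s > 0)
}

as_binary <- function(y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1))) stop("labels must be binary", call. = FALSE)
  as.integer(y)
}

#' Balanced accuracy from a confusion matrix
#'
#' The average of sensitivity `tp/(tp+fn)` and specificity `tn/(tn+fp)`.
#'
#' @param tp,fp,tn,fn Confusion-matrix counts.
#' @return Balanced accuracy in \[0, 1\].
#' @export
balanced_accuracy <- function(tp, fp, tn, fn) {
  if (any(c(tp, fp, tn, fn) < 0)) stop("counts must be nonnegative",
                                       call. = FALSE)
  if (tp + fn == 0 || tn + fp == 0)
    stop("both classes must be represented", call. = FALSE)
  (tp / (tp + fn) + tn / (tn + fp)) / 2
}

#' Area under the ROC curve (Mann-Whitney statistic)
#'
#' Rank-based AUC: the probability that a random positive scores above a
#' random negative, with ties credited 0.5 (midranks).
#'
#' @param scores Numeric scores, higher meaning more positive.
#' @param y Binary labels.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, y) {
  y <- as_binary(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified fold assignment: within each class, indices are shuffled under
# the given seed and dealt round-robin into folds.
stratified_folds <- function(y, folds, seed) {
  y <- as_binary(y)
  fold_of <- integer(length(y))
  with_seed(seed, {
    for (cl in c(0, 1)) {
      idx <- sample(which(y == cl))
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold_of
}

# Confusion counts of 0/1 predictions against truth.
confusion <- function(pred, truth) {
  c(tp = sum(pred == 1 & truth == 1), fp = sum(pred == 1 & truth == 0),
    tn = sum(pred == 0 & truth == 0), fn = sum(pred == 0 & truth == 1))
}

# Cross-validated statistics for a fixed feature subset over fixed folds.
# Returns NULL when any fold's fit fails (singular subset).
cv_evaluate <- function(X, y, features, fold_of, ridge) {
  folds <- max(fold_of)
  train_ba <- test_ba <- numeric(folds)
  pooled_scores <- numeric(length(y))
  for (f in seq_len(folds)) {
    tr <- fold_of != f
    fit <- tryCatch(lda_fit(X[tr, features, drop = FALSE], y[tr],
                            ridge = ridge),
                    error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    ptr <- predict(fit, X[tr, features, drop = FALSE], type = "class")
    pte <- predict(fit, X[!tr, features, drop = FALSE], type = "class")
    ctr <- confusion(ptr, y[tr])
    cte <- confusion(pte, y[!tr])
    train_ba[f] <- balanced_accuracy(ctr["tp"], ctr["fp"], ctr["tn"], ctr["fn"])
    test_ba[f] <- balanced_accuracy(cte["tp"], cte["fp"], cte["tn"], cte["fn"])
    pooled_scores[!tr] <- predict(fit, X[!tr, features, drop = FALSE])
  }
  list(train_ba = mean(train_ba), test_ba = mean(test_ba),
       pooled_scores = pooled_scores)
}

# Operating point maximizing Youden's J over pooled held-out scores; ties go
# to the smallest threshold. Predicts positive at score >= threshold.
best_operating_point <- function(scores, y) {
  thr <- sort(unique(scores))
  best <- list(j = -Inf, sens = NA_real_, spec = NA_real_)
  for (t in thr) {
    cc <- confusion(as.integer(scores >= t), y)
    sens <- cc["tp"] / (cc["tp"] + cc["fn"])
    spec <- cc["tn"] / (cc["tn"] + cc["fp"])
    if (sens + spec - 1 > best$j + 1e-12) {
      best <- list(j = sens + spec - 1, sens = unname(sens),
                   spec = unname(spec))
    }
  }
  best
}

#' Forward stepwise LDA signature with stratified cross-validation
#'
#' Starting from the empty model (chance balanced accuracy 0.5), repeatedly
#' adds the feature that maximizes mean held-out balanced accuracy over
#' stratified k-folds, breaking ties by lowest feature index, and stops when
#' the improvement is at most `epsilon` or `max_features` is reached. The
#' final feature set is re-evaluated on the same fold partition for the
#' reported statistics; fold assignment is deterministic given `seed`.
#'
#' "Best" sensitivity and specificity are taken at the operating point
#' maximizing Youden's J on the pooled held-out scores, and AUC is the
#' Mann-Whitney statistic on those scores.
#'
#' @param X Numeric feature matrix, samples x features (e.g. from
#'   [build_feature_matrix()]).
#' @param y Binary labels; each class must have at least `folds` members.
#' @param folds Number of cross-validation folds (default 5).
#' @param seed Integer seed controlling fold assignment.
#' @param max_features Maximum model size (default 10).
#' @param epsilon Minimum balanced-accuracy improvement to keep adding
#'   features (default 1e-6).
#' @param ridge Ridge for [lda_fit()] (default 1e-6).
#' @return A `signature_model`: `features` (in inclusion order),
#'   `coefficients` and `intercept` refit on all samples, `cv_stats`
#'   (`train_ba`, `test_ba`, `sensitivity`, `specificity`, `auc`), `folds`,
#'   `seed`.
#' @export
stepwise_select <- function(X, y, folds = 5, seed = 1, max_features = 10,
                            epsilon = 1e-6, ridge = 1e-6) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  y <- as_binary(y)
  if (min(sum(y == 1), sum(y == 0)) < folds)
    stop("each class needs at least `folds` members", call. = FALSE)
  fold_of <- stratified_folds(y, folds, seed)
  selected <- integer(0)
  current_ba <- 0.5
  while (length(selected) < max_features) {
    cand <- setdiff(seq_len(ncol(X)), selected)
    best_j <- NA_integer_
    best_ba <- -Inf
    for (j in cand) {   # ascending index order implements the tie rule
      ev <- cv_evaluate(X, y, c(selected, j), fold_of, ridge)
      if (!is.null(ev) && ev$test_ba > best_ba) {
        best_ba <- ev$test_ba
        best_j <- j
      }
    }
    if (is.na(best_j) || best_ba - current_ba <= epsilon) break
    selected <- c(selected, best_j)
    current_ba <- best_ba
  }
  if (length(selected) > 0) {
    ev <- cv_evaluate(X, y, selected, fold_of, ridge)
    op <- best_operating_point(ev$pooled_scores, y)
    fit <- lda_fit(X[, selected, drop = FALSE], y, ridge = ridge)
    cv_stats <- list(train_ba = ev$train_ba, test_ba = ev$test_ba,
                     sensitivity = op$sens, specificity = op$spec,
                     auc = auc_score(ev$pooled_scores, y))
    coefs <- fit$coefficients
    intercept <- fit$intercept
  } else {
    cv_stats <- list(train_ba = 0.5, test_ba = 0.5, sensitivity = NA_real_,
                     specificity = NA_real_, auc = 0.5)
    coefs <- numeric(0)
    intercept <- 0
  }
  structure(list(features = colnames(X)[selected], coefficients = coefs,
                 intercept = intercept, cv_stats = cv_stats, folds = folds,
                 seed = seed, n = nrow(X)),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat("<signature_model>\n")
  cat("  features:", if (length(x$features) > 0)
    paste(x$features, collapse = ", ") else "(none)", "\n")
  cat(sprintf("  %d-fold CV (seed %d): BA train %.3f / BA test %.3f, sens %.3f, spec %.3f, AUC %.3f\n",
              x$folds, x$seed, x$cv_stats$train_ba, x$cv_stats$test_ba,
              x$cv_stats$sensitivity, x$cv_stats$specificity,
              x$cv_stats$auc))
  invisible(x)
}

#' Stability of the stepwise signature across repeated runs
#'
#' With `vary_seeds = FALSE` the same seed is reused, so repeated runs must
#' be bit-identical; with `vary_seeds = TRUE` consecutive seeds give the
#' dispersion of the test balanced accuracy across fold partitions.
#' Degenerate inputs (too few samples per class) are reported as NA rather
#' than raising.
#'
#' @param X,y,folds,seed,... As in [stepwise_select()].
#' @param repeats Number of runs (>= 2).
#' @param vary_seeds Re-seed each run (`seed + 0:(repeats-1)`)?
#' @return List with `test_ba` per run, `dispersion` (sd, 0 when all runs
#'   are identical), and `identical` (all cv_stats bit-identical).
#' @export
stability_check <- function(X, y, repeats = 5, folds = 5, seed = 1,
                            vary_seeds = FALSE, ...) {
  if (repeats < 2) stop("repeats must be >= 2", call. = FALSE)
  seeds <- if (vary_seeds) seed + seq_len(repeats) - 1 else rep(seed, repeats)
  runs <- lapply(seeds, function(s) {
    tryCatch(stepwise_select(X, y, folds = folds, seed = s, ...),
             error = function(e) NULL)
  })
  ba <- vapply(runs, function(r)
    if (is.null(r)) NA_real_ else r$cv_stats$test_ba, numeric(1))
  stats_eq <- length(unique(lapply(runs, function(r) r$cv_stats))) == 1
  list(test_ba = ba,
       dispersion = if (all(is.na(ba))) NA_real_ else sd(ba, na.rm = TRUE),
       identical = stats_eq)
}

#' Assemble a unit-scale feature matrix for signature modeling
#'
#' Assay features are [assay_unit_score()]s of every assay column; pathway
#' features are the unit score of each defined chemical-pathway perturbation
#' score, with undefined scores entering as 0 (no perturbation). Feature
#' names carry provenance prefixes `assay:` and `pathway:`.
#'
#' @param m A [potency_matrix()].
#' @param annotations Annotation data.frame.
#' @param config A [vbs_config()] supplying the unit-score transform.
#' @param pathways Optional [pathway_set()] to add pathway features.
#' @param min_targets Activity threshold for pathway scores (default 5).
#' @return Numeric matrix, chemicals x features, no missing values.
#' @export
build_feature_matrix <- function(m, annotations, config = vbs_config(),
                                 pathways = NULL, min_targets = 5) {
  stopifnot(inherits(m, "potency_matrix"))
  X <- matrix(assay_unit_score(unclass(m), config), nrow = nrow(m),
              dimnames = list(rownames(m), paste0("assay:", colnames(m))))
  if (!is.null(pathways)) {
    ps <- score_pathways(m, annotations, pathways, min_targets = min_targets)
    P <- matrix(0, nrow(m), length(pathways$ids),
                dimnames = list(rownames(m),
                                paste0("pathway:", pathways$ids)))
    def <- !is.na(ps$score)
    P[cbind(match(ps$chemical[def], rownames(m)),
            match(ps$pathway[def], pathways$ids))] <-
      assay_unit_score(ps$score[def], config)
    X <- cbind(X, P)
  }
  X
}
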