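# Two-class linear discriminant analysis, written from first principles:
# class means and pooled within-class covariance give the discriminant
# weights; leave-one-out cross-validation yields out-of-sample predictions;
# a label-permutation procedure yields the null accuracy distribution.
# (MASS::lda is used only as an independent cross-check in the test suite.)

.as_feature_matrix <- function(features, ids = NULL) {
  if (inherits(features, "feature_table") ||
      (is.data.frame(features) && "group" %in% names(features))) {
    ids <- ids %||% feature_ids(features)
    X <- as.matrix(features[ids])
    y <- factor(features$group, levels = c("control", "patient"))
    list(X = X, y = y)
  } else {
    stop("expected a feature_table; pass X and labels explicitly to lda_fit")
  }
}

#' Fit per-feature standardization (z-scoring) parameters
#'
#' @param X Numeric matrix (subjects x features).
#' @param rows Fitting rows (default all).
#' @param sd_tol Features with SD below this are dropped with a warning.
#' @return List with `mean`, `sd` and `keep` (retained column indices).
#' @export
zscore_fit <- function(X, rows = seq_len(nrow(X)), sd_tol = 1e-12) {
  if (length(rows) < 2) stop("need >= 2 fitting rows")
  Xf <- X[rows, , drop = FALSE]
  mu <- colMeans(Xf)
  sd <- sqrt(colSums(sweep(Xf, 2, mu)^2) / (nrow(Xf) - 1L))
  keep <- which(sd > sd_tol)
  if (length(keep) < ncol(X)) {
    warning("dropping zero-variance feature(s): ",
            paste(colnames(X)[setdiff(seq_len(ncol(X)), keep)], collapse = ", "))
  }
  list(mean = mu[keep], sd = sd[keep], keep = keep,
       features = colnames(X)[keep])
}

#' Apply (or invert) standardization parameters
#'
#' @param params From [zscore_fit()].
#' @param X Matrix to transform.
#' @param inverse Undo the transformation.
#' @return Transformed matrix restricted to the retained features.
#' @export
zscore_apply <- function(params, X, inverse = FALSE) {
  X <- X[, params$keep, drop = FALSE]
  if (inverse) {
    sweep(sweep(X, 2, params$sd, `*`), 2, params$mean, `+`)
  } else {
    sweep(sweep(X, 2, params$mean), 2, params$sd, `/`)
  }
}

# core weight computation on a plain matrix; y1 logical (TRUE = patient)
.lda_core <- function(X, y1, ridge) {
  X0 <- X[!y1, , drop = FALSE]
  X1 <- X[y1, , drop = FALSE]
  n0 <- nrow(X0); n1 <- nrow(X1)
  m0 <- colMeans(X0); m1 <- colMeans(X1)
  C0 <- sweep(X0, 2, m0); C1 <- sweep(X1, 2, m1)
  S <- (crossprod(C0) + crossprod(C1)) / (n0 + n1 - 2)
  ridge_val <- if (is.null(ridge)) 1e-6 * mean(diag(S)) else ridge
  if (ridge_val > 0) S <- S + diag(ridge_val, ncol(X))
  w <- tryCatch(solve(S, m1 - m0), error = function(e)
    stop("singular pooled covariance; use ridge > 0 (", conditionMessage(e), ")",
         call. = FALSE))
  list(w = w, m0 = m0, m1 = m1, S = S, ridge = ridge_val, n0 = n0, n1 = n1)
}

#' Fit a two-class linear discriminant model
#'
#' The discriminant weight solves `(S_pooled + ridge I) w = mu_patient -
#' mu_control`; the decision threshold lies midway between the projected
#' class means, shifted by the log prior ratio (equal priors by default).
#' With 58 features and cohort-scale samples the pooled covariance is
#' numerically fragile, so a small relative ridge (`1e-6` times the mean
#' covariance diagonal) is applied unless `ridge` is given explicitly;
#' `ridge = 0` is permitted when the covariance has full rank.
#'
#' @param features A `feature_table`, or a numeric matrix.
#' @param labels Class labels (`control`/`patient`); taken from the feature
#'   table's `group` column when omitted.
#' @param ridge Ridge added to the pooled covariance diagonal (`NULL` =
#'   relative default, `0` = none).
#' @param priors Length-2 prior probabilities `(control, patient)`;
#'   `"proportional"` uses class frequencies.
#' @return Object of class `lda_model`.
#' @export
lda_fit <- function(features, labels = NULL, ridge = NULL, priors = c(0.5, 0.5)) {
  if (is.null(labels)) {
    fm <- .as_feature_matrix(features)
    X <- fm$X; y <- fm$y
  } else {
    X <- as.matrix(features)
    y <- factor(labels, levels = c("control", "patient"))
  }
  if (anyNA(X)) stop("missing feature values; impute or drop before lda_fit")
  if (min(table(y)) < 2) stop("both classes need >= 2 rows")
  if (identical(priors, "proportional")) priors <- as.numeric(table(y) / length(y))
  y1 <- y == "patient"
  core <- .lda_core(X, y1, ridge)
  threshold <- 0.5 * sum(core$w * (core$m0 + core$m1)) - log(priors[2] / priors[1])
  structure(list(weights = core$w, mean_control = core$m0,
                 mean_patient = core$m1, cov_pooled = core$S,
                 ridge = core$ridge, threshold = threshold, priors = priors,
                 features = colnames(X), n = c(control = core$n0, patient = core$n1)),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat("<lda_model> ", length(x$weights), " features; n = (",
      x$n["control"], " control, ", x$n["patient"], " patient); ridge ",
      format(x$ridge), "\n", sep = "")
  invisible(x)
}

#' Predict group membership with a fitted LDA model
#'
#' Scores are `w . x - threshold`; positive scores classify as patient,
#' negative as control, and an exact zero deterministically as control.
#'
#' @param model An `lda_model`.
#' @param X Matrix (or single row) over the model's features.
#' @return data.frame with `score` and `group`.
#' @export
lda_predict <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1, dimnames = list(NULL, names(X)))
  X <- as.matrix(X)
  if (!is.null(colnames(X))) {
    miss <- setdiff(model$features, colnames(X))
    if (length(miss)) stop("missing feature(s): ", paste(miss, collapse = ", "))
    X <- X[, model$features, drop = FALSE]
  } else if (ncol(X) != length(model$weights)) {
    stop("feature count mismatch")
  }
  score <- as.numeric(X %*% model$weights) - model$threshold
  data.frame(score = score,
             group = factor(ifelse(score > 0, "patient", "control"),
                            levels = c("control", "patient")))
}

#' Leave-one-out cross-validated LDA predictions
#'
#' For each subject, standardization parameters and the LDA model are fitted
#' on the other `n - 1` subjects only (no leakage), and the held-out subject
#' is predicted out-of-sample. `standardize = "global"` reproduces a
#' whole-sample z-scoring before the folds, `"none"` skips scaling.
#'
#' @param features `feature_table` or matrix.
#' @param labels Labels (see [lda_fit()]).
#' @param ridge,priors Passed to the per-fold fit.
#' @param standardize `"fold"` (default), `"global"` or `"none"`.
#' @return Object of class `cv_result` with per-subject predictions, the
#'   confusion matrix and overall accuracy.
#' @export
loocv <- function(features, labels = NULL, ridge = NULL, priors = c(0.5, 0.5),
                  standardize = c("fold", "global", "none")) {
  standardize <- match.arg(standardize)
  if (is.null(labels)) {
    fm <- .as_feature_matrix(features)
    X <- fm$X; y <- fm$y
  } else {
    X <- as.matrix(features)
    y <- factor(labels, levels = c("control", "patient"))
  }
  n <- nrow(X)
  if (n < 4 || min(table(y)) < 2) stop("need n >= 4 with >= 2 per class")
  if (identical(priors, "proportional")) priors <- as.numeric(table(y) / length(y))
  if (standardize == "global") {
    X <- zscore_apply(zscore_fit(X), X)
  }
  y1 <- y == "patient"
  pred <- factor(rep(NA_character_, n), levels = c("control", "patient"))
  score <- rep(NA_real_, n)

  # Each fold removes one subject, so the per-fold class means, pooled
  # within-class scatter and (for fold standardization) per-feature
  # mean/variance are exact rank-one downdates of whole-sample statistics;
  # z-scoring is affine per feature, so the fold's covariance and means are
  # rescaled rather than recomputed. Algebraically identical to refitting
  # each fold from scratch (the test suite checks this against a naive
  # refit), but O(p^2) per fold.
  p <- ncol(X)
  X0 <- X[!y1, , drop = FALSE]; X1 <- X[y1, , drop = FALSE]
  G0 <- crossprod(X0); G1 <- crossprod(X1)
  s0 <- colSums(X0); s1 <- colSums(X1)
  n0 <- nrow(X0); n1 <- nrow(X1)
  s_tot <- s0 + s1
  ss_tot <- colSums(X^2)
  log_prior <- log(priors[2] / priors[1])
  for (i in seq_len(n)) {
    xi <- X[i, ]
    if (y1[i]) {
      n1p <- n1 - 1L; n0p <- n0
      if (n1p < 1L) { warning("fold ", i, " lost an entire class; subject unpredictable"); next }
      m1 <- (s1 - xi) / n1p; m0 <- s0 / n0
      P <- (G0 - n0p * tcrossprod(m0)) +
        (G1 - tcrossprod(xi) - n1p * tcrossprod(m1))
    } else {
      n0p <- n0 - 1L; n1p <- n1
      if (n0p < 1L) { warning("fold ", i, " lost an entire class; subject unpredictable"); next }
      m0 <- (s0 - xi) / n0p; m1 <- s1 / n1
      P <- (G0 - tcrossprod(xi) - n0p * tcrossprod(m0)) +
        (G1 - n1p * tcrossprod(m1))
    }
    nt <- n - 1L
    S <- P / (nt - 2L)
    if (standardize == "fold") {
      mu <- (s_tot - xi) / nt
      va <- (ss_tot - xi^2 - nt * mu^2) / (nt - 1L)
      sdv <- sqrt(pmax(va, 0))
      keep <- sdv > 1e-12
      S <- (S / sdv)[keep, keep, drop = FALSE] / rep(sdv[keep], each = sum(keep))
      mz0 <- ((m0 - mu) / sdv)[keep]; mz1 <- ((m1 - mu) / sdv)[keep]
      xz <- ((xi - mu) / sdv)[keep]
    } else {
      mz0 <- m0; mz1 <- m1; xz <- xi
    }
    ridge_val <- if (is.null(ridge)) 1e-6 * mean(diag(S)) else ridge
    if (ridge_val > 0) S <- S + diag(ridge_val, nrow(S))
    w <- tryCatch(solve(S, mz1 - mz0), error = function(e)
      stop("singular pooled covariance in fold ", i,
           "; use ridge > 0 (", conditionMessage(e), ")", call. = FALSE))
    s <- sum(xz * w) - (0.5 * sum(w * (mz0 + mz1)) - log_prior)
    score[i] <- s
    pred[i] <- if (s > 0) "patient" else "control"
  }
  ok <- !is.na(pred)
  cm <- table(predicted = pred[ok], truth = y[ok])
  structure(list(predicted = pred, truth = y, score = score,
                 confusion = cm, accuracy = sum(diag(cm)) / sum(cm),
                 n_predicted = sum(ok)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> accuracy ", format(round(x$accuracy, 4)), " (",
      x$n_predicted, " subjects)\n", sep = "")
  print(x$confusion)
  invisible(x)
}

#' Overall accuracy from a confusion matrix
#'
#' @param confusion Square table/matrix of predicted x true counts.
#' @return Proportion correct (diagonal sum over total).
#' @export
confusion_accuracy <- function(confusion) {
  confusion <- as.matrix(confusion)
  sum(diag(confusion)) / sum(confusion)
}

#' Label-permutation null for the LOOCV accuracy
#'
#' Repeats the full leave-one-out procedure `B` times with the group labels
#' uniformly shuffled, forming the null distribution of the accuracy. The
#' p-value uses the add-one permutation estimator
#' `(1 + #\{null >= observed\}) / (B + 1)`.
#'
#' @param features,labels,ridge,priors,standardize As [loocv()].
#' @param B Number of permutations.
#' @param seed RNG seed (required for reproducibility).
#' @return Object of class `permutation_result`: `observed`, `null`
#'   (length `B`), `p_value`, `B`, `seed`.
#' @export
permutation_test <- function(features, labels = NULL, B = 10000L, seed = 1L,
                             ridge = NULL, priors = c(0.5, 0.5),
                             standardize = "fold") {
  if (B < 1) stop("B must be >= 1")
  if (is.null(labels)) {
    fm <- .as_feature_matrix(features)
    X <- fm$X; y <- fm$y
  } else {
    X <- as.matrix(features)
    y <- factor(labels, levels = c("control", "patient"))
  }
  obs <- loocv(X, y, ridge = ridge, priors = priors, standardize = standardize)
  null_acc <- numeric(B)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (b in seq_len(B)) {
    yp <- sample(y)
    null_acc[b] <- loocv(X, yp, ridge = ridge, priors = priors,
                         standardize = standardize)$accuracy
  }
  structure(list(observed = obs$accuracy, null = null_acc,
                 p_value = (1 + sum(null_acc >= obs$accuracy)) / (B + 1),
                 B = B, seed = seed, cv = obs),
            class = "permutation_result")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("<permutation_result> observed accuracy ", format(round(x$observed, 4)),
      ", p = ", format(x$p_value), " (B = ", x$B, ")\n", sep = "")
  invisible(x)
}

#' Standardized discriminant loadings
#'
#' Fits the LDA on the z-scored full sample and reports each feature's
#' loading coefficient; because all features are on a common scale, the
#' absolute magnitudes rank their contribution to the separation. Ranking
#' ties are broken lexicographically by feature id.
#'
#' @param features,labels,ridge,priors As [lda_fit()].
#' @return data.frame `feature`, `loading`, `rank`, ordered by decreasing
#'   absolute loading.
#' @export
lda_loadings <- function(features, labels = NULL, ridge = NULL,
                         priors = c(0.5, 0.5)) {
  if (is.null(labels)) {
    fm <- .as_feature_matrix(features)
    X <- fm$X; y <- fm$y
  } else {
    X <- as.matrix(features)
    y <- factor(labels, levels = c("control", "patient"))
  }
  zp <- zscore_fit(X)
  Z <- zscore_apply(zp, X)
  fit <- lda_fit(Z, y, ridge = ridge, priors = priors)
  ord <- order(-abs(fit$weights), colnames(Z))
  data.frame(feature = colnames(Z)[ord], loading = unname(fit$weights[ord]),
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

#' Box's M test for homogeneity of covariance matrices
#'
#' Chi-square approximation to Box's M comparing the class covariance
#' matrices (df `p (p + 1) (k - 1) / 2`). Requires more observations than
#' features in every class.
#'
#' @param X Numeric matrix.
#' @param labels Class labels.
#' @return List with `M`, `chi_sq`, `df`, `p`.
#' @export
box_m_test <- function(X, labels) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(labels))
  k <- nlevels(y)
  p <- ncol(X)
  ns <- table(y)
  if (any(ns <= p)) {
    stop("Box's M needs n > p in every class (have n = ",
         paste(ns, collapse = ","), ", p = ", p,
         "); reduce the feature set or use a ridge-regularized comparison")
  }
  N <- nrow(X)
  Si <- lapply(levels(y), function(l) stats::cov(X[y == l, , drop = FALSE]))
  Sp <- Reduce(`+`, Map(function(S, n) (n - 1) * S, Si, as.list(as.numeric(ns)))) / (N - k)
  logdet <- function(S) determinant(S, logarithm = TRUE)$modulus
  M <- (N - k) * logdet(Sp) - sum((as.numeric(ns) - 1) * vapply(Si, logdet, 0))
  c1 <- (2 * p^2 + 3 * p - 1) / (6 * (p + 1) * (k - 1)) *
    (sum(1 / (as.numeric(ns) - 1)) - 1 / (N - k))
  chi <- as.numeric(M * (1 - c1))
  df <- p * (p + 1) * (k - 1) / 2
  list(M = as.numeric(M), chi_sq = chi, df = df,
       p = stats::pchisq(chi, df, lower.tail = FALSE))
}
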