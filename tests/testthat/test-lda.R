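test_that("z-scoring fits, inverts, and drops constant features", {
  set.seed(51)
  X <- cbind(a = stats::rnorm(20, 5, 2), b = stats::rnorm(20), const = 1)
  expect_warning(zp <- zscore_fit(X), "const")
  Z <- zscore_apply(zp, X)
  expect_lt(max(abs(colMeans(Z))), 1e-9)
  expect_lt(max(abs(apply(Z, 2, stats::sd) - 1)), 1e-9)
  expect_equal(zscore_apply(zp, Z, inverse = TRUE), X[, c("a", "b")],
               tolerance = 1e-9)
  # parameters fit on a training subset never see the held-out row
  rows <- 1:19
  zp1 <- suppressWarnings(zscore_fit(X, rows))
  X2 <- X; X2[20, ] <- X2[20, ] + 100
  zp2 <- suppressWarnings(zscore_fit(X2, rows))
  expect_identical(zp1, zp2)
})

test_that("one-dimensional LDA has the midpoint boundary and perfect LOOCV", {
  set.seed(52)
  x <- matrix(c(stats::rnorm(20, 0), stats::rnorm(20, 10)), ncol = 1,
              dimnames = list(NULL, "f"))
  lab <- rep(c("control", "patient"), each = 20)
  fit <- lda_fit(x, lab, ridge = 0)
  boundary <- fit$threshold / fit$weights
  expect_equal(unname(boundary), (mean(x[1:20]) + mean(x[21:40])) / 2,
               tolerance = 1e-9)
  expect_equal(loocv(x, lab, standardize = "none")$accuracy, 1.0)
})

test_that("a two-feature toy matches the closed-form 2x2 solution", {
  X <- rbind(c(0, 0), c(1, 1), c(0, 1), c(4, 3), c(5, 4), c(4, 4))
  colnames(X) <- c("u", "v")
  lab <- rep(c("control", "patient"), each = 3)
  fit <- lda_fit(X, lab, ridge = 0)
  m0 <- colMeans(X[1:3, ]); m1 <- colMeans(X[4:6, ])
  S <- (stats::cov(X[1:3, ]) * 2 + stats::cov(X[4:6, ]) * 2) / 4
  inv <- solve(S)  # explicit 2x2 inverse via solve as an independent route
  det2 <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
  inv_hand <- matrix(c(S[2, 2], -S[2, 1], -S[1, 2], S[1, 1]), 2) / det2
  expect_equal(inv, inv_hand, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(fit$weights), unname(as.numeric(inv_hand %*% (m1 - m0))),
               tolerance = 1e-9)
})

test_that("prediction ties at the boundary resolve to control", {
  x <- matrix(c(-1, 1, 3, 5), ncol = 1, dimnames = list(NULL, "f"))
  fit <- lda_fit(x, c("control", "control", "patient", "patient"), ridge = 0)
  at_mid <- matrix(2, 1, 1, dimnames = list(NULL, "f"))
  pr <- lda_predict(fit, at_mid)
  expect_equal(pr$score, 0, tolerance = 1e-12)
  expect_equal(as.character(pr$group), "control")
  expect_error(lda_predict(fit, matrix(1, 1, 1, dimnames = list(NULL, "g"))),
               "missing feature")
})

test_that("from-scratch predictions match the reference implementation", {
  set.seed(53)
  for (rep in 1:10) {
    inst <- random_lda_instance(n = 30, p = 4, shift = stats::runif(1, 0, 2))
    fit <- lda_fit(inst$X, inst$labels, ridge = 0)
    ours <- lda_predict(fit, inst$X)$group
    ref <- MASS::lda(inst$X, grouping = factor(inst$labels,
                                               levels = c("control", "patient")),
                     prior = c(0.5, 0.5))
    theirs <- predict(ref, inst$X)$class
    expect_identical(as.character(ours), as.character(theirs))
  }
})

test_that("fast LOOCV equals a naive per-fold refit", {
  set.seed(54)
  for (rep in 1:4) {
    inst <- random_lda_instance(n = 26, p = 5, shift = stats::runif(1, 0, 1.5))
    fast <- loocv(inst$X, inst$labels)
    naive <- naive_loocv_labels(inst$X, inst$labels)
    expect_identical(as.character(fast$predicted), naive)
    expect_equal(fast$accuracy,
                 mean(naive == inst$labels))
  }
})

test_that("altering the held-out subject never changes the fold's model", {
  set.seed(55)
  inst <- random_lda_instance(n = 20, p = 3, shift = 1)
  y <- factor(inst$labels, levels = c("control", "patient"))
  fold_weights <- function(X, i) {
    tr <- setdiff(seq_len(nrow(X)), i)
    zp <- zscore_fit(X[tr, , drop = FALSE])
    lda_fit(zscore_apply(zp, X[tr, , drop = FALSE]), y[tr])$weights
  }
  X2 <- inst$X
  X2[7, ] <- X2[7, ] + 50
  expect_identical(fold_weights(inst$X, 7), fold_weights(X2, 7))
})

test_that("permutation test is seed-deterministic with a valid p estimator", {
  set.seed(56)
  inst <- random_lda_instance(n = 24, p = 3, shift = 4)
  p1 <- permutation_test(inst$X, inst$labels, B = 49, seed = 11)
  p2 <- permutation_test(inst$X, inst$labels, B = 49, seed = 11)
  expect_identical(p1$null, p2$null)
  expect_identical(p1$p_value, p2$p_value)
  expect_equal(p1$p_value,
               (1 + sum(p1$null >= p1$observed)) / (49 + 1))
  # strongly separated classes: no permutation should reach the observed 1.0
  expect_equal(p1$observed, 1.0)
  expect_lte(p1$p_value, 2 / 50)
})

test_that("loadings rank the informative feature and ignore raw scales", {
  set.seed(57)
  X <- matrix(stats::rnorm(60 * 5), 60)
  colnames(X) <- paste0("f", 1:5)
  lab <- rep(c("control", "patient"), each = 30)
  X[lab == "patient", 3] <- X[lab == "patient", 3] + 3
  ld <- lda_loadings(X, lab)
  expect_equal(ld$feature[1], "f3")
  # pre-scaling features leaves standardized loadings unchanged
  Xs <- sweep(X, 2, c(10, 0.1, 3, 100, 0.5), `*`)
  lds <- lda_loadings(Xs, lab)
  expect_equal(ld$loading, lds$loading, tolerance = 1e-9)
  # duplicated feature with ridge: deterministic lexicographic tie-break
  Xd <- cbind(X[, 3, drop = FALSE], X[, 3, drop = FALSE], X[, 1:2])
  colnames(Xd) <- c("dup_a", "dup_b", "f1", "f2")
  ldd <- lda_loadings(Xd, lab, ridge = 0.1)
  expect_equal(abs(ldd$loading[1]), abs(ldd$loading[2]), tolerance = 1e-9)
  expect_identical(ldd$feature[1:2], c("dup_a", "dup_b"))
})

test_that("Box's M agrees with Bartlett for one feature and detects inflation", {
  set.seed(58)
  x <- matrix(stats::rnorm(120), ncol = 1, dimnames = list(NULL, "f"))
  lab <- rep(c("control", "patient"), each = 60)
  bm <- box_m_test(x, lab)
  bt <- stats::bartlett.test(x[, 1], lab)
  expect_equal(bm$chi_sq, unname(bt$statistic), tolerance = 0.05)
  expect_equal(bm$p, bt$p.value, tolerance = 0.02)
  # a 4x covariance inflation in one class at n = 200/class, p = 3
  X <- rbind(matrix(stats::rnorm(200 * 3), 200),
             matrix(stats::rnorm(200 * 3, sd = 2), 200))
  colnames(X) <- paste0("f", 1:3)
  lab2 <- rep(c("control", "patient"), each = 200)
  expect_lt(box_m_test(X, lab2)$p, 0.01)
  expect_error(box_m_test(matrix(stats::rnorm(12), 4), c("a", "a", "b", "b")),
               "n > p")
})

test_that("confusion accuracy is the diagonal proportion", {
  cm <- matrix(c(9, 1, 2, 8), 2)
  expect_equal(confusion_accuracy(cm), 17 / 20)
})
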