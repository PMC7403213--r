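# Shared fixtures, built in code.

template_scan <- function(mesh = FALSE, sex = "male", group = "control") {
  face_scan("template", sex, group, template_face(),
            mesh = if (mesh) template_head_mesh() else NULL, aligned = TRUE)
}

# random rotation matrix (uniform axis, bounded angle)
random_rotation <- function(max_angle = pi) {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, -max_angle, max_angle)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

rigidly_moved <- function(scan, R = random_rotation(), t = stats::runif(3, -50, 50)) {
  co <- sweep(scan$coords %*% t(R), 2, t, `+`)
  mesh <- scan$mesh
  if (!is.null(mesh)) mesh$vertices <- sweep(mesh$vertices %*% t(R), 2, t, `+`)
  face_scan(scan$subject_id, scan$sex, scan$group, co, mesh)
}

# axis-aligned unit cube surface as 12 triangles
unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = 1
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = 1
  face_mesh(v, f)
}

# a small random cohort feature matrix with an optional class shift
random_lda_instance <- function(n = 30L, p = 4L, shift = 0) {
  X <- matrix(stats::rnorm(n * p), n)
  colnames(X) <- paste0("f", seq_len(p))
  lab <- rep(c("control", "patient"), length.out = n)
  X[lab == "patient", 1] <- X[lab == "patient", 1] + shift
  list(X = X, labels = lab)
}

naive_loocv_labels <- function(X, labels, ridge = NULL, priors = c(0.5, 0.5)) {
  y <- factor(labels, levels = c("control", "patient"))
  n <- nrow(X)
  pred <- character(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    zp <- suppressWarnings(zscore_fit(X[tr, , drop = FALSE]))
    fit <- lda_fit(zscore_apply(zp, X[tr, , drop = FALSE]), y[tr],
                   ridge = ridge, priors = priors)
    pred[i] <- as.character(lda_predict(fit, zscore_apply(zp, X[i, , drop = FALSE]))$group)
  }
  pred
}
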