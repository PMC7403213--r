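# Univariate sex-by-disease screening battery: Levene homogeneity checks,
# two-way ANOVA per variable, within-sex post-hoc pooled t-tests, Bonferroni
# filtering, and the count/direction summaries.

#' Cohort design from a feature table
#'
#' @param features A `feature_table` (or data.frame with `sex` and `group`).
#' @return List with per-cell counts `n_mc`, `n_mp`, `n_fc`, `n_fp` and the
#'   sex/group factors.
#' @export
cohort_design <- function(features) {
  sex <- factor(features$sex, levels = c("male", "female"))
  group <- factor(features$group, levels = c("control", "patient"))
  n <- table(sex, group)
  list(sex = sex, group = group,
       n_mc = n["male", "control"], n_mp = n["male", "patient"],
       n_fc = n["female", "control"], n_fp = n["female", "patient"])
}

#' Levene's homogeneity-of-variance test
#'
#' Classic mean-centered Levene test (per-cell absolute deviations from the
#' cell mean, one-way ANOVA across cells); `center = "median"` gives the
#' Brown-Forsythe variant.
#'
#' @param values Numeric vector.
#' @param cells Factor (or coercible) of cell labels, each with >= 2
#'   observations.
#' @param center `"mean"` (default) or `"median"`.
#' @return List with `W` (the F statistic), `df1`, `df2` and `p`.
#' @export
levene_test <- function(values, cells, center = c("mean", "median")) {
  center <- match.arg(center)
  cells <- droplevels(as.factor(cells))
  if (any(table(cells) < 2)) stop("each cell needs at least 2 observations")
  if (anyNA(values)) stop("missing values in levene_test")
  z <- abs(values - stats::ave(values, cells,
                               FUN = if (center == "mean") mean else stats::median))
  if (all(abs(z - mean(z)) < 1e-300)) {  # all deviations equal -> no evidence
    return(list(W = 0, df1 = nlevels(cells) - 1L,
                df2 = length(values) - nlevels(cells), p = 1))
  }
  fit <- stats::anova(stats::lm(z ~ cells))
  list(W = fit$`F value`[1], df1 = fit$Df[1], df2 = fit$Df[2],
       p = fit$`Pr(>F)`[1])
}

#' Two-way sex-by-disease ANOVA for one variable
#'
#' Fits `value ~ sex * group` and reports F and p for the disease main
#' effect, the sex (gender) main effect and their interaction. The design is
#' unbalanced across sexes, so sums of squares default to Type II
#' (each main effect adjusted for the other, interaction adjusted for both);
#' Type I (sequential) and Type III are available.
#'
#' @param values Numeric vector.
#' @param sex,group Factors (male/female, control/patient).
#' @param ss_type `"II"` (default), `"I"` or `"III"`.
#' @return List with `p_disease`, `p_gender`, `p_interaction`, the F
#'   statistics, dfs, and `ss_type`.
#' @export
two_way_anova <- function(values, sex, group, ss_type = c("II", "I", "III")) {
  ss_type <- match.arg(ss_type)
  sex <- factor(sex); group <- factor(group)
  if (any(table(sex, group) == 0)) stop("empty sex-by-group cell")
  if (anyNA(values)) stop("missing values in two_way_anova")
  y <- as.numeric(values)
  n <- length(y)
  # sum-coded design columns; sums of squares via explicit nested-model
  # residual comparisons (equivalent to car::Anova, which the test suite
  # cross-checks, but robust to zero residual variance)
  s <- ifelse(sex == levels(sex)[1], 1, -1)
  g <- ifelse(group == levels(group)[1], 1, -1)
  one <- rep(1, n)
  rss <- function(...) {
    X <- cbind(one, ...)
    sum(stats::lm.fit(X, y)$residuals^2)
  }
  r_full <- rss(s, g, s * g)
  r_sg <- rss(s, g)
  ss <- switch(ss_type,
    II = c(gender = rss(g) - r_sg, disease = rss(s) - r_sg,
           interaction = r_sg - r_full),
    I = c(gender = rss() - rss(s), disease = rss(s) - r_sg,
          interaction = r_sg - r_full),
    III = c(gender = rss(g, s * g) - r_full, disease = rss(s, s * g) - r_full,
            interaction = r_sg - r_full))
  df_res <- n - 4L
  scale_y <- sum((y - mean(y))^2)
  if (r_full <= 1e-12 * max(scale_y, 1e-300)) {
    # zero residual variance: any non-zero effect sum of squares is
    # infinitely significant, an exactly zero one carries no evidence
    tol <- 1e-9 * max(scale_y, 1e-300)
    Fv <- ifelse(ss > tol, Inf, 0)
    pv <- ifelse(ss > tol, 0, 1)
  } else {
    mse <- r_full / df_res
    Fv <- ss / mse
    pv <- stats::pf(Fv, 1, df_res, lower.tail = FALSE)
  }
  list(p_disease = unname(pv["disease"]),
       p_gender = unname(pv["gender"]),
       p_interaction = unname(pv["interaction"]),
       F_disease = unname(Fv["disease"]),
       F_gender = unname(Fv["gender"]),
       F_interaction = unname(Fv["interaction"]),
       df_effect = c(disease = 1L, gender = 1L, interaction = 1L),
       df_residual = df_res,
       ss_type = ss_type)
}

#' Pooled-variance two-sample t-test
#'
#' Student's independent-samples t-test with pooled variance (the
#' homogeneity-of-variance assumption is screened by [levene_test()]);
#' `welch = TRUE` switches to the Welch test.
#'
#' @param a,b Numeric vectors (>= 2 observations each).
#' @param welch Use Welch's unequal-variance test.
#' @return List with `t`, `df`, `p`, `mean_diff` (`mean(a) - mean(b)`) and a
#'   `degenerate` flag (zero pooled variance).
#' @export
pooled_t_test <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2) stop("need >= 2 observations per group")
  if (stats::var(a) + stats::var(b) == 0) {
    return(.t_degenerate(mean(a) - mean(b), length(a) + length(b) - 2L))
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
       mean_diff = mean(a) - mean(b), degenerate = FALSE)
}

.t_degenerate <- function(mean_diff, df) {
  list(t = if (mean_diff == 0) 0 else sign(mean_diff) * Inf, df = df,
       p = if (mean_diff == 0) 1 else 0, mean_diff = mean_diff,
       degenerate = TRUE)
}

#' Pooled t-test from summary statistics
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b Group summaries.
#' @return As [pooled_t_test()].
#' @export
t_test_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (n_a < 2 || n_b < 2) stop("need >= 2 observations per group")
  df <- n_a + n_b - 2
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
  if (sp2 == 0) return(.t_degenerate(mean_a - mean_b, df))
  tval <- (mean_a - mean_b) / sqrt(sp2 * (1 / n_a + 1 / n_b))
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df),
       mean_diff = mean_a - mean_b, degenerate = FALSE)
}

#' Bonferroni family-wise significance threshold
#'
#' @param alpha Family-wise level in (0, 1).
#' @param m Number of tests (>= 1).
#' @return `alpha / m`, the per-test threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 58L) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

#' Bonferroni significance filter and count summary
#'
#' Flags each variable's p-values against a strict threshold (`p < threshold`)
#' and reports per-column counts plus the disease-by-gender and
#' male-by-female post-hoc overlaps. Variables with a missing p-value in a
#' column are excluded from that column's counts and reported.
#'
#' @param p_table data.frame with a `variable` column (or row names) and any
#'   of the p-value columns `p_disease`, `p_gender`, `p_interaction`,
#'   `p_t_male`, `p_t_female`.
#' @param threshold Per-test significance threshold (e.g.
#'   [bonferroni_threshold()]).
#' @return Object of class `significance_summary`: the flag matrix, counts,
#'   overlap counts, the threshold and excluded variables.
#' @export
significance_filter <- function(p_table, threshold) {
  p_table <- as.data.frame(p_table)
  if (!"variable" %in% names(p_table)) {
    p_table$variable <- if (!is.null(rownames(p_table))) rownames(p_table) else
      seq_len(nrow(p_table))
  }
  cols <- intersect(c("p_disease", "p_gender", "p_interaction",
                      "p_t_male", "p_t_female"), names(p_table))
  if (!length(cols)) stop("no p-value columns found")
  P <- as.matrix(p_table[cols])
  if (any(P < 0 | P > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  flags <- P < threshold          # strict inequality; NA propagates
  rownames(flags) <- p_table$variable
  counts <- stats::setNames(as.integer(colSums(flags, na.rm = TRUE)),
                            sub("^p_", "", cols))
  overlaps <- integer(0)
  if (all(c("p_disease", "p_gender") %in% cols)) {
    overlaps["disease_gender"] <- sum(flags[, "p_disease"] & flags[, "p_gender"],
                                      na.rm = TRUE)
  }
  if (all(c("p_t_male", "p_t_female") %in% cols)) {
    overlaps["t_male_t_female"] <- sum(flags[, "p_t_male"] & flags[, "p_t_female"],
                                       na.rm = TRUE)
  }
  excluded <- p_table$variable[apply(is.na(P), 1, any)]
  structure(list(threshold = threshold, flags = flags, counts = counts,
                 overlaps = overlaps, excluded = excluded),
            class = "significance_summary")
}

#' @export
print.significance_summary <- function(x, ...) {
  cat("<significance_summary> threshold ", format(x$threshold), "\n", sep = "")
  print(x$counts)
  if (length(x$overlaps)) print(x$overlaps)
  if (length(x$excluded)) cat("excluded:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Direction of the disease effect for flagged variables
#'
#' For each disease-significant variable, pools the patient and control cell
#' means weighted by cell size and classifies the variable as higher or lower
#' in patients (an exact zero difference is a tie, counted in neither).
#'
#' @param cell_means data.frame/matrix with columns `mc_mean`, `mp_mean`,
#'   `fc_mean`, `fp_mean` and variable ids as row names or a `variable`
#'   column.
#' @param cell_ns Named counts `c(mc=, mp=, fc=, fp=)`.
#' @param disease_flags Logical vector (same order) marking
#'   disease-significant variables.
#' @return List with `direction` (per flagged variable:
#'   `"higher_in_patients"`, `"lower_in_patients"` or `"tie"`), `n_higher`,
#'   `n_lower` and the signed pooled differences.
#' @export
direction_summary <- function(cell_means, cell_ns, disease_flags) {
  cm <- as.data.frame(cell_means)
  vars <- if ("variable" %in% names(cm)) cm$variable else rownames(cm)
  pat <- (cell_ns[["mp"]] * cm$mp_mean + cell_ns[["fp"]] * cm$fp_mean) /
    (cell_ns[["mp"]] + cell_ns[["fp"]])
  con <- (cell_ns[["mc"]] * cm$mc_mean + cell_ns[["fc"]] * cm$fc_mean) /
    (cell_ns[["mc"]] + cell_ns[["fc"]])
  diff <- pat - con
  names(diff) <- vars
  flagged <- which(disease_flags)
  dir <- ifelse(diff[flagged] > 0, "higher_in_patients",
                ifelse(diff[flagged] < 0, "lower_in_patients", "tie"))
  list(direction = dir,
       n_higher = sum(dir == "higher_in_patients"),
       n_lower = sum(dir == "lower_in_patients"),
       pooled_diff = diff)
}

#' Full per-variable univariate report
#'
#' One row per measurement in catalog order: per-cell means and SDs, the
#' Levene check, two-way ANOVA p-values, and within-sex post-hoc pooled
#' t-test p-values. Variables with any empty cell, or missing values, are
#' flagged incomplete and carry `NA` statistics.
#'
#' @param features A `feature_table`.
#' @param ss_type ANOVA sums-of-squares type (see [two_way_anova()]).
#' @return data.frame with one row per variable.
#' @export
univariate_battery <- function(features, ss_type = "II") {
  des <- cohort_design(features)
  ids <- feature_ids(features)
  male <- features$sex == "male"; fem <- !male
  pat <- features$group == "patient"; con <- !pat
  rows <- lapply(ids, function(id) {
    y <- features[[id]]
    base <- data.frame(variable = id,
                       mc_mean = NA, mc_sd = NA, mp_mean = NA, mp_sd = NA,
                       fc_mean = NA, fc_sd = NA, fp_mean = NA, fp_sd = NA,
                       levene_p = NA, p_disease = NA, p_gender = NA,
                       p_interaction = NA, p_t_male = NA, p_t_female = NA,
                       incomplete = TRUE, stringsAsFactors = FALSE)
    cells <- list(mc = y[male & con], mp = y[male & pat],
                  fc = y[fem & con], fp = y[fem & pat])
    if (anyNA(y) || any(lengths(cells) < 2)) return(base)
    base[c("mc_mean", "mc_sd")] <- c(mean(cells$mc), stats::sd(cells$mc))
    base[c("mp_mean", "mp_sd")] <- c(mean(cells$mp), stats::sd(cells$mp))
    base[c("fc_mean", "fc_sd")] <- c(mean(cells$fc), stats::sd(cells$fc))
    base[c("fp_mean", "fp_sd")] <- c(mean(cells$fp), stats::sd(cells$fp))
    base$levene_p <- levene_test(y, interaction(des$sex, des$group))$p
    av <- two_way_anova(y, des$sex, des$group, ss_type = ss_type)
    base[c("p_disease", "p_gender", "p_interaction")] <-
      c(av$p_disease, av$p_gender, av$p_interaction)
    base$p_t_male <- pooled_t_test(cells$mp, cells$mc)$p
    base$p_t_female <- pooled_t_test(cells$fp, cells$fc)$p
    base$incomplete <- FALSE
    base
  })
  out <- do.call(rbind, rows)
  attr(out, "design") <- des[c("n_mc", "n_mp", "n_fc", "n_fp")]
  attr(out, "ss_type") <- ss_type
  out
}
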