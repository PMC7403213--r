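test_that("levene test flags heteroscedastic cells and handles degeneracy", {
  set.seed(41)
  cells <- factor(rep(c("mc", "mp", "fc", "fp"), each = 30))
  equal <- stats::rnorm(120)
  lt <- levene_test(equal, cells)
  expect_true(lt$p > 1e-4)  # no evidence expected under homogeneity
  hetero <- equal
  hetero[cells == "mp"] <- stats::rnorm(30, sd = 10)
  expect_lt(levene_test(hetero, cells)$p, 1e-3)
  flat <- rep(c(1, 2, 3, 4), each = 30)
  lt0 <- levene_test(flat, cells)
  expect_equal(lt0$W, 0)
  expect_equal(lt0$p, 1)
  expect_error(levene_test(1:5, factor(c("a", "a", "a", "a", "b"))), "2 observations")
})

test_that("levene p-values are roughly uniform under the null", {
  set.seed(42)
  ps <- replicate(200, {
    levene_test(stats::rnorm(80), factor(rep(1:4, each = 20)))$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 1e-3)
})

test_that("two-way ANOVA matches a nested-model RSS oracle (Type II)", {
  set.seed(43)
  for (rep in 1:5) {
    # deliberately unbalanced toy
    sex <- c(rep("male", 6), rep("female", 4))
    grp <- c(rep(c("control", "patient"), 3), "control", "control", "patient", "patient")
    y <- stats::rnorm(10) + (grp == "patient") * stats::rnorm(1)
    av <- two_way_anova(y, sex, grp, ss_type = "II")
    d <- data.frame(y = y, s = factor(sex), g = factor(grp))
    rss <- function(f) sum(stats::resid(stats::lm(f, d))^2)
    mse <- rss(y ~ s * g) / (10 - 4)
    expect_equal(av$F_disease, (rss(y ~ s) - rss(y ~ s + g)) / mse, tolerance = 1e-9)
    expect_equal(av$F_gender, (rss(y ~ g) - rss(y ~ s + g)) / mse, tolerance = 1e-9)
    expect_equal(av$F_interaction, (rss(y ~ s + g) - rss(y ~ s * g)) / mse,
                 tolerance = 1e-9)
    expect_equal(av$df_residual, 6)
  }
})

test_that("an additive zero-noise design has a null interaction", {
  sex <- rep(c("male", "female"), each = 8)
  grp <- rep(c("control", "patient"), 8)
  y <- 2 * (sex == "male") + 3 * (grp == "patient")
  av <- two_way_anova(y, sex, grp)
  expect_equal(av$F_interaction, 0)
  expect_equal(av$p_interaction, 1)
  expect_equal(av$p_disease, 0)
})

test_that("all three SS types agree with the established implementation", {
  set.seed(47)
  sex <- c(rep("male", 14), rep("female", 10))
  grp <- sample(rep(c("control", "patient"), 12))
  y <- stats::rnorm(24) + 0.5 * (grp == "patient") + 0.3 * (sex == "male")
  d <- data.frame(y = y, sex = factor(sex), group = factor(grp))
  av2 <- two_way_anova(y, sex, grp, "II")
  tab2 <- car::Anova(stats::lm(y ~ sex * group, d), type = 2)
  expect_equal(av2$F_disease, tab2["group", "F value"], tolerance = 1e-9)
  expect_equal(av2$p_gender, tab2["sex", "Pr(>F)"], tolerance = 1e-9)
  expect_equal(av2$p_interaction, tab2["sex:group", "Pr(>F)"], tolerance = 1e-9)
  av3 <- two_way_anova(y, sex, grp, "III")
  tab3 <- car::Anova(stats::lm(y ~ sex * group, d,
                               contrasts = list(sex = "contr.sum", group = "contr.sum")),
                     type = 3)
  expect_equal(av3$F_disease, tab3["group", "F value"], tolerance = 1e-9)
  expect_equal(av3$F_gender, tab3["sex", "F value"], tolerance = 1e-9)
  av1 <- two_way_anova(y, sex, grp, "I")
  tab1 <- stats::anova(stats::lm(y ~ sex * group, d))
  expect_equal(av1$F_gender, tab1["sex", "F value"], tolerance = 1e-9)
  expect_equal(av1$F_disease, tab1["group", "F value"], tolerance = 1e-9)
})

test_that("pooled t-tests match the printed-summary arithmetic", {
  x <- c(1.2, 3.4, 2.2, 0.1)
  expect_equal(pooled_t_test(x, x)$t, 0)
  expect_equal(pooled_t_test(x, x)$p, 1)
  # male-control vs male-patient face height summaries give |t| ~ 7.90 on 66 df
  ts <- t_test_from_summary(122.15, 7.79, 34, 136.57, 7.26, 34)
  expect_equal(abs(ts$t), 7.897, tolerance = 1e-3)
  expect_equal(ts$df, 66)
  # summary and raw-data paths agree
  set.seed(44)
  a <- stats::rnorm(20, 1); b <- stats::rnorm(15)
  full <- pooled_t_test(a, b)
  summ <- t_test_from_summary(mean(a), stats::sd(a), 20, mean(b), stats::sd(b), 15)
  expect_equal(full$t, summ$t, tolerance = 1e-9)
  expect_equal(full$p, summ$p, tolerance = 1e-9)
  # degenerate zero-variance case is flagged
  dg <- pooled_t_test(c(1, 1, 1), c(2, 2, 2))
  expect_true(dg$degenerate)
  expect_equal(dg$p, 0)
})

test_that("the pooled t p-value agrees with a permutation oracle", {
  set.seed(45)
  a <- stats::rnorm(12, 0.8); b <- stats::rnorm(12)
  p_t <- pooled_t_test(a, b)$p
  pool <- c(a, b)
  B <- 4000
  t_obs <- abs(pooled_t_test(a, b)$t)
  exceed <- replicate(B, {
    idx <- sample(24, 12)
    abs(pooled_t_test(pool[idx], pool[-idx])$t) >= t_obs
  })
  p_perm <- (1 + sum(exceed)) / (B + 1)
  expect_lt(abs(p_t - p_perm), 3 * sqrt(p_perm * (1 - p_perm) / B) + 0.01)
})

test_that("bonferroni threshold is the exact rational alpha over m", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 5), 0.01)
  expect_identical(bonferroni_threshold(0.05, 58), 0.05 / 58)
  expect_error(bonferroni_threshold(1.2, 5), "alpha")
})

test_that("significance filter uses strict inequality and reports exclusions", {
  p <- data.frame(variable = c("a", "b", "c"),
                  p_disease = c(0.01, 0.01 - 1e-12, NA),
                  p_gender = c(1, 0.001, 0.5))
  sf <- significance_filter(p, 0.01)
  expect_equal(unname(sf$counts["disease"]), 1L)  # strict: p == threshold fails
  expect_equal(unname(sf$counts["gender"]), 1L)
  expect_equal(sf$excluded, "c")
  all_one <- data.frame(variable = "x", p_disease = 1, p_gender = 1)
  expect_equal(sum(significance_filter(all_one, 0.05)$counts), 0L)
  expect_error(significance_filter(data.frame(variable = "x", p_disease = 1.4), 0.05),
               "0, 1")
})

test_that("direction pooling is weighted and degenerates gracefully", {
  cm <- data.frame(variable = c("up", "down", "tie"),
                   mc_mean = c(1, 5, 2), mp_mean = c(2, 4, 2),
                   fc_mean = c(1, 5, 2), fp_mean = c(2, 4, 2))
  ds <- direction_summary(cm, c(mc = 34, mp = 34, fc = 28, fp = 28),
                          c(TRUE, TRUE, TRUE))
  expect_equal(unname(ds$direction[c("up", "down", "tie")]),
               c("higher_in_patients", "lower_in_patients", "tie"))
  expect_equal(ds$n_higher, 1L)
  expect_equal(ds$n_lower, 1L)
  # balanced cells: weighted and unweighted pooling coincide
  dsu <- direction_summary(cm, c(mc = 10, mp = 10, fc = 10, fp = 10),
                           c(TRUE, TRUE, TRUE))
  expect_equal(unname(sign(ds$pooled_diff)), unname(sign(dsu$pooled_diff)))
})

test_that("the univariate battery reproduces a zero-noise specification", {
  summ <- reference_cohort_summary()
  zero <- summ
  zero[grep("_sd$", names(zero))] <- 0
  spec <- group_spec(zero, sizes = c(mc = 4L, mp = 4L, fc = 4L, fp = 4L))
  ft <- generate_feature_table(spec, seed = 7)
  ub <- univariate_battery(ft)
  expect_equal(ub$mc_mean, summ$mc_mean, tolerance = 1e-9)
  expect_equal(ub$fp_mean, summ$fp_mean, tolerance = 1e-9)
  expect_equal(ub$mc_sd, rep(0, 58), tolerance = 1e-9)
  # shuffling subjects leaves the battery unchanged
  set.seed(48)
  ft2 <- generate_feature_table(group_spec(sizes = c(mc = 6L, mp = 6L, fc = 6L, fp = 6L)),
                                seed = 9)
  ub2 <- univariate_battery(ft2)
  ub3 <- univariate_battery(ft2[sample(nrow(ft2)), ])
  expect_equal(ub2, ub3, ignore_attr = TRUE)
})
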