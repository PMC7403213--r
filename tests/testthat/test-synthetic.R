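test_that("the packaged cohort summary matches its documented shape", {
  summ <- reference_cohort_summary()
  expect_equal(nrow(summ), 58L)
  expect_equal(summ$mc_mean[summ$id == "MFH"], 122.15)
  expect_equal(summ$mc_sd[summ$id == "MFH"], 7.79)
  expect_equal(summ$fp_mean[summ$id == "NW"], 45.59)
  expect_equal(summ$fp_sd[summ$id == "NW"], 2.25)
  expect_identical(summ$id, names(default_catalog()))
})

test_that("feature generation is seed-deterministic and moment-consistent", {
  spec <- group_spec()
  a <- generate_feature_table(spec, seed = 123)
  b <- generate_feature_table(spec, seed = 123)
  expect_identical(a, b)
  expect_false(identical(a, generate_feature_table(spec, seed = 124)))
  # empirical cell means approach the specification (law of large numbers)
  big <- group_spec(correlation = "independent",
                    sizes = c(mc = 10000L, mp = 4L, fc = 4L, fp = 4L))
  ft <- generate_feature_table(big, seed = 9)
  mc <- ft[ft$sex == "male" & ft$group == "control", ]
  expect_lt(abs(mean(mc$MFH) - 122.15), 0.3)
  expect_lt(abs(stats::sd(mc$MFH) - 7.79), 0.3)
  # zero SDs give the cell means exactly
  zero <- reference_cohort_summary()
  zero[grep("_sd$", names(zero))] <- 0
  ftz <- generate_feature_table(group_spec(zero, sizes = c(mc = 2L, mp = 2L, fc = 2L, fp = 2L)),
                                seed = 1)
  expect_equal(unname(as.matrix(ftz[ftz$subject_id == "mc001", feature_ids(ftz)])[1, ]),
               zero$mc_mean, tolerance = 1e-12)
})

test_that("exchangeable correlation is realized and PSD-checked", {
  spec <- group_spec(rho = 0.5, sizes = c(mc = 4000L, mp = 4L, fc = 4L, fp = 4L))
  ft <- generate_feature_table(spec, seed = 10)
  mc <- as.matrix(ft[ft$sex == "male" & ft$group == "control",
                     feature_ids(ft)[1:10]])
  offdiag <- stats::cor(mc)[upper.tri(diag(10))]
  expect_lt(max(abs(offdiag - 0.5)), 0.1)
  expect_error(group_spec(rho = 1.2), "rho")
})

test_that("the template face is bilaterally symmetric", {
  tf <- template_face()
  lefts <- grep("_l$", rownames(tf), value = TRUE)
  partner <- sub("_l$", "_r", lefts)
  expect_equal(tf[lefts, 1], -tf[partner, 1], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(tf[lefts, 2:3], tf[partner, 2:3], tolerance = 1e-6,
               ignore_attr = TRUE)
  mids <- setdiff(rownames(tf), c(lefts, partner))
  expect_lt(max(abs(tf[mids, 1])), 1e-6)
})

test_that("landmark cohorts are deterministic and reduce to the template", {
  a <- generate_landmark_cohort(sizes = c(mc = 2L, mp = 2L, fc = 2L, fp = 2L), seed = 5)
  b <- generate_landmark_cohort(sizes = c(mc = 2L, mp = 2L, fc = 2L, fp = 2L), seed = 5)
  expect_identical(lapply(a, `[[`, "coords"), lapply(b, `[[`, "coords"))
  # zero fields, zero noise, no jitter: every scan equals the template
  plain <- generate_landmark_cohort(sizes = c(mc = 2L, mp = 2L, fc = 2L, fp = 2L),
                                    disease_field = list(), sex_field = list(),
                                    noise_sd = 0, seed = 5, rigid_jitter = FALSE)
  for (s in plain) expect_equal(s$coords, template_face(), tolerance = 1e-12)
})

test_that("a constructed displacement is measured back exactly", {
  field <- list(al_l = c(2.5, 0, 0), al_r = c(-2.5, 0, 0))
  scans <- generate_landmark_cohort(sizes = c(mc = 2L, mp = 2L, fc = 2L, fp = 2L),
                                    disease_field = field, sex_field = list(),
                                    noise_sd = 0, seed = 5, rigid_jitter = TRUE)
  ft <- measure_cohort(scans)
  nw_patient <- mean(ft$NW[ft$group == "patient"])
  nw_control <- mean(ft$NW[ft$group == "control"])
  expect_equal(nw_patient - nw_control, 5, tolerance = 1e-6)
  expect_equal(stats::sd(ft$NW[ft$group == "patient"]), 0, tolerance = 1e-6)
})

test_that("deformed meshes follow their landmarks", {
  field <- acromegaly_field(scale = 2)
  scans <- generate_landmark_cohort(sizes = c(mc = 2L, mp = 2L, fc = 2L, fp = 2L),
                                    disease_field = field, sex_field = list(),
                                    noise_sd = 0, seed = 6, rigid_jitter = FALSE,
                                    mesh = TRUE)
  pat <- scans[[3]]
  expect_false(is.null(pat$mesh))
  # the patient mesh vertex sheet near the displaced gnathion moved with it
  gn_new <- pat$coords["gn", ]
  d_pat <- min(sqrt(rowSums(sweep(pat$mesh$vertices, 2, gn_new)^2)))
  d_ctl <- min(sqrt(rowSums(sweep(scans[[1]]$mesh$vertices, 2, gn_new)^2)))
  expect_lt(d_pat, d_ctl)
})
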