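test_that("the default catalog is the 58-entry battery with valid structure", {
  cat <- default_catalog()
  expect_length(cat, 58L)
  expect_false(any(duplicated(names(cat))))
  units <- catalog_units(cat)
  expect_setequal(unique(units), c("mm", "degree", "index"))
  # a catalog referencing a later measurement has no topological order
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    list(id = "A", kind = "index", units = "index", num = "B", den = "B"),
    list(id = "B", kind = "linear", units = "mm", a = "n", b = "gn")),
    bad, auto_unbox = TRUE)
  expect_error(read_catalog(bad), "topological|later")
})

test_that("measure_scan is complete with a mesh and bookkeeps without one", {
  v_mesh <- measure_scan(template_scan(mesh = TRUE))
  expect_length(v_mesh, 58L)
  expect_equal(sum(is.na(v_mesh)), 0L)
  expect_equal(unname(attr(v_mesh, "provenance")[c("UVCL", "MCL", "PTGP")]),
               rep("mesh", 3))

  # without a mesh the three cross-section semi-perimeters are missing with
  # diagnostics; curve entries fall back to landmark chains
  v <- measure_scan(template_scan())
  expect_equal(sum(is.na(v)), 3L)
  expect_setequal(names(v)[is.na(v)], c("PTGP", "PMFP", "PTNP"))
  expect_match(attr(v, "diagnostics")["PTGP"], "mesh")
  expect_equal(unname(attr(v, "provenance")["UVCL"]), "landmark")
  expect_equal(unname(v["UVCL"]), unname(v["UVH"]), tolerance = 1e-9)
})

test_that("index arithmetic matches the published construction", {
  # intercanthal width over binocular width, as printed for male controls
  expect_equal(100 * 41.56 / 93.60, 44.40, tolerance = 5e-3)
  ftab <- feature_table(data.frame(subject_id = "s", sex = "male",
                                   group = "control", a = 41.56, b = 93.60))
  expect_equal(100 * ftab$a / ftab$b, 44.40171, tolerance = 1e-5)
  v <- measure_scan(template_scan())
  expect_equal(unname(v["II"]), unname(100 * v["ICW"] / v["BnW"]), tolerance = 1e-9)
  expect_equal(unname(v["LIE_LSE"]), unname(v["LIEPD"] - v["LSEPD"]), tolerance = 1e-12)
})

test_that("measurements are invariant under rigid motion of the raw scan", {
  set.seed(21)
  base <- measure_scan(template_scan(mesh = TRUE))
  for (rep in 1:3) {
    moved <- rigidly_moved(template_scan(mesh = TRUE))
    v <- measure_scan(moved)
    expect_lt(max(abs(v - base)), 1e-6)
  }
})

test_that("uniform scaling doubles lengths and fixes angles and indices", {
  scan <- template_scan(mesh = TRUE)
  scaled <- face_scan("t2", "male", "control", 2 * scan$coords,
                      mesh = face_mesh(2 * scan$mesh$vertices, scan$mesh$faces),
                      aligned = TRUE)
  v1 <- measure_scan(scan)
  v2 <- measure_scan(scaled)
  units <- attr(v1, "units")
  mm <- names(v1)[units == "mm"]
  expect_equal(unname(v2[mm]), unname(2 * v1[mm]), tolerance = 1e-6)
  fixed <- names(v1)[units != "mm"]
  expect_equal(unname(v2[fixed]), unname(v1[fixed]), tolerance = 1e-6)
})

test_that("mirroring a scan with left/right relabeling changes nothing", {
  set.seed(22)
  co <- template_face() + stats::rnorm(111, 0, 1.5)  # asymmetric scan
  mirrored <- co %*% diag(c(-1, 1, 1))
  swap <- rownames(co)
  lefts <- grep("_l$", swap); rights <- grep("_r$", swap)
  swap[lefts] <- sub("_l$", "_r", rownames(co)[lefts])
  swap[rights] <- sub("_r$", "_l", rownames(co)[rights])
  rownames(mirrored) <- swap
  v1 <- measure_scan(face_scan("orig", "male", "control", co))
  v2 <- measure_scan(face_scan("mirr", "male", "control", mirrored))
  expect_lt(max(abs(v1 - v2), na.rm = TRUE), 1e-6)
})

test_that("per-subject dependency failures degrade to NA, not errors", {
  co <- template_face()
  co <- co[setdiff(rownames(co), c("al_l", "prn")), ]
  v <- measure_scan(face_scan("s", "male", "control", co, aligned = TRUE))
  expect_true(is.na(v["NW"]))
  expect_match(attr(v, "diagnostics")["NW"], "al_l")
  expect_true(is.na(v["NWI"]))   # index on a missing operand
  expect_false(is.na(v["MFH"]))
})

test_that("feature tables round-trip through CSV with units metadata", {
  scans <- generate_landmark_cohort(sizes = c(mc = 2L, mp = 2L, fc = 2L, fp = 2L),
                                    seed = 3)
  ft <- measure_cohort(scans)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ft, path)
  back <- read_feature_table(path)
  expect_equal(feature_ids(back), feature_ids(ft))
  expect_equal(as.matrix(back[feature_ids(back)]),
               as.matrix(ft[feature_ids(ft)]), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(attr(back, "units")[["MFH"]], "mm")
})

test_that("affected_measurements tracks landmark dependencies", {
  ids <- affected_measurements(c("al_l", "al_r"))
  expect_true(all(c("NW", "NWI", "EAI", "ACI") %in% ids))
  expect_false("MFH" %in% ids)
  # FH-defining landmarks conservatively touch frame-dependent entries
  expect_true("PrTVLD" %in% affected_measurements("tr_l"))
})
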