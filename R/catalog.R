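# The 58-parameter measurement catalog and its evaluation engine.
#
# The catalog is data, not code: each entry declares an id (the acronym used
# in the cohort summary), a kind, its landmark/plane/measurement operands and
# units. The packaged default realizes the published 58-parameter battery
# with standard soft-tissue anthropometric operand choices; an alternative
# catalog file can be dropped in without touching the engine.

.acroface_cache <- new.env(parent = emptyenv())

#' Read a measurement catalog from JSON
#'
#' @param path Path to a catalog JSON file.
#' @return An object of class `measurement_catalog` (list of definitions,
#'   with ids unique and a valid evaluation order).
#' @export
read_catalog <- function(path) {
  entries <- jsonlite::read_json(path, simplifyVector = FALSE)
  ids <- vapply(entries, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate measurement id(s): ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  kinds <- vapply(entries, `[[`, "", "kind")
  ok_kinds <- c("linear", "depth", "chain", "index", "tri_index",
                "tragion_depth", "pdist", "pdiff", "angle", "vangle", "semi")
  if (!all(kinds %in% ok_kinds)) {
    stop("unknown measurement kind(s): ",
         paste(setdiff(kinds, ok_kinds), collapse = ", "))
  }
  names(entries) <- ids
  cat <- structure(entries, class = "measurement_catalog")
  .catalog_check_deps(cat)
  cat
}

# measurement-to-measurement dependencies must be resolvable in catalog order
# (the dependency graph is acyclic and topologically sorted as listed)
.catalog_check_deps <- function(catalog) {
  ids <- names(catalog)
  seen <- character(0)
  for (e in catalog) {
    deps <- character(0)
    if (e$kind == "index") {
      ops <- c(unlist(e$num), unlist(e$den))
      deps <- ops[!grepl(":", ops)]
    } else if (e$kind == "pdiff") {
      deps <- c(e$a, e$b)
    }
    bad <- setdiff(deps, seen)
    bad_missing <- setdiff(bad, ids)
    if (length(bad_missing)) {
      stop("measurement ", e$id, " references unknown id(s): ",
           paste(bad_missing, collapse = ", "))
    }
    if (length(bad)) {
      stop("measurement ", e$id, " depends on ", paste(bad, collapse = ", "),
           " which appear later in the catalog (no topological order)")
    }
    seen <- c(seen, e$id)
  }
  invisible(TRUE)
}

#' The packaged default 58-parameter catalog
#'
#' @return A `measurement_catalog` with 58 entries.
#' @export
default_catalog <- function() {
  if (is.null(.acroface_cache$catalog)) {
    .acroface_cache$catalog <- read_catalog(
      system.file("extdata", "catalog.json", package = "acroface", mustWork = TRUE))
  }
  .acroface_cache$catalog
}

#' @export
print.measurement_catalog <- function(x, ...) {
  cat("<measurement_catalog> ", length(x), " entries: ",
      paste(utils::head(names(x), 8), collapse = ", "), ", ...\n", sep = "")
  invisible(x)
}

#' Units of each catalog entry
#'
#' @param catalog A `measurement_catalog`.
#' @return Named character vector (`"mm"`, `"degree"` or `"index"`).
#' @export
catalog_units <- function(catalog = default_catalog()) {
  vapply(catalog, `[[`, "", "units")
}

# landmark keys a catalog entry reads (used e.g. to predict which
# measurements a landmark displacement can affect)
.entry_landmarks <- function(e, catalog) {
  keyify <- function(code) {
    if (code %in% .lm_midline_codes()) code
    else if (code %in% .lm_bilateral_codes()) paste0(code, c("_l", "_r"))
    else code  # already a key like "go_l"
  }
  pair_keys <- function(op) {
    if (grepl(":", op)) unlist(lapply(strsplit(op, ":")[[1]], keyify)) else
      .entry_landmarks(catalog[[op]], catalog)
  }
  switch(e$kind,
    linear = c(keyify(e$a), keyify(e$b)),
    depth = c(keyify(e$a), keyify(e$b)),
    tragion_depth = c(keyify(e$a), "tr_l", "tr_r"),
    chain = unlist(lapply(e$codes, keyify)),
    index = unlist(lapply(c(unlist(e$num), unlist(e$den)), pair_keys)),
    tri_index = c(keyify(e$apex), keyify(e$base)),
    pdist = keyify(e$point),
    pdiff = c(.entry_landmarks(catalog[[e$a]], catalog),
              .entry_landmarks(catalog[[e$b]], catalog)),
    angle = c(keyify(e$a), keyify(e$vertex), keyify(e$b)),
    vangle = c(keyify(e$from1), keyify(e$to1), keyify(e$from2), keyify(e$to2)),
    semi = character(0))
}

#' Measurements affected by displacing a set of landmarks
#'
#' Walks the catalog dependency graph and returns the ids of all entries
#' whose value can change when the given landmark keys move.
#'
#' @param keys Landmark storage keys (e.g. `"al_l"`).
#' @param catalog A `measurement_catalog`.
#' @param include_planes Also count entries evaluated against reference
#'   planes built from midline/preaurale landmarks (plane-distance, angle and
#'   section entries are conservatively included when a plane-defining
#'   landmark moves).
#' @return Character vector of measurement ids.
#' @export
affected_measurements <- function(keys, catalog = default_catalog(),
                                  include_planes = TRUE) {
  hit <- vapply(catalog, function(e) any(.entry_landmarks(e, catalog) %in% keys), NA)
  ids <- names(catalog)[hit]
  if (include_planes) {
    plane_defs <- list(
      esthetic = c("prn", "pg", .lm_midline_codes()),
      TVL = c("sn", .lm_midline_codes()),
      transglabellar = "g", midfacial = c("or_l", "or_r"),
      transverse_nasal = "sn")
    codes_moved <- unique(sub("_(l|r)$", "", keys))
    for (e in catalog) {
      pl <- switch(e$kind, pdist = e$plane, semi = e$level, NULL)
      if (!is.null(pl) && any(plane_defs[[pl]] %in% c(keys, codes_moved))) {
        ids <- union(ids, e$id)
      }
    }
    # FH-plane landmarks re-orient the whole frame: depth/plane entries move
    if (any(c("tr_l", "tr_r", "or_l", "or_r", "pra_l", "pra_r") %in% keys)) {
      frame_dep <- vapply(catalog, function(e)
        e$kind %in% c("depth", "pdist", "pdiff", "semi", "tragion_depth"), NA)
      ids <- union(ids, names(catalog)[frame_dep])
    }
  }
  ids
}

# ---- evaluation -------------------------------------------------------------

.side_distance <- function(co, a, b) {
  # resolve a landmark pair to a distance with bilateral side handling:
  # same bilateral code twice -> left-right width; otherwise bilateral
  # operands are evaluated per side and averaged
  bil <- .lm_bilateral_codes()
  get <- function(k) {
    if (!k %in% rownames(co)) stop("missing landmark(s): ", k)
    co[k, ]
  }
  if (a %in% bil && b %in% bil && a == b) {
    return(linear_distance(get(paste0(a, "_l")), get(paste0(a, "_r"))))
  }
  keys_of <- function(code) {
    if (code %in% bil) paste0(code, c("_l", "_r")) else c(code, code)
  }
  ka <- keys_of(a); kb <- keys_of(b)
  if (all(c(ka, kb) %in% c(a, b))) {  # both midline
    return(linear_distance(get(a), get(b)))
  }
  mean(c(linear_distance(get(ka[1]), get(kb[1])),
         linear_distance(get(ka[2]), get(kb[2]))))
}

.eval_entry <- function(e, scan, planes, values) {
  co <- scan$coords
  get <- function(k) {
    if (!k %in% rownames(co)) stop("missing landmark(s): ", k)
    co[k, ]
  }
  resolve <- function(op) {
    # operand: measurement id or "a:b" landmark pair; vectors are summed
    vals <- vapply(unlist(op), function(o) {
      if (grepl(":", o)) {
        p <- strsplit(o, ":")[[1]]
        .side_distance(co, p[1], p[2])
      } else {
        v <- values[[o]]
        if (is.null(v) || is.na(v)) stop("unresolved operand measurement: ", o)
        v
      }
    }, 0)
    sum(vals)
  }
  need_plane <- function(kind) {
    if (is.null(planes[[kind]])) stop("missing reference plane: ", kind)
    planes[[kind]]
  }
  switch(e$kind,
    linear = .side_distance(co, e$a, e$b),
    depth = get(e$a)[3] - get(e$b)[3],
    tragion_depth = {
      tm <- (get("tr_l") + get("tr_r")) / 2
      if (e$a %in% .lm_bilateral_codes()) {
        mean(c(linear_distance(get(paste0(e$a, "_l")), tm),
               linear_distance(get(paste0(e$a, "_r")), tm)))
      } else linear_distance(get(e$a), tm)
    },
    chain = {
      mesh_val <- NA_real_
      if (!is.null(scan$mesh) && !is.null(e$mesh)) {
        m <- e$mesh
        sect_plane <- if (identical(m$section, "midsagittal")) {
          need_plane("midsagittal")
        } else {
          pts <- do.call(rbind, lapply(m$plane_through, get))
          normal <- .cross3(pts[2, ] - pts[1, ], pts[3, ] - pts[1, ])
          ref_plane("through", pts[1, ], normal)
        }
        mesh_val <- .mesh_curve_length(scan$mesh, sect_plane,
                                       get(m$between[[1]]), get(m$between[[2]]),
                                       get(m$anchor))
      }
      if (is.finite(mesh_val)) {
        attr(mesh_val, "provenance") <- "mesh"
        mesh_val
      } else {
        polyline_length(do.call(rbind, lapply(e$codes, get)))
      }
    },
    index = 100 * {
      num <- resolve(e$num); den <- resolve(e$den)
      if (den == 0) stop("zero denominator for index ", e$id)
      num / den
    },
    tri_index = {
      bl <- get(paste0(e$base, "_l")); br <- get(paste0(e$base, "_r"))
      100 * point_line_distance(get(e$apex), bl, br) / linear_distance(bl, br)
    },
    pdist = signed_plane_distance(get(e$point), need_plane(e$plane)),
    pdiff = {
      va <- values[[e$a]]; vb <- values[[e$b]]
      if (is.null(va) || is.null(vb) || is.na(va) || is.na(vb)) {
        stop("unresolved operand measurement for ", e$id)
      }
      va - vb
    },
    angle = angle_at(get(e$a), get(e$vertex), get(e$b)),
    vangle = vector_angle(get(e$to1) - get(e$from1), get(e$to2) - get(e$from2)),
    semi = {
      if (is.null(scan$mesh)) stop("no mesh: ", e$id, " requires a surface mesh")
      v <- semi_perimeter(scan$mesh, e$level, planes)
      if (is.na(v)) stop(attr(v, "reason"))
      attr(v, "provenance") <- "mesh"
      v
    })
}

#' Evaluate the measurement catalog on one scan
#'
#' Aligns the scan to the Frankfort Horizontal plane if necessary, builds the
#' reference planes, and evaluates every catalog entry in order. Entries
#' whose landmark or mesh dependencies are unmet yield `NA` with a
#' per-entry diagnostic rather than an error.
#'
#' @param scan A [face_scan()].
#' @param catalog A `measurement_catalog` (default: the packaged 58-entry
#'   battery).
#' @return Named numeric vector with attributes `units`, `provenance`
#'   (`"landmark"`, `"mesh"` or `NA`) and `diagnostics` (per-entry message
#'   for missing values).
#' @export
measure_scan <- function(scan, catalog = default_catalog()) {
  if (!isTRUE(scan$aligned)) scan <- align_frankfort(scan)$scan
  planes <- build_reference_planes(scan)
  ids <- names(catalog)
  values <- stats::setNames(vector("list", length(ids)), ids)
  prov <- stats::setNames(rep(NA_character_, length(ids)), ids)
  diag <- stats::setNames(rep(NA_character_, length(ids)), ids)
  for (id in ids) {
    res <- tryCatch(.eval_entry(catalog[[id]], scan, planes, values),
                    error = function(err) structure(NA_real_, msg = conditionMessage(err)))
    if (is.na(res)) {
      values[[id]] <- NA_real_
      diag[[id]] <- attr(res, "msg") %||% "missing"
    } else {
      values[[id]] <- as.numeric(res)
      prov[[id]] <- attr(res, "provenance") %||% "landmark"
    }
  }
  out <- unlist(values)
  attr(out, "units") <- catalog_units(catalog)
  attr(out, "provenance") <- prov
  attr(out, "diagnostics") <- diag
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Measure a cohort of scans into a feature table
#'
#' @param scans List of [face_scan()] objects.
#' @param catalog A `measurement_catalog`.
#' @return A `feature_table`: data.frame with `subject_id`, `sex`, `group`
#'   and one column per measurement; per-column units in `attr(, "units")`
#'   and per-cell provenance in `attr(, "provenance")`.
#' @export
measure_cohort <- function(scans, catalog = default_catalog()) {
  vals <- lapply(scans, measure_scan, catalog = catalog)
  M <- do.call(rbind, vals)
  prov <- do.call(rbind, lapply(vals, attr, "provenance"))
  df <- data.frame(
    subject_id = vapply(scans, `[[`, "", "subject_id"),
    sex = vapply(scans, `[[`, "", "sex"),
    group = vapply(scans, `[[`, "", "group"),
    M, stringsAsFactors = FALSE, row.names = NULL, check.names = FALSE)
  if (any(apply(is.na(M), 1, all))) {
    stop("subject with no measurable entries: ",
         paste(df$subject_id[apply(is.na(M), 1, all)], collapse = ", "))
  }
  feature_table(df, units = catalog_units(catalog), provenance = prov)
}

#' Construct a feature table
#'
#' @param df data.frame with columns `subject_id`, `sex`, `group` followed by
#'   measurement columns.
#' @param units Named units per measurement column.
#' @param provenance Optional matrix of per-value provenance flags.
#' @return Object of classes `feature_table` and `data.frame`.
#' @export
feature_table <- function(df, units = NULL, provenance = NULL) {
  need <- c("subject_id", "sex", "group")
  if (!all(need %in% names(df))) stop("feature table needs columns ", paste(need, collapse = ", "))
  stopifnot(all(df$sex %in% c("male", "female")), all(df$group %in% c("patient", "control")))
  attr(df, "units") <- units
  attr(df, "provenance") <- provenance
  class(df) <- unique(c("feature_table", class(df)))
  df
}

#' Measurement columns of a feature table
#'
#' @param features A `feature_table`.
#' @return Character vector of measurement column names.
#' @export
feature_ids <- function(features) {
  setdiff(names(features), c("subject_id", "sex", "group"))
}

#' Write / read a feature table as CSV with a units comment and JSON sidecar
#'
#' The CSV carries a `# units:` comment line after the header; provenance
#' flags and units are also written to a `<path>.meta.json` sidecar.
#'
#' @param features A `feature_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  ids <- feature_ids(features)
  units <- attr(features, "units")
  con <- file(path, "w")
  writeLines(paste(names(features), collapse = ","), con)
  if (!is.null(units)) {
    writeLines(paste0("# units: ", paste(ids, unname(units[ids]), sep = "=", collapse = ",")), con)
  }
  utils::write.table(features, con, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  close(con)
  meta <- list(units = as.list(units),
               provenance = attr(features, "provenance"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        check.names = FALSE)
  units <- NULL
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    units <- unlist(meta$units)
  }
  feature_table(df, units = units)
}
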