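#' Soft-tissue landmark catalog
#'
#' The 35-point facial landmark set used throughout the package (11 midline
#' and 12 bilateral landmarks), extended by the bilateral preaurale `pra`
#' (the most anterior point of the ear at the base of the tragus), which is
#' needed to clip the facial cross-sections. Bilateral landmarks are stored
#' with a `_l` / `_r` key suffix; midline landmarks use the bare code.
#'
#' @return A data.frame with columns `code`, `name`, `laterality`
#'   (`"midline"`, `"left"` or `"right"`) and `key` (the storage key).
#' @export
landmark_catalog <- function() {
  if (!is.null(.landmark_cache$catalog)) return(.landmark_cache$catalog)
  mid <- c(
    g   = "glabella",
    n   = "nasion",
    prn = "pronasale",
    sn  = "subnasale",
    ls  = "labiale superius",
    sto = "stomion",
    li  = "labiale inferius",
    sm  = "supramentale",
    pg  = "pogonion",
    gn  = "gnathion",
    cm  = "cervico-mandibular point"
  )
  bil <- c(
    en  = "endocanthion",
    ec  = "ectocanthion",
    im  = "iridion mediale",
    il  = "iridion laterale",
    ii  = "iridion inferius",
    or  = "inferior orbital groove",
    al  = "alare",
    ch  = "chelion",
    zy  = "zygion",
    tr  = "tragion",
    sba = "subaurale",
    go  = "gonion",
    pra = "preaurale"
  )
  out <- rbind(
    data.frame(code = names(mid), name = unname(mid), laterality = "midline",
               key = names(mid), stringsAsFactors = FALSE),
    data.frame(code = rep(names(bil), each = 2L), name = rep(unname(bil), each = 2L),
               laterality = rep(c("left", "right"), times = length(bil)),
               key = paste0(rep(names(bil), each = 2L), "_",
                            rep(c("l", "r"), times = length(bil))),
               stringsAsFactors = FALSE)
  )
  .landmark_cache$catalog <- out
  out
}

.landmark_cache <- new.env(parent = emptyenv())

.lm_keys <- function() landmark_catalog()$key
.lm_midline_codes <- function() {
  cat <- landmark_catalog()
  cat$code[cat$laterality == "midline"]
}
.lm_bilateral_codes <- function() unique(landmark_catalog()$code[landmark_catalog()$laterality != "midline"])

#' Construct a single-subject face scan
#'
#' A `face_scan` bundles a subject's labelled 3D landmark coordinates (mm)
#' with sex and patient/control group metadata and, optionally, a
#' triangulated surface mesh. Coordinates use a right-handed frame; after
#' Frankfort alignment the convention is +x subject-left, +y superior,
#' +z anterior.
#'
#' @param subject_id Character scalar.
#' @param sex `"male"` or `"female"`.
#' @param group `"patient"` or `"control"`.
#' @param coords Numeric matrix with 3 columns and row names drawn from
#'   [landmark_catalog()] keys (e.g. `"n"`, `"tr_l"`).
#' @param mesh Optional mesh as returned by [face_mesh()].
#' @param aligned Logical; whether the scan is already Frankfort-aligned.
#' @return An object of class `face_scan`.
#' @export
face_scan <- function(subject_id, sex, group, coords, mesh = NULL,
                      aligned = FALSE) {
  sex <- match.arg(sex, c("male", "female"))
  group <- match.arg(group, c("patient", "control"))
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must have 3 columns (x, y, z)")
  if (is.null(rownames(coords))) stop("coords must have landmark keys as row names")
  if (!all(is.finite(coords))) stop("non-finite landmark coordinate for subject ", subject_id)
  bad <- setdiff(rownames(coords), .lm_keys())
  if (length(bad)) {
    stop("unknown landmark code(s) for subject ", subject_id, ": ",
         paste(bad, collapse = ", "))
  }
  if (anyDuplicated(rownames(coords))) {
    stop("duplicate landmark entries for subject ", subject_id, ": ",
         paste(unique(rownames(coords)[duplicated(rownames(coords))]), collapse = ", "))
  }
  colnames(coords) <- c("x", "y", "z")
  if (!is.null(mesh)) mesh <- .validate_mesh(mesh)
  structure(list(subject_id = as.character(subject_id), sex = sex,
                 group = group, coords = coords, mesh = mesh,
                 aligned = isTRUE(aligned)),
            class = "face_scan")
}

#' @export
print.face_scan <- function(x, ...) {
  cat("<face_scan> ", x$subject_id, " [", x$sex, ", ", x$group, "] ",
      nrow(x$coords), " landmarks",
      if (!is.null(x$mesh)) paste0(", mesh (", nrow(x$mesh$vertices), " vertices)"),
      if (x$aligned) ", FH-aligned", "\n", sep = "")
  invisible(x)
}

#' Look up landmark coordinates on a scan
#'
#' @param scan A [face_scan()].
#' @param keys Landmark storage keys (`"n"`, `"tr_l"`, ...).
#' @param required If `TRUE` (default), missing keys are an error naming the
#'   offending codes; otherwise rows of `NA` are returned.
#' @return Numeric matrix, one row per key.
#' @export
landmark_coords <- function(scan, keys, required = TRUE) {
  miss <- setdiff(keys, rownames(scan$coords))
  if (length(miss)) {
    if (required) stop("missing landmark(s): ", paste(miss, collapse = ", "))
    out <- matrix(NA_real_, length(keys), 3L, dimnames = list(keys, c("x", "y", "z")))
    ok <- intersect(keys, rownames(scan$coords))
    out[ok, ] <- scan$coords[ok, , drop = FALSE]
    return(out)
  }
  scan$coords[keys, , drop = FALSE]
}

# ---- landmark file I/O ------------------------------------------------------

# Long-format CSV dialect: subject_id,sex,group,code,laterality,x,y,z with
# laterality empty for midline codes; an equivalent JSON (one object per
# subject, coords keyed by storage key). Round-trip is exact at 6 decimals.

.key_from_code <- function(code, laterality) {
  cat <- landmark_catalog()
  lat <- ifelse(is.na(laterality) | laterality == "", "midline", laterality)
  key <- character(length(code))
  for (i in seq_along(code)) {
    hit <- cat$code == code[i] & cat$laterality == lat[i]
    if (!any(hit)) {
      if (!code[i] %in% cat$code) {
        stop("unknown landmark code: ", code[i])
      }
      stop("invalid laterality '", lat[i], "' for landmark code: ", code[i])
    }
    key[i] <- cat$key[hit]
  }
  key
}

#' Read face scans from a landmark file
#'
#' Reads the long-format landmark CSV
#' (`subject_id,sex,group,code,laterality,x,y,z`) or the equivalent JSON
#' written by [write_landmarks()]. Unknown landmark codes and duplicate
#' `(subject, code, laterality)` rows are rejected.
#'
#' @param path File path; format chosen by extension (`.csv` or `.json`).
#' @return A list of [face_scan()] objects.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) return(.read_landmarks_json(path))
  d <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = c(
      subject_id = "character", sex = "character", group = "character",
      code = "character", laterality = "character",
      x = "numeric", y = "numeric", z = "numeric")),
    error = function(e) stop("malformed landmark CSV '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  need <- c("subject_id", "sex", "group", "code", "laterality", "x", "y", "z")
  if (!all(need %in% names(d))) {
    stop("landmark CSV must have columns ", paste(need, collapse = ","))
  }
  bad <- which(!is.finite(d$x) | !is.finite(d$y) | !is.finite(d$z))
  if (length(bad)) {
    stop("malformed landmark row at line ", bad[1] + 1L,
         " of ", path, " (non-finite coordinate)")
  }
  scans <- lapply(split(d, factor(d$subject_id, levels = unique(d$subject_id))),
                  function(s) {
    key <- .key_from_code(s$code, s$laterality)
    if (anyDuplicated(key)) {
      dup <- key[duplicated(key)][1]
      stop("duplicate landmark row for subject ", s$subject_id[1], ": ", dup)
    }
    coords <- cbind(x = s$x, y = s$y, z = s$z)
    rownames(coords) <- key
    face_scan(s$subject_id[1], s$sex[1], s$group[1], coords)
  })
  names(scans) <- NULL
  scans
}

.read_landmarks_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(j, function(s) {
    coords <- do.call(rbind, lapply(s$coords, function(p) unlist(p)))
    rownames(coords) <- names(s$coords)
    face_scan(s$subject_id, s$sex, s$group, coords)
  })
}

#' Write face scans to a landmark file
#'
#' @param scans A list of [face_scan()] objects (or a single scan).
#' @param path Output path; `.csv` or `.json` selects the dialect.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(scans, path) {
  if (inherits(scans, "face_scan")) scans <- list(scans)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- lapply(scans, function(s) {
      co <- round(s$coords, 6)
      list(subject_id = s$subject_id, sex = s$sex, group = s$group,
           coords = stats::setNames(
             lapply(seq_len(nrow(co)), function(i) unname(co[i, ])),
             rownames(co)))
    })
    jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  cat_tab <- landmark_catalog()
  rows <- do.call(rbind, lapply(scans, function(s) {
    key <- rownames(s$coords)
    i <- match(key, cat_tab$key)
    data.frame(subject_id = s$subject_id, sex = s$sex, group = s$group,
               code = cat_tab$code[i],
               laterality = ifelse(cat_tab$laterality[i] == "midline", "",
                                   cat_tab$laterality[i]),
               x = round(s$coords[, 1], 6), y = round(s$coords[, 2], 6),
               z = round(s$coords[, 3], 6), stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
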