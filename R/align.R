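# Frankfort Horizontal (FH) alignment and reference-plane construction.
#
# The classic FH plane runs through porion and orbitale on bone; on the
# soft-tissue landmark set the closest proxies are the tragion (tr) and the
# inferior orbital groove (or), so the FH here is the least-squares plane
# through those four points. The aligned frame is right-handed with
# +x subject-left, +y superior, +z anterior, origin at the tragion midpoint.

.fit_plane_normal <- function(P) {
  # smallest principal axis of the centered points
  C <- sweep(P, 2, colMeans(P))
  s <- svd(C)
  if (s$d[2] < 1e-9 * max(s$d[1], 1e-300)) {
    stop("degenerate (collinear) landmark configuration for plane fit")
  }
  s$v[, 3]
}

#' Align a face scan to the Frankfort Horizontal plane
#'
#' Rigidly rotates and translates the scan so that the best-fit plane through
#' left/right tragion and left/right inferior orbital groove is horizontal,
#' the tragion midpoint is at the origin, and the left-right tragion axis is
#' the lateral (+x towards subject-left) axis. The mesh, when present, is
#' transformed with the same rigid map, so all pairwise distances are
#' preserved exactly.
#'
#' @param scan A [face_scan()] containing `tr` and `or` on both sides.
#' @return A list with elements `scan` (the aligned [face_scan()]) and
#'   `alignment` (class `rigid_alignment`: `rotation` 3x3 with determinant +1
#'   and `translation` length-3, mapping input points `p` to `R p + t`).
#' @export
align_frankfort <- function(scan) {
  need <- c("tr_l", "tr_r", "or_l", "or_r")
  P <- landmark_coords(scan, need)
  y_axis <- .fit_plane_normal(P)

  tr_mid <- (P["tr_l", ] + P["tr_r", ]) / 2
  lat <- P["tr_l", ] - P["tr_r", ]
  lat <- lat - sum(lat * y_axis) * y_axis
  nlat <- sqrt(sum(lat^2))
  if (nlat < 1e-9) stop("degenerate landmark configuration: tragion axis parallel to FH normal")
  x_axis <- lat / nlat

  build <- function(y) {
    z <- .cross3(x_axis, y)
    rbind(x_axis, y, z, deparse.level = 0)
  }
  R <- build(y_axis)
  # Disambiguate the vertical sign: facial landmarks sit anterior of the
  # tragion axis, so the aligned landmark centroid must have positive z.
  face_keys <- setdiff(rownames(scan$coords), c("tr_l", "tr_r", "sba_l", "sba_r", "pra_l", "pra_r"))
  if (!length(face_keys)) face_keys <- rownames(scan$coords)
  ctr <- colMeans(scan$coords[face_keys, , drop = FALSE]) - tr_mid
  if ((R %*% ctr)[3] < 0) R <- build(-y_axis)

  t_vec <- -as.numeric(R %*% tr_mid)
  apply_rigid <- function(M) sweep(M %*% t(R), 2, t_vec, `+`)

  co <- apply_rigid(scan$coords)
  rownames(co) <- rownames(scan$coords)
  mesh <- scan$mesh
  if (!is.null(mesh)) mesh$vertices <- apply_rigid(mesh$vertices)
  out <- face_scan(scan$subject_id, scan$sex, scan$group, co, mesh, aligned = TRUE)
  alignment <- structure(list(rotation = unname(R), translation = t_vec),
                         class = "rigid_alignment")
  list(scan = out, alignment = alignment)
}

#' Apply or invert a rigid alignment
#'
#' @param alignment A `rigid_alignment` from [align_frankfort()].
#' @param points Matrix of points (rows).
#' @param inverse Apply the inverse map.
#' @return Transformed points.
#' @export
apply_alignment <- function(alignment, points, inverse = FALSE) {
  points <- as.matrix(points)
  if (inverse) {
    sweep(points, 2, alignment$translation) %*% alignment$rotation
  } else {
    sweep(points %*% t(alignment$rotation), 2, alignment$translation, `+`)
  }
}

#' Export a rigid alignment as JSON
#'
#' @param alignment A `rigid_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  jsonlite::write_json(list(rotation = as.numeric(t(alignment$rotation)),
                            translation = alignment$translation,
                            layout = "row-major"),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Build the measurement reference planes of an FH-aligned scan
#'
#' Constructs the planes the catalog measurements refer to:
#' \describe{
#'   \item{FH}{horizontal plane through the tragion midpoint.}
#'   \item{midsagittal}{vertical plane minimizing the summed squared signed
#'     distance of the midline landmarks; positive towards subject-left.}
#'   \item{esthetic}{Ricketts E-line (pronasale-pogonion) extruded
#'     vertically, perpendicular to the midsagittal plane; anterior positive.}
#'   \item{TVL}{true vertical line: vertical plane through subnasale
#'     perpendicular to the midsagittal plane; anterior positive.}
#'   \item{transglabellar, midfacial, transverse_nasal}{horizontal planes
#'     through glabella, the inferior-orbital midpoint, and subnasale.}
#'   \item{plumb_left, plumb_right}{vertical planes through each preaurale,
#'     perpendicular to the anterior axis (clipping half-spaces).}
#' }
#' Planes whose landmarks are absent are skipped unless listed in `require`.
#'
#' @param scan An FH-aligned [face_scan()].
#' @param require Character vector of plane kinds that must be constructible
#'   (error listing missing landmarks otherwise).
#' @return Named list of [ref_plane()] objects.
#' @export
build_reference_planes <- function(scan, require = character()) {
  if (!isTRUE(scan$aligned)) stop("scan must be FH-aligned (see align_frankfort)")
  co <- scan$coords
  has <- function(k) all(k %in% rownames(co))
  planes <- list()
  planes$FH <- ref_plane("FH", c(0, 0, 0), c(0, 1, 0), "superior")

  mid_keys <- intersect(.lm_midline_codes(), rownames(co))
  if (length(mid_keys) >= 2) {
    XZ <- co[mid_keys, c(1, 3), drop = FALSE]
    Cxz <- sweep(XZ, 2, colMeans(XZ))
    ev <- eigen(crossprod(Cxz), symmetric = TRUE)
    nrm2 <- ev$vectors[, 2]  # smallest-variance direction in the xz plane
    normal <- c(nrm2[1], 0, nrm2[2])
    if (normal[1] < 0) normal <- -normal
    planes$midsagittal <- ref_plane("midsagittal",
                                    c(mean(XZ[, 1]), 0, mean(XZ[, 2])),
                                    normal, "left")
  }

  if (!is.null(planes$midsagittal)) {
    n_ms <- planes$midsagittal$normal
    if (has(c("prn", "pg"))) {
      e_dir <- co["pg", ] - co["prn", ]
      normal <- .cross3(e_dir, n_ms)
      if (sqrt(sum(normal^2)) > 1e-12) {
        if (normal[3] < 0) normal <- -normal
        planes$esthetic <- ref_plane("esthetic", co["prn", ], normal, "anterior")
      }
    }
    if (has("sn")) {
      normal <- .cross3(n_ms, c(0, 1, 0))
      if (normal[3] < 0) normal <- -normal
      planes$TVL <- ref_plane("TVL", co["sn", ], normal, "anterior")
    }
  }

  if (has("g")) planes$transglabellar <- ref_plane("transglabellar", co["g", ], c(0, 1, 0), "superior")
  if (has(c("or_l", "or_r"))) {
    planes$midfacial <- ref_plane("midfacial", (co["or_l", ] + co["or_r", ]) / 2,
                                  c(0, 1, 0), "superior")
  }
  if (has("sn")) planes$transverse_nasal <- ref_plane("transverse_nasal", co["sn", ], c(0, 1, 0), "superior")
  if (has("pra_l")) planes$plumb_left <- ref_plane("plumb_left", co["pra_l", ], c(0, 0, 1), "anterior")
  if (has("pra_r")) planes$plumb_right <- ref_plane("plumb_right", co["pra_r", ], c(0, 0, 1), "anterior")

  missing_kinds <- setdiff(require, names(planes))
  if (length(missing_kinds)) {
    need <- list(midsagittal = .lm_midline_codes(), esthetic = c("prn", "pg"),
                 TVL = "sn", transglabellar = "g", midfacial = c("or_l", "or_r"),
                 transverse_nasal = "sn", plumb_left = "pra_l", plumb_right = "pra_r")
    miss_lm <- unique(unlist(lapply(missing_kinds, function(k)
      setdiff(need[[k]], rownames(co)))))
    stop("cannot build plane(s) ", paste(missing_kinds, collapse = ", "),
         "; missing landmark(s): ", paste(miss_lm, collapse = ", "))
  }
  planes
}
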