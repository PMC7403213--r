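# Triangulated surface meshes: ingestion, plane sectioning and the derived
# curve measurements (cross-section semi-perimeters, profile curves).

.validate_mesh <- function(mesh, area_tol = 1e-12) {
  if (is.null(mesh$vertices) || is.null(mesh$faces)) {
    stop("mesh must have $vertices and $faces")
  }
  V <- as.matrix(mesh$vertices); F <- as.matrix(mesh$faces)
  storage.mode(F) <- "integer"
  if (ncol(V) != 3L) stop("mesh vertices must be an n x 3 matrix")
  if (ncol(F) != 3L) stop("mesh faces must be triangles (m x 3 index matrix)")
  if (!all(is.finite(V))) stop("non-finite mesh vertex")
  if (min(F) < 1L || max(F) > nrow(V)) stop("mesh face references a missing vertex")
  a <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  b <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  area2 <- sqrt(rowSums(cr^2))
  scale <- max(1, max(abs(V)))
  if (any(area2 <= area_tol * scale^2)) stop("mesh has a zero-area triangle")
  structure(list(vertices = unname(V), faces = unname(F)), class = "face_mesh")
}

#' Construct a triangulated surface mesh
#'
#' @param vertices Numeric n x 3 matrix (mm).
#' @param faces Integer m x 3 matrix of vertex indices (1-based, triangles
#'   only).
#' @return An object of class `face_mesh`.
#' @export
face_mesh <- function(vertices, faces) {
  .validate_mesh(list(vertices = vertices, faces = faces))
}

#' Read a triangle mesh from an OBJ or ASCII PLY file
#'
#' Only triangular faces are accepted; quads are rejected.
#'
#' @param path File path (`.obj` or `.ply`).
#' @return A [face_mesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.ply$", path, ignore.case = TRUE)) return(.read_ply(path))
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  V <- do.call(rbind, lapply(strsplit(vl, "[[:space:]]+"), function(p)
    as.numeric(p[2:4])))
  F <- lapply(strsplit(fl, "[[:space:]]+"), function(p) {
    idx <- p[-1]; idx <- idx[nzchar(idx)]
    if (length(idx) != 3L) stop("non-triangular face in OBJ (", length(idx), " vertices); triangulate first")
    as.integer(vapply(strsplit(idx, "/"), `[[`, "", 1L))
  })
  face_mesh(V, do.call(rbind, F))
}

.read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^ply", lines[1])) stop("not a PLY file: ", path)
  if (!any(grepl("format ascii", lines))) stop("only ASCII PLY is supported")
  endh <- grep("^end_header", lines)[1]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)[1]))
  body <- lines[(endh + 1L):length(lines)]
  V <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "[[:space:]]+"),
                             function(p) as.numeric(p[1:3])))
  F <- lapply(strsplit(trimws(body[nv + seq_len(nf)]), "[[:space:]]+"), function(p) {
    k <- as.integer(p[1])
    if (k != 3L) stop("non-triangular face in PLY (", k, " vertices); triangulate first")
    as.integer(p[2:4]) + 1L
  })
  face_mesh(V, do.call(rbind, F))
}

#' Write a triangle mesh as OBJ
#'
#' @param mesh A [face_mesh()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.6f %.6f %.6f", mesh$vertices[, 1], mesh$vertices[, 2],
                     mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  invisible(path)
}

# ---- plane sectioning -------------------------------------------------------

.bbox_diag <- function(V) {
  r <- apply(V, 2, range)
  sqrt(sum((r[2, ] - r[1, ])^2))
}

#' Intersect a triangle mesh with a plane
#'
#' Every triangle crossing the plane contributes one straight segment; the
#' segments are chained into maximal polylines by endpoint matching within a
#' tolerance of `1e-6` times the mesh bounding-box diagonal. Polylines are
#' returned ordered by arc length, longest first.
#'
#' @param mesh A [face_mesh()].
#' @param plane A [ref_plane()].
#' @return A list of polylines (k x 3 matrices); a closed loop repeats its
#'   first point as the last row. Empty list when the plane misses the mesh.
#' @export
mesh_plane_section <- function(mesh, plane) {
  V <- mesh$vertices
  d <- signed_plane_distance(V, plane)
  # vertices (numerically) on the plane make the section topology unstable;
  # shift the whole plane by a negligible deterministic offset instead of
  # nudging individual vertices, so the cut stays a consistent polyline
  eps <- 1e-9 * max(1, .bbox_diag(V))
  for (tries in 1:8) {
    if (!any(abs(d) < eps)) break
    d <- d + 2 * eps
  }
  F <- mesh$faces
  dA <- d[F[, 1]]; dB <- d[F[, 2]]; dC <- d[F[, 3]]
  crossing <- (pmin(dA, dB, dC) < 0) & (pmax(dA, dB, dC) > 0)
  if (!any(crossing)) return(list())
  segs <- vector("list", sum(crossing))
  k <- 0L
  for (fi in which(crossing)) {
    ids <- F[fi, ]
    dd <- d[ids]
    pts <- matrix(NA_real_, 2L, 3L)
    m <- 0L
    for (e in list(c(1L, 2L), c(2L, 3L), c(3L, 1L))) {
      d1 <- dd[e[1]]; d2 <- dd[e[2]]
      if (d1 * d2 < 0) {
        t <- d1 / (d1 - d2)
        m <- m + 1L
        pts[m, ] <- V[ids[e[1]], ] + t * (V[ids[e[2]], ] - V[ids[e[1]], ])
      }
    }
    if (m == 2L) {
      k <- k + 1L
      segs[[k]] <- pts
    }
  }
  segs <- segs[seq_len(k)]
  .chain_segments(segs, tol = 1e-6 * .bbox_diag(V))
}

# Chain unordered segments into maximal polylines by matching endpoints on a
# tolerance grid.
.chain_segments <- function(segs, tol) {
  if (!length(segs)) return(list())
  ends <- do.call(rbind, segs)                 # 2 rows per segment
  key <- apply(round(ends / tol), 1, paste, collapse = ",")
  # drop degenerate segments from triangles grazed tangentially
  same <- key[seq(1, length(key), 2)] == key[seq(2, length(key), 2)]
  if (any(same)) {
    segs <- segs[!same]
    if (!length(segs)) return(list())
    keep_rows <- rep(!same, each = 2)
    ends <- ends[keep_rows, , drop = FALSE]
    key <- key[keep_rows]
  }
  nodes <- unique(key)
  node_id <- match(key, nodes)
  nseg <- length(segs)
  segnode <- matrix(node_id, ncol = 2, byrow = TRUE)  # node ids per segment end
  # adjacency: node -> segment indices
  adj <- split(rep(seq_len(nseg), each = 2), node_id)
  used <- logical(nseg)
  node_pt <- ends[!duplicated(key), , drop = FALSE]

  walk <- function(seg0, start_node) {
    path_nodes <- integer(0)
    cur_seg <- seg0
    cur_node <- start_node
    path_nodes <- c(path_nodes, cur_node)
    repeat {
      used[cur_seg] <<- TRUE
      nxt_node <- setdiff(segnode[cur_seg, ], cur_node)
      if (length(nxt_node) == 0L) nxt_node <- cur_node  # degenerate loop segment
      nxt_node <- nxt_node[1]
      path_nodes <- c(path_nodes, nxt_node)
      cand <- adj[[as.character(nxt_node)]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      cur_seg <- cand[1]
      cur_node <- nxt_node
    }
    path_nodes
  }

  polylines <- list()
  degree <- table(factor(as.vector(segnode), levels = seq_along(nodes)))
  # open chains first (start at odd-degree nodes), then remaining cycles
  for (pass in 1:2) {
    for (s in seq_len(nseg)) {
      if (used[s]) next
      a <- segnode[s, 1]; b <- segnode[s, 2]
      if (pass == 1L) {
        start <- if (degree[a] == 1) a else if (degree[b] == 1) b else NA
        if (is.na(start)) next
      } else {
        start <- a
      }
      pn <- walk(s, start)
      polylines[[length(polylines) + 1L]] <- node_pt[pn, , drop = FALSE]
    }
  }
  lens <- vapply(polylines, polyline_length, 0)
  polylines[order(lens, decreasing = TRUE)]
}

# ---- clipping and sub-paths -------------------------------------------------

# Keep the parts of a polyline where value_fun(points) >= 0 (linear along
# segments), interpolating the crossings; returns a list of sub-polylines.
.clip_polyline <- function(poly, value_fun) {
  n <- nrow(poly)
  v <- value_fun(poly)              # >= 0 means keep, linear along segments
  keep <- v >= 0
  pieces <- list()
  cur <- NULL
  push <- function(p) cur <<- rbind(cur, p)
  for (i in seq_len(n - 1L)) {
    a <- poly[i, ]; b <- poly[i + 1L, ]
    va <- v[i]; vb <- v[i + 1L]
    if (va >= 0) {
      if (is.null(cur)) push(a) else push(a)
    }
    if ((va >= 0) != (vb >= 0)) {
      t <- va / (va - vb)
      x <- a + t * (b - a)
      push(x)
      if (va >= 0) {  # leaving the kept region
        pieces[[length(pieces) + 1L]] <- cur
        cur <- NULL
      }
    }
  }
  if (keep[n]) push(poly[n, ])
  if (!is.null(cur) && nrow(cur) >= 2) pieces[[length(pieces) + 1L]] <- cur
  pieces
}

# Extract the sub-path of a polyline between the points nearest to a and b.
# For closed loops the arc passing nearest `anchor` is returned.
.polyline_subpath <- function(poly, a, b, anchor = NULL) {
  closed <- all(abs(poly[1, ] - poly[nrow(poly), ]) < 1e-12)
  P <- if (closed) poly[-nrow(poly), , drop = FALSE] else poly
  n <- nrow(P)
  nearest <- function(q) which.min(rowSums(sweep(P, 2, q)^2))
  ia <- nearest(a); ib <- nearest(b)
  if (!closed) {
    idx <- if (ia <= ib) ia:ib else ia:ib
    return(P[idx, , drop = FALSE])
  }
  arc1 <- if (ia <= ib) ia:ib else c(ia:n, 1:ib)
  arc2 <- if (ib <= ia) ib:ia else c(ib:n, 1:ia)
  if (is.null(anchor)) {
    arcs <- list(arc1, arc2)
    lens <- vapply(arcs, function(ix) polyline_length(P[ix, , drop = FALSE]), 0)
    return(P[arcs[[which.min(lens)]], , drop = FALSE])
  }
  ic <- nearest(anchor)
  if (ic %in% arc1) P[arc1, , drop = FALSE] else P[rev(arc2), , drop = FALSE]
}

# ---- semi-perimeters and profile curves ------------------------------------

#' Facial cross-section semi-perimeter at a horizontal level
#'
#' Sections the FH-aligned mesh with the named horizontal plane
#' (transglabellar, midfacial or transverse nasal), keeps the connected
#' component of the section facing the anterior midline, clips away the parts
#' posterior to the vertical plumb planes through each preaurale, and returns
#' the remaining arc length. This realizes the head semi-perimeter measured
#' between the two ears at a given level.
#'
#' @param mesh An FH-aligned [face_mesh()].
#' @param level One of `"transglabellar"`, `"midfacial"`, `"transverse_nasal"`.
#' @param planes Reference planes from [build_reference_planes()] (must
#'   contain the level plane and both plumb planes).
#' @return Arc length in mm, or `NA` with a `"reason"` attribute when the
#'   section is empty.
#' @export
semi_perimeter <- function(mesh, level = c("transglabellar", "midfacial", "transverse_nasal"),
                           planes) {
  level <- match.arg(level)
  if (is.null(planes[[level]])) stop("missing reference plane: ", level)
  if (is.null(planes$plumb_left) || is.null(planes$plumb_right)) {
    stop("missing plumb planes (preaurale landmarks required)")
  }
  sect <- mesh_plane_section(mesh, planes[[level]])
  if (!length(sect)) {
    return(structure(NA_real_, reason = paste0("empty section at ", level)))
  }
  # component facing the anterior midline: contains the most anterior point
  front <- which.max(vapply(sect, function(p) max(p[, 3]), 0))
  poly <- sect[[front]]
  zl <- planes$plumb_left$point[3]
  zr <- planes$plumb_right$point[3]
  # keep z >= plumb level of the matching side (x > 0 is subject-left)
  value_fun <- function(P) P[, 3] - ifelse(P[, 1] > 0, zl, zr)
  pieces <- .clip_polyline(poly, value_fun)
  if (!length(pieces)) {
    return(structure(NA_real_, reason = paste0("section fully clipped at ", level)))
  }
  sum(vapply(pieces, polyline_length, 0))
}

#' Extract midsagittal profile curves for the lip and chin windows
#'
#' Sections the mesh with the midsagittal plane and clips the resulting
#' profile to a lip window (subnasale to supramentale) and a chin window
#' (supramentale to cervico-mandibular point), using the scan's landmark
#' heights as window bounds.
#'
#' @param mesh An FH-aligned [face_mesh()].
#' @param planes Reference planes (must contain `midsagittal`).
#' @param scan The FH-aligned [face_scan()] providing `sn`, `sm`, `cm`.
#' @return List with polylines `lip` and `chin` (either may be `NA` with a
#'   reason attribute when the window is empty).
#' @export
extract_profile_curves <- function(mesh, planes, scan) {
  if (is.null(planes$midsagittal)) stop("missing reference plane: midsagittal")
  co <- landmark_coords(scan, c("sn", "sm", "cm"))
  sect <- mesh_plane_section(mesh, planes$midsagittal)
  if (!length(sect)) {
    return(list(lip = structure(NA, reason = "empty midsagittal section"),
                chin = structure(NA, reason = "empty midsagittal section")))
  }
  front <- which.max(vapply(sect, function(p) max(p[, 3]), 0))
  poly <- sect[[front]]
  window <- function(ytop, ybot, label) {
    if (ytop <= ybot) stop("inverted profile window bounds for ", label)
    pieces <- .clip_polyline(poly, function(P) {
      pmin(ytop - P[, 2], P[, 2] - ybot)
    })
    if (!length(pieces)) {
      return(structure(NA, reason = paste0("empty ", label, " window")))
    }
    pieces[[which.max(vapply(pieces, function(p) max(p[, 3]), 0))]]
  }
  list(lip = window(co["sn", 2], co["sm", 2], "lip"),
       chin = window(co["sm", 2], co["cm", 2], "chin"))
}

# Mesh-borne curve length between two landmarks along a section (used for the
# vermilion and mandible curve measurements). `section_plane` cuts the mesh,
# the component nearest `anchor` is selected, and the sub-path between the
# points nearest `a` and `b` is measured.
.mesh_curve_length <- function(mesh, section_plane, a, b, anchor) {
  sect <- mesh_plane_section(mesh, section_plane)
  if (!length(sect)) return(structure(NA_real_, reason = "empty section"))
  near <- which.min(vapply(sect, function(p)
    min(rowSums(sweep(p, 2, anchor)^2)), 0))
  sub <- .polyline_subpath(sect[[near]], a, b, anchor)
  if (nrow(sub) < 2) return(structure(NA_real_, reason = "degenerate section path"))
  polyline_length(sub)
}

# ---- analytic test meshes ---------------------------------------------------

#' UV-sphere triangulation of an ellipsoid
#'
#' A latitude/longitude triangulation used for the closed-form section
#' oracles and for the synthetic template head.
#'
#' @param center Length-3 center.
#' @param radii Length-3 semi-axes (mm).
#' @param n_theta,n_phi Latitude/longitude resolution.
#' @return A [face_mesh()].
#' @export
ellipsoid_mesh <- function(center = c(0, 0, 0), radii = c(1, 1, 1),
                           n_theta = 32L, n_phi = 64L) {
  theta <- seq(0, pi, length.out = n_theta + 1L)[-c(1L, n_theta + 1L)]
  phi <- seq(0, 2 * pi, length.out = n_phi + 1L)[-(n_phi + 1L)]
  grid <- expand.grid(phi = phi, theta = theta)
  V <- cbind(radii[1] * sin(grid$theta) * cos(grid$phi),
             radii[2] * cos(grid$theta),
             radii[3] * sin(grid$theta) * sin(grid$phi))
  V <- rbind(c(0, radii[2], 0), V, c(0, -radii[2], 0))
  V <- sweep(V, 2, center, `+`)
  idx <- function(i, j) 1L + (i - 1L) * n_phi + ((j - 1L) %% n_phi) + 1L
  F <- list()
  for (j in seq_len(n_phi)) F[[length(F) + 1L]] <- c(1L, idx(1L, j + 1L), idx(1L, j))
  for (i in seq_len(n_theta - 2L)) {
    for (j in seq_len(n_phi)) {
      a <- idx(i, j); b <- idx(i, j + 1L); cc <- idx(i + 1L, j); dd <- idx(i + 1L, j + 1L)
      F[[length(F) + 1L]] <- c(a, b, dd)
      F[[length(F) + 1L]] <- c(a, dd, cc)
    }
  }
  south <- nrow(V)
  for (j in seq_len(n_phi)) {
    F[[length(F) + 1L]] <- c(south, idx(n_theta - 1L, j), idx(n_theta - 1L, j + 1L))
  }
  face_mesh(V, do.call(rbind, F))
}

#' Open cylinder triangulation (vertical axis)
#'
#' @param radius Cylinder radius (mm).
#' @param height Cylinder height (mm); axis along +y, centered at `center`.
#' @param center Length-3 center.
#' @param n_phi Angular resolution.
#' @param n_y Axial resolution.
#' @return A [face_mesh()] (lateral surface only, no caps).
#' @export
cylinder_mesh <- function(radius = 1, height = 2, center = c(0, 0, 0),
                          n_phi = 96L, n_y = 8L) {
  phi <- seq(0, 2 * pi, length.out = n_phi + 1L)[-(n_phi + 1L)]
  y <- seq(-height / 2, height / 2, length.out = n_y + 1L)
  V <- do.call(rbind, lapply(y, function(yy)
    cbind(radius * cos(phi), yy, radius * sin(phi))))
  V <- sweep(V, 2, center, `+`)
  idx <- function(i, j) (i - 1L) * n_phi + ((j - 1L) %% n_phi) + 1L
  F <- list()
  for (i in seq_len(n_y)) {
    for (j in seq_len(n_phi)) {
      a <- idx(i, j); b <- idx(i, j + 1L); cc <- idx(i + 1L, j); dd <- idx(i + 1L, j + 1L)
      F[[length(F) + 1L]] <- c(a, b, dd)
      F[[length(F) + 1L]] <- c(a, dd, cc)
    }
  }
  face_mesh(V, do.call(rbind, F))
}
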