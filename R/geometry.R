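#' Euclidean distance between two 3D points
#'
#' @param p,q Numeric length-3 vectors (mm).
#' @return Distance in mm.
#' @export
linear_distance <- function(p, q) {
  if (!all(is.finite(p)) || !all(is.finite(q))) stop("non-finite point")
  sqrt(sum((p - q)^2))
}

#' Arc length of an ordered 3D polyline
#'
#' @param points Numeric matrix, one row per point, 3 columns.
#' @return Total length (mm).
#' @export
polyline_length <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("polyline needs at least 2 points")
  d <- diff(points)
  sum(sqrt(rowSums(d^2)))
}

#' Angle at a vertex between two points, in degrees
#'
#' Interior angle of the triangle `p`-`vertex`-`q` at `vertex`, i.e. the
#' arccosine of the normalized dot product of the two arms, in `[0, 180]`.
#'
#' @param p,vertex,q Numeric length-3 vectors.
#' @return Angle in degrees.
#' @export
angle_at <- function(p, vertex, q) {
  u <- p - vertex
  v <- q - vertex
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("zero-length angle arm at vertex")
  cosang <- sum(u * v) / (nu * nv)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

#' Angle between two direction vectors, in degrees
#'
#' Used for profile angles defined between two lines (e.g. the facial line
#' g-pg versus the nasal line n-prn) rather than at a shared vertex.
#'
#' @param u,v Numeric length-3 direction vectors.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
vector_angle <- function(u, v) {
  angle_at(u, c(0, 0, 0), v)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Perpendicular distance from a point to the line through two points
#'
#' @param p Query point.
#' @param a,b Two distinct points defining the line.
#' @return Distance in mm.
#' @export
point_line_distance <- function(p, a, b) {
  ab <- b - a
  nab <- sqrt(sum(ab^2))
  if (nab == 0) stop("degenerate line (a == b)")
  sqrt(sum(.cross3(p - a, ab)^2)) / nab
}

#' Construct a reference plane
#'
#' @param kind Label, e.g. `"FH"`, `"midsagittal"`, `"esthetic"`, `"TVL"`.
#' @param point A point on the plane.
#' @param normal Plane normal (normalized internally).
#' @param positive_sense Label of the half-space counted positive for signed
#'   distances (e.g. `"anterior"`, `"superior"`).
#' @return An object of class `ref_plane`.
#' @export
ref_plane <- function(kind, point, normal, positive_sense = NA_character_) {
  nn <- sqrt(sum(normal^2))
  if (nn == 0) stop("zero plane normal")
  structure(list(kind = kind, point = as.numeric(point),
                 normal = as.numeric(normal) / nn,
                 positive_sense = positive_sense),
            class = "ref_plane")
}

#' Signed distance from a point to a reference plane
#'
#' Positive on the side of the plane normal (whose direction encodes the
#' plane's `positive_sense`).
#'
#' @param point Numeric length-3 vector, or a matrix of points (rows).
#' @param plane A [ref_plane()].
#' @return Signed distance(s) in mm.
#' @export
signed_plane_distance <- function(point, plane) {
  stopifnot(inherits(plane, "ref_plane"))
  if (is.matrix(point)) {
    as.numeric((point - matrix(plane$point, nrow(point), 3, byrow = TRUE)) %*% plane$normal)
  } else {
    sum((point - plane$point) * plane$normal)
  }
}
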