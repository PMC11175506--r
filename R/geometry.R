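# Low-level planar geometry shared by the mesh, initializer and morphometrics.

#' Signed polygon area (surveyor's formula)
#'
#' @param xy Two-column matrix of vertex coordinates, loop not repeated.
#' @return Signed area; positive for counter-clockwise winding.
#' @keywords internal
polygon_area_signed <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(0)
  i2 <- c(2:n, 1)
  0.5 * sum(xy[, 1] * xy[i2, 2] - xy[i2, 1] * xy[, 2])
}

polygon_perimeter <- function(xy) {
  n <- nrow(xy)
  if (n < 2) return(0)
  i2 <- c(2:n, 1)
  sum(sqrt(rowSums((xy[i2, , drop = FALSE] - xy)^2)))
}

polygon_centroid <- function(xy) {
  n <- nrow(xy)
  i2 <- c(2:n, 1)
  cr <- xy[, 1] * xy[i2, 2] - xy[i2, 1] * xy[, 2]
  a <- 0.5 * sum(cr)
  if (abs(a) < 1e-300) return(colMeans(xy))
  c(sum((xy[, 1] + xy[i2, 1]) * cr), sum((xy[, 2] + xy[i2, 2]) * cr)) / (6 * a)
}

# Vectorised proper-intersection test on coordinate vectors (avoids building
# large temporary matrices): segment i is (px1,py1)-(px2,py2) vs
# (qx1,qy1)-(qx2,qy2). Proper = the open segments cross (strict straddling).
segments_cross_xy <- function(px1, py1, px2, py2, qx1, qy1, qx2, qy2,
                              eps = 1e-12) {
  qdx <- qx2 - qx1; qdy <- qy2 - qy1
  d1 <- qdx * (py1 - qy1) - qdy * (px1 - qx1)
  d2 <- qdx * (py2 - qy1) - qdy * (px2 - qx1)
  pdx <- px2 - px1; pdy <- py2 - py1
  d3 <- pdx * (qy1 - py1) - pdy * (qx1 - px1)
  d4 <- pdx * (qy2 - py1) - pdy * (qx2 - px1)
  (((d1 > eps & d2 < -eps) | (d1 < -eps & d2 > eps)) &
     ((d3 > eps & d4 < -eps) | (d3 < -eps & d4 > eps)))
}

# matrix-argument convenience wrapper
segments_cross <- function(p1, p2, q1, q2, eps = 1e-12) {
  segments_cross_xy(p1[, 1], p1[, 2], p2[, 1], p2[, 2],
                    q1[, 1], q1[, 2], q2[, 1], q2[, 2], eps = eps)
}

#' Is a polygon simple (non-self-intersecting)?
#'
#' Pairwise proper-crossing test between non-adjacent boundary segments.
#' O(k^2); faces in this package are small.
#' @keywords internal
polygon_is_simple <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(FALSE)
  i2 <- c(2:n, 1)
  a1 <- xy
  a2 <- xy[i2, , drop = FALSE]
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]  # skip segments adjacent to i
    if (!length(js)) next
    hit <- segments_cross(
      a1[rep(i, length(js)), , drop = FALSE], a2[rep(i, length(js)), , drop = FALSE],
      a1[js, , drop = FALSE], a2[js, , drop = FALSE]
    )
    if (any(hit)) return(FALSE)
  }
  TRUE
}

#' Regular polygon on a circle
#'
#' @param n Number of vertices.
#' @param radius Circumradius.
#' @param center Length-2 centre.
#' @return `n` x 2 coordinate matrix (counter-clockwise).
#' @export
regular_polygon <- function(n, radius = 1, center = c(0, 0)) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

# Point-in-polygon (strictly inside up to mgcv's boundary convention).
points_in_polygon <- function(pts, poly) {
  bnd <- rbind(poly, poly[1, ])
  mgcv::in.out(as.matrix(bnd), as.matrix(pts))
}

# Bin 2-D points on a square grid; returns integer bin keys.
grid_keys <- function(xy, origin, cell) {
  ix <- floor((xy[, 1] - origin[1]) / cell)
  iy <- floor((xy[, 2] - origin[2]) / cell)
  list(ix = as.integer(ix), iy = as.integer(iy))
}
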