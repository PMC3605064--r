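# Planar geometric primitives shared by the network, growth and field
# modules. All coordinates are in micrometres.

#' Distance from points to a line segment
#'
#' Euclidean distance from each query point to the closed segment
#' \code{(x1,y1)--(x2,y2)}, together with the parameter of the nearest point.
#'
#' @param px,py numeric vectors of query-point coordinates (um).
#' @param x1,y1,x2,y2 segment endpoint coordinates (um).
#' @return list with \code{dist} (um) and \code{t} in \[0, 1\], the fraction
#'   along the segment of the foot of the perpendicular (clamped).
#' @keywords internal
point_segment_distance <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1
  dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  if (len2 < .Machine$double.eps) {
    return(list(dist = sqrt((px - x1)^2 + (py - y1)^2),
                t = rep(0, length(px))))
  }
  t <- ((px - x1) * dx + (py - y1) * dy) / len2
  t <- pmin(1, pmax(0, t))
  qx <- x1 + t * dx
  qy <- y1 + t * dy
  list(dist = sqrt((px - qx)^2 + (py - qy)^2), t = t)
}

#' Pairwise angle between direction vectors, in degrees
#' @keywords internal
vector_angle_deg <- function(ux, uy, vx, vy) {
  dot <- ux * vx + uy * vy
  det <- ux * vy - uy * vx
  ang <- atan2(abs(det), dot) * 180 / pi
  ang
}

#' Test whether points lie inside or on a closed polygon
#'
#' Ray-casting containment with an on-boundary tolerance; the tissue domain
#' is treated as a closed region, so boundary points count as inside.
#'
#' @param px,py query coordinates (um).
#' @param poly two-column matrix of polygon vertices (um), implicitly closed.
#' @param tol distance (um) within which a point is considered on the edge.
#' @return logical vector.
#' @keywords internal
points_in_polygon <- function(px, py, poly, tol = 1e-9) {
  nv <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  if (tol > 0) {
    on_edge <- rep(FALSE, length(px))
    j <- nv
    for (i in seq_len(nv)) {
      d <- point_segment_distance(px, py, poly[j, 1], poly[j, 2],
                                  poly[i, 1], poly[i, 2])$dist
      on_edge <- on_edge | d <= tol
      j <- i
    }
    inside <- inside | on_edge
  }
  inside
}

#' Area of a simple polygon (shoelace formula)
#' @keywords internal
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Rotate 2-D vectors by an angle (radians)
#' @keywords internal
rotate_vec <- function(x, y, theta) {
  cbind(x * cos(theta) - y * sin(theta),
        x * sin(theta) + y * cos(theta))
}

#' First intersection of a directed step with a polygon boundary
#'
#' Used to detect sprout tips crossing the tissue boundary during a 5 um
#' growth increment.
#' @keywords internal
segment_crosses_polygon <- function(x1, y1, x2, y2, poly) {
  nv <- nrow(poly)
  j <- nv
  for (i in seq_len(nv)) {
    x3 <- poly[j, 1]; y3 <- poly[j, 2]
    x4 <- poly[i, 1]; y4 <- poly[i, 2]
    d <- (x2 - x1) * (y4 - y3) - (y2 - y1) * (x4 - x3)
    if (abs(d) > .Machine$double.eps) {
      t <- ((x3 - x1) * (y4 - y3) - (y3 - y1) * (x4 - x3)) / d
      u <- ((x3 - x1) * (y2 - y1) - (y3 - y1) * (x2 - x1)) / d
      if (t > 1e-9 && t <= 1 && u >= 0 && u <= 1) return(TRUE)
    }
    j <- i
  }
  FALSE
}
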