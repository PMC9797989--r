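# Planar polygon / polyline primitives shared by the anatomy, tracking and
# slicing code. Polygons are n x 2 matrices of vertices, implicitly closed
# (last vertex joins the first), counterclockwise for positive area.

#' Signed polygon area (shoelace formula)
#'
#' @param xy n x 2 matrix of vertices of an implicitly closed polygon.
#' @return Signed area; positive for counterclockwise orientation.
#' @export
polygon_area <- function(xy) {
  xy <- as.matrix(xy)
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * sum(x * yn - xn * y)
}

#' Polygon centroid
#'
#' @param xy n x 2 vertex matrix.
#' @return Length-2 centroid of the enclosed region.
#' @export
polygon_centroid <- function(xy) {
  xy <- as.matrix(xy)
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- 0.5 * sum(cr)
  if (abs(a) < .Machine$double.eps) return(colMeans(xy))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

ensure_ccw <- function(xy) {
  if (polygon_area(xy) < 0) xy[rev(seq_len(nrow(xy))), , drop = FALSE] else xy
}

#' Test whether points fall inside a polygon
#'
#' @param pts m x 2 matrix of query points.
#' @param poly n x 2 vertex matrix (implicitly closed).
#' @return Logical vector of length m.
#' @export
points_in_polygon <- function(pts, poly) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  bnd <- rbind(as.matrix(poly), as.matrix(poly)[1, , drop = FALSE])
  mgcv::in.out(bnd, pts)
}

# distance from each point in pts (m x 2) to a segment a-b; vectorized in pts
dist_points_to_segment <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 < .Machine$double.eps) {
    return(sqrt((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2))
  }
  t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
  t <- pmin(1, pmax(0, t))
  dx <- pts[, 1] - (a[1] + t * ab[1])
  dy <- pts[, 2] - (a[2] + t * ab[2])
  sqrt(dx^2 + dy^2)
}

# min distance from each point to a polyline given as an n x 2 matrix
# (open chain; close it first if a loop is wanted)
dist_points_to_polyline <- function(pts, chain) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  d <- rep(Inf, nrow(pts))
  for (k in seq_len(nrow(chain) - 1)) {
    d <- pmin(d, dist_points_to_segment(pts, chain[k, ], chain[k + 1, ]))
  }
  d
}

# do segments p1-p2 and p3-p4 properly intersect (excluding shared endpoints)?
segs_cross <- function(p1, p2, p3, p4, eps = 1e-12) {
  d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
  d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
  d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
  d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
  (d1 * d2 < -eps) && (d3 * d4 < -eps)
}

# brute-force simplicity check; adequate for the boundary sizes used here
polygon_is_simple <- function(xy) {
  n <- nrow(xy)
  idx <- seq_len(n)
  nxt <- c(idx[-1], 1L)
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      if (j == i || nxt[j] == i) next
      if (segs_cross(xy[i, ], xy[nxt[i], ], xy[j, ], xy[nxt[j], ])) return(FALSE)
    }
  }
  TRUE
}

# Sutherland-Hodgman clip of an arbitrary subject polygon by one half-plane
# keep { x : n . x <= c }
clip_halfplane <- function(subject, nrm, cval, eps = 1e-12) {
  if (is.null(subject) || nrow(subject) == 0) return(subject)
  n <- nrow(subject)
  out <- matrix(0, n * 2, 2)
  m <- 0L
  d <- subject %*% nrm - cval
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    di <- d[i]; dj <- d[j]
    if (di <= eps) {
      m <- m + 1L; out[m, ] <- subject[i, ]
    }
    if ((di < -eps && dj > eps) || (di > eps && dj < -eps)) {
      t <- di / (di - dj)
      m <- m + 1L; out[m, ] <- subject[i, ] + t * (subject[j, ] - subject[i, ])
    }
  }
  out[seq_len(m), , drop = FALSE]
}

#' Intersect a polygon with a convex polygon
#'
#' Sutherland-Hodgman clipping of an arbitrary simple subject polygon against a
#' convex clip polygon. The result is valid for area computation even when the
#' subject is non-convex.
#'
#' @param subject n x 2 vertex matrix (any simple polygon).
#' @param clip m x 2 vertex matrix of a convex polygon (either orientation).
#' @return Vertex matrix of the intersection (possibly with 0 rows).
#' @export
clip_polygon_convex <- function(subject, clip) {
  clip <- ensure_ccw(as.matrix(clip))
  out <- as.matrix(subject)
  m <- nrow(clip)
  for (k in seq_len(m)) {
    a <- clip[k, ]; b <- clip[if (k == m) 1L else k + 1L, ]
    e <- b - a
    nrm <- c(e[2], -e[1])            # outward normal of a CCW edge
    out <- clip_halfplane(out, nrm, sum(nrm * a))
    if (is.null(out) || nrow(out) < 3) return(matrix(numeric(0), 0, 2))
  }
  out
}

# cumulative arc length of an open chain
chain_arclength <- function(xy) {
  d <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  c(0, cumsum(d))
}

# resample an open chain to n points uniformly in arc length
resample_chain <- function(xy, n) {
  s <- chain_arclength(xy)
  si <- seq(0, s[length(s)], length.out = n)
  cbind(approx(s, xy[, 1], xout = si)$y, approx(s, xy[, 2], xout = si)$y)
}

smoothstep <- function(x) {
  x <- pmin(1, pmax(0, x))
  x * x * (3 - 2 * x)
}
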