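# 3D geometric pre-procedural assessment: pose a cylindrical device at the
# mitral annulus of a surface mesh, find the neo-LVOT axis, slice the free
# lumen perpendicular to it and report the minimal area, the aortomitral
# angle and the anatomic risk class.

#' Least-squares plane through the annulus landmarks
#'
#' Total-least-squares fit (SVD of the centred landmark coordinates); the
#' normal is oriented toward the ventricular side, taken as the side holding
#' the centroid of all mesh vertices.
#'
#' @param mesh A `surface_mesh3d` with >= 3 non-collinear annulus landmarks.
#' @return List with `point` (plane centroid) and `normal` (unit vector).
#' @export
fit_annulus_plane <- function(mesh) {
  lm <- mesh$vertices[mesh$annulus_landmarks, , drop = FALSE]
  ctr <- colMeans(lm)
  sv <- svd(sweep(lm, 2, ctr))
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-12)) {
    abort("annulus landmarks are collinear; a plane is not determined")
  }
  n <- sv$v[, 3]
  body <- colMeans(mesh$vertices)
  if (sum((body - ctr) * n) < 0) n <- -n
  list(point = ctr, normal = n / sqrt(sum(n^2)))
}

# finite-cylinder / plane cross-section as a convex polygon in the plane's
# 2D basis; returns a k x 2 matrix (possibly empty)
cylinder_section_polygon <- function(dev, basis, n_theta = 180) {
  n <- basis$n; p0 <- basis$point
  a <- dev$axis; b <- dev$base_center
  cth <- sum(a * n)
  to2d <- function(P) cbind(as.numeric((sweep(P, 2, p0)) %*% basis$e1),
                            as.numeric((sweep(P, 2, p0)) %*% basis$e2))
  if (abs(cth) > 1e-8) {
    # oblique ellipse: centre where the axis meets the plane, semi-major
    # r/|cos| along the in-plane projection of the axis, semi-minor r
    tstar <- sum((p0 - b) * n) / cth
    ec <- b + tstar * a
    m1 <- a - cth * n
    l1 <- sqrt(sum(m1^2))
    if (l1 < 1e-12) {
      # plane perpendicular to the axis: a circle
      m1 <- basis$e1; m2 <- basis$e2
      rmaj <- dev$radius; rmin <- dev$radius
    } else {
      m1 <- m1 / l1
      m2 <- c(n[2] * m1[3] - n[3] * m1[2],
              n[3] * m1[1] - n[1] * m1[3],
              n[1] * m1[2] - n[2] * m1[1])
      rmaj <- dev$radius / abs(cth); rmin <- dev$radius
    }
    th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
    P <- sweep(outer(rmaj * cos(th), m1) + outer(rmin * sin(th), m2), 2, ec, "+")
    # clip by the two cap half-planes 0 <= (q - b).a <= h  (linear in-plane)
    q2 <- to2d(P)
    tt <- as.numeric(sweep(P, 2, b) %*% a)
    # express (q - b).a as affine function of the 2D coords to clip exactly
    g1 <- sum(basis$e1 * a); g2 <- sum(basis$e2 * a)
    c0 <- sum((p0 - b) * a)
    poly <- q2
    poly <- clip_halfplane(poly, c(-g1, -g2), c0)              # t >= 0
    poly <- clip_halfplane(poly, c(g1, g2), dev$height - c0)   # t <= h
    if (is.null(poly) || nrow(poly) < 3) return(matrix(numeric(0), 0, 2))
    poly
  } else {
    # axis parallel to the plane: the section is a rectangle (chord strip)
    delta <- sum((b - p0) * n)
    if (abs(delta) >= dev$radius) return(matrix(numeric(0), 0, 2))
    half_chord <- sqrt(dev$radius^2 - delta^2)
    # in-plane axis direction and transverse direction
    a2 <- c(sum(basis$e1 * a), sum(basis$e2 * a))
    b2 <- c(sum((b - p0) * basis$e1), sum((b - p0) * basis$e2))
    # transverse unit in-plane, perpendicular to a2
    t2 <- c(-a2[2], a2[1])
    ctr2 <- b2 + delta * 0  # base centre projected into the plane
    rect <- rbind(ctr2 + half_chord * t2,
                  ctr2 + half_chord * t2 + dev$height * a2,
                  ctr2 - half_chord * t2 + dev$height * a2,
                  ctr2 - half_chord * t2)
    rect
  }
}

# lumen loop of a mesh section: the closed loop with the largest area;
# errors if no closed loop exists
section_lumen <- function(mesh, point, normal, slice_label = "") {
  sec <- mesh_plane_section(mesh, point, normal)
  closed <- Filter(function(l) isTRUE(l$closed), sec$loops)
  if (length(closed) == 0) {
    abort(sprintf("slice%s failed to produce a closed mesh cross-section",
                  slice_label))
  }
  areas <- vapply(closed, function(l) abs(polygon_area(l$pts)), numeric(1))
  list(poly = ensure_ccw(closed[[which.max(areas)]]$pts), basis = sec$basis)
}

# free-lumen polygon area at one slice: lumen minus the device section
slice_free_area <- function(mesh, dev, point, normal, slice_label = "") {
  lum <- section_lumen(mesh, point, normal, slice_label)
  a_lum <- polygon_area(lum$poly)
  dpoly <- cylinder_section_polygon(dev, lum$basis)
  if (nrow(dpoly) < 3) return(list(area = a_lum, lumen = lum))
  inter <- clip_polygon_convex(lum$poly, dpoly)
  a_int <- if (nrow(inter) >= 3) abs(polygon_area(inter)) else 0
  list(area = max(a_lum - a_int, 0), lumen = lum, inter = inter)
}

# centroid of the free lumen at a slice (area-weighted difference)
slice_free_centroid3d <- function(mesh, dev, point, normal) {
  sf <- slice_free_area(mesh, dev, point, normal)
  lum <- sf$lumen
  a_l <- polygon_area(lum$poly)
  c_l <- polygon_centroid(lum$poly)
  if (!is.null(sf$inter) && nrow(sf$inter) >= 3) {
    a_i <- abs(polygon_area(sf$inter))
    c_i <- polygon_centroid(sf$inter)
    if (a_l - a_i <= 1e-9) abort("slice is fully obstructed; centroid undefined")
    c2 <- (a_l * c_l - a_i * c_i) / (a_l - a_i)
  } else {
    c2 <- c_l
  }
  b <- lum$basis
  b$point + c2[1] * b$e1 + c2[2] * b$e2
}

#' Neo-LVOT axis of a mesh with a posed device
#'
#' The axis runs from the centroid of the free lumen in the slice at the
#' device's ventricular edge (the cap nearer the annulus) to the centroid of
#' the LVOT outlet landmarks.
#'
#' @param mesh A `surface_mesh3d`.
#' @param device A `cylinder_device`.
#' @return List with `point` (ventricular end), `direction` (unit vector) and
#'   `length` (mm).
#' @export
neo_lvot_axis <- function(mesh, device) {
  ann <- colMeans(mesh$vertices[mesh$annulus_landmarks, , drop = FALSE])
  out <- colMeans(mesh$vertices[mesh$lvot_outlet_landmarks, , drop = FALSE])
  d0 <- out - ann
  l0 <- sqrt(sum(d0^2))
  if (l0 < 1e-9) abort("annulus and outlet centroids coincide; axis degenerate")
  d0 <- d0 / l0
  caps <- rbind(device$base_center,
                device$base_center + device$height * device$axis)
  edge <- caps[which.min(caps %*% d0), ]
  # slice at the ventricular edge, nudged into the channel interior
  s_edge <- sum((edge - ann) * d0)
  s_edge <- max(s_edge, 0.02 * l0)
  start <- slice_free_centroid3d(mesh, device, ann + s_edge * d0, d0)
  dirv <- out - start
  len <- sqrt(sum(dirv^2))
  if (len < 1e-9) abort("neo-LVOT axis has zero length")
  list(point = start, direction = dirv / len, length = len)
}

#' Minimal neo-LVOT free-lumen area
#'
#' Slices the channel with `n_slices` planes perpendicular to the neo-LVOT
#' axis between the device's ventricular edge and the outlet. At each slice
#' the free-lumen area is the mesh cross-section area minus the part covered
#' by the (solid) device cylinder, computed by exact polygon clipping.
#'
#' @param mesh A `surface_mesh3d`.
#' @param device A `cylinder_device`.
#' @param n_slices Number of slices (>= 3, default 50).
#' @return List with `min_area` (mm^2), `profile` (tibble: `slice`, `s_mm`
#'   along the axis, `area_mm2`) and `axis`.
#' @export
neo_lvot_area <- function(mesh, device, n_slices = 50) {
  if (n_slices < 3) abort("`n_slices` must be >= 3")
  ax <- neo_lvot_axis(mesh, device)
  svals <- seq(0.01, 0.99, length.out = n_slices) * ax$length
  areas <- vapply(seq_along(svals), function(i) {
    slice_free_area(mesh, device, ax$point + svals[i] * ax$direction,
                    ax$direction, slice_label = sprintf(" %d", i))$area
  }, numeric(1))
  list(min_area = min(areas),
       profile = tibble(slice = seq_len(n_slices), s_mm = svals,
                        area_mm2 = areas),
       axis = ax)
}

#' Aortomitral angle between annulus plane and LVOT axis
#'
#' Reported by the obtuse convention used on long-axis CT reads: with `phi`
#' the elevation of the axis out of the annulus plane, the angle is
#' `180 - phi` degrees. An axis lying in the plane gives 180 degrees, an axis
#' perpendicular to the plane gives 90.
#'
#' @param plane List with `point` and unit `normal` (from
#'   [fit_annulus_plane()]).
#' @param axis List with unit `direction` (from [neo_lvot_axis()]), or a unit
#'   3-vector.
#' @return Angle in degrees, in (90, 180].
#' @export
aortomitral_angle <- function(plane, axis) {
  d <- if (is.list(axis)) axis$direction else axis
  l <- sqrt(sum(d^2))
  if (l < 1e-12) abort("axis direction has zero length")
  d <- d / l
  sphi <- abs(sum(d * plane$normal))
  phi <- asin(pmin(1, sphi)) * 180 / pi
  180 - phi
}

#' Anatomic LVOT-obstruction risk class from the neo-LVOT area
#'
#' The clinical rule of thumb: a neo-LVOT area below 180 mm^2 predicts an
#' unacceptable degree of obstruction, 180-200 mm^2 (inclusive) is borderline,
#' above 200 mm^2 acceptable.
#'
#' @param min_area Minimal neo-LVOT area (mm^2), non-negative.
#' @return One of `"unacceptable"`, `"borderline"`, `"acceptable"`.
#' @export
classify_anatomic_risk <- function(min_area) {
  if (any(!is.finite(min_area)) || any(min_area < 0)) {
    abort("`min_area` must be non-negative")
  }
  out <- ifelse(min_area < 180, "unacceptable",
                ifelse(min_area <= 200, "borderline", "acceptable"))
  unname(out)
}

#' One-call neo-LVOT geometric report
#'
#' @param mesh A `surface_mesh3d`.
#' @param device A `cylinder_device`.
#' @param n_slices Number of slices.
#' @return A `neolvot_report`: list with `min_area_mm2`, `angle_deg`,
#'   `risk_class`, `profile` and `axis`.
#' @export
neolvot_report <- function(mesh, device, n_slices = 50) {
  res <- neo_lvot_area(mesh, device, n_slices)
  pl <- fit_annulus_plane(mesh)
  ang <- aortomitral_angle(pl, res$axis)
  structure(list(min_area_mm2 = res$min_area, angle_deg = ang,
                 risk_class = classify_anatomic_risk(res$min_area),
                 profile = res$profile, axis = res$axis, plane = pl),
            class = "neolvot_report")
}

#' @export
print.neolvot_report <- function(x, ...) {
  cat(sprintf("<neolvot_report> min area %.1f mm^2 (%s), aortomitral angle %.1f deg\n",
              x$min_area_mm2, x$risk_class, x$angle_deg))
  invisible(x)
}

#' @rdname neolvot_report
#' @param x A `neolvot_report`.
#' @param ... Unused.
#' @export
tidy.neolvot_report <- function(x, ...) {
  x$profile
}

#' @rdname neolvot_report
#' @export
glance.neolvot_report <- function(x, ...) {
  tibble(min_area_mm2 = x$min_area_mm2, angle_deg = x$angle_deg,
         risk_class = x$risk_class)
}
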