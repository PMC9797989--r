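# Triangle surface meshes for the 3D neo-LVOT stage: construction of
# tube-and-cylinder phantoms, watertightness checks, STL export and
# plane-mesh cross-sections.

#' Triangle surface mesh with valve landmarks
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param triangles m x 3 integer matrix of 1-based vertex indices with
#'   consistent winding.
#' @param annulus_landmarks Indices of >= 3 vertices on the mitral annulus.
#' @param lvot_outlet_landmarks Indices of >= 3 vertices on the LVOT outlet.
#' @return A `surface_mesh3d` object.
#' @export
surface_mesh3d <- function(vertices, triangles, annulus_landmarks,
                           lvot_outlet_landmarks) {
  vertices <- as.matrix(vertices)
  dimnames(vertices) <- NULL
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  if (ncol(vertices) != 3) abort("`vertices` must be n x 3")
  nv <- nrow(vertices)
  if (any(triangles < 1 | triangles > nv)) abort("triangle indices out of range")
  for (lm in list(annulus_landmarks, lvot_outlet_landmarks)) {
    if (length(lm) < 3 || any(lm < 1 | lm > nv)) {
      abort("landmarks must be >= 3 valid vertex indices")
    }
  }
  structure(list(vertices = vertices, triangles = triangles,
                 annulus_landmarks = as.integer(annulus_landmarks),
                 lvot_outlet_landmarks = as.integer(lvot_outlet_landmarks)),
            class = "surface_mesh3d")
}

#' @export
print.surface_mesh3d <- function(x, ...) {
  cat(sprintf("<surface_mesh3d> %d vertices, %d triangles, watertight: %s\n",
              nrow(x$vertices), nrow(x$triangles), mesh_is_watertight(x)))
  invisible(x)
}

#' Check that every mesh edge is shared by exactly two triangles
#'
#' @param mesh A `surface_mesh3d`.
#' @return Logical scalar.
#' @export
mesh_is_watertight <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2)
}

#' Rigid cylinder model of the bioprosthetic device
#'
#' @param radius,height Cylinder dimensions (mm), both positive.
#' @param base_center 3D point (mm) of the annulus-side cap centre.
#' @param axis Unit 3D vector from the base cap toward the opposite cap.
#' @return A `cylinder_device` object.
#' @export
cylinder_device <- function(radius, height, base_center, axis) {
  if (radius <= 0 || height <= 0) abort("`radius` and `height` must be positive")
  nrm <- sqrt(sum(axis^2))
  if (abs(nrm - 1) > 1e-8) abort("`axis` must be a unit vector")
  structure(list(radius = radius, height = height,
                 base_center = as.numeric(base_center),
                 axis = as.numeric(axis)),
            class = "cylinder_device")
}

# are 3D points inside the (closed) finite cylinder?
points_in_cylinder <- function(pts, dev) {
  rel <- sweep(matrix(pts, ncol = 3), 2, dev$base_center)
  t <- rel %*% dev$axis
  perp2 <- rowSums(rel^2) - t^2
  (t >= 0) & (t <= dev$height) & (perp2 <= dev$radius^2 + 1e-12)
}

# triangulated tube (cylindrical surface of radius r along +z from 0 to len,
# capped) used as the analytic LVOT-channel phantom
tube_mesh <- function(radius, len, n_around = 48, n_axial = 24) {
  th <- seq(0, 2 * pi, length.out = n_around + 1)[-(n_around + 1)]
  zs <- seq(0, len, length.out = n_axial + 1)
  ring <- cbind(radius * cos(th), radius * sin(th))
  verts <- do.call(rbind, lapply(zs, function(z) cbind(ring, z)))
  idx <- function(i, k) (k - 1L) * n_around + i        # ring k, position i
  tris <- list()
  for (k in seq_len(n_axial)) {
    i <- seq_len(n_around); i2 <- c(i[-1], 1L)
    a <- idx(i, k); b <- idx(i2, k); c2 <- idx(i, k + 1); d <- idx(i2, k + 1)
    tris[[length(tris) + 1L]] <- cbind(a, b, d)
    tris[[length(tris) + 1L]] <- cbind(a, d, c2)
  }
  nv <- nrow(verts)
  bot_c <- nv + 1L; top_c <- nv + 2L
  verts <- rbind(verts, c(0, 0, 0), c(0, 0, len))
  i <- seq_len(n_around); i2 <- c(i[-1], 1L)
  tris[[length(tris) + 1L]] <- cbind(idx(i2, 1L), idx(i, 1L), bot_c)
  tris[[length(tris) + 1L]] <- cbind(idx(i, n_axial + 1L), idx(i2, n_axial + 1L), top_c)
  list(vertices = verts, triangles = do.call(rbind, tris),
       bottom_ring = idx(seq_len(n_around), 1L),
       top_ring = idx(seq_len(n_around), n_axial + 1L))
}

#' Generate a 3D tube-and-cylinder phantom
#'
#' A watertight triangulated straight tube stands in for the LVOT channel,
#' with annulus landmarks on its bottom rim and outlet landmarks on its top
#' rim; a cylindrical device is posed at the annulus with its axis parallel to
#' the tube and a lateral offset controlled by the valve spec's
#' `protrusion_fraction`: 0 places the device just touching the channel from
#' outside (no obstruction), 1 buries it one diameter deep. Cross-section
#' areas are then known in closed form (circle minus circle-circle lens).
#'
#' @param params An [lv_shape_params()]; `lvot_width` sets the tube diameter.
#' @param spec A [valve_frame_spec()]; diameter, height and
#'   `protrusion_fraction` pose the cylinder.
#' @param tube_length Tube length (mm).
#' @param n_around,n_axial Mesh resolution.
#' @return List with `mesh` (a `surface_mesh3d`) and `device`
#'   (a `cylinder_device`).
#' @export
generate_3d_phantom <- function(params, spec, tube_length = 40,
                                n_around = 64, n_axial = 30) {
  stopifnot(inherits(params, "lv_shape_params"),
            inherits(spec, "valve_frame_spec"))
  rt <- params$lvot_width / 2
  tm <- tube_mesh(rt, tube_length, n_around, n_axial)
  mesh <- surface_mesh3d(tm$vertices, tm$triangles,
                         annulus_landmarks = tm$bottom_ring,
                         lvot_outlet_landmarks = tm$top_ring)
  rd <- spec$diameter / 2
  offset <- (rt + rd) - spec$protrusion_fraction * 2 * rd
  dev <- cylinder_device(radius = rd, height = spec$height,
                         base_center = c(offset, 0, 2),
                         axis = c(0, 0, 1))
  list(mesh = mesh, device = dev)
}

#' Write a triangle mesh as STL
#'
#' @param mesh A `surface_mesh3d` (or list with `vertices`/`triangles`).
#' @param path Output file.
#' @param binary Write binary STL (default) or ASCII.
#' @return Invisibly, `path`.
#' @export
write_stl <- function(mesh, path, binary = TRUE) {
  v <- mesh$vertices; tr <- mesh$triangles
  p1 <- v[tr[, 1], , drop = FALSE]
  p2 <- v[tr[, 2], , drop = FALSE]
  p3 <- v[tr[, 3], , drop = FALSE]
  nrm <- cbind((p2[, 2] - p1[, 2]) * (p3[, 3] - p1[, 3]) - (p2[, 3] - p1[, 3]) * (p3[, 2] - p1[, 2]),
               (p2[, 3] - p1[, 3]) * (p3[, 1] - p1[, 1]) - (p2[, 1] - p1[, 1]) * (p3[, 3] - p1[, 3]),
               (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) - (p2[, 2] - p1[, 2]) * (p3[, 1] - p1[, 1]))
  nl <- sqrt(rowSums(nrm^2)); nl[nl == 0] <- 1
  nrm <- nrm / nl
  nt <- nrow(tr)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nt), con, size = 4, endian = "little")
    dat <- t(cbind(nrm, p1, p2, p3))
    for (i in seq_len(nt)) {
      writeBin(as.numeric(dat[, i]), con, size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  } else {
    con <- file(path, "wt")
    on.exit(close(con))
    writeLines("solid mesh", con)
    for (i in seq_len(nt)) {
      writeLines(c(
        sprintf("  facet normal %g %g %g", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
        "    outer loop",
        sprintf("      vertex %g %g %g", p1[i, 1], p1[i, 2], p1[i, 3]),
        sprintf("      vertex %g %g %g", p2[i, 1], p2[i, 2], p2[i, 3]),
        sprintf("      vertex %g %g %g", p3[i, 1], p3[i, 2], p3[i, 3]),
        "    endloop",
        "  endfacet"), con)
    }
    writeLines("endsolid mesh", con)
  }
  invisible(path)
}

#' Read an STL surface mesh
#'
#' Reads binary or ASCII STL, merging coincident vertices. Landmarks come from
#' a JSON sidecar (see [write_mesh_landmarks()]).
#'
#' @param path STL file.
#' @param landmarks Optional path to a landmarks JSON sidecar.
#' @param tol Vertex-merge tolerance (mm).
#' @return A `surface_mesh3d` (with dummy landmarks if no sidecar is given).
#' @export
read_stl <- function(path, landmarks = NULL, tol = 1e-6) {
  con <- file(path, "rb")
  head80 <- readBin(con, "raw", 80)
  nt <- readBin(con, "integer", 1, size = 4, endian = "little")
  expected <- 84 + nt * 50
  is_binary <- length(nt) == 1 && !is.na(nt) && file.size(path) == expected
  close(con)
  if (is_binary) {
    con <- file(path, "rb")
    on.exit(close(con))
    invisible(readBin(con, "raw", 84))
    tri_pts <- matrix(0, nt * 3, 3)
    for (i in seq_len(nt)) {
      vals <- readBin(con, "numeric", 12, size = 4, endian = "little")
      invisible(readBin(con, "raw", 2))
      tri_pts[(3 * i - 2):(3 * i), ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
    }
  } else {
    txt <- readLines(path)
    vl <- grep("^\\s*vertex", txt, value = TRUE)
    tri_pts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(w) {
      as.numeric(w[2:4])
    }))
    nt <- nrow(tri_pts) / 3
  }
  key <- apply(round(tri_pts / tol) * tol, 1, paste, collapse = "|")
  uk <- !duplicated(key)
  verts <- tri_pts[uk, , drop = FALSE]
  map <- match(key, key[uk])
  tris <- matrix(map, ncol = 3, byrow = TRUE)
  lm <- if (!is.null(landmarks)) {
    j <- jsonlite::read_json(landmarks, simplifyVector = TRUE)
    list(ann = j$annulus_landmarks, out = j$lvot_outlet_landmarks)
  } else {
    list(ann = 1:3, out = 4:6)
  }
  surface_mesh3d(verts, tris, lm$ann, lm$out)
}

#' Write mesh landmarks to a JSON sidecar
#'
#' @param mesh A `surface_mesh3d`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_mesh_landmarks <- function(mesh, path) {
  jsonlite::write_json(list(annulus_landmarks = mesh$annulus_landmarks,
                            lvot_outlet_landmarks = mesh$lvot_outlet_landmarks),
                       path, auto_unbox = FALSE)
  invisible(path)
}

# Intersect a surface mesh with a plane. Returns a list of closed loops, each
# a matrix of 2D coordinates in the in-plane basis (e1, e2), plus the basis.
mesh_plane_section <- function(mesh, point, normal) {
  n <- normal / sqrt(sum(normal^2))
  v <- mesh$vertices
  d <- as.numeric(v %*% n) - sum(point * n)
  # nudge the plane off any vertex it passes through exactly
  if (any(abs(d) < 1e-9)) {
    point <- point + n * 1e-6
    d <- as.numeric(v %*% n) - sum(point * n)
  }
  tr <- mesh$triangles
  s1 <- d[tr[, 1]]; s2 <- d[tr[, 2]]; s3 <- d[tr[, 3]]
  crossed <- !(pmin(s1, s2, s3) > 0 | pmax(s1, s2, s3) < 0)
  if (!any(crossed)) return(list(loops = list(), basis = NULL))
  segs <- list()
  edge_cut <- function(i, j, di, dj) {
    t <- di / (di - dj)
    v[i, ] + t * (v[j, ] - v[i, ])
  }
  for (ti in which(crossed)) {
    a <- tr[ti, 1]; b <- tr[ti, 2]; c2 <- tr[ti, 3]
    dd <- d[c(a, b, c2)]
    vv <- c(a, b, c2)
    pts <- list()
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      if ((dd[e[1]] > 0) != (dd[e[2]] > 0)) {
        pts[[length(pts) + 1L]] <- edge_cut(vv[e[1]], vv[e[2]], dd[e[1]], dd[e[2]])
      }
    }
    if (length(pts) == 2) segs[[length(segs) + 1L]] <- rbind(pts[[1]], pts[[2]])
  }
  if (length(segs) == 0) return(list(loops = list(), basis = NULL))
  # in-plane orthonormal basis
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * n) * n; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  to2d <- function(p) c(sum((p - point) * e1), sum((p - point) * e2))
  ends <- do.call(rbind, lapply(segs, function(sg) {
    c(to2d(sg[1, ]), to2d(sg[2, ]))
  }))
  # chain segments into loops by matching endpoints
  nseg <- nrow(ends)
  used <- rep(FALSE, nseg)
  scale <- max(abs(ends)) + 1
  tol <- 1e-7 * scale
  loops <- list()
  for (start in seq_len(nseg)) {
    if (used[start]) next
    used[start] <- TRUE
    loop <- rbind(ends[start, 1:2], ends[start, 3:4])
    repeat {
      cur <- loop[nrow(loop), ]
      hit <- NA
      for (k in which(!used)) {
        if (max(abs(ends[k, 1:2] - cur)) < tol) { hit <- k; flip <- FALSE; break }
        if (max(abs(ends[k, 3:4] - cur)) < tol) { hit <- k; flip <- TRUE; break }
      }
      if (is.na(hit)) break
      used[hit] <- TRUE
      nxt <- if (flip) ends[hit, 1:2] else ends[hit, 3:4]
      loop <- rbind(loop, nxt)
    }
    closed <- max(abs(loop[1, ] - loop[nrow(loop), ])) < tol
    if (closed && nrow(loop) > 3) {
      loops[[length(loops) + 1L]] <- list(pts = loop[-nrow(loop), , drop = FALSE],
                                          closed = TRUE)
    } else {
      loops[[length(loops) + 1L]] <- list(pts = loop, closed = closed)
    }
  }
  list(loops = loops, basis = list(point = point, n = n, e1 = e1, e2 = e2))
}
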