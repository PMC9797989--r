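# Binary raster masks of the cavity, the 2D stand-in for segmented CT frames.
# Used as fixtures for the wall-tracking stage.

#' Rasterize a motion series into binary cavity masks
#'
#' One logical matrix per frame; a pixel is set when its centre lies inside
#' the cavity boundary. Mask area converges to the polygon (shoelace) area as
#' `pixel_size` decreases.
#'
#' @param series A `motion_series`.
#' @param pixel_size Pixel edge length (mm).
#' @param pad Margin around the all-frame bounding box (mm).
#' @return A `mask_stack`: list of logical matrices (rows index x, columns y)
#'   with `origin` (centre of pixel \[1,1\]), `pixel_size` and frame `times`.
#' @export
make_masks <- function(series, pixel_size, pad = 2) {
  stopifnot(inherits(series, "motion_series"))
  if (!is.finite(pixel_size) || pixel_size <= 0) abort("`pixel_size` must be > 0")
  if (min(series$areas) <= pixel_size^2) {
    abort("boundary has (near-)empty interior at this pixel size")
  }
  xr <- range(series$xs) + c(-pad, pad)
  yr <- range(series$ys) + c(-pad, pad)
  xg <- seq(xr[1], xr[2], by = pixel_size)
  yg <- seq(yr[1], yr[2], by = pixel_size)
  pts <- cbind(rep(xg, times = length(yg)), rep(yg, each = length(xg)))
  masks <- lapply(seq_along(series$times), function(k) {
    matrix(points_in_polygon(pts, frame_boundary(series, k)),
           nrow = length(xg), ncol = length(yg))
  })
  structure(list(masks = masks, origin = c(xr[1], yr[1]),
                 pixel_size = pixel_size, times = series$times),
            class = "mask_stack")
}

#' Mask areas of a stack
#'
#' @param stack A `mask_stack`.
#' @return Tibble with `frame`, `time` and `area` (mm^2, pixel count times
#'   pixel area).
#' @export
mask_areas <- function(stack) {
  tibble(frame = seq_along(stack$masks), time = stack$times,
         area = vapply(stack$masks, sum, numeric(1)) * stack$pixel_size^2)
}

#' Extract the cavity contour of one mask
#'
#' Marching-squares contour at level 0.5 (via `grDevices::contourLines`);
#' returns the longest contour as an n x 2 polyline in mm.
#'
#' @param stack A `mask_stack`.
#' @param frame Frame index.
#' @return n x 2 matrix of contour points (mm).
#' @export
mask_contour <- function(stack, frame = 1L) {
  m <- stack$masks[[frame]]
  xg <- stack$origin[1] + (seq_len(nrow(m)) - 1) * stack$pixel_size
  yg <- stack$origin[2] + (seq_len(ncol(m)) - 1) * stack$pixel_size
  cl <- grDevices::contourLines(xg, yg, m + 0, levels = 0.5)
  if (length(cl) == 0) abort("mask has no contour (empty interior)")
  lens <- vapply(cl, function(c0) length(c0$x), numeric(1))
  c0 <- cl[[which.max(lens)]]
  cbind(c0$x, c0$y)
}

#' Write a mask stack as PNG images
#'
#' @param stack A `mask_stack`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the written paths.
#' @export
write_masks_png <- function(stack, dir, prefix = "mask") {
  if (!requireNamespace("png", quietly = TRUE)) {
    abort("PNG export needs the `png` package")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(seq_along(stack$masks), function(k) {
    p <- file.path(dir, sprintf("%s_%03d.png", prefix, k))
    # image rows are y (top first), columns x
    m <- t(stack$masks[[k]])[rev(seq_len(ncol(stack$masks[[k]]))), ]
    png::writePNG(m * 1, p)
    p
  }, character(1))
  invisible(paths)
}
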