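#' Polygonal region of interest
#'
#' A closed polygon around a tumor in frame physical coordinates:
#' `(depth_mm, lateral_mm)` pairs, depth measured from the transducer face.
#'
#' @param vertices numeric matrix with two columns `depth_mm`, `lateral_mm`
#'   (>= 3 rows, not closed; the closing edge is implicit).
#' @param frame_ref optional identifier of the frame the ROI was drawn on.
#' @return object of class `roi_polygon`.
#' @export
roi_polygon <- function(vertices, frame_ref = NA_character_) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2, nrow(vertices) >= 3, all(is.finite(vertices)))
  colnames(vertices) <- c("depth_mm", "lateral_mm")
  if (abs(polygon_area(vertices)) <= 0)
    stop("degenerate polygon: zero area")
  structure(list(vertices = vertices, frame_ref = frame_ref),
            class = "roi_polygon")
}

#' Axis-aligned elliptical ROI
#'
#' Convenience constructor for simulated tumors: an ellipse approximated by a
#' polygon.
#'
#' @param center_depth_mm,center_lateral_mm ellipse center, mm.
#' @param semi_depth_mm,semi_lateral_mm semi-axes, mm.
#' @param n_vertices polygon resolution.
#' @inheritParams roi_polygon
#' @return an `roi_polygon`.
#' @export
ellipse_roi <- function(center_depth_mm, center_lateral_mm,
                        semi_depth_mm, semi_lateral_mm,
                        n_vertices = 72, frame_ref = NA_character_) {
  stopifnot(semi_depth_mm > 0, semi_lateral_mm > 0)
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  roi_polygon(cbind(center_depth_mm + semi_depth_mm * cos(th),
                    center_lateral_mm + semi_lateral_mm * sin(th)),
              frame_ref = frame_ref)
}

# Shoelace area (signed), mm^2.
polygon_area <- function(v) {
  n <- nrow(v)
  i2 <- c(2:n, 1)
  sum(v[, 1] * v[i2, 2] - v[i2, 1] * v[, 2]) / 2
}

#' ROI area in mm^2
#' @param roi an `roi_polygon`.
#' @export
roi_area <- function(roi) abs(polygon_area(roi$vertices))

# Even-odd (ray casting) point-in-polygon test, vectorized over points.
# px = depth, py = lateral coordinates of the query points.
points_in_polygon <- function(px, py, vertices) {
  n <- nrow(vertices)
  vx <- vertices[, 1]; vy <- vertices[, 2]
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# Depths at which the vertical line lateral = x0 crosses the polygon
# boundary; sorted ascending. Empty if no crossing.
polygon_crossings <- function(vertices, lateral_mm) {
  n <- nrow(vertices)
  i2 <- c(2:n, 1)
  d1 <- vertices[, 1]; l1 <- vertices[, 2]
  d2 <- vertices[i2, 1]; l2 <- vertices[i2, 2]
  hit <- ((l1 > lateral_mm) != (l2 > lateral_mm))
  if (!any(hit)) return(numeric(0))
  t <- (lateral_mm - l1[hit]) / (l2[hit] - l1[hit])
  sort(d1[hit] + t * (d2[hit] - d1[hit]))
}

#' Tile an ROI into overlapping square analysis blocks
#'
#' Lays square blocks (`block_mm` on a side, 2 mm default: about ten
#' wavelengths at the pulse center frequency) on a regular grid anchored to
#' the ROI bounding box with step `(1 - overlap_fraction) * block_mm` along
#' both axes (80% linear overlap between successive blocks by default). A
#' block is kept iff its center lies inside the polygon and its footprint
#' lies inside the frame.
#'
#' For each kept block, `z_i` is the depth at which the block's central scan
#' line first enters the ROI (the transducer-to-tumor-interface distance used
#' for intervening-tissue attenuation) and `z_m = center_depth - z_i` is the
#' depth of the block center below that interface (the distance used for
#' local attenuation), so `z_i + z_m` equals the block center depth exactly.
#'
#' Index columns are 1-based inclusive: the block covers RF samples
#' `axial_start .. axial_start + axial_len - 1` and scan lines
#' `line_start .. line_start + line_len - 1`.
#'
#' @param roi an `roi_polygon`.
#' @param frame an `rf_frame` (see [simulate_frame()]).
#' @param block_mm block side length, mm.
#' @param overlap_fraction linear overlap between successive blocks (0.8 =
#'   step of 0.2 * block).
#' @return a data.frame of class `data_blocks` with one row per block:
#'   `axial_start, axial_len, line_start, line_len, center_depth_mm,
#'   center_lateral_mm, z_i_mm, z_m_mm`.
#' @export
tile_blocks <- function(roi, frame, block_mm = 2, overlap_fraction = 0.8) {
  stopifnot(inherits(roi, "roi_polygon"), inherits(frame, "rf_frame"))
  stopifnot(overlap_fraction >= 0, overlap_fraction < 1)
  v <- roi$vertices
  step_mm <- (1 - overlap_fraction) * block_mm
  dz <- frame$axial_spacing_mm
  pitch <- frame$profile$line_pitch
  axial_len <- as.integer(round(block_mm / dz))
  line_len <- max(2L, as.integer(round(block_mm / pitch)))

  bbox_d <- range(v[, 1]); bbox_l <- range(v[, 2])
  if (diff(bbox_d) < block_mm || diff(bbox_l) < block_mm)
    stop("ROI smaller than one analysis block (",
         sprintf("%.1f x %.1f mm < %g mm", diff(bbox_d), diff(bbox_l), block_mm), ")")
  eps <- 1e-9
  cd <- seq(bbox_d[1] + block_mm / 2, bbox_d[2] - block_mm / 2 + eps, by = step_mm)
  cl <- seq(bbox_l[1] + block_mm / 2, bbox_l[2] - block_mm / 2 + eps, by = step_mm)
  grid <- expand.grid(center_depth_mm = cd, center_lateral_mm = cl,
                      KEEP.OUT.ATTRS = FALSE)
  keep <- points_in_polygon(grid$center_depth_mm, grid$center_lateral_mm, v)
  grid <- grid[keep, , drop = FALSE]
  if (nrow(grid) == 0)
    stop("no block centers fall inside the ROI polygon")

  # snap footprints to RF sample / line indices (1-based)
  a_start <- as.integer(round((grid$center_depth_mm - frame$origin_depth_mm) / dz
                              - axial_len / 2)) + 1L
  l_start <- as.integer(round(grid$center_lateral_mm / pitch - line_len / 2)) + 1L
  inside <- a_start >= 1L & (a_start + axial_len - 1L) <= nrow(frame$samples) &
    l_start >= 1L & (l_start + line_len - 1L) <= ncol(frame$samples)
  grid <- grid[inside, , drop = FALSE]
  a_start <- a_start[inside]; l_start <- l_start[inside]
  if (nrow(grid) == 0)
    stop("all candidate blocks fall outside the frame")

  z_i <- vapply(grid$center_lateral_mm, function(l) {
    cr <- polygon_crossings(v, l)
    if (length(cr) == 0) grid$center_depth_mm[1] else cr[1]
  }, numeric(1))
  # guard: entry cannot lie below the block center (center is inside)
  z_i <- pmin(z_i, grid$center_depth_mm)

  out <- data.frame(axial_start = a_start, axial_len = axial_len,
                    line_start = l_start, line_len = line_len,
                    center_depth_mm = grid$center_depth_mm,
                    center_lateral_mm = grid$center_lateral_mm,
                    z_i_mm = z_i, z_m_mm = grid$center_depth_mm - z_i)
  rownames(out) <- NULL
  attr(out, "block_mm") <- block_mm
  attr(out, "step_mm") <- step_mm
  class(out) <- c("data_blocks", "data.frame")
  out
}

#' Rasterize an ROI polygon at RF-sample resolution
#'
#' Even-odd rasterization: a pixel belongs to the mask iff its center lies
#' inside the polygon. Pixel centers are at `origin + (i - 0.5) * spacing`
#' axially and `(j - 0.5) * pitch` laterally.
#'
#' @param roi an `roi_polygon`.
#' @param frame an `rf_frame`.
#' @return logical matrix with the dimensions of `frame$samples`.
#' @export
block_mask <- function(roi, frame) {
  stopifnot(inherits(roi, "roi_polygon"), inherits(frame, "rf_frame"))
  nr <- nrow(frame$samples); nc <- ncol(frame$samples)
  d <- frame$origin_depth_mm + (seq_len(nr) - 0.5) * frame$axial_spacing_mm
  l <- (seq_len(nc) - 0.5) * frame$profile$line_pitch
  px <- rep(d, times = nc); py <- rep(l, each = nr)
  m <- matrix(points_in_polygon(px, py, roi$vertices), nr, nc)
  if (!any(m)) warning("ROI polygon does not cover any frame pixel")
  m
}
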