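#' Parametric map from overlapping block estimates
#'
#' Reconstructs a feature image by averaging, at each map pixel, the
#' estimates of all blocks whose 2 mm footprint contains the pixel center.
#' The map covers the frame's physical extent on an isotropic grid whose
#' pixel size defaults to the tiling step (0.4 mm), so GLCM offsets of 1-4
#' pixels correspond to 0.4-1.6 mm in both directions. Pixels inside the ROI
#' covered by no block, and pixels outside the ROI, are invalid (`NA`).
#'
#' @param values numeric vector, one feature estimate per block.
#' @param blocks the `data_blocks` the values belong to.
#' @param roi the `roi_polygon` defining validity.
#' @param frame the `rf_frame` the blocks were tiled on.
#' @param pixel_mm map pixel size; defaults to the tiling step.
#' @return object of class `parametric_map`: `values` (matrix, NA where
#'   invalid), `valid` (logical matrix), `pixel_mm`, `origin_depth_mm`.
#' @export
build_parametric_map <- function(values, blocks, roi, frame,
                                 pixel_mm = attr(blocks, "step_mm")) {
  stopifnot(length(values) == nrow(blocks), inherits(frame, "rf_frame"))
  if (is.null(pixel_mm)) pixel_mm <- 0.4
  block_mm <- attr(blocks, "block_mm"); if (is.null(block_mm)) block_mm <- 2
  depth_extent <- nrow(frame$samples) * frame$axial_spacing_mm
  lat_extent <- ncol(frame$samples) * frame$profile$line_pitch
  nr <- max(1L, floor(depth_extent / pixel_mm))
  nc <- max(1L, floor(lat_extent / pixel_mm))
  o <- frame$origin_depth_mm
  acc <- matrix(0, nr, nc); cnt <- matrix(0L, nr, nc)
  if (nrow(blocks) == 0) warning("no blocks: all-invalid parametric map")
  half <- block_mm / 2
  for (b in seq_len(nrow(blocks))) {
    if (!is.finite(values[b])) next
    d0 <- blocks$center_depth_mm[b] - half; d1 <- blocks$center_depth_mm[b] + half
    l0 <- blocks$center_lateral_mm[b] - half; l1 <- blocks$center_lateral_mm[b] + half
    i0 <- max(1L, ceiling((d0 - o) / pixel_mm + 0.5))
    i1 <- min(nr, floor((d1 - o) / pixel_mm + 0.5))
    j0 <- max(1L, ceiling(l0 / pixel_mm + 0.5))
    j1 <- min(nc, floor(l1 / pixel_mm + 0.5))
    if (i0 > i1 || j0 > j1) next
    acc[i0:i1, j0:j1] <- acc[i0:i1, j0:j1] + values[b]
    cnt[i0:i1, j0:j1] <- cnt[i0:i1, j0:j1] + 1L
  }
  d_centers <- o + (seq_len(nr) - 0.5) * pixel_mm
  l_centers <- (seq_len(nc) - 0.5) * pixel_mm
  in_roi <- matrix(points_in_polygon(rep(d_centers, times = nc),
                                     rep(l_centers, each = nr),
                                     roi$vertices), nr, nc)
  valid <- in_roi & cnt > 0L
  vals <- ifelse(valid, acc / pmax(cnt, 1L), NA_real_)
  structure(list(values = vals, valid = valid, pixel_mm = pixel_mm,
                 origin_depth_mm = o),
            class = "parametric_map")
}

#' Quantize a parametric map to integer gray levels
#'
#' Uniform binning of the valid-pixel `[min, max]` range into `n_levels`
#' levels 0..`n_levels`-1: `level = floor((n_levels - 0.001) * (v - min) /
#' (max - min))`. The level map is invariant under positive affine
#' transforms of the values. A constant map is degenerate: all levels 0 and
#' the `degenerate` flag set (downstream correlation will be missing).
#'
#' @param map a `parametric_map`.
#' @param n_levels number of gray levels (16 by default).
#' @return object of class `level_map`: integer `levels` matrix (NA
#'   invalid), `n_levels`, `degenerate`.
#' @export
quantize_map <- function(map, n_levels = 16) {
  stopifnot(inherits(map, "parametric_map"), n_levels >= 2)
  v <- map$values
  vv <- v[map$valid]
  if (length(vv) == 0) stop("no valid pixels to quantize")
  rng <- range(vv)
  degenerate <- !(diff(rng) > 0)
  lev <- matrix(NA_integer_, nrow(v), ncol(v))
  if (degenerate) {
    lev[map$valid] <- 0L
  } else {
    lev[map$valid] <- as.integer(floor((n_levels - 1e-3) *
                                         (vv - rng[1]) / diff(rng)))
  }
  structure(list(levels = lev, n_levels = as.integer(n_levels),
                 degenerate = degenerate),
            class = "level_map")
}

# (angle, distance) offsets in (row = axial, col = lateral) steps.
# 0 deg = lateral, 90 deg = axial; 45/135 deg are diagonal steps of d
# pixels along each axis. With symmetric accumulation the offset sign is
# irrelevant.
glcm_offsets <- function(distances = 1:4) {
  ang <- data.frame(angle = c(0, 45, 90, 135),
                    dr = c(0, 1, 1, 1), dc = c(1, 1, 0, -1))
  out <- merge(ang, data.frame(distance = distances))
  out$dr <- out$dr * out$distance
  out$dc <- out$dc * out$distance
  out[order(out$angle, out$distance), c("angle", "distance", "dr", "dc")]
}

#' Gray-level co-occurrence matrix and its Haralick statistics
#'
#' Counts, symmetrically (both orderings), all pixel pairs `(p, p + offset)`
#' where both pixels are valid, normalizes the joint histogram to sum 1 and
#' computes contrast `sum (i-j)^2 p(i,j)`, correlation
#' `sum (i-mu_x)(j-mu_y) p(i,j) / (sigma_x sigma_y)`, energy `sum p^2` and
#' homogeneity `sum p / (1 + |i-j|)`, with the means and standard deviations
#' taken from the marginals `p_x(i) = sum_j p(i,j)`, `p_y(j) = sum_i p(i,j)`.
#' Levels are indexed 0..`n_levels`-1.
#'
#' @param lmap a `level_map`.
#' @param dr,dc pixel offset (rows = axial, cols = lateral).
#' @return list of class `glcm_stats`: `p` (the normalized GLCM),
#'   `contrast`, `correlation` (NA when a marginal is degenerate),
#'   `energy`, `homogeneity`, `n_pairs`.
#' @export
glcm <- function(lmap, dr, dc) {
  stopifnot(inherits(lmap, "level_map"))
  m <- lmap$levels
  nr <- nrow(m); nc <- ncol(m)
  if (abs(dr) >= nr || abs(dc) >= nc) return(NULL)
  r1 <- max(1, 1 - dr):min(nr, nr - dr)
  c1 <- max(1, 1 - dc):min(nc, nc - dc)
  a <- m[r1, c1, drop = FALSE]
  b <- m[r1 + dr, c1 + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  n_pairs <- sum(ok)
  if (n_pairs == 0) return(NULL)
  L <- lmap$n_levels
  idx <- a[ok] * L + b[ok]                       # 0-based (i, j)
  counts <- tabulate(idx + 1L, nbins = L * L)
  P <- matrix(counts, L, L, byrow = TRUE)        # row i, col j
  P <- P + t(P)                                  # symmetric accumulation
  p <- P / sum(P)
  glcm_statistics(p, n_pairs)
}

# Statistics of a normalized GLCM (levels 0..L-1).
glcm_statistics <- function(p, n_pairs = NA_integer_) {
  L <- nrow(p)
  lev <- 0:(L - 1)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(lev * px); muy <- sum(lev * py)
  sx <- sqrt(sum((lev - mux)^2 * px)); sy <- sqrt(sum((lev - muy)^2 * py))
  D <- outer(lev, lev, `-`)
  contrast <- sum(D^2 * p)
  energy <- sum(p^2)
  homogeneity <- sum(p / (1 + abs(D)))
  correlation <- if (sx > 0 && sy > 0)
    (sum(outer(lev, lev) * p) - mux * muy) / (sx * sy)
  else NA_real_
  structure(list(p = p, contrast = contrast, correlation = correlation,
                 energy = energy, homogeneity = homogeneity,
                 n_pairs = n_pairs),
            class = "glcm_stats")
}

#' GLCM texture statistics of one parametric map
#'
#' Quantizes the map to 16 gray levels, builds the 16 GLCMs (four angles 0,
#' 45, 90, 135 degrees x four step sizes 1-4 pixels), computes contrast,
#' correlation, energy and homogeneity from each, and averages each
#' statistic over the 16 configurations. Configurations with no valid pixel
#' pair are skipped (and counted); degenerate correlations are excluded from
#' the correlation average.
#'
#' @param map a `parametric_map`.
#' @param n_levels gray levels for quantization.
#' @param distances GLCM step sizes in pixels.
#' @return named numeric vector `CON`, `COR`, `ENE`, `HOM` (NA where every
#'   configuration was skipped/degenerate), with attributes `n_skipped` and
#'   `n_configs`.
#' @export
texture_features <- function(map, n_levels = 16, distances = 1:4) {
  if (!any(map$valid & is.finite(map$values))) {
    # every contributing block was missing/unreliable: features are missing
    out <- c(CON = NA_real_, COR = NA_real_, ENE = NA_real_, HOM = NA_real_)
    attr(out, "n_skipped") <- length(distances) * 4L
    attr(out, "n_configs") <- length(distances) * 4L
    return(out)
  }
  lmap <- quantize_map(map, n_levels)
  offs <- glcm_offsets(distances)
  stats <- lapply(seq_len(nrow(offs)), function(k)
    glcm(lmap, offs$dr[k], offs$dc[k]))
  keep <- !vapply(stats, is.null, logical(1))
  n_skipped <- sum(!keep)
  stats <- stats[keep]
  pull <- function(field) {
    v <- vapply(stats, `[[`, numeric(1), field)
    v <- v[is.finite(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  out <- c(CON = pull("contrast"), COR = pull("correlation"),
           ENE = pull("energy"), HOM = pull("homogeneity"))
  attr(out, "n_skipped") <- n_skipped
  attr(out, "n_configs") <- nrow(offs)
  out
}
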