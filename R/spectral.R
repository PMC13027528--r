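#' Symmetric Hann (Hanning) analysis window
#'
#' `w(n) = 0.5 * (1 - cos(2*pi*n/(N-1)))`, `n = 0..N-1`: zero at the
#' endpoints, unit peak at the center. At the cart-based scanner's 40 MHz
#' sampling a 2 mm analysis block is 104 samples, for which the discrete
#' at-or-above-half-maximum span is 51 sample intervals (first index 26,
#' last 77, 0-based).
#'
#' @param length window length in samples (>= 3).
#' @return numeric vector of window values.
#' @export
hann_window <- function(length) {
  n <- as.integer(length)
  if (is.na(n) || n < 3) stop("window length must be at least 3 samples")
  k <- 0:(n - 1)
  0.5 * (1 - cos(2 * pi * k / (n - 1)))
}

#' Full width at half maximum of a discrete window
#'
#' Index span (in sample intervals) between the first and last samples whose
#' value is at or above half the window's peak.
#'
#' @param w numeric window values.
#' @return integer span in sample intervals.
#' @export
window_fwhm_samples <- function(w) {
  idx <- which(w >= max(w) / 2)
  idx[length(idx)] - idx[1]
}

next_pow2 <- function(n) 2^ceiling(log2(n))

new_block_spectra <- function(freq, power, blocks, stage, profile_name,
                              window_len) {
  structure(list(freq = freq, power = power, blocks = blocks, stage = stage,
                 profile_name = profile_name, window_len = window_len),
            class = "block_spectra")
}

#' @export
print.block_spectra <- function(x, ...) {
  cat(sprintf("<block_spectra> %d blocks x %d bins (%.2f-%.2f MHz), stage %s, %s\n",
              nrow(x$power), length(x$freq), min(x$freq), max(x$freq),
              x$stage, x$profile_name))
  invisible(x)
}

stopifnot_stage <- function(x, stage) {
  if (!inherits(x, "block_spectra")) stop("expected a block_spectra object")
  if (x$stage != stage)
    stop(sprintf("expected stage '%s' spectra, got '%s' (stage transitions are raw -> normalized -> compensated)",
                 stage, x$stage))
}

#' Per-block averaged power spectra
#'
#' For every analysis block: per RF line, subtract the line-segment mean,
#' taper with a Hann window over the block's axial samples, FFT (zero-padded
#' to the next power of two), squared magnitude; average across the block's
#' lines; interpolate (linearly in log power) onto a fixed 0.05 MHz
#' frequency grid restricted to the analysis band, so spectra from scanners
#' with different sampling rates share bins.
#'
#' @param frame an `rf_frame`.
#' @param blocks a `data_blocks` tiling of the frame (every block must have
#'   at least 2 lines).
#' @param band analysis band `(f_low, f_high)` in MHz; defaults to the
#'   common RP/CL15 band 5.1-8 MHz used for cross-system comparison.
#' @param grid_step_MHz analysis frequency grid step.
#' @return a `block_spectra` object at stage `"raw"`: `freq` (MHz), `power`
#'   (blocks x bins, linear units), `blocks`.
#' @export
block_spectra <- function(frame, blocks, band = c(5.1, 8),
                          grid_step_MHz = 0.05) {
  stopifnot(inherits(frame, "rf_frame"), inherits(blocks, "data_blocks"))
  if (any(blocks$line_len < 2)) stop("blocks must span at least 2 RF lines")
  alen <- blocks$axial_len[1]
  stopifnot(all(blocks$axial_len == alen))
  win <- hann_window(alen)
  nfft <- next_pow2(alen)
  fs <- frame$profile$sampling_rate
  f_bins <- (0:(nfft - 1)) * fs / nfft
  keep <- which(f_bins >= band[1] - 2 * fs / nfft &
                  f_bins <= band[2] + 2 * fs / nfft)
  grid <- seq(band[1], band[2], by = grid_step_MHz)
  if (max(grid) > max(f_bins[keep]) || min(grid) < min(f_bins[keep]))
    stop("analysis band exceeds the available FFT bins")

  power <- matrix(NA_real_, nrow(blocks), length(grid))
  pad <- matrix(0, nfft - alen, ncol(frame$samples))
  for (a0 in unique(blocks$axial_start)) {
    rows <- a0:(a0 + alen - 1L)
    X <- frame$samples[rows, , drop = FALSE]
    X <- sweep(X, 2, colMeans(X))             # per-line mean removal
    X <- X * win
    P <- Mod(stats::mvfft(rbind(X, pad[, seq_len(ncol(X)), drop = FALSE])))^2
    P <- P[keep, , drop = FALSE]
    for (b in which(blocks$axial_start == a0)) {
      cols <- blocks$line_start[b]:(blocks$line_start[b] + blocks$line_len[b] - 1L)
      p_avg <- rowMeans(P[, cols, drop = FALSE])
      power[b, ] <- exp(stats::approx(f_bins[keep], log(pmax(p_avg, 1e-300)),
                                      xout = grid)$y)
    }
  }
  new_block_spectra(grid, power, blocks, "raw", frame$profile$name, alen)
}

#' Power spectrum of a single block
#'
#' Convenience wrapper around [block_spectra()] for one block.
#' @inheritParams block_spectra
#' @param block one-row `data_blocks`.
#' @return a `block_spectra` with one row.
#' @export
block_power_spectrum <- function(frame, block, band = c(5.1, 8),
                                 grid_step_MHz = 0.05) {
  block_spectra(frame, block[1, , drop = FALSE], band, grid_step_MHz)
}

#' Build a depth-resolved reference spectrum table from phantom frames
#'
#' Tiles each homogeneous reference frame with the same block geometry as
#' the sample analysis (2 mm Hann-windowed blocks) on a regular depth/lateral
#' grid spanning the frame, and averages the raw power spectra of all blocks
#' at the same depth across lateral positions and frames, giving
#' `W_r(f, z)` on the analysis grid.
#'
#' @param ref_frames list of `rf_frame` from [simulate_reference()] (or real
#'   phantom acquisitions); >= 1, same profile.
#' @param band,grid_step_MHz as in [block_spectra()].
#' @param block_mm,step_mm block geometry (must match the sample tiling).
#' @return object of class `reference_table`: `depth_mm`, `freq`, `power`
#'   (depth bins x frequency bins), `n_frames`, `profile_name`.
#' @export
reference_spectrum_table <- function(ref_frames, band = c(5.1, 8),
                                     grid_step_MHz = 0.05,
                                     block_mm = 2, step_mm = 0.4) {
  stopifnot(length(ref_frames) >= 1)
  fr1 <- ref_frames[[1]]
  prof <- fr1$profile
  dz <- fr1$axial_spacing_mm
  alen <- as.integer(round(block_mm / dz))
  llen <- max(2L, as.integer(round(block_mm / prof$line_pitch)))
  S <- nrow(fr1$samples); nl <- ncol(fr1$samples)
  depth_lo <- fr1$origin_depth_mm + block_mm / 2
  depth_hi <- fr1$origin_depth_mm + S * dz - block_mm / 2
  centers <- seq(depth_lo, depth_hi, by = step_mm)
  a_starts <- as.integer(round((centers - fr1$origin_depth_mm) / dz - alen / 2)) + 1L
  ok <- a_starts >= 1L & a_starts + alen - 1L <= S
  centers <- centers[ok]; a_starts <- a_starts[ok]
  # depth rows step finely (sample blocks must find a matching bin); lateral
  # positions are non-overlapping -- every RF line enters each depth row
  # exactly once, which carries the same statistical information as an
  # overlapped lateral tiling at a fifth of the cost
  l_starts <- seq(1L, nl - llen + 1L, by = llen)

  blocks <- data.frame(
    axial_start = rep(a_starts, each = length(l_starts)),
    axial_len = alen,
    line_start = rep(l_starts, times = length(a_starts)),
    line_len = llen,
    center_depth_mm = rep(centers, each = length(l_starts)),
    center_lateral_mm = NA_real_, z_i_mm = 0,
    z_m_mm = rep(centers, each = length(l_starts)))
  class(blocks) <- c("data_blocks", "data.frame")
  attr(blocks, "block_mm") <- block_mm; attr(blocks, "step_mm") <- step_mm

  g <- factor(blocks$center_depth_mm,
              levels = sort(unique(blocks$center_depth_mm)))
  acc <- NULL
  for (fr in ref_frames) {
    stopifnot(fr$profile$name == prof$name)
    sp <- block_spectra(fr, blocks, band, grid_step_MHz)
    m <- rowsum(sp$power, group = g) / as.vector(table(g))
    acc <- if (is.null(acc)) m else acc + m
  }
  acc <- acc / length(ref_frames)
  structure(list(depth_mm = sort(unique(blocks$center_depth_mm)),
                 freq = seq(band[1], band[2], by = grid_step_MHz),
                 power = acc, n_frames = length(ref_frames),
                 profile_name = prof$name, block_mm = block_mm,
                 window_len = alen),
            class = "reference_table")
}

#' Concatenate block spectra from several frames
#'
#' Stacks the blocks of multiple `block_spectra` objects (same stage, grid
#' and profile) into one, e.g. to pool all frames of a tumor for the
#' depth-regression attenuation estimate.
#'
#' @param ... `block_spectra` objects, or a single list of them.
#' @return a `block_spectra` with the rows of all inputs.
#' @export
concat_block_spectra <- function(...) {
  xs <- list(...)
  if (length(xs) == 1 && !inherits(xs[[1]], "block_spectra")) xs <- xs[[1]]
  stopifnot(length(xs) >= 1, all(vapply(xs, inherits, logical(1), "block_spectra")))
  x1 <- xs[[1]]
  for (x in xs[-1]) {
    if (x$stage != x1$stage || x$profile_name != x1$profile_name ||
        length(x$freq) != length(x1$freq) ||
        max(abs(x$freq - x1$freq)) > 1e-9)
      stop("block_spectra objects differ in stage, profile or grid")
  }
  blocks <- do.call(rbind, lapply(xs, `[[`, "blocks"))
  attr(blocks, "block_mm") <- attr(x1$blocks, "block_mm")
  attr(blocks, "step_mm") <- attr(x1$blocks, "step_mm")
  class(blocks) <- c("data_blocks", "data.frame")
  new_block_spectra(x1$freq, do.call(rbind, lapply(xs, `[[`, "power")),
                    blocks, x1$stage, x1$profile_name, x1$window_len)
}

#' Reference-phantom normalization of block spectra
#'
#' Divides each sample block spectrum by the depth-matched phantom spectrum
#' `W_r(f, z)` (nearest reference depth bin within 1 mm of the block center),
#' cancelling the system transfer function that multiplies both.
#'
#' @param spectra a `block_spectra` at stage `"raw"`.
#' @param reference a `reference_table` built from the same scanner profile
#'   with the same window settings.
#' @param depth_tol_mm maximum sample/reference depth mismatch.
#' @return a `block_spectra` at stage `"normalized"`.
#' @export
normalize_spectra <- function(spectra, reference, depth_tol_mm = 1) {
  stopifnot_stage(spectra, "raw")
  stopifnot(inherits(reference, "reference_table"))
  if (spectra$profile_name != reference$profile_name)
    stop(sprintf("profile mismatch: sample '%s' vs reference '%s'",
                 spectra$profile_name, reference$profile_name))
  if (spectra$window_len != reference$window_len)
    stop("sample and reference use different window lengths")
  if (length(spectra$freq) != length(reference$freq) ||
      max(abs(spectra$freq - reference$freq)) > 1e-9)
    stop("sample and reference frequency grids differ")
  idx <- vapply(spectra$blocks$center_depth_mm, function(z) {
    j <- which.min(abs(reference$depth_mm - z))
    if (abs(reference$depth_mm[j] - z) > depth_tol_mm)
      stop(sprintf("no reference depth bin within %g mm of block depth %.2f mm",
                   depth_tol_mm, z))
    j
  }, integer(1))
  power <- spectra$power / reference$power[idx, , drop = FALSE]
  new_block_spectra(spectra$freq, power, spectra$blocks, "normalized",
                    spectra$profile_name, spectra$window_len)
}
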