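# Minimal file interchange: one binary file per RF frame (32-bit float,
# column-major samples x lines) with a JSON sidecar carrying the scanner
# profile and coordinate mapping; ROIs as JSON vertex lists.

#' Write an RF frame to a binary container with JSON sidecar
#'
#' @param frame an `rf_frame`.
#' @param path output path for the binary payload; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_rf_frame <- function(frame, path) {
  stopifnot(inherits(frame, "rf_frame"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(frame$samples), con, size = 4, endian = "little")
  sidecar <- c(frame$profile[c("name", "n_elements", "center_freq",
                               "band_low", "band_high", "sampling_rate",
                               "n_lines", "samples_per_line",
                               "focal_position", "aperture_mm")],
               list(axial_spacing_mm = frame$axial_spacing_mm,
                    origin_depth_mm = frame$origin_depth_mm,
                    seed = frame$seed,
                    dtype = "float32", order = "column-major"))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an RF frame written by [write_rf_frame()]
#' @param path path to the binary payload (sidecar at `path.json`).
#' @return an `rf_frame`.
#' @export
read_rf_frame <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  prof <- scanner_profile(meta$name, meta$n_elements, meta$center_freq,
                          meta$band_low, meta$band_high, meta$sampling_rate,
                          meta$n_lines, meta$samples_per_line,
                          meta$focal_position, meta$aperture_mm)
  n <- prof$samples_per_line * prof$n_lines
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, what = "numeric", n = n, size = 4, endian = "little")
  structure(list(samples = matrix(x, prof$samples_per_line, prof$n_lines),
                 profile = prof,
                 axial_spacing_mm = meta$axial_spacing_mm,
                 origin_depth_mm = meta$origin_depth_mm,
                 seed = if (is.null(meta$seed)) NA_integer_ else meta$seed,
                 meta = list()),
            class = "rf_frame")
}

#' Write / read an ROI polygon as JSON
#'
#' @param roi an `roi_polygon`.
#' @param path output path.
#' @return `path` invisibly (write) or an `roi_polygon` (read).
#' @export
write_roi_json <- function(roi, path) {
  stopifnot(inherits(roi, "roi_polygon"))
  jsonlite::write_json(list(frame_ref = roi$frame_ref,
                            vertices = unname(as.data.frame(roi$vertices))),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_json
#' @export
read_roi_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  roi_polygon(as.matrix(x$vertices),
              frame_ref = if (is.null(x$frame_ref)) NA_character_ else x$frame_ref)
}
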