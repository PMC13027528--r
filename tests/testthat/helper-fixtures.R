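# Shared fixtures, built lazily and cached per test file.

.fx <- new.env(parent = emptyenv())
fx <- function(name, builder) {
  if (!exists(name, envir = .fx)) assign(name, builder(), envir = .fx)
  get(name, envir = .fx)
}

# small profiles for unit tests (full-scale physics, small frames)
desk_rp <- function(n_lines = 64, samples = 768)
  scale_profile(profile_rp(), n_lines, samples)
desk_cl15 <- function(n_lines = 48, samples = 576)
  scale_profile(profile_cl15(), n_lines, samples)

# a frame shell with given dimensions and zero samples; enough for geometry
# code (tiling, masks, maps) that never touches the RF values
empty_frame <- function(profile = desk_rp(), origin_depth_mm = 0) {
  structure(list(samples = matrix(0, profile$samples_per_line, profile$n_lines),
                 profile = profile,
                 axial_spacing_mm = axial_spacing_mm(profile),
                 origin_depth_mm = origin_depth_mm,
                 seed = 0L, meta = list()),
            class = "rf_frame")
}

rect_roi <- function(d0, d1, l0, l1) {
  roi_polygon(rbind(c(d0, l0), c(d0, l1), c(d1, l1), c(d1, l0)))
}

# hand-built block_spectra at a chosen stage (for algebraic tests)
fake_spectra <- function(power, freq, blocks, stage = "normalized",
                         profile_name = "RP-desk", window_len = 104L) {
  structure(list(freq = freq, power = power, blocks = blocks, stage = stage,
                 profile_name = profile_name, window_len = window_len),
            class = "block_spectra")
}

fake_blocks <- function(center_depth_mm, center_lateral_mm = 19,
                        z_i_mm = 5) {
  n <- length(center_depth_mm)
  b <- data.frame(axial_start = 1L, axial_len = 104L, line_start = 1L,
                  line_len = 3L, center_depth_mm = center_depth_mm,
                  center_lateral_mm = rep_len(center_lateral_mm, n),
                  z_i_mm = pmin(rep_len(z_i_mm, n), center_depth_mm),
                  z_m_mm = NA_real_)
  b$z_m_mm <- b$center_depth_mm - b$z_i_mm
  attr(b, "block_mm") <- 2; attr(b, "step_mm") <- 0.4
  class(b) <- c("data_blocks", "data.frame")
  b
}

make_level_map <- function(m, n_levels = 16) {
  structure(list(levels = m, n_levels = as.integer(n_levels),
                 degenerate = length(unique(stats::na.omit(as.vector(m)))) < 2),
            class = "level_map")
}

make_parametric_map <- function(values, valid = is.finite(values),
                                pixel_mm = 0.4) {
  structure(list(values = ifelse(valid, values, NA_real_), valid = valid,
                 pixel_mm = pixel_mm, origin_depth_mm = 0),
            class = "parametric_map")
}

# well-averaged phantom reference fixture on a 96-line profile, shared by
# the self-normalization, attenuation and fidelity checks
phantom_reference_fixture <- function(n_ref = 48, seed = 401) {
  fx("phantom_ref", function() {
    prof <- desk_rp(n_lines = 96, samples = 768)
    ph <- default_phantom()
    rt <- reference_spectrum_table(simulate_reference(prof, ph, n_ref,
                                                      seed = seed))
    list(profile = prof, phantom = ph, ref_table = rt)
  })
}

# phantom-vs-phantom: sample spectra of phantom frames normalized by a
# reference table built from independent phantom frames (same scanner)
self_normalized_fixture <- function(n_sample = 48, seed = 402) {
  fx("selfnorm", function() {
    base <- phantom_reference_fixture()
    roi <- rect_roi(3, 12, 4, 34)
    sp <- lapply(simulate_reference(base$profile, base$phantom, n_sample,
                                    seed = seed), function(fr) {
      blocks <- tile_blocks(roi, fr)
      normalize_spectra(block_spectra(fr, blocks), base$ref_table)
    })
    c(base, list(spectra = sp))
  })
}
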