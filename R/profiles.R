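#' Scanner profile
#'
#' Acquisition geometry and band of one (virtual or real) linear-array
#' ultrasound scanner. Frequencies in MHz, distances in mm. `band_low` and
#' `band_high` are the -6 dB band edges of the transmit-receive response.
#'
#' The lateral aperture width is not part of the published transducer tables;
#' a 38 mm aperture is assumed for both systems, so the line pitch is
#' `aperture_mm / n_lines`. This is configurable and recorded in every frame
#' sidecar.
#'
#' @param name label for the scanner.
#' @param n_elements transducer element count.
#' @param center_freq pulse center frequency, MHz.
#' @param band_low,band_high -6 dB band edges, MHz.
#' @param sampling_rate RF sampling rate, MHz.
#' @param n_lines number of scan lines per frame.
#' @param samples_per_line RF samples per scan line.
#' @param focal_position transmit focus depth, mm.
#' @param aperture_mm lateral aperture width, mm.
#' @return an object of class `scanner_profile`.
#' @export
scanner_profile <- function(name, n_elements, center_freq, band_low, band_high,
                            sampling_rate, n_lines, samples_per_line,
                            focal_position, aperture_mm = 38) {
  stopifnot(band_low < center_freq, center_freq < band_high,
            sampling_rate > 2 * band_high,
            n_lines >= 2, samples_per_line >= 128,
            aperture_mm > 0)
  structure(list(
    name = as.character(name),
    n_elements = as.integer(n_elements),
    center_freq = center_freq,
    band_low = band_low,
    band_high = band_high,
    sampling_rate = sampling_rate,
    n_lines = as.integer(n_lines),
    samples_per_line = as.integer(samples_per_line),
    focal_position = focal_position,
    aperture_mm = aperture_mm,
    line_pitch = aperture_mm / n_lines
  ), class = "scanner_profile")
}

#' @export
print.scanner_profile <- function(x, ...) {
  cat(sprintf("<scanner_profile %s> fc %.1f MHz, band %.1f-%.1f MHz, fs %g MHz, %d lines x %d samples\n",
              x$name, x$center_freq, x$band_low, x$band_high,
              x$sampling_rate, x$n_lines, x$samples_per_line))
  invisible(x)
}

#' Cart-based scanner profile (Sonix RP, L14-5W/60)
#'
#' Published transducer/imaging parameters of the cart-based system:
#' 128 elements, 6.3 MHz center frequency, 3-8 MHz band, 40 MHz sampling,
#' 510 scan lines of 2064 samples, 17.5 mm focus.
#' @return a `scanner_profile`.
#' @export
profile_rp <- function() {
  scanner_profile("RP", 128, 6.3, 3, 8, 40, 510, 2064, 17.5)
}

#' Handheld scanner profile (Clarius L15HD)
#'
#' Published parameters of the handheld system: 192 elements, 6.9 MHz center
#' frequency, 5.1-8.3 MHz band, 30 MHz sampling, 192 scan lines of 1568
#' samples, 20.03 mm focus.
#' @return a `scanner_profile`.
#' @export
profile_cl15 <- function() {
  scanner_profile("CL15", 192, 6.9, 5.1, 8.3, 30, 192, 1568, 20.03)
}

#' Scale a scanner profile to a smaller frame
#'
#' Keeps sampling rate, band and aperture (hence per-line physics) while
#' reducing the number of scan lines and samples per line, so the whole
#' simulation/estimation chain runs at desk scale. Line pitch grows as the
#' line count shrinks.
#'
#' @param profile a `scanner_profile`.
#' @param n_lines,samples_per_line new frame dimensions.
#' @return a `scanner_profile`.
#' @export
scale_profile <- function(profile, n_lines, samples_per_line) {
  scanner_profile(paste0(profile$name, "-desk"), profile$n_elements,
                  profile$center_freq, profile$band_low, profile$band_high,
                  profile$sampling_rate, n_lines, samples_per_line,
                  profile$focal_position, profile$aperture_mm)
}

#' Common analysis band of two scanners
#'
#' Intersection of the two -6 dB bands; cross-system feature comparison is
#' restricted to it (5.1-8 MHz for the RP/CL15 pair).
#' @param a,b `scanner_profile` objects.
#' @return numeric length-2 `(f_low, f_high)` in MHz.
#' @export
common_band <- function(a, b) {
  lo <- max(a$band_low, b$band_low)
  hi <- min(a$band_high, b$band_high)
  if (lo >= hi) stop("scanner bands do not overlap")
  c(lo, hi)
}

#' Axial sample spacing of a profile
#'
#' `c / (2 * sampling_rate)`: the echo from depth z arrives at time 2z/c.
#' The scanner's assumed sound speed (1540 m/s, the soft-tissue convention)
#' is used for the coordinate mapping regardless of the true medium speed.
#'
#' @param profile a `scanner_profile`.
#' @param c_mps assumed speed of sound, m/s.
#' @return spacing in mm.
#' @export
axial_spacing_mm <- function(profile, c_mps = 1540) {
  c_mps / (2 * profile$sampling_rate * 1e6) * 1e3
}

#' Reference phantom specification
#'
#' A homogeneous tissue-mimicking phantom with known acoustic constants used
#' for spectral normalization: attenuation 0.7861 dB cm^-1 MHz^-1 and speed
#' of sound 1488 m/s for the phantom shipped with this pipeline, plus a
#' tabulated backscatter coefficient spectrum sigma_r(f).
#'
#' @param attenuation_coeff dB cm^-1 MHz^-1 (one-way, frequency-linear).
#' @param speed_of_sound m/s.
#' @param bsc_freq_MHz frequency grid of the BSC table, MHz (strictly increasing).
#' @param bsc per-frequency backscatter coefficient, sr^-1 cm^-1 (positive).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(attenuation_coeff, speed_of_sound, bsc_freq_MHz, bsc) {
  stopifnot(attenuation_coeff >= 0, speed_of_sound > 0,
            length(bsc_freq_MHz) == length(bsc),
            all(diff(bsc_freq_MHz) > 0), all(bsc > 0))
  structure(list(attenuation_coeff = attenuation_coeff,
                 speed_of_sound = speed_of_sound,
                 bsc_freq_MHz = bsc_freq_MHz,
                 bsc = bsc),
            class = "phantom_spec")
}

#' Default reference phantom
#'
#' Gelatin phantom with glass-bead-like scatterers (diameters 5-30 um).
#' Acoustic constants as measured for the physical phantom: attenuation
#' 0.7861 dB cm^-1 MHz^-1, speed of sound 1488 m/s. Its BSC spectrum is
#' modeled with the same Gaussian form-factor law used throughout the
#' package, with an 8.75 um effective radius (mid-range bead size).
#'
#' @param freq_MHz tabulation grid, MHz.
#' @return a `phantom_spec`.
#' @export
default_phantom <- function(freq_MHz = seq(1, 15, by = 0.05)) {
  bsc <- theoretical_bsc(freq_MHz, a_eff_um = 8.75, conc_cm3 = 5e5, c_mps = 1488)
  phantom_spec(0.7861, 1488, freq_MHz, bsc)
}

#' Interpolate a phantom BSC table onto a frequency grid
#' @param phantom a `phantom_spec`.
#' @param freq_MHz target grid, MHz (must lie inside the tabulated grid).
#' @return numeric vector of sigma_r(f).
#' @export
phantom_bsc <- function(phantom, freq_MHz) {
  rng <- range(phantom$bsc_freq_MHz)
  if (min(freq_MHz) < rng[1] || max(freq_MHz) > rng[2])
    stop("requested frequencies outside the phantom BSC table")
  # interpolate in log power: BSC spans orders of magnitude over the band
  exp(stats::approx(phantom$bsc_freq_MHz, log(phantom$bsc), xout = freq_MHz)$y)
}

#' Tissue ground truth for simulation
#'
#' Microstructural parameters of a simulated medium: effective scatterer
#' radius a_eff (um), acoustic concentration n*gamma0^2 (cm^-3, the product
#' of number density and mean-square impedance variation), frequency-linear
#' attenuation (dB cm^-1 MHz^-1) and speed of sound.
#'
#' @param a_eff_um effective scatterer radius, micrometers.
#' @param conc_cm3 acoustic concentration n*gamma0^2, cm^-3.
#' @param attenuation dB cm^-1 MHz^-1.
#' @param c_mps speed of sound, m/s (1540 soft-tissue convention).
#' @return object of class `tissue_truth`.
#' @export
tissue_truth <- function(a_eff_um, conc_cm3, attenuation, c_mps = 1540) {
  stopifnot(a_eff_um > 0, conc_cm3 > 0, attenuation >= 0, c_mps > 0)
  structure(list(a_eff_um = a_eff_um, conc_cm3 = conc_cm3,
                 attenuation = attenuation, c_mps = c_mps),
            class = "tissue_truth")
}
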