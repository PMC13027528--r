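# Seeded synthetic RF: each scan line is synthesized in overlapping depth
# segments; within a segment the line is stationary colored Gaussian noise
# whose power spectrum is sigma_truth(f) * |P(f)|^2 * 10^(-2 f A(z)/10),
# where P is the scanner's Gaussian pulse spectrum and A(z) the cumulative
# one-way attenuation path integral (dB/MHz) to the segment center.
# Segments are Hann-windowed and overlap-added at a quarter-window hop, so
# the summed window *power* is constant with depth (no spectral seams); the
# constant cancels in reference normalization.

SEG_LEN <- 128L
SEG_HOP <- 32L

# |P(f)|^2 (power, peak 1): Gaussian centered at the pulse center frequency
# whose -6 dB points sit half the quoted bandwidth away from the center.
gaussian_pulse_power <- function(f_MHz, profile) {
  half_bw <- (profile$band_high - profile$band_low) / 2
  s2 <- half_bw^2 / (2 * (6 / 10) * log(10))
  exp(-(f_MHz - profile$center_freq)^2 / (2 * s2))
}

# Backscatter coefficient of a simulated medium at f (MHz); dispatches on
# the truth object (microstructural model vs tabulated phantom).
truth_bsc <- function(truth, f_MHz) {
  if (inherits(truth, "phantom_spec")) {
    rng <- range(truth$bsc_freq_MHz)
    exp(stats::approx(truth$bsc_freq_MHz, log(truth$bsc),
                      xout = pmin(pmax(f_MHz, rng[1]), rng[2]), rule = 2)$y)
  } else if (inherits(truth, "tissue_truth")) {
    theoretical_bsc(pmax(f_MHz, 1e-6), truth$a_eff_um, truth$conc_cm3,
                    truth$c_mps)
  } else stop("unknown truth object")
}

truth_alpha <- function(truth) {
  if (inherits(truth, "phantom_spec")) truth$attenuation_coeff
  else truth$attenuation
}

#' Ground-truth map for frame simulation
#'
#' Assigns tissue properties over a frame: a background medium everywhere,
#' optionally overridden by a tumor medium inside an ROI polygon.
#'
#' @param background a [tissue_truth()] or [phantom_spec()] (the latter for
#'   homogeneous reference-phantom frames).
#' @param tumor optional [tissue_truth()] for the interior of `roi`.
#' @param roi optional [roi_polygon()]; required when `tumor` is given.
#' @return object of class `truth_map`.
#' @export
truth_map <- function(background, tumor = NULL, roi = NULL) {
  if (!is.null(tumor) && is.null(roi))
    stop("a tumor medium requires an ROI polygon")
  structure(list(background = background, tumor = tumor, roi = roi),
            class = "truth_map")
}

#' Simulate one beamformed RF frame
#'
#' Phenomenological speckle synthesis (see the package vignette): the
#' expected block power spectrum over a homogeneous region converges, in the
#' many-realization mean, to `sigma_truth(f) * |P(f)|^2` times the
#' round-trip attenuation factor `10^(-2 alpha f z / 10)` (up to a constant
#' that cancels in reference normalization).
#'
#' @param truth a `truth_map`.
#' @param profile a `scanner_profile`.
#' @param seed integer seed; required (reproducibility contract: the same
#'   seed and inputs give a bit-identical frame).
#' @param origin_depth_mm depth of the first RF sample, mm.
#' @param extra_gain_db optional frequency response perturbation, a function
#'   `f_MHz -> dB` applied (in power dB) on top of the pulse spectrum; used
#'   to model inter-scanner transfer-function nuisance.
#' @return object of class `rf_frame`: `samples` (samples x lines matrix),
#'   `profile`, `axial_spacing_mm`, `origin_depth_mm`, `seed`, `meta`.
#' @export
simulate_frame <- function(truth, profile, seed, origin_depth_mm = 0,
                           extra_gain_db = NULL) {
  stopifnot(inherits(truth, "truth_map"), inherits(profile, "scanner_profile"))
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("a seed is required (reproducibility contract)")
  S <- profile$samples_per_line
  nl <- profile$n_lines
  dz <- axial_spacing_mm(profile)
  frame_depth_mm <- origin_depth_mm + S * dz
  if (!is.null(truth$roi)) {
    bb <- range(truth$roi$vertices[, 1])
    if (bb[1] < origin_depth_mm - 1e-9 || bb[2] > frame_depth_mm + 1e-9)
      stop("truth map ROI extends beyond the frame's physical extent")
  }

  L <- SEG_LEN; hop <- SEG_HOP
  fs <- profile$sampling_rate
  k <- 0:(L - 1)
  f_seg <- pmin(k, L - k) * fs / L      # |f| of each FFT bin, MHz
  w <- 0.5 * (1 - cos(2 * pi * k / (L - 1)))  # Hann, length L

  pp <- gaussian_pulse_power(f_seg, profile)
  if (!is.null(extra_gain_db)) pp <- pp * 10^(extra_gain_db(f_seg) / 10)
  sig_bg <- truth_bsc(truth$background, f_seg)
  amp_bg <- sqrt(sig_bg * pp)
  has_tumor <- !is.null(truth$tumor)
  if (has_tumor) amp_tu <- sqrt(truth_bsc(truth$tumor, f_seg) * pp)

  a_bg <- truth_alpha(truth$background)
  lat <- (seq_len(nl) - 0.5) * profile$line_pitch
  if (has_tumor) {
    a_tu <- truth_alpha(truth$tumor)
    ent <- matrix(NA_real_, nl, 2)      # tumor entry/exit depth per line, mm
    for (j in seq_len(nl)) {
      cr <- polygon_crossings(truth$roi$vertices, lat[j])
      if (length(cr) >= 2) ent[j, ] <- c(cr[1], cr[length(cr)])
    }
  }

  # cumulative one-way attenuation path integral to depth z (cm), dB/MHz
  cum_att <- function(z_mm, j) {
    z <- pmax(z_mm, 0) / 10
    if (!has_tumor || is.na(ent[j, 1])) return(a_bg * z)
    e1 <- ent[j, 1] / 10; e2 <- ent[j, 2] / 10
    a_bg * pmin(z, e1) + a_tu * pmax(pmin(z, e2) - e1, 0) + a_bg * pmax(z - e2, 0)
  }

  pad <- L
  Sx <- S + 2L * pad                    # extended line, cropped after OLA
  starts <- seq(1L, Sx - L + 1L, by = hop)
  acc <- matrix(0, Sx, nl)

  with_seed(as.integer(seed), {
    for (s0 in starts) {
      zc_mm <- origin_depth_mm + (s0 - pad + L / 2 - 0.5) * dz
      in_tumor <- if (has_tumor)
        !is.na(ent[, 1]) & zc_mm >= ent[, 1] & zc_mm <= ent[, 2]
      else rep(FALSE, nl)
      A <- vapply(seq_len(nl), function(j) cum_att(zc_mm, j), numeric(1))
      H <- matrix(amp_bg, L, nl)
      if (any(in_tumor)) H[, in_tumor] <- amp_tu
      H <- H * 10^(-(f_seg %o% A) / 10)  # one-way amplitude: 10^(-2 f A / 20)
      noise <- matrix(stats::rnorm(L * nl), L, nl)
      y <- Re(stats::mvfft(stats::mvfft(noise) * H, inverse = TRUE)) / L
      rows <- s0:(s0 + L - 1L)
      acc[rows, ] <- acc[rows, ] + y * w
    }
  })

  samples <- acc[(pad + 1L):(pad + S), , drop = FALSE]
  structure(list(samples = samples, profile = profile,
                 axial_spacing_mm = dz, origin_depth_mm = origin_depth_mm,
                 seed = as.integer(seed),
                 meta = list(truth = truth)),
            class = "rf_frame")
}

#' @export
print.rf_frame <- function(x, ...) {
  cat(sprintf("<rf_frame> %d samples x %d lines, %s, dz %.4f mm, origin %.1f mm, seed %d\n",
              nrow(x$samples), ncol(x$samples), x$profile$name,
              x$axial_spacing_mm, x$origin_depth_mm, x$seed))
  invisible(x)
}

#' Simulate reference phantom frames
#'
#' Laterally and axially homogeneous frames of the reference phantom (known
#' backscatter spectrum and attenuation), used to build the normalization
#' reference. Frames share the profile and differ only in speckle.
#'
#' @param profile a `scanner_profile`.
#' @param phantom a `phantom_spec`.
#' @param n_frames number of frames (>= 1).
#' @param seed integer master seed.
#' @inheritParams simulate_frame
#' @return list of `rf_frame`; each frame's `meta$phantom` records the
#'   phantom constants (attenuation 0.7861 dB cm^-1 MHz^-1 and sound speed
#'   1488 m/s for the default phantom).
#' @export
simulate_reference <- function(profile, phantom, n_frames, seed,
                               origin_depth_mm = 0, extra_gain_db = NULL) {
  stopifnot(n_frames >= 1, inherits(phantom, "phantom_spec"))
  tm <- truth_map(background = phantom)
  lapply(seq_len(n_frames), function(i) {
    fr <- simulate_frame(tm, profile, derive_seed(seed, 9001, i),
                         origin_depth_mm, extra_gain_db)
    fr$meta$phantom <- list(attenuation_coeff = phantom$attenuation_coeff,
                            speed_of_sound = phantom$speed_of_sound)
    fr
  })
}

# Smooth multiplicative transfer-function perturbation, in power dB:
# flat gain plus a slow sinusoidal ripple across the analysis band.
nuisance_fun <- function(gain_db = 0, ripple_db = 0, ripple_cycles = 1.5,
                         phase = 0, band = c(3, 9)) {
  force(gain_db); force(ripple_db)
  function(f_MHz) {
    gain_db + ripple_db * sin(2 * pi * ripple_cycles *
                                (f_MHz - band[1]) / (band[2] - band[1]) + phase)
  }
}

#' Cohort simulation settings
#'
#' Defaults emulate the study conditions at desk scale: 30 patients, 28/30
#' responders, two virtual scanners with the published band/sampling-rate
#' contrast, elliptical tumors that shrink to about half their area by week
#' 4 in responders, and an inter-scanner nuisance made of (a) a cancelling
#' smooth transfer function applied to both sample and reference frames of
#' each scanner (removed exactly by normalization) and (b) a non-cancelling
#' residual applied to sample frames only (imperfect normalization), which
#' produces the absolute-feature disagreement between systems while feature
#' differences stay in agreement.
#'
#' @param n_patients cohort size (>= 2).
#' @param responder_fraction fraction of responders in `[0, 1]`.
#' @param frames_per_set frames per (system, timepoint), 4-6.
#' @param profiles named list of two `scanner_profile`s (desk-scaled
#'   RP-like and CL15-like by default).
#' @param baseline_major_mm range of baseline tumor major axis, mm.
#' @param center_depth_mm tumor center depth, mm.
#' @param shrink_mean,shrink_sd responder week-4 linear shrink factor
#'   distribution (area factor = shrink^2; 0.71 linear = half area).
#' @param tumor_a_um,tumor_a_sd baseline effective scatterer radius, um.
#' @param tumor_conc_db,tumor_conc_sd baseline acoustic concentration,
#'   dB re 1 cm^-3.
#' @param tumor_alpha baseline tumor attenuation, dB cm^-1 MHz^-1.
#' @param week4_a_factor,week4_conc_shift_db,week4_alpha_shift responder
#'   week-4 property shifts (multiplicative on radius, additive in dB and in
#'   dB cm^-1 MHz^-1). Effect sizes are synthetic settings, not biological
#'   claims.
#' @param background background tissue truth (attenuation fixed at the
#'   1 dB cm^-1 MHz^-1 breast literature value assumed by the compensator).
#' @param residual_gain_db,residual_ripple_db non-cancelling residual
#'   (applied to the second scanner's sample frames only).
#' @param cancelling_gain_db,cancelling_ripple_db cancelling transfer
#'   function amplitude per scanner (applied to sample and reference alike).
#' @param n_reference_frames phantom frames averaged into each scanner's
#'   reference table.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 30,
                          responder_fraction = 28 / 30,
                          frames_per_set = 4,
                          profiles = list(RP = scale_profile(profile_rp(), 192, 1024),
                                          CL15 = scale_profile(profile_cl15(), 144, 768)),
                          baseline_major_mm = c(9, 14),
                          center_depth_mm = 10.5,
                          shrink_mean = 0.71, shrink_sd = 0.05,
                          tumor_a_um = 30, tumor_a_sd = 2.5,
                          tumor_conc_db = 40, tumor_conc_sd = 1.5,
                          tumor_alpha = 1.0,
                          week4_a_factor = 1.15,
                          week4_conc_shift_db = 3,
                          week4_alpha_shift = 0.15,
                          background = tissue_truth(20, 10^3.6, 1.0),
                          residual_gain_db = 4,
                          residual_ripple_db = 1.5,
                          cancelling_gain_db = c(0, 6),
                          cancelling_ripple_db = c(1, 2),
                          n_reference_frames = 4) {
  if (responder_fraction < 0 || responder_fraction > 1)
    stop("responder fraction must lie in [0, 1]")
  stopifnot(n_patients >= 2, frames_per_set >= 4, frames_per_set <= 6,
            length(profiles) == 2)
  structure(as.list(environment()), class = "cohort_config")
}

#' Simulate a two-scanner, two-time-point cohort
#'
#' Per patient: an elliptical baseline tumor ROI, a (possibly shrunken)
#' week-4 ROI at the same location, ground-truth media for both time points,
#' and `frames_per_set` RF frames for each of the two scanner profiles at
#' each time point. Reference phantom frames for each scanner (sharing that
#' scanner's cancelling transfer function) are attached to the result.
#'
#' A fixed seed gives a bit-identical cohort.
#'
#' @param config a [cohort_config()].
#' @param seed integer master seed.
#' @param phantom reference phantom, a `phantom_spec`.
#' @return list of class `synthetic_cohort`: `cases` (one entry per
#'   patient), `references` (per system), `profiles`, `config`, `seed`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed,
                            phantom = default_phantom()) {
  stopifnot(inherits(config, "cohort_config"))
  if (missing(seed)) stop("a seed is required")
  n <- config$n_patients
  systems <- names(config$profiles)
  n_nonresp <- round((1 - config$responder_fraction) * n)
  nonresp_ids <- with_seed(derive_seed(seed, 1),
                           sample(seq_len(n), n_nonresp))

  cancelling <- lapply(seq_along(systems), function(si)
    nuisance_fun(config$cancelling_gain_db[si], config$cancelling_ripple_db[si],
                 phase = si))
  names(cancelling) <- systems
  residual <- nuisance_fun(config$residual_gain_db, config$residual_ripple_db,
                           ripple_cycles = 1.0, phase = 2.2)
  sample_gain <- list(
    function(f) cancelling[[1]](f),
    function(f) cancelling[[2]](f) + residual(f))
  names(sample_gain) <- systems

  cases <- vector("list", n)
  for (p in seq_len(n)) {
    gp <- with_seed(derive_seed(seed, 2, p), {
      major <- stats::runif(1, config$baseline_major_mm[1], config$baseline_major_mm[2])
      aspect <- stats::runif(1, 0.6, 0.9)
      shrink <- if (p %in% nonresp_ids) 1.0 else
        min(1, stats::rnorm(1, config$shrink_mean, config$shrink_sd))
      a0 <- stats::rnorm(1, config$tumor_a_um, config$tumor_a_sd)
      cdb0 <- stats::rnorm(1, config$tumor_conc_db, config$tumor_conc_sd)
      list(major = major, aspect = aspect, shrink = shrink, a0 = a0, cdb0 = cdb0)
    })
    responder <- !(p %in% nonresp_ids)
    lat_c <- config$profiles[[1]]$aperture_mm / 2
    roi_b <- ellipse_roi(config$center_depth_mm, lat_c,
                         gp$aspect * gp$major / 2, gp$major / 2)
    roi_w <- ellipse_roi(config$center_depth_mm, lat_c,
                         max(1.2, gp$aspect * gp$major / 2 * gp$shrink),
                         max(1.2, gp$major / 2 * gp$shrink))
    tr_b <- tissue_truth(gp$a0, 10^(gp$cdb0 / 10), config$tumor_alpha)
    tr_w <- if (responder)
      tissue_truth(gp$a0 * config$week4_a_factor,
                   10^((gp$cdb0 + config$week4_conc_shift_db) / 10),
                   config$tumor_alpha + config$week4_alpha_shift)
    else tr_b
    rois <- list(baseline = roi_b, week4 = roi_w)
    truths <- list(baseline = tr_b, week4 = tr_w)

    frames <- list()
    for (si in seq_along(systems)) {
      sys <- systems[si]
      frames[[sys]] <- list()
      for (tp in c("baseline", "week4")) {
        tm <- truth_map(config$background, truths[[tp]], rois[[tp]])
        frames[[sys]][[tp]] <- lapply(seq_len(config$frames_per_set), function(k)
          simulate_frame(tm, config$profiles[[sys]],
                         derive_seed(seed, 3, p, si, match(tp, c("baseline", "week4")), k),
                         extra_gain_db = sample_gain[[sys]]))
      }
    }
    cases[[p]] <- structure(list(
      patient_id = p, responder = responder,
      baseline_roi = roi_b, week4_roi = roi_w,
      baseline_truth = tr_b, week4_truth = tr_w,
      background_truth = config$background,
      frames = frames), class = "synthetic_case")
  }

  references <- lapply(seq_along(systems), function(si)
    simulate_reference(config$profiles[[si]], phantom,
                       config$n_reference_frames,
                       derive_seed(seed, 4, si),
                       extra_gain_db = cancelling[[si]]))
  names(references) <- systems

  structure(list(cases = cases, references = references,
                 profiles = config$profiles, phantom = phantom,
                 config = config, seed = as.integer(seed)),
            class = "synthetic_cohort")
}
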