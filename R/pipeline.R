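#' QUS feature extraction for one RF frame
#'
#' Runs the whole per-frame chain: ROI tiling into 2 mm blocks with 80%
#' overlap, Hann-windowed per-block power spectra, reference-phantom
#' normalization, local attenuation estimation (spectral-difference method,
#' with fallback to the assumed 1 dB cm^-1 MHz^-1 breast value when
#' unstable), point compensation, the linear spectral features (MBF, SS,
#' SI), BSC estimation and the Gaussian form-factor fit (ASD, AAC), and
#' optionally the five parametric maps with their GLCM texture statistics.
#'
#' @param frame an `rf_frame`.
#' @param roi an `roi_polygon`.
#' @param reference a `reference_table` for the frame's scanner.
#' @param phantom the `phantom_spec` behind the reference table.
#' @param band analysis band, MHz.
#' @param attenuation `"estimate"` (spectral-difference with fallback) or
#'   `"fixed"` (use `alpha_fixed` directly).
#' @param alpha_fixed,alpha_i assumed tumor / intervening-tissue
#'   attenuation, dB cm^-1 MHz^-1.
#' @param with_texture compute parametric maps and texture features.
#' @param sweep_a_um ASD sweep grid, um (radius).
#' @return list: `blocks`, `block_features` (per-block data.frame),
#'   `primary` (named 5-vector of block means; unreliable ASD/AAC fits
#'   excluded), `texture` (named 20-vector or NULL), `attenuation`
#'   (the `attenuation_model`), `n_excluded`.
#' @export
extract_frame_features <- function(frame, roi, reference, phantom,
                                   band = c(5.1, 8),
                                   attenuation = c("estimate", "fixed"),
                                   alpha_fixed = 1, alpha_i = 1,
                                   with_texture = TRUE,
                                   sweep_a_um = seq(1, 150, by = 0.25)) {
  attenuation <- match.arg(attenuation)
  blocks <- tile_blocks(roi, frame)
  raw <- block_spectra(frame, blocks, band)
  norm <- normalize_spectra(raw, reference)
  model <- if (attenuation == "estimate")
    estimate_local_attenuation(norm, alpha_r = phantom$attenuation_coeff,
                               alpha_i = alpha_i,
                               fallback_alpha = alpha_fixed)
  else attenuation_model(alpha_fixed, alpha_i, phantom$attenuation_coeff)
  comp <- compensate_spectra(norm, model)
  lin <- fit_linear_band(comp, band)
  sc <- estimate_asd_aac(sample_bsc(comp, phantom), sweep_a_um = sweep_a_um)
  bf <- cbind(blocks[, c("center_depth_mm", "center_lateral_mm")],
              lin[, c("MBF", "SS", "SI")],
              data.frame(ASD = sc$ASD_um, AAC = sc$AAC_db,
                         unreliable = sc$boundary))
  primary <- c(MBF = mean(bf$MBF), SS = mean(bf$SS), SI = mean(bf$SI),
               ASD = mean(bf$ASD[!bf$unreliable]),
               AAC = mean(bf$AAC[!bf$unreliable]))
  texture <- NULL
  if (with_texture) {
    texture <- numeric(0)
    for (fe in c("MBF", "SS", "SI", "ASD", "AAC")) {
      v <- bf[[fe]]
      if (fe %in% c("ASD", "AAC")) v[bf$unreliable] <- NA_real_
      map <- build_parametric_map(v, blocks, roi, frame)
      tf <- texture_features(map)
      names(tf) <- paste(fe, names(tf), sep = "_")
      texture <- c(texture, tf)
    }
  }
  list(blocks = blocks, block_features = bf, primary = primary,
       texture = texture, attenuation = model,
       n_excluded = sum(bf$unreliable))
}

#' Patient-level feature vector for one system at one time point
#'
#' Per-frame feature estimates averaged across frames (frames weighted
#' equally; the two-stage block-then-frame averaging of
#' [aggregate_blocks()]), yielding the 25-entry feature vector: 5 primary
#' features and 5 x 4 texture features. Missing values stay `NA`.
#'
#' @param frames list of `rf_frame` (4-6 per acquisition in the emulated
#'   protocol).
#' @param roi the tumor ROI shared by the frames.
#' @inheritParams extract_frame_features
#' @return named numeric vector of length 25 (see [feature_names()]).
#' @export
patient_feature_vector <- function(frames, roi, reference, phantom,
                                   band = c(5.1, 8), with_texture = TRUE, ...) {
  per_frame <- lapply(frames, function(fr)
    extract_frame_features(fr, roi, reference, phantom, band = band,
                           with_texture = with_texture, ...))
  prim <- do.call(rbind, lapply(per_frame, `[[`, "primary"))
  out <- colMeans(prim, na.rm = TRUE)
  if (with_texture) {
    tex <- do.call(rbind, lapply(per_frame, `[[`, "texture"))
    out <- c(out, colMeans(tex, na.rm = TRUE))
  } else {
    out <- c(out, stats::setNames(rep(NA_real_, 20),
                                  setdiff(feature_names(),
                                          c("MBF", "SS", "SI", "ASD", "AAC"))))
  }
  out[!is.finite(out)] <- NA_real_
  out[feature_names()]
}

#' Extract the tidy feature table of a simulated cohort
#'
#' Builds one reference spectrum table per scanner from the cohort's
#' phantom frames, then runs [patient_feature_vector()] for every (patient,
#' system, time point), returning the tidy table consumed by
#' [agreement_report()].
#'
#' @param cohort a `synthetic_cohort` from [simulate_cohort()].
#' @param band analysis band, MHz.
#' @param with_texture compute the 20 texture features as well.
#' @param verbose print progress.
#' @param ... passed to [extract_frame_features()].
#' @return data.frame: `patient`, `system`, `timepoint`, `feature`, `value`.
#' @export
cohort_features <- function(cohort, band = c(5.1, 8), with_texture = TRUE,
                            verbose = FALSE, ...) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  refs <- lapply(cohort$references, reference_spectrum_table, band = band)
  rows <- list()
  for (case in cohort$cases) {
    for (sys in names(cohort$profiles)) {
      for (tp in c("baseline", "week4")) {
        roi <- if (tp == "baseline") case$baseline_roi else case$week4_roi
        fv <- suppressWarnings(
          patient_feature_vector(case$frames[[sys]][[tp]], roi, refs[[sys]],
                                 cohort$phantom, band = band,
                                 with_texture = with_texture, ...))
        rows[[length(rows) + 1]] <- data.frame(
          patient = case$patient_id, system = sys, timepoint = tp,
          feature = names(fv), value = unname(fv))
      }
    }
    if (verbose)
      message(sprintf("patient %d/%d done", case$patient_id,
                      length(cohort$cases)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
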