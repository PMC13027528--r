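#' Linear spectral features: MBF, SS, SI
#'
#' Ordinary least squares of the log-compressed (dB) attenuation-compensated
#' normalized power spectrum against frequency over the analysis band
#' (5.1-8 MHz, the overlap of the two scanners' -6 dB bands): SS is the
#' slope (dB/MHz), SI the intercept extrapolated to 0 MHz (dB), and MBF the
#' fitted value at the band midpoint, so `MBF = SS * f_mid + SI` exactly.
#'
#' @param spectra a `block_spectra` at stage `"compensated"`.
#' @param band fit band `(f_low, f_high)` MHz; must contain >= 5 bins.
#' @return data.frame, one row per block: `MBF`, `SS`, `SI`, `r2`, plus the
#'   band as attributes `band` and `f_mid`.
#' @export
fit_linear_band <- function(spectra, band = c(5.1, 8)) {
  stopifnot_stage(spectra, "compensated")
  sel <- spectra$freq >= band[1] - 1e-9 & spectra$freq <= band[2] + 1e-9
  if (sum(sel) < 5) stop("fewer than 5 frequency bins in the fit band")
  f <- spectra$freq[sel]
  Y <- 10 * log10(spectra$power[, sel, drop = FALSE])
  fc <- f - mean(f)
  denom <- sum(fc^2)
  ss <- as.vector(Y %*% fc) / denom
  ybar <- rowMeans(Y)
  si <- ybar - ss * mean(f)
  f_mid <- (band[1] + band[2]) / 2
  mbf <- ss * f_mid + si
  fitted <- outer(ss, fc) + ybar
  ss_res <- rowSums((Y - fitted)^2)
  ss_tot <- rowSums((Y - ybar)^2)
  out <- data.frame(MBF = mbf, SS = ss, SI = si,
                    r2 = ifelse(ss_tot > 0, 1 - ss_res / ss_tot, NA_real_))
  attr(out, "band") <- band
  attr(out, "f_mid") <- f_mid
  out
}

#' Theoretical backscatter coefficient under the Gaussian form factor
#'
#' `sigma_theory(f) = pi^4/(36 c^4) * f^4 * a_eff^6 * n*gamma0^2 * FF_G`,
#' with the Gaussian form factor `FF_G = exp(-0.827 * (2*pi*f*a_eff/c)^2)`
#' describing the departure from Rayleigh f^4 scattering for finite
#' effective scatterer radius `a_eff`. Computed in SI units and reported in
#' sr^-1 cm^-1.
#'
#' @param freq_MHz frequency grid, MHz.
#' @param a_eff_um effective scatterer radius, micrometers (> 0).
#' @param conc_cm3 acoustic concentration n*gamma0^2, cm^-3.
#' @param c_mps speed of sound, m/s (1540 soft-tissue convention).
#' @return numeric vector, sr^-1 cm^-1.
#' @export
theoretical_bsc <- function(freq_MHz, a_eff_um, conc_cm3, c_mps = 1540) {
  if (a_eff_um <= 0) stop("effective scatterer radius must be positive")
  stopifnot(conc_cm3 > 0)
  f <- freq_MHz * 1e6
  a <- a_eff_um * 1e-6
  conc_m3 <- conc_cm3 * 1e6
  ka <- 2 * pi * f * a / c_mps
  sigma_m <- pi^4 / 36 * (f / c_mps)^4 * a^6 * conc_m3 * exp(-0.827 * ka^2)
  sigma_m / 100                        # m^-1 sr^-1 -> cm^-1 sr^-1
}

#' Gaussian form factor
#' @inheritParams theoretical_bsc
#' @return `exp(-0.827 * (2*pi*f*a_eff/c)^2)`.
#' @export
gaussian_form_factor <- function(freq_MHz, a_eff_um, c_mps = 1540) {
  ka <- 2 * pi * freq_MHz * 1e6 * a_eff_um * 1e-6 / c_mps
  exp(-0.827 * ka^2)
}

#' Sample backscatter coefficient spectra
#'
#' `sigma_s(f, z) = (W_s / W_r) * sigma_r(f) * exp(4*kappa*f*(alpha_m*z_m +
#' alpha_i*z_i - alpha_r*z))`. Stage bookkeeping guarantees the attenuation
#' exponent is applied exactly once: compensated input is only multiplied by
#' the phantom BSC, normalized input is compensated here first (requiring
#' `model`); raw input is rejected.
#'
#' @param spectra a `block_spectra` at stage `"normalized"` or
#'   `"compensated"`.
#' @param phantom a `phantom_spec` whose BSC table covers the band.
#' @param model an `attenuation_model`; required for normalized input,
#'   ignored (with the stage trace in the error if supplied twice) for
#'   compensated input.
#' @return object of class `bsc_estimate`: `freq`, `sigma` (blocks x bins,
#'   sr^-1 cm^-1), `blocks`.
#' @export
sample_bsc <- function(spectra, phantom, model = NULL) {
  if (!inherits(spectra, "block_spectra")) stop("expected a block_spectra")
  stopifnot(inherits(phantom, "phantom_spec"))
  if (spectra$stage == "raw")
    stop("raw spectra must be normalized before BSC estimation (stage trace: raw)")
  if (spectra$stage == "compensated") {
    if (!is.null(model))
      stop("double-compensation attempt: spectra are already compensated (stage trace: raw -> normalized -> compensated)")
    comp <- spectra
  } else {
    if (is.null(model))
      stop("normalized spectra require an attenuation_model for compensation")
    comp <- compensate_spectra(spectra, model)
  }
  sigma_r <- phantom_bsc(phantom, comp$freq)
  sigma <- sweep(comp$power, 2, sigma_r, `*`)
  structure(list(freq = comp$freq, sigma = sigma, blocks = comp$blocks),
            class = "bsc_estimate")
}

#' Scatterer size and concentration from the BSC (ASD, AAC)
#'
#' Fits each block's measured BSC to the Gaussian form-factor model by a
#' parameter sweep over effective scatterer radius. The fit is least squares
#' on the dB scale, where the optimal concentration for each candidate
#' radius is closed-form: the mean dB offset between the measured BSC and
#' the unit-concentration theoretical BSC. The radius minimizing the
#' residual (ties broken toward the smallest radius) gives
#' `ASD = 2 * a_eff` (reported as a diameter, um) and `AAC` = the offset,
#' i.e. `10*log10(n*gamma0^2)` in dB re 1 cm^-3.
#'
#' Fits whose minimizer sits on the sweep-grid boundary are flagged
#' unreliable; non-positive BSC bins are dropped per block, with an error if
#' fewer than 5 bins remain.
#'
#' @param bsc a `bsc_estimate`.
#' @param sweep_a_um candidate effective radii, um (default 1-150 um in
#'   0.25 um steps).
#' @param c_mps speed of sound for the theoretical model, m/s.
#' @return data.frame per block: `ASD_um`, `AAC_db`, `residual` (sum of
#'   squared dB differences), `boundary` (logical reliability flag).
#' @export
estimate_asd_aac <- function(bsc, sweep_a_um = seq(1, 150, by = 0.25),
                             c_mps = 1540) {
  stopifnot(inherits(bsc, "bsc_estimate"))
  nf <- length(bsc$freq)
  if (nf < 5) stop("fewer than 5 frequency bins")
  Tdb <- t(vapply(sweep_a_um, function(a)
    10 * log10(theoretical_bsc(bsc$freq, a, conc_cm3 = 1, c_mps = c_mps)),
    numeric(nf)))                              # candidates x freq
  Tc <- Tdb - rowMeans(Tdb)
  Tss <- rowSums(Tc^2)
  Tmean <- rowMeans(Tdb)

  fit_rows <- function(S) {                    # S: blocks x freq, dB, complete
    Sc <- S - rowMeans(S)
    R <- matrix(rowSums(Sc^2), nrow(S), length(sweep_a_um)) +
      matrix(Tss, nrow(S), length(sweep_a_um), byrow = TRUE) -
      2 * tcrossprod(Sc, Tc)
    j <- max.col(-R, ties.method = "first")    # smallest radius on ties
    data.frame(ASD_um = 2 * sweep_a_um[j],
               AAC_db = rowMeans(S) - Tmean[j],
               residual = pmax(R[cbind(seq_len(nrow(S)), j)], 0),
               boundary = j == 1L | j == length(sweep_a_um))
  }

  ok <- bsc$sigma > 0
  if (all(ok)) return(fit_rows(10 * log10(bsc$sigma)))
  out <- vector("list", nrow(bsc$sigma))
  for (b in seq_len(nrow(bsc$sigma))) {
    sel <- ok[b, ]
    if (sum(sel) < 5)
      stop(sprintf("block %d: fewer than 5 positive BSC bins remain", b))
    s <- 10 * log10(bsc$sigma[b, sel])
    Tb <- Tdb[, sel, drop = FALSE]
    Tbc <- Tb - rowMeans(Tb)
    r <- sum((s - mean(s))^2) + rowSums(Tbc^2) -
      2 * as.vector(Tbc %*% (s - mean(s)))
    j <- which.min(r)
    out[[b]] <- data.frame(ASD_um = 2 * sweep_a_um[j],
                           AAC_db = mean(s) - rowMeans(Tb)[j],
                           residual = max(r[j], 0),
                           boundary = j == 1L | j == length(sweep_a_um))
  }
  do.call(rbind, out)
}

#' Two-stage aggregation of block features
#'
#' Unweighted mean over blocks within each frame, then unweighted mean over
#' frames: the patient-level estimate weights frames equally regardless of
#' block count. Blocks flagged unreliable are excluded; if all blocks of all
#' frames are unreliable the feature is returned as `NA` (missing, never
#' silently zero).
#'
#' @param frame_values list with one numeric vector of block-level values
#'   per frame.
#' @param exclude optional list of logical vectors (same shapes) marking
#'   unreliable blocks.
#' @return list: `value` (scalar, possibly NA), `n_excluded`.
#' @export
aggregate_blocks <- function(frame_values, exclude = NULL) {
  stopifnot(length(frame_values) >= 1)
  n_excluded <- 0L
  frame_means <- vapply(seq_along(frame_values), function(i) {
    v <- frame_values[[i]]
    if (!is.null(exclude)) {
      n_excluded <<- n_excluded + sum(exclude[[i]] & !is.na(v))
      v <- v[!exclude[[i]]]
    }
    v <- v[is.finite(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  ok <- is.finite(frame_means)
  list(value = if (any(ok)) mean(frame_means[ok]) else NA_real_,
       n_excluded = n_excluded)
}

#' Names of the 25 per-patient QUS features
#'
#' Five primary features (MBF, SS, SI, ASD, AAC) plus each crossed with the
#' four GLCM texture statistics (CON, COR, ENE, HOM).
#' @return character vector of length 25.
#' @export
feature_names <- function() {
  primary <- c("MBF", "SS", "SI", "ASD", "AAC")
  c(primary, as.vector(t(outer(primary, c("CON", "COR", "ENE", "HOM"),
                               paste, sep = "_"))))
}
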