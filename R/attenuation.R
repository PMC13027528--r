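#' Attenuation model for point compensation
#'
#' Bundles the three frequency-linear attenuation coefficients entering the
#' backscatter-coefficient compensation exponent
#' `exp(4*kappa*f*(alpha_m*z_m + alpha_i*z_i - alpha_r*z))` (f in MHz, z in
#' cm, `kappa = ln(10)/20` converting dB-convention coefficients to the Np
#' amplitude form; the multiplier is `2*f*(...)` dB of power exactly):
#' tumor (`alpha_m`, estimated), intervening breast tissue (`alpha_i`, the
#' literature value 1 dB cm^-1 MHz^-1) and the reference phantom
#' (`alpha_r`, 0.7861 dB cm^-1 MHz^-1 for the shipped phantom).
#'
#' @param alpha_m tumor attenuation, dB cm^-1 MHz^-1.
#' @param alpha_i intervening-tissue attenuation, dB cm^-1 MHz^-1.
#' @param alpha_r reference phantom attenuation, dB cm^-1 MHz^-1.
#' @param fallback TRUE when `alpha_m` is the assumed literature value
#'   because the local estimate was unavailable or implausible.
#' @param diagnostics optional list of fit diagnostics.
#' @return object of class `attenuation_model`.
#' @export
attenuation_model <- function(alpha_m, alpha_i = 1, alpha_r = 0.7861,
                              fallback = FALSE, diagnostics = list()) {
  stopifnot(alpha_i > 0, alpha_r > 0, is.finite(alpha_m))
  structure(list(alpha_m = alpha_m, alpha_i = alpha_i, alpha_r = alpha_r,
                 fallback = fallback, diagnostics = diagnostics),
            class = "attenuation_model")
}

#' @export
print.attenuation_model <- function(x, ...) {
  cat(sprintf("<attenuation_model> alpha_m %.3f (alpha_i %.3f, alpha_r %.4f) dB/cm/MHz%s\n",
              x$alpha_m, x$alpha_i, x$alpha_r,
              if (x$fallback) " [fallback to assumed value]" else ""))
  invisible(x)
}

#' Local attenuation by the reference-phantom spectral-difference method
#'
#' From normalized block spectra: (1) per block, the log-compressed power
#' `10*log10(W_s/W_r)`; (2) average across all blocks at the same axial
#' depth, giving the depth profile `P(f, z)` in dB; (3) per in-band
#' frequency, the ordinary least-squares slope `b(f)` of `P` versus depth
#' (dB/cm); (4) `alpha_m(f) = alpha_r - b(f) / (2 f)` -- the dB slope of the
#' normalized log spectrum is `-2*(alpha_s - alpha_r)*f` under the
#' round-trip power convention; (5) average over frequency.
#'
#' If fewer than `min_rows` distinct depth rows carry at least two blocks,
#' or the estimate falls outside the plausibility gate, the assumed breast
#' value (1 dB cm^-1 MHz^-1) is used instead and the model is flagged as a
#' fallback (with a warning).
#'
#' @param spectra a `block_spectra` at stage `"normalized"` (typically the
#'   blocks of one or more frames of the same tumor, concatenated).
#' @param alpha_r reference phantom attenuation, dB cm^-1 MHz^-1.
#' @param alpha_i intervening-tissue attenuation, dB cm^-1 MHz^-1.
#' @param gate plausibility interval for the estimate.
#' @param fallback_alpha assumed breast attenuation used on fallback.
#' @param min_rows minimum number of usable depth rows.
#' @return an `attenuation_model` with diagnostics (`slopes_db_cm` per
#'   frequency, per-frequency regression `r2`, `n_rows`).
#' @export
estimate_local_attenuation <- function(spectra, alpha_r = 0.7861,
                                       alpha_i = 1, gate = c(0.2, 2.5),
                                       fallback_alpha = 1, min_rows = 4) {
  stopifnot_stage(spectra, "normalized")
  z_all <- spectra$blocks$center_depth_mm
  rows <- sort(unique(z_all))
  use_rows <- rows[vapply(rows, function(z) sum(z_all == z) >= 2, logical(1))]
  if (length(use_rows) < min_rows) {
    warning(sprintf("only %d usable depth rows (< %d): falling back to assumed alpha_m = %g dB/cm/MHz",
                    length(use_rows), min_rows, fallback_alpha))
    return(attenuation_model(fallback_alpha, alpha_i, alpha_r, fallback = TRUE,
                             diagnostics = list(n_rows = length(use_rows))))
  }
  keep <- z_all %in% use_rows
  g <- factor(z_all[keep], levels = use_rows)
  Pdb <- 10 * log10(spectra$power[keep, , drop = FALSE])
  Pbar <- rowsum(Pdb, g) / as.vector(table(g))     # depth rows x freq, dB
  z_cm <- use_rows / 10
  zc <- z_cm - mean(z_cm)
  denom <- sum(zc^2)
  slopes <- as.vector(crossprod(zc, Pbar)) / denom  # dB/cm per frequency
  fitted <- outer(zc, slopes) +
    matrix(colMeans(Pbar), length(z_cm), ncol(Pbar), byrow = TRUE)
  ss_res <- colSums((Pbar - fitted)^2)
  ss_tot <- colSums(sweep(Pbar, 2, colMeans(Pbar))^2)
  r2 <- ifelse(ss_tot > 0, 1 - ss_res / ss_tot, NA_real_)
  alpha_f <- alpha_r - slopes / (2 * spectra$freq)
  alpha_m <- mean(alpha_f)
  diag <- list(slopes_db_cm = slopes, freq = spectra$freq, r2 = r2,
               n_rows = length(use_rows), alpha_f = alpha_f)
  if (alpha_m < gate[1] || alpha_m > gate[2]) {
    warning(sprintf("local attenuation estimate %.3f outside plausibility gate [%g, %g]: falling back to assumed alpha_m = %g",
                    alpha_m, gate[1], gate[2], fallback_alpha))
    return(attenuation_model(fallback_alpha, alpha_i, alpha_r, fallback = TRUE,
                             diagnostics = c(diag, list(rejected_alpha = alpha_m))))
  }
  attenuation_model(alpha_m, alpha_i, alpha_r, fallback = FALSE,
                    diagnostics = diag)
}

#' Point-compensate normalized spectra for total attenuation
#'
#' Multiplies each normalized block spectrum, per frequency, by
#' `exp(4*kappa*f*(alpha_m*z_m + alpha_i*z_i - alpha_r*z))` with
#' `z = z_i + z_m` the block center depth (cm), `z_i` the intervening-tissue
#' path and `z_m` the intra-tumor path, and `kappa = ln(10)/20`
#' (equivalently a gain of `2*f*(alpha_m*z_m + alpha_i*z_i - alpha_r*z)`
#' dB). When all three coefficients are equal the multiplier is exactly 1.
#'
#' @param spectra a `block_spectra` at stage `"normalized"`.
#' @param model an `attenuation_model`.
#' @param max_exponent overflow guard on the natural-log exponent.
#' @return a `block_spectra` at stage `"compensated"`.
#' @export
compensate_spectra <- function(spectra, model, max_exponent = 20) {
  stopifnot_stage(spectra, "normalized")
  stopifnot(inherits(model, "attenuation_model"))
  b <- spectra$blocks
  z_m <- b$z_m_mm / 10; z_i <- b$z_i_mm / 10
  z <- z_m + z_i
  path <- model$alpha_m * z_m + model$alpha_i * z_i - model$alpha_r * z  # dB MHz^-1
  expo <- 4 * kappa_db_np * (path %o% spectra$freq)
  bad <- which(abs(expo) > max_exponent, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("attenuation compensation exponent exceeds %g for block %d (depth %.1f mm)",
                 max_exponent, bad[1, 1], b$center_depth_mm[bad[1, 1]]))
  out <- new_block_spectra(spectra$freq, spectra$power * exp(expo),
                           spectra$blocks, "compensated",
                           spectra$profile_name, spectra$window_len)
  attr(out, "attenuation_model") <- model
  out
}
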