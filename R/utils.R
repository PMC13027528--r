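# dB / Np conventions used throughout.
#
# Attenuation coefficients are quoted in dB cm^-1 MHz^-1 in the clinical
# one-way convention: a signal loses alpha*f*z dB of level (amplitude and
# intensity dB are the same number) per one-way path z. Hence:
#   * amplitude Np coefficient: alpha_np = alpha_db * ln(10)/20  (1/8.686)
#   * round-trip POWER loss in dB over depth z: 2 * alpha_db * f * z
#   * the e^{4 alpha z} exponential of backscatter-coefficient algebra uses
#     the Np amplitude coefficient, and 10*log10(e^{4 alpha_np f z}) equals
#     2 * alpha_db * f * z exactly.
# The constant below converts dB-convention coefficients into the Np form
# entering e^{4 kappa alpha_db f z}; it is unit-tested.

#' dB-to-Np conversion constant for the round-trip exponent
#'
#' `kappa_db_np` = ln(10)/20, so that `exp(4 * kappa_db_np * alpha_db * f * z)`
#' is the round-trip power compensation for a one-way attenuation of
#' `alpha_db` dB cm^-1 MHz^-1 over `z` cm at `f` MHz, i.e. exactly
#' `2 * alpha_db * f * z` dB.
#' @export
kappa_db_np <- log(10) / 20

db <- function(x) 10 * log10(x)
undb <- function(x) 10^(x / 10)

#' Round-trip attenuation in dB power
#'
#' @param alpha_db one-way attenuation coefficient, dB cm^-1 MHz^-1 (may be a
#'   cumulative path integral in dB MHz^-1 if `z_cm = 1`).
#' @param f_MHz frequency, MHz.
#' @param z_cm one-way path length, cm.
#' @return dB of round-trip power loss (positive number = loss).
#' @keywords internal
roundtrip_att_db <- function(alpha_db, f_MHz, z_cm) 2 * alpha_db * f_MHz * z_cm

# Deterministic child seeds: derive a stream of sub-seeds from one master
# seed without consuming the global RNG state unpredictably. Keeps every
# derived seed in the 32-bit integer range.
derive_seed <- function(seed, ...) {
  key <- c(seed, unlist(list(...)))
  x <- 0
  for (k in key) x <- (x * 69069 + (as.numeric(k) %% 2147483647) + 1) %% 2147483647
  as.integer(x)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
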