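test_that("Hann window matches its closed form and FWHM contract", {
  expect_equal(hann_window(3), c(0, 1, 0))
  w <- hann_window(104)
  expect_equal(length(w), 104L)
  expect_equal(w[1], 0); expect_equal(w[104], 0)
  expect_equal(max(hann_window(105)), 1)       # odd length: exact unit peak
  expect_gt(max(w), 0.999)
  # at-or-above-half-maximum span: 51 sample intervals (0-based 26..77)
  expect_equal(window_fwhm_samples(w), 51L)
  expect_equal(range(which(w >= 0.5)) - 1L, c(26L, 77L))
  # window power: sum of squares = 0.375 * (N - 1) for this endpoint convention
  for (n in c(16, 51, 104, 257))
    expect_equal(sum(hann_window(n)^2), 0.375 * (n - 1), tolerance = 1e-6)
  expect_error(hann_window(2), "at least 3")
})

test_that("block power spectrum finds a pure tone and averages lines", {
  prof <- desk_rp()
  fr <- empty_frame(prof)
  t_us <- (seq_len(nrow(fr$samples)) - 1) / prof$sampling_rate
  tone <- sin(2 * pi * 6 * t_us)
  fr$samples <- matrix(tone, nrow(fr$samples), ncol(fr$samples))
  blocks <- fake_blocks(9)
  blocks$axial_start <- 200L; blocks$line_start <- 10L
  sp <- block_power_spectrum(fr, blocks)
  expect_s3_class(sp, "block_spectra")
  expect_equal(sp$stage, "raw")
  expect_lt(abs(sp$freq[which.max(sp$power)] - 6), 0.35)

  # identical lines: averaging over 3 vs 9 lines gives the same spectrum
  b2 <- blocks; b2$line_len <- 9L
  expect_equal(block_power_spectrum(fr, b2)$power, sp$power)
})

test_that("white-noise block spectra are flat across the band", {
  prof <- desk_rp(n_lines = 192, samples = 1536)
  set.seed(71)
  pow <- 0
  for (k in 1:2) {
    fr <- empty_frame(prof)
    fr$samples <- matrix(rnorm(length(fr$samples)), nrow(fr$samples))
    # non-overlapping tiling: every block is an independent look
    blocks <- tile_blocks(rect_roi(2, 28, 3, 35), fr, overlap_fraction = 0)
    pow <- pow + colMeans(block_spectra(fr, blocks)$power) / 2
  }
  mean_db <- 10 * log10(pow)
  expect_lt(diff(range(mean_db)), 0.3)
})

test_that("normalization divides by the depth-matched reference", {
  freq <- seq(5.1, 8, by = 0.05)
  ref <- structure(list(depth_mm = c(5, 7, 9), freq = freq,
                        power = matrix(rep(c(2, 4, 8), length(freq)), 3),
                        n_frames = 3, profile_name = "RP-desk",
                        block_mm = 2, window_len = 104L),
                   class = "reference_table")
  sp <- fake_spectra(matrix(8, 2, length(freq)), freq,
                     fake_blocks(c(7.1, 9.2)), stage = "raw")
  nm <- normalize_spectra(sp, ref)
  expect_equal(nm$stage, "normalized")
  expect_equal(nm$power[1, ], rep(2, length(freq)), ignore_attr = TRUE)
  expect_equal(nm$power[2, ], rep(1, length(freq)), ignore_attr = TRUE)
  # missing depth bin and profile mismatch are rejected by name
  sp_far <- fake_spectra(matrix(8, 1, length(freq)), freq, fake_blocks(12),
                         stage = "raw")
  expect_error(normalize_spectra(sp_far, ref), "12.00 mm")
  sp_wrong <- fake_spectra(matrix(8, 1, length(freq)), freq, fake_blocks(7),
                           stage = "raw", profile_name = "CL15-desk")
  expect_error(normalize_spectra(sp_wrong, ref), "profile mismatch")
})

test_that("a common multiplicative transfer function cancels exactly", {
  freq <- seq(5.1, 8, by = 0.05)
  set.seed(5)
  ref_p <- matrix(runif(3 * length(freq), 1, 2), 3)
  ref <- structure(list(depth_mm = c(5, 7, 9), freq = freq, power = ref_p,
                        n_frames = 3, profile_name = "RP-desk",
                        block_mm = 2, window_len = 104L),
                   class = "reference_table")
  samp <- matrix(runif(2 * length(freq), 0.5, 3), 2)
  sp <- fake_spectra(samp, freq, fake_blocks(c(5, 9)), stage = "raw")
  base <- normalize_spectra(sp, ref)
  g <- 10^(sin(freq) / 10)                      # smooth system response
  ref2 <- ref; ref2$power <- sweep(ref_p, 2, g, `*`)
  sp2 <- fake_spectra(sweep(samp, 2, g, `*`), freq, sp$blocks, stage = "raw")
  with_g <- normalize_spectra(sp2, ref2)
  expect_equal(with_g$power, base$power, tolerance = 1e-12)
})

test_that("self-normalization of the phantom yields a 0 dB spectrum", {
  fixt <- self_normalized_fixture()
  pooled <- concat_block_spectra(fixt$spectra)
  mean_db <- 10 * log10(colMeans(pooled$power))
  expect_lt(max(abs(mean_db)), 0.3)
})

test_that("stage ordering is enforced through the chain", {
  freq <- seq(5.1, 8, by = 0.05)
  raw <- fake_spectra(matrix(1, 1, length(freq)), freq, fake_blocks(7),
                      stage = "raw")
  model <- attenuation_model(1)
  expect_error(compensate_spectra(raw, model), "expected stage 'normalized'")
  norm <- fake_spectra(raw$power, freq, raw$blocks, stage = "normalized")
  expect_error(fit_linear_band(norm), "expected stage 'compensated'")
  expect_error(estimate_local_attenuation(
    fake_spectra(raw$power, freq, raw$blocks, stage = "compensated")),
    "expected stage 'normalized'")
})
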