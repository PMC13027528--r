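test_that("linear band fit is exact on linear spectra and keeps its identity", {
  freq <- seq(5.1, 8, by = 0.05)
  # dB spectrum 2 f + 3: SS = 2, SI = 3, MBF = 2 * 6.55 + 3 = 16.1
  sp <- fake_spectra(rbind(10^((2 * freq + 3) / 10), rep(1, length(freq))),
                     freq, fake_blocks(c(7, 9)), stage = "compensated")
  fit <- fit_linear_band(sp)
  expect_equal(fit$SS[1], 2, tolerance = 1e-10)
  expect_equal(fit$SI[1], 3, tolerance = 1e-10)
  expect_equal(fit$MBF[1], 16.1, tolerance = 1e-10)
  expect_equal(unlist(fit[2, c("MBF", "SS", "SI")]), c(MBF = 0, SS = 0, SI = 0),
               tolerance = 1e-12)
  # regression identity MBF = SS * f_mid + SI on random spectra
  set.seed(9)
  rnd <- fake_spectra(matrix(10^(rnorm(5 * length(freq)) / 10), 5), freq,
                      fake_blocks(rep(8, 5)), stage = "compensated")
  f2 <- fit_linear_band(rnd)
  expect_equal(f2$MBF, f2$SS * 6.55 + f2$SI, tolerance = 1e-12)
  narrow <- fake_spectra(matrix(1, 1, 3), c(6, 6.05, 6.1), fake_blocks(8),
                         stage = "compensated")
  expect_error(fit_linear_band(narrow, band = c(6, 6.1)), "fewer than 5")
})

test_that("theoretical BSC obeys Rayleigh, linearity and form-factor limits", {
  # Rayleigh limit: f^4 scaling for vanishing scatterer size
  r <- theoretical_bsc(8, 0.1, 1e4) / theoretical_bsc(4, 0.1, 1e4)
  expect_equal(r, 16, tolerance = 1e-5)   # residual form factor ~7e-6 at 0.1 um
  # linear in concentration
  f <- seq(5.1, 8, by = 0.1)
  expect_equal(theoretical_bsc(f, 25, 2e4), 2 * theoretical_bsc(f, 25, 1e4))
  # Gaussian form factor at ka = 1
  a <- 25
  f_ka1 <- 1540 / (2 * pi * a)                    # MHz, since a in um
  expect_equal(gaussian_form_factor(f_ka1, a), exp(-0.827), tolerance = 1e-12)
  expect_error(theoretical_bsc(f, -1, 1e4), "positive")
})

test_that("ASD/AAC sweep inverts its own forward model exactly on the grid", {
  freq <- seq(5.1, 8, by = 0.05)
  sigma <- theoretical_bsc(freq, a_eff_um = 25, conc_cm3 = 1e4)
  bsc <- structure(list(freq = freq, sigma = rbind(sigma, 10 * sigma),
                        blocks = fake_blocks(c(7, 7))),
                   class = "bsc_estimate")
  fit <- estimate_asd_aac(bsc)
  expect_equal(fit$ASD_um[1], 50)                  # diameter = 2 * a_eff
  expect_equal(fit$AAC_db[1], 40, tolerance = 1e-9)
  expect_false(any(fit$boundary))
  # x10 BSC scaling: ASD invariant, AAC shifted by exactly +10 dB
  expect_equal(fit$ASD_um[2], fit$ASD_um[1])
  expect_equal(fit$AAC_db[2] - fit$AAC_db[1], 10, tolerance = 1e-9)

  # truth beyond the sweep grid hits the boundary and is flagged
  big <- structure(list(freq = freq,
                        sigma = rbind(theoretical_bsc(freq, 400, 1e4)),
                        blocks = fake_blocks(7)),
                   class = "bsc_estimate")
  expect_true(estimate_asd_aac(big)$boundary)

  # non-positive bins are dropped; too few remaining bins error out
  sig2 <- rbind(sigma)
  sig2[1, seq(1, 50)] <- -1
  ok <- estimate_asd_aac(structure(list(freq = freq, sigma = sig2,
                                        blocks = fake_blocks(7)),
                                   class = "bsc_estimate"))
  expect_equal(ok$ASD_um, 50, tolerance = 2)       # fewer bins, same optimum
  sig3 <- rbind(sigma); sig3[1, -(1:4)] <- 0
  expect_error(estimate_asd_aac(structure(list(freq = freq, sigma = sig3,
                                               blocks = fake_blocks(7)),
                                          class = "bsc_estimate")),
               "fewer than 5")
})

test_that("sample BSC applies the phantom spectrum and guards its stages", {
  freq <- seq(5.1, 8, by = 0.05)
  ph <- default_phantom()
  comp <- fake_spectra(matrix(2, 1, length(freq)), freq, fake_blocks(7),
                       stage = "compensated")
  bsc <- sample_bsc(comp, ph)
  expect_equal(bsc$sigma[1, ], 2 * phantom_bsc(ph, freq), ignore_attr = TRUE)
  expect_error(sample_bsc(comp, ph, model = attenuation_model(1)),
               "double-compensation")
  raw <- fake_spectra(comp$power, freq, comp$blocks, stage = "raw")
  expect_error(sample_bsc(raw, ph), "normalized")
  norm <- fake_spectra(comp$power, freq, comp$blocks, stage = "normalized")
  expect_error(sample_bsc(norm, ph), "attenuation_model")
  # normalized + model path: all-equal coefficients make it the compensated path
  same <- attenuation_model(0.9, 0.9, 0.9)
  expect_equal(sample_bsc(norm, ph, model = same)$sigma, bsc$sigma,
               tolerance = 1e-12)
})

test_that("aggregation is two-stage (blocks within frame, then frames)", {
  expect_equal(aggregate_blocks(list(c(1, 2, 3)))$value, 2)
  # frame means 2 and 4 with unequal block counts -> 3, not the pooled mean
  agg <- aggregate_blocks(list(c(1, 2, 3), c(4, 4)))
  expect_equal(agg$value, 3)
  ex <- aggregate_blocks(list(c(1, 2, 100)), exclude = list(c(FALSE, FALSE, TRUE)))
  expect_equal(ex$value, 1.5)
  expect_equal(ex$n_excluded, 1L)
  all_bad <- aggregate_blocks(list(c(1, 2)), exclude = list(c(TRUE, TRUE)))
  expect_true(is.na(all_bad$value))
  expect_length(feature_names(), 25)
})
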