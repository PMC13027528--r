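test_that("parametric maps average overlapping block estimates per pixel", {
  prof <- desk_rp()
  fr <- empty_frame(prof)
  roi <- rect_roi(4, 12, 14, 24)
  blocks <- tile_blocks(roi, fr)
  # single block: constant over its footprint
  one <- blocks[1, , drop = FALSE]
  attr(one, "block_mm") <- 2; attr(one, "step_mm") <- 0.4
  class(one) <- class(blocks)
  m1 <- build_parametric_map(7, one, roi, fr)
  expect_equal(unique(stats::na.omit(as.vector(m1$values))), 7)
  # two overlapping blocks: strip = mean, outside strip = own value
  two <- blocks[1:2, , drop = FALSE]
  two$center_depth_mm <- c(6, 7); two$center_lateral_mm <- c(19, 19)
  attr(two, "block_mm") <- 2; attr(two, "step_mm") <- 0.4
  class(two) <- class(blocks)
  m2 <- build_parametric_map(c(1, 3), two, roi, fr)
  vals <- sort(unique(stats::na.omit(as.vector(m2$values))))
  expect_equal(vals, c(1, 2, 3))

  # random layouts match the brute-force per-pixel enumeration
  set.seed(42)
  for (k in 1:5) {
    nb <- 12
    rb <- blocks[sample(nrow(blocks), nb), ]
    rb$center_depth_mm <- runif(nb, 5, 11)
    rb$center_lateral_mm <- runif(nb, 15, 23)
    attr(rb, "block_mm") <- 2; attr(rb, "step_mm") <- 0.4
    class(rb) <- class(blocks)
    v <- rnorm(nb)
    got <- build_parametric_map(v, rb, roi, fr)
    want <- parametric_map_oracle(v, rb, roi, fr, pixel_mm = 0.4)
    expect_equal(got$values, want, tolerance = 1e-12)
  }
})

test_that("quantization maps extremes to extreme levels, affine-invariantly", {
  m <- make_parametric_map(matrix(c(0, 1, 0, 1), 2))
  q <- quantize_map(m)
  expect_setequal(as.vector(q$levels), c(0L, 15L))
  # a ramp of 16 plateaus occupies every level once
  ramp <- make_parametric_map(matrix(rep(seq(0, 15) / 15, each = 2), 4, 8))
  expect_setequal(as.vector(quantize_map(ramp)$levels), 0:15)
  # affine invariance v -> a v + b, a > 0
  set.seed(3)
  v <- matrix(rnorm(200), 10)
  q1 <- quantize_map(make_parametric_map(v))
  q2 <- quantize_map(make_parametric_map(2.7 * v + 11))
  expect_identical(q1$levels, q2$levels)
  # constant map is degenerate
  expect_true(quantize_map(make_parametric_map(matrix(5, 3, 3)))$degenerate)
})

test_that("GLCM statistics match hand-computed small cases", {
  lm1 <- make_level_map(matrix(c(0L, 1L, 0L, 1L), 2))   # [[0,0],[1,1]] rows
  g <- glcm(lm1, dr = 0, dc = 1)
  expect_equal(g$p[1, 1], 0.5); expect_equal(g$p[2, 2], 0.5)
  expect_equal(g$contrast, 0)
  expect_equal(g$energy, 0.5)
  expect_equal(g$homogeneity, 1)
  expect_equal(g$correlation, 1)
  # constant map: single-cell GLCM
  gc <- glcm(make_level_map(matrix(3L, 4, 4)), 0, 1)
  expect_equal(gc$contrast, 0); expect_equal(gc$energy, 1)
  expect_equal(gc$homogeneity, 1); expect_true(is.na(gc$correlation))
  # checkerboard of levels {0, 15}: every horizontal pair differs by 15
  chk <- matrix(rep(c(0L, 15L), 8), 4, 4)
  chk[, c(2, 4)] <- 15L - chk[, c(2, 4)]
  gk <- glcm(make_level_map(chk), 0, 1)
  expect_equal(gk$contrast, 225)
  expect_equal(gk$homogeneity, 1 / 16)
  o <- glcm_oracle(chk, 0, 1)
  expect_equal(gk$contrast, o$contrast)
  expect_equal(gk$energy, o$energy)
})

test_that("GLCM equals the brute-force oracle on random masked maps", {
  set.seed(17)
  offs <- qusagree:::glcm_offsets()
  expect_equal(nrow(offs), 16L)
  for (k in 1:20) {
    m <- matrix(sample(0:15, 20 * 20, replace = TRUE), 20)
    m[matrix(runif(400) < 0.25, 20)] <- NA_integer_
    lm <- make_level_map(m)
    for (i in seq_len(nrow(offs))) {
      got <- glcm(lm, offs$dr[i], offs$dc[i])
      want <- glcm_oracle(m, offs$dr[i], offs$dc[i])
      expect_equal(got$p, want$p, tolerance = 1e-12, ignore_attr = TRUE)
      for (f in c("contrast", "correlation", "energy", "homogeneity"))
        expect_equal(got[[f]], want[[f]], tolerance = 1e-12)
      expect_equal(sum(got$p), 1, tolerance = 1e-12)
      expect_true(got$energy > 0 && got$energy <= 1)
      expect_true(got$homogeneity > 0 && got$homogeneity <= 1)
      expect_lte(got$contrast, 225)
      if (!is.na(got$correlation))
        expect_true(abs(got$correlation) <= 1 + 1e-12)
    }
  }
})

test_that("gray-level inversion leaves the symmetric GLCM statistics fixed", {
  set.seed(23)
  m <- matrix(sample(0:15, 144, replace = TRUE), 12)
  g1 <- glcm(make_level_map(m), 1, 1)
  g2 <- glcm(make_level_map(15L - m), 1, 1)
  for (f in c("contrast", "correlation", "energy", "homogeneity"))
    expect_equal(g1[[f]], g2[[f]], tolerance = 1e-12)
})

test_that("texture summary averages the 16 configurations isotropically", {
  set.seed(31)
  v <- matrix(rnorm(60 * 60), 60)
  map <- make_parametric_map(v)
  tf <- texture_features(map)
  expect_named(tf, c("CON", "COR", "ENE", "HOM"))
  expect_equal(attr(tf, "n_configs"), 16L)
  expect_equal(attr(tf, "n_skipped"), 0L)
  # iid map: the four per-angle contrasts at d = 1 agree within sampling noise
  lm <- quantize_map(map)
  cons <- vapply(list(c(0, 1), c(1, 1), c(1, 0), c(1, -1)),
                 function(o) glcm(lm, o[1], o[2])$contrast, numeric(1))
  expect_lt(diff(range(cons)) / mean(cons), 0.1)
  # a tiny all-NA-but-one map skips every offset beyond its extent
  small <- make_parametric_map(matrix(c(1, 2, NA, NA), 1, 4))
  tf2 <- texture_features(small)
  expect_gt(attr(tf2, "n_skipped"), 0)
})
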