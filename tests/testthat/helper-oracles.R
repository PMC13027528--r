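# Independent brute-force oracles, kept deliberately naive.

# GLCM statistics by direct pair enumeration over every pixel.
glcm_oracle <- function(levels, dr, dc, n_levels = 16) {
  nr <- nrow(levels); nc <- ncol(levels)
  P <- matrix(0, n_levels, n_levels)
  n_pairs <- 0L
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      r2 <- r + dr; c2 <- cc + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      a <- levels[r, cc]; b <- levels[r2, c2]
      if (is.na(a) || is.na(b)) next
      P[a + 1, b + 1] <- P[a + 1, b + 1] + 1
      P[b + 1, a + 1] <- P[b + 1, a + 1] + 1
      n_pairs <- n_pairs + 1L
    }
  }
  if (n_pairs == 0) return(NULL)
  p <- P / sum(P)
  lev <- 0:(n_levels - 1)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(lev * px); muy <- sum(lev * py)
  sx <- sqrt(sum((lev - mux)^2 * px)); sy <- sqrt(sum((lev - muy)^2 * py))
  con <- 0; ene <- 0; hom <- 0; cor_num <- 0
  for (i in lev) for (j in lev) {
    pij <- p[i + 1, j + 1]
    con <- con + (i - j)^2 * pij
    ene <- ene + pij^2
    hom <- hom + pij / (1 + abs(i - j))
    cor_num <- cor_num + (i - mux) * (j - muy) * pij
  }
  list(p = p, contrast = con, energy = ene, homogeneity = hom,
       correlation = if (sx > 0 && sy > 0) cor_num / (sx * sy) else NA_real_,
       n_pairs = n_pairs)
}

# Exact two-sided Wilcoxon signed-rank p-value by full 2^n sign-flip
# enumeration (tie-free differences assumed).
wilcoxon_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  ev <- n * (n + 1) / 4
  p <- mean(abs(v_all - ev) >= abs(v_obs - ev) - 1e-12)
  min(1, p)
}

# Parametric-map oracle: loop over pixels, test containment in each block
# footprint, average.
parametric_map_oracle <- function(values, blocks, roi, frame, pixel_mm,
                                  block_mm = 2) {
  depth_extent <- nrow(frame$samples) * frame$axial_spacing_mm
  lat_extent <- ncol(frame$samples) * frame$profile$line_pitch
  nr <- max(1L, floor(depth_extent / pixel_mm))
  nc <- max(1L, floor(lat_extent / pixel_mm))
  o <- frame$origin_depth_mm
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      d <- o + (i - 0.5) * pixel_mm
      l <- (j - 0.5) * pixel_mm
      if (!qusagree:::points_in_polygon(d, l, roi$vertices)) next
      hits <- which(is.finite(values) &
                      abs(blocks$center_depth_mm - d) <= block_mm / 2 &
                      abs(blocks$center_lateral_mm - l) <= block_mm / 2)
      if (length(hits)) out[i, j] <- mean(values[hits])
    }
  }
  out
}
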