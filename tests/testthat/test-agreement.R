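test_that("Wilcoxon signed-rank matches exhaustive sign-flip enumeration", {
  set.seed(61)
  for (k in 1:100) {
    n <- sample(5:12, 1)
    d <- round(rnorm(n, sd = 3), 3)
    while (any(d == 0) || any(duplicated(abs(d))))
      d <- round(rnorm(n, sd = 3), 3)
    got <- wilcoxon_signed_rank(d)
    expect_equal(got$p_value, wilcoxon_oracle(d), tolerance = 1e-12)
    expect_equal(got$n_effective, n)
  }
})

test_that("Wilcoxon handles zeros, ties and degenerate inputs", {
  z <- wilcoxon_signed_rank(rep(0, 8))
  expect_equal(z$p_value, 1)
  expect_equal(z$n_effective, 0L)
  expect_false(z$reliable)
  # zero differences dropped before ranking
  d <- c(0, 0, 1.3, -0.4, 2.2, 0.9, -1.8, 0.6, 1.1)
  expect_equal(wilcoxon_signed_rank(d)$n_effective, 7L)
  # an antisymmetric difference set sits deep in the null
  sym <- c(-(1:5), 1:5) + 0
  expect_gte(wilcoxon_signed_rank(sym)$p_value, 0.9)
  # ties fall back to the corrected normal approximation
  tied <- c(1, 1, 1, -1, 2, 2, -2, 3, 3, -3)
  expect_match(wilcoxon_signed_rank(tied)$method, "approximation")
  expect_false(wilcoxon_signed_rank(c(1, 2, -1))$reliable)
})

test_that("Bland-Altman limits reproduce the closed form", {
  ident <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$mean_diff, 0); expect_equal(ident$sd_diff, 0)
  expect_equal(c(ident$lower, ident$upper), c(0, 0))
  two <- bland_altman(c(1, 0), c(0, 1))          # differences {1, -1}
  expect_equal(two$mean_diff, 0)
  expect_equal(two$sd_diff, sqrt(2))
  expect_equal(two$upper, 1.96 * sqrt(2))
  set.seed(8)
  for (k in 1:20) {
    x <- rnorm(15); y <- rnorm(15)
    ba <- bland_altman(x, y)
    d <- x - y
    expect_equal(ba$mean_diff, mean(d), tolerance = 1e-12)
    expect_equal(ba$sd_diff, sd(d), tolerance = 1e-12)
    expect_equal(ba$lower, mean(d) - 1.96 * sd(d), tolerance = 1e-12)
    expect_equal(ba$upper, mean(d) + 1.96 * sd(d), tolerance = 1e-12)
    # translation equivariance
    ba2 <- bland_altman(x + 2.5, y)
    expect_equal(ba2$mean_diff, ba$mean_diff + 2.5, tolerance = 1e-12)
    expect_equal(ba2$sd_diff, ba$sd_diff, tolerance = 1e-12)
  }
  expect_error(bland_altman(1, 1), "at least 2")
})

# synthetic tidy feature tables for the report machinery
make_feature_table <- function(n_patients, features = feature_names(),
                               gain = 0, seed = 1) {
  set.seed(seed)
  rows <- expand.grid(patient = seq_len(n_patients),
                      system = c("RP", "CL15"),
                      timepoint = c("baseline", "week4"),
                      feature = features, stringsAsFactors = FALSE)
  base <- rnorm(nrow(rows) / 4)                  # per (patient, feature) truth
  key <- with(rows, paste(patient, feature, timepoint))
  truth <- rnorm(length(unique(key)))[match(key, unique(key))]
  rows$value <- truth + rnorm(nrow(rows), sd = 0.2) +
    ifelse(rows$system == "CL15", gain, 0)
  rows
}

test_that("feature differences subtract week 4 from baseline per key", {
  ft <- make_feature_table(4, features = c("MBF", "SS"))
  d <- feature_differences(ft)
  expect_true(all(d$timepoint == "difference"))
  one <- ft[ft$patient == 2 & ft$system == "RP" & ft$feature == "SS", ]
  dd <- d[d$patient == 2 & d$system == "RP" & d$feature == "SS", "value"]
  expect_equal(dd, one$value[one$timepoint == "week4"] -
                 one$value[one$timepoint == "baseline"])
  same <- ft; same$value <- 1
  expect_true(all(feature_differences(same)$value == 0))
})

test_that("agreement report has 25 x 3 structure with consistent flags", {
  ft <- make_feature_table(10)
  rep <- agreement_report(ft, systems = c("RP", "CL15"))
  expect_equal(nrow(rep), 75L)
  expect_equal(length(unique(rep$feature)), 25L)
  expect_setequal(unique(rep$set), c("baseline", "week4", "difference"))
  expect_equal(rep$significant, rep$p_value < 0.05)
  expect_true(all(rep$n_pairs == 10))
  expect_equal(rep$ba_lower, rep$ba_mean - 1.96 * rep$ba_sd, tolerance = 1e-12)
  expect_equal(rep$ba_upper, rep$ba_mean + 1.96 * rep$ba_sd, tolerance = 1e-12)
})

test_that("a flat cross-system gain breaks absolute agreement, not differences", {
  ft <- make_feature_table(14, gain = 3, seed = 5)
  rep <- agreement_report(ft, systems = c("RP", "CL15"))
  cnt <- attr(rep, "agreement_counts")
  expect_gt(cnt[["difference"]], cnt[["baseline"]])
  expect_true(all(!rep$significant[rep$set == "difference"] |
                    rep$p_value[rep$set == "difference"] < 0.05))
  base <- rep[rep$set == "baseline", ]
  expect_gt(mean(base$significant), 0.9)
  # Bland-Altman mean difference reflects the injected gain (RP - CL15 = -3)
  expect_lt(max(abs(base$ba_mean + 3)), 0.5)
})

test_that("per-feature testing keeps its nominal type-I error under the null", {
  set.seed(99)
  n_rep <- 400
  p <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    truth <- rnorm(15)
    a <- truth + rnorm(15, sd = 0.3)
    b <- truth + rnorm(15, sd = 0.3)
    p[r] <- wilcoxon_signed_rank(a, b)$p_value
  }
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 2.6 * sqrt(0.05 * 0.95 / n_rep) + 0.01)
})

test_that("cohort table summary reproduces the published demographics", {
  tab <- load_cohort_table()
  expect_equal(nrow(tab), 30L)
  s <- cohort_summary(tab)
  expect_equal(unname(s$age["median"]), 53)
  expect_equal(unname(s$age[c("min", "max")]), c(37, 82))
  expect_equal(unname(s$mass_size_cm[c("min", "max")]), c(1.3, 7.3))
  # single-row table degenerates to that row
  s1 <- cohort_summary(tab[7, ])
  expect_equal(unname(s1$age), rep(53, 3))
  # malformed rows are rejected with a message
  bad <- tab; bad$age[2] <- "unknown"
  expect_message(s2 <- cohort_summary(bad), "rejected")
  expect_equal(s2$n, 29)
})
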