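#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test on paired differences with the classic zero-handling:
#' zero differences are dropped, ties among the remaining absolute
#' differences are mid-ranked. The exact null distribution is used for up to
#' `exact_max` tie-free non-zero differences; otherwise the normal
#' approximation with continuity and tie correction. Fewer than 6 non-zero
#' differences makes the p-value unreliable (flagged, still returned); all
#' differences zero gives p = 1 with `n_effective = 0`.
#'
#' @param x,y paired measurements; or differences in `x` with `y = NULL`.
#' @param exact_max largest tie-free sample size for exact enumeration.
#' @return list: `p_value`, `statistic` (V, sum of positive ranks),
#'   `n_effective`, `method`, `reliable`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 25) {
  d <- if (is.null(y)) x else x - y
  d <- d[is.finite(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(p_value = 1, statistic = NA_real_, n_effective = 0L,
                method = "degenerate (all differences zero)",
                reliable = FALSE))
  ties <- any(duplicated(abs(d)))
  exact <- !ties && n <= exact_max
  wt <- suppressWarnings(stats::wilcox.test(d, exact = exact, correct = TRUE))
  list(p_value = unname(wt$p.value), statistic = unname(wt$statistic),
       n_effective = n,
       method = if (exact) "exact" else "normal approximation (continuity + tie correction)",
       reliable = n >= 6)
}

#' Bland-Altman agreement summary
#'
#' Mean difference, sample standard deviation (n-1 denominator) and limits
#' of agreement at mean +/- 1.96 SD for paired measurements.
#'
#' @param x,y paired measurements from the two methods (differences are
#'   `x - y`); >= 2 complete pairs required.
#' @return list: `mean_diff`, `sd_diff`, `lower`, `upper`, `n`, and
#'   `means` / `diffs` for plotting.
#' @export
bland_altman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) stop("Bland-Altman needs at least 2 complete pairs")
  d <- x - y
  m <- mean(d); s <- stats::sd(d)
  list(mean_diff = m, sd_diff = s,
       lower = m - 1.96 * s, upper = m + 1.96 * s,
       n = length(d), means = (x + y) / 2, diffs = d)
}

#' Week-4 minus baseline feature differences
#'
#' @param features tidy data.frame with columns `patient`, `system`,
#'   `timepoint` (`"baseline"` / `"week4"`), `feature`, `value`.
#' @return data.frame with the same shape and `timepoint = "difference"`;
#'   a missing member at either time point gives a missing difference.
#' @export
feature_differences <- function(features) {
  b <- features[features$timepoint == "baseline", ]
  w <- features[features$timepoint == "week4", ]
  if (nrow(b) == 0 || nrow(w) == 0)
    stop("both baseline and week4 rows are required")
  key <- function(d) paste(d$patient, d$system, d$feature, sep = "\r")
  m <- match(key(b), key(w))
  if (all(is.na(m))) stop("no overlapping (patient, system, feature) keys")
  out <- b
  out$value <- w$value[m] - b$value
  out$timepoint <- "difference"
  out
}

#' Cross-system agreement report
#'
#' For each of the 25 features and each feature set (baseline, week 4,
#' week4 - baseline differences): the paired cross-system Wilcoxon
#' signed-rank p-value with a 5%-level significance flag (flag = systems
#' significantly DISagree; no multiple-testing adjustment, matching the raw
#' per-feature reporting convention), and the Bland-Altman summary of the
#' cross-system differences (first system minus second). Patients missing a
#' member of a pair are excluded pairwise.
#'
#' @param features tidy data.frame (`patient`, `system`, `timepoint`,
#'   `feature`, `value`) containing both systems at both time points.
#' @param systems character(2): the two system labels, difference direction
#'   `systems[1] - systems[2]`.
#' @param alpha significance level for the disagreement flag.
#' @return data.frame of class `agreement_report`, one row per feature x
#'   set: `feature, set, n_pairs, p_value, significant, ba_mean, ba_sd,
#'   ba_lower, ba_upper`; per-set agreement counts in
#'   `attr(, "agreement_counts")`.
#' @export
agreement_report <- function(features, systems = NULL, alpha = 0.05) {
  stopifnot(all(c("patient", "system", "timepoint", "feature", "value")
                %in% names(features)))
  if (is.null(systems)) systems <- unique(features$system)
  if (length(systems) != 2) stop("exactly two systems are required")
  for (tp in c("baseline", "week4"))
    if (!any(features$timepoint == tp)) stop("missing time point: ", tp)
  all_sets <- rbind(features[features$timepoint %in% c("baseline", "week4"), ],
                    feature_differences(features))
  feats <- unique(features$feature)
  rows <- list()
  for (set in c("baseline", "week4", "difference")) {
    dset <- all_sets[all_sets$timepoint == set, ]
    for (fe in feats) {
      d1 <- dset[dset$feature == fe & dset$system == systems[1], ]
      d2 <- dset[dset$feature == fe & dset$system == systems[2], ]
      m <- match(d1$patient, d2$patient)
      v1 <- d1$value; v2 <- d2$value[m]
      ok <- is.finite(v1) & is.finite(v2)
      wt <- wilcoxon_signed_rank(v1[ok], v2[ok])
      ba <- if (sum(ok) >= 2) bland_altman(v1[ok], v2[ok]) else
        list(mean_diff = NA_real_, sd_diff = NA_real_,
             lower = NA_real_, upper = NA_real_)
      rows[[length(rows) + 1]] <- data.frame(
        feature = fe, set = set, n_pairs = sum(ok),
        p_value = wt$p_value, significant = wt$p_value < alpha,
        ba_mean = ba$mean_diff, ba_sd = ba$sd_diff,
        ba_lower = ba$lower, ba_upper = ba$upper)
    }
  }
  out <- do.call(rbind, rows)
  counts <- tapply(!out$significant, out$set, sum)
  attr(out, "agreement_counts") <- counts
  attr(out, "systems") <- systems
  attr(out, "alpha") <- alpha
  class(out) <- c("agreement_report", "data.frame")
  out
}

#' @export
print.agreement_report <- function(x, ...) {
  cnt <- attr(x, "agreement_counts")
  nf <- length(unique(x$feature))
  cat(sprintf("<agreement_report> %d features x 3 sets (systems %s - %s)\n",
              nf, attr(x, "systems")[1], attr(x, "systems")[2]))
  for (s in names(cnt))
    cat(sprintf("  %-10s %d / %d features in agreement (p >= %g)\n",
                s, cnt[[s]], nf, attr(x, "alpha")))
  invisible(x)
}

#' Load the shipped patient characteristics table
#'
#' The 30-patient cohort table (age, mass size, laterality, grade,
#' histology, ER/PR/HER2 receptor status) shipped as a CSV fixture.
#' @return data.frame with 30 rows.
#' @export
load_cohort_table <- function() {
  path <- system.file("extdata", "cohort_table2.csv", package = "qusagree",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Cohort summary statistics
#'
#' Median/min/max of age and mass size (even-n median = mean of the two
#' central order statistics) and counts by grade, side and receptor status.
#' Rows with non-numeric age or size are rejected with a message.
#'
#' @param table a cohort data.frame with columns `age`, `mass_size_cm`,
#'   `side`, `grade`, `er`, `pr`, `her2`.
#' @return list of summaries.
#' @export
cohort_summary <- function(table) {
  stopifnot(nrow(table) >= 1)
  age <- suppressWarnings(as.numeric(table$age))
  size <- suppressWarnings(as.numeric(table$mass_size_cm))
  bad <- !is.finite(age) | !is.finite(size) | age <= 0 | size <= 0
  if (any(bad)) {
    message(sum(bad), " row(s) rejected: non-numeric or non-positive age/size")
    table <- table[!bad, ]; age <- age[!bad]; size <- size[!bad]
  }
  list(n = nrow(table),
       age = c(median = stats::median(age), min = min(age), max = max(age)),
       mass_size_cm = c(median = stats::median(size), min = min(size),
                        max = max(size)),
       by_grade = table(table$grade),
       by_side = table(table$side),
       receptors = list(er = table(table$er), pr = table(table$pr),
                        her2 = table(table$her2)))
}
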