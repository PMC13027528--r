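#!/usr/bin/env Rscript
# Cross-system agreement analysis of the three feature sets.
#
# Builds baseline, week-4 and difference (week4 - baseline) feature sets,
# runs the paired cross-system Wilcoxon signed-rank test per feature at the
# 5% level (raw p-values, no multiplicity adjustment) and the Bland-Altman
# summary (mean difference +- 1.96 SD limits), and summarizes the shipped
# patient-characteristics table.
#
# Input: results/features.csv. Outputs: results/agreement_report.csv,
# results/cohort_summary.txt.

suppressPackageStartupMessages(library(qusagree))
features <- read.csv("results/features.csv")

report <- agreement_report(features, systems = c("RP", "CL15"))
print(report)
write.csv(report, "results/agreement_report.csv", row.names = FALSE)

cnt <- attr(report, "agreement_counts")
primary <- c("MBF", "SS", "SI", "ASD", "AAC")
for (set in c("baseline", "week4", "difference")) {
  sub <- report[report$set == set, ]
  message(sprintf(
    "%-10s: %2d/25 features agree (p >= 0.05); primary %d/5; texture %d/20",
    set, cnt[[set]], sum(!sub$significant[sub$feature %in% primary]),
    sum(!sub$significant[!sub$feature %in% primary])))
}

tab <- load_cohort_table()
s <- cohort_summary(tab)
lines <- c(
  sprintf("n = %d patients", s$n),
  sprintf("age: median %g, range %g-%g years", s$age["median"], s$age["min"], s$age["max"]),
  sprintf("mass size: median %g, range %g-%g cm", s$mass_size_cm["median"],
          s$mass_size_cm["min"], s$mass_size_cm["max"]),
  paste("grade counts:", paste(names(s$by_grade), s$by_grade, sep = ":", collapse = " ")))
writeLines(lines, "results/cohort_summary.txt")
message(paste(lines, collapse = "\n"))
message("wrote results/agreement_report.csv, results/cohort_summary.txt")
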