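#!/usr/bin/env Rscript
# Step 3: narrative summary of the study outputs.
#
# Reads the suppressed tables written by 02_run_study.R and reports what the
# synthetic study found: category ranking, the most frequent comorbidities,
# and whether the two samples are homogeneous. Writes results/summary.txt.

suppressPackageStartupMessages(library(data.table))

est <- fread("results/study/estimates.csv")
com <- fread("results/study/comorbidities.csv")
het <- fread("results/study/heterogeneity.csv")

lines <- character()
say <- function(...) {
  msg <- sprintf(...)
  cat(msg, "\n")
  lines <<- c(lines, msg)
}

prev18 <- est[measure == "prevalence" & stratum == "all" & year == 2018 &
                !group %in% c("overall", "polyJIA")]
prev18[, rate_num := suppressWarnings(as.numeric(rate))]
ranking <- prev18[order(-rate_num), .(sample, group, rate_num)]
top <- ranking[, .SD[1], by = sample]
say("Most prevalent ILAR category in 2018, per sample:")
for (r in seq_len(nrow(top))) {
  say("  %s: %s (%.1f per 100,000 standardized)",
      top$sample[r], top$group[r], top$rate_num[r])
}

say("Top comorbidities among prevalent JIA cases in 2018:")
comj <- com[population == "JIA"]
comj[, rate_num := suppressWarnings(as.numeric(rate_pct))]
topc <- comj[order(-rate_num)][!is.na(rate_num)][, head(.SD, 3), by = sample]
for (r in seq_len(nrow(topc))) {
  say("  %s: %s (%.1f%%)", topc$sample[r], topc$name[r], topc$rate_num[r])
}
n_supp <- sum(com$n == "<5")
say("%d comorbidity cells suppressed under the n >= 5 rule.", n_supp)

say("Two-sample homogeneity (both samples share one generating process):")
for (r in seq_len(nrow(het))) {
  say("  %s %d: chi2 = %.2f, p = %.3f, Cohen's h = %.4f",
      het$measure[r], het$year[r], het$chi2[r], het$p[r], het$effect_size[r])
}

writeLines(lines, "results/summary.txt")
cat("wrote results/summary.txt\n")
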