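#!/usr/bin/env Rscript
# Step 4: report.
#
# Renders the summary table (condition means, differences, failure counts),
# compares the synthetic cohort's decisions with the published verdicts, and
# draws the forest-style noninferiority figure.

library(obstaclegait)

decisions <- read.csv("results/decisions.csv")
cs <- read.csv("results/condition_stats.csv")
stats_tb <- read.csv("results/difference_stats.csv")
failures <- read.csv("results/failures.csv")

res_like <- structure(list(condition_stats = cs, stats = stats_tb,
                           failures = failures), class = "pipeline_result")
lines <- render_summary_table(res_like)
writeLines(lines, "results/summary_table.txt")
message(paste(lines, collapse = "\n"))

ref <- reference_decisions()
cmp <- merge(decisions, ref, by = c("task", "parameter"),
             suffixes = c("_synthetic", "_published"))
write.csv(cmp[, c("task", "parameter", "decision_synthetic",
                  "decision_published")],
          "results/decision_comparison.csv", row.names = FALSE)
message(sprintf("%d of %d primary verdicts match the published study",
                sum(cmp$decision_synthetic == cmp$decision_published),
                nrow(cmp)))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  decisions$label <- paste(decisions$task, decisions$parameter, sep = "\n")
  p <- ggplot(decisions, aes(y = label)) +
    geom_vline(xintercept = 0, linetype = 2, colour = "grey40") +
    geom_segment(aes(x = ci_low, xend = ci_high, yend = label,
                     colour = decision), linewidth = 1.2) +
    geom_point(aes(x = mean_diff, colour = decision), size = 2.5) +
    geom_point(aes(x = margin), shape = 124, size = 6, colour = "red") +
    labs(x = "VR - physical difference (cm), 95% CI; red bar = margin",
         y = NULL, colour = "decision") +
    theme_minimal(base_size = 11)
  ggsave("results/noninferiority_forest.pdf", p, width = 7, height = 4.5)
  message("wrote results/noninferiority_forest.pdf")
}
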