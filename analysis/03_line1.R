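#!/usr/bin/env Rscript
# LINE-1 global methylation: three-CpG averages per fraction, baseline vs
# post paired comparisons, per-patient relative changes, and the HCY
# correlation per response group.

library(faresponse)

cohort <- read.delim("results/data/cohort.tsv")
line1 <- read.delim("results/data/line1.tsv")
labels <- read.delim("results/stratification/labels.tsv")
dir.create("results/line1", recursive = TRUE, showWarnings = FALSE)

res <- line1_change_analysis(line1, labels, hcy = cohort)
write.table(res$table, "results/line1/table.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(res$relative_change, "results/line1/relative_change.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(res$hcy_correlation, "results/line1/hcy_correlation.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

rc <- res$relative_change
for (fr in unique(rc$fraction)) {
  row <- rc[rc$fraction == fr & rc$group == "all", ]
  p <- res$table$p_value[res$table$fraction == fr & res$table$measure == "average" &
                           res$table$group == "all"]
  cat(sprintf("%-12s mean relative change %+.2f%% (paired p = %.3g)\n",
              fr, row$mean_relative_change_percent, p))
}
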