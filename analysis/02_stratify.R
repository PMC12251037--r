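#!/usr/bin/env Rscript
# Stratify patients into folic-acid responders / non-responders by the sign
# of their homocysteine change and run the normality-gated paired tests on
# HCY, folate and cfDNA, overall and per group.

library(faresponse)

cohort <- read.delim("results/data/cohort.tsv")
dir.create("results/stratification", recursive = TRUE, showWarnings = FALSE)

s <- stratify_cohort(cohort)
write.table(s$labels, "results/stratification/labels.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(s$group_summary, "results/stratification/group_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("%d responders / %d non-responders\n",
            sum(s$labels$label == "responder"),
            sum(s$labels$label == "non_responder")))
for (k in c("hcy.responder", "hcy.non_responder", "cfdna.all", "folate.all")) {
  cat(k, ": ")
  print(s$tests[[k]])
}
cat(sprintf("Mean cfDNA relative change: %.1f%%\n",
            s$group_summary$mean[s$group_summary$measurement == "cfdna" &
                                   s$group_summary$group == "all" &
                                   s$group_summary$timepoint == "relative_change_percent"]))
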