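#!/usr/bin/env Rscript
# Mutation burden vs biological-age change: per-gene Spearman correlation and
# univariate linear fit of the age delta on the mutation count, per response
# group (unadjusted p by convention; a BH column is carried alongside).

library(faresponse)

labels <- read.delim("results/stratification/labels.tsv")
deltas <- read.delim("results/clock/age_deltas.tsv")
variants <- read_variants("results/data/variants.maf.tsv")
panel <- default_panel()
dir.create("results/association", recursive = TRUE, showWarnings = FALSE)

burden <- burden_matrix(restrict_to_panel(variants, panel),
                        patients = labels$patient_id,
                        panel_genes = unique(panel$gene))

for (g in c("non_responder", "responder")) {
  res <- associate(burden, deltas, labels, group = g)
  write.table(res, sprintf("results/association/%s.tsv", g),
              sep = "\t", quote = FALSE, row.names = FALSE)
  top <- res[!res$skipped_constant, ][1, ]
  cat(sprintf("%-14s best gene %s: rho = %.3f, p = %.3f, delta = %.3f %+.3f * count\n",
              g, top$gene, top$spearman_r, top$p_value, top$intercept, top$slope))
}
cct3 <- read.delim("results/association/non_responder.tsv")
cct3 <- cct3[cct3$gene == "CCT3", ]
cat(sprintf("CCT3 (non-responders): rho = %.3f, p = %.3f, line y = %.3f %+.3f x\n",
            cct3$spearman_r, cct3$p_value, cct3$intercept, cct3$slope))
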