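#!/usr/bin/env Rscript
# Variant hotspots: restrict the MAF to the one-carbon gene panel, split by
# ClinVar-style annotation, compute per-group carrier frequencies, apply the
# dual-threshold hotspot rule, and export the pathway-gene-mutation graph.

library(faresponse)

labels <- read.delim("results/stratification/labels.tsv")
dir.create("results/variants", recursive = TRUE, showWarnings = FALSE)

variants <- read_variants("results/data/variants.maf.tsv")
db <- read.delim("results/data/annotation.tsv")
panel <- default_panel()

pv <- restrict_to_panel(variants, panel)
cat(sprintf("%d of %d variant records fall on the %d-gene panel\n",
            nrow(pv), nrow(variants), length(unique(panel$gene))))

split <- classify_by_annotation(pv, db)
cat(sprintf("%d classified / %d unclassified records\n",
            nrow(split$classified), nrow(split$unclassified)))
write.table(split$classified, "results/variants/classified.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(split$unclassified, "results/variants/unclassified.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

freqs <- carrier_frequency(pv, labels)
hot <- call_hotspots(freqs)
write.table(hot, "results/variants/hotspots.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Highlighted hotspots (>=70% of non-responders, <50% of responders):\n")
hi <- hot[hot$is_highlighted, ]
for (i in seq_len(nrow(hi))) {
  cat(sprintf("  %-7s %-20s %6.2f%% vs %5.2f%%\n", hi$gene[i], hi$hgvs_label[i],
              hi$freq_nonresponder[i], hi$freq_responder[i]))
}

for (g in c("responder", "non_responder")) {
  ids <- labels$patient_id[labels$label == g]
  s <- summarize_mutations(pv[pv$patient_id %in% ids, ])
  onc <- s$oncomatrix
  write.table(data.frame(gene = rownames(onc), onc, check.names = FALSE),
              sprintf("results/variants/oncomatrix_%s.tsv", g),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("Top mutated genes (%s): %s\n", g,
              paste(head(s$top_genes, 5), collapse = ", ")))
}

graph <- build_pathway_graph(hot, default_pathway_map())
write_pathway_graph(graph, "results/variants/pathway_graph.graphml",
                    "results/variants/pathway_graph.dot")
cat(sprintf("Pathway graph: %d vertices, %d edges (%d highlighted)\n",
            igraph::vcount(graph), igraph::ecount(graph),
            sum(igraph::E(graph)$highlighted)))
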