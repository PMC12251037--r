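write_fixture_maf <- function(path, rows) {
  header <- c("Hugo_Symbol", "Chromosome", "Start_Position", "End_Position",
              "Reference_Allele", "Tumor_Seq_Allele2", "Variant_Classification",
              "Variant_Type", "Tumor_Sample_Barcode")
  writeLines(c(paste(header, collapse = "\t"),
               vapply(rows, paste, character(1), collapse = "\t")), path)
  path
}

test_that("read_variants normalizes a small MAF fixture", {
  path <- withr::local_tempfile(fileext = ".maf")
  write_fixture_maf(path, list(
    c("MTRR", "chr5", "101", "101", "C", "T", "Missense_Mutation", "SNP", "P001"),
    c("CHAT", "chr10", "500", "501", "CA", "C", "Frame_Shift_Del", "DEL", "P002"),
    c("TYMS", "chr18", "70", "70", "A", "G", "Weird_Class", "SNP", "P003")))
  expect_warning(v <- read_variants(path), "other")
  expect_equal(nrow(v), 3)
  expect_equal(v$variant_key[1], "chr5:101:C:T")
  expect_equal(v$snv_class[1], "C>T")
  expect_equal(v$variant_type[2], "DEL")
  expect_true(is.na(v$snv_class[2]))
  expect_equal(v$snv_class[3], "T>C")  # purine ref complemented
  expect_equal(v$variant_classification[3], "other")
})

test_that("read_variants names a missing mandatory column", {
  path <- withr::local_tempfile(fileext = ".maf")
  writeLines(c("Hugo_Symbol\tChromosome", "MTRR\tchr5"), path)
  expect_error(read_variants(path), "Start_Position")
})

test_that("panel restriction reconciles BED half-open with MAF 1-based", {
  regions <- data.frame(chrom = "chr1", start0 = 100L, end0 = 101L, gene = "G1")
  v <- data.frame(patient_id = "P1", gene = "G1", chrom = "chr1",
                  pos = c(101L, 100L, 102L), variant_key = c("a", "b", "c"),
                  stringsAsFactors = FALSE)
  kept <- restrict_to_panel(v, regions)
  expect_equal(kept$variant_key, "a")
  expect_error(restrict_to_panel(v, regions[0, ]), "non-empty")
})

test_that("planted variants survive panel restriction and off-panel ones are dropped", {
  co <- generate_cohort(small_sim(seed = 4))
  panel <- default_panel()
  off <- co$variants[1, ]
  off$chrom <- "chrOff"
  off$pos <- 5L
  off$variant_key <- "chrOff:5:A:G"
  kept <- restrict_to_panel(rbind(co$variants, off), panel)
  expect_equal(nrow(kept), nrow(co$variants))
  expect_false("chrOff:5:A:G" %in% kept$variant_key)
})

test_that("annotation split is an exact partition keyed on non-empty significance", {
  v <- data.frame(patient_id = c("P1", "P2", "P3"),
                  gene = "MTRR",
                  variant_key = c("k1", "k2", "k3"),
                  stringsAsFactors = FALSE)
  db <- data.frame(variant_key = c("k1", "k2", NA),
                   clinical_significance = c("Uncertain significance", "", "Benign"),
                   stringsAsFactors = FALSE)
  expect_warning(split <- classify_by_annotation(v, db), "malformed")
  expect_equal(split$classified$variant_key, "k1")
  expect_setequal(split$unclassified$variant_key, c("k2", "k3"))
  expect_equal(nrow(split$classified) + nrow(split$unclassified), nrow(v))
  empty <- classify_by_annotation(v, db[0, ])
  expect_equal(nrow(empty$classified), 0)
})

test_that("carrier frequencies match the printed worked ratios", {
  labels <- data.frame(
    patient_id = c(sprintf("R%02d", 1:21), sprintf("N%02d", 1:22)),
    label = c(rep("responder", 21), rep("non_responder", 22)),
    stringsAsFactors = FALSE)
  v <- data.frame(
    patient_id = c(sprintf("N%02d", 1:21), "R01"),
    gene = "HIF3A", variant_key = "chr19:100:A:G", hgvs_label = "n.*1977A > G",
    stringsAsFactors = FALSE)
  fr <- carrier_frequency(v, labels)
  expect_equal(fr$freq_nonresponder, 95.45)
  expect_equal(fr$freq_responder, 4.76)
  expect_equal(fr$carriers_nonresponder, 21)
  # multiplicity and zygosity do not double-count a patient
  fr2 <- carrier_frequency(rbind(v, v[1, ]), labels)
  expect_equal(fr2$carriers_nonresponder, 21)
  v$patient_id[1] <- "UNKNOWN"
  expect_error(carrier_frequency(v, labels), "unlabeled")
})

test_that("hotspot thresholds are inclusive in, strict out, and monotone", {
  freqs <- data.frame(variant_key = letters[1:4], gene = "G",
                      freq_responder = c(4.76, 49.99, 50, 0),
                      freq_nonresponder = c(95.45, 70, 70, 49.9))
  hot <- call_hotspots(freqs)
  expect_equal(hot$is_highlighted, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(hot$is_graph_node, c(TRUE, TRUE, TRUE, FALSE))
  # raising the node threshold never adds nodes
  for (thr in c(0, 25, 50, 75, 100)) {
    lo <- call_hotspots(freqs, node_threshold = thr)
    hi <- call_hotspots(freqs, node_threshold = thr + 10)
    expect_true(all(!hi$is_graph_node | lo$is_graph_node))
  }
})

test_that("mutation summaries count classes and flag Multi_Hit", {
  v <- data.frame(
    patient_id = c("P1", "P1", "P2", "P2"),
    gene = c("MTRR", "MTRR", "CHAT", "TYMS"),
    variant_key = c("k1", "k2", "k3", "k4"),
    variant_classification = c("missense", "missense", "silent", "nonsense"),
    variant_type = c("SNP", "SNP", "SNP", "SNP"),
    snv_class = c("C>T", "T>C", "C>G", "C>T"),
    stringsAsFactors = FALSE)
  s <- summarize_mutations(v)
  expect_equal(unname(s$classification_counts["missense"]), 2L)
  expect_equal(sum(s$classification_counts), nrow(v))
  expect_equal(s$oncomatrix["MTRR", "P1"], "Multi_Hit")
  expect_equal(s$oncomatrix["CHAT", "P2"], "silent")
  expect_equal(s$oncomatrix["CHAT", "P1"], "")
  expect_true(naive_multi_hit(v, "MTRR", "P1"))
  expect_false(naive_multi_hit(v, "CHAT", "P2"))
  # deterministic tie-break: equal counts ordered by gene symbol
  expect_equal(s$top_genes, c("MTRR", "CHAT", "TYMS"))
  one <- summarize_mutations(v[3, ])
  expect_equal(unname(one$classification_counts["silent"]), 1L)
  expect_equal(sum(one$classification_counts), 1L)
})

test_that("pathway graph has one mutation node per graph hotspot and flagged edges", {
  hot <- data.frame(
    variant_key = c("k1", "k2", "k3"),
    gene = c("HIF3A", "TYMS", "NOVEL"),
    hgvs_label = c("n.*1977A > G", "c.*89A > G", "c.1A > T"),
    freq_responder = c(4.76, 42.86, 10),
    freq_nonresponder = c(95.45, 81.82, 60),
    is_graph_node = c(TRUE, TRUE, TRUE),
    is_highlighted = c(TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  pmap <- default_pathway_map()
  expect_warning(g <- build_pathway_graph(hot, pmap), "unassigned")
  vt <- igraph::V(g)$type
  expect_equal(sum(vt == "mutation"), 3)
  # TYMS sits in two pathways: two edges from one mutation node
  tyms_node <- which(igraph::V(g)$gene == "TYMS")
  expect_equal(unname(igraph::degree(g, tyms_node)), 2)
  expect_equal(sum(igraph::E(g)$highlighted),
               2 + 1)  # HIF3A (1 pathway) + TYMS (2 pathways), all highlighted
  # no hotspot above threshold: only central nodes remain
  none <- hot[0, ]
  expect_warning(g0 <- build_pathway_graph(none, pmap), "only central")
  expect_true(all(igraph::V(g0)$type == "pathway"))
  expect_equal(igraph::ecount(g0), 0)
  # exports are parseable
  gm <- withr::local_tempfile(fileext = ".graphml")
  dot <- withr::local_tempfile(fileext = ".dot")
  suppressWarnings(write_pathway_graph(g, gm, dot))
  g2 <- igraph::read_graph(gm, format = "graphml")
  expect_equal(igraph::vcount(g2), igraph::vcount(g))
  expect_true(file.size(dot) > 0)
})

test_that("MAF writing round-trips the generator's records", {
  co <- generate_cohort(small_sim(seed = 6))
  path <- withr::local_tempfile(fileext = ".maf")
  write_variants_maf(co$variants, path)
  v <- read_variants(path)
  expect_equal(nrow(v), nrow(co$variants))
  expect_equal(v$variant_key, co$variants$variant_key)
  expect_equal(v$variant_classification, co$variants$variant_classification)
  expect_equal(v$hgvs_label, co$variants$hgvs_label)
})
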