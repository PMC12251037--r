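# Naive reference implementations used as independent oracles: straight
# double loops over patients and variants, no vectorization, no sharing of
# code with the package internals.

naive_carrier_counts <- function(variants, labels, key) {
  carriers_r <- 0L
  carriers_n <- 0L
  for (p in unique(labels$patient_id)) {
    lab <- labels$label[labels$patient_id == p][1]
    carries <- FALSE
    for (i in seq_len(nrow(variants))) {
      if (variants$patient_id[i] == p && variants$variant_key[i] == key) {
        carries <- TRUE
      }
    }
    if (carries && !is.na(lab) && lab == "responder") carriers_r <- carriers_r + 1L
    if (carries && !is.na(lab) && lab == "non_responder") carriers_n <- carriers_n + 1L
  }
  c(responder = carriers_r, non_responder = carriers_n)
}

naive_classified_split <- function(variants, db) {
  good_keys <- character(0)
  for (i in seq_len(nrow(db))) {
    k <- db$variant_key[i]
    s <- db$clinical_significance[i]
    if (!is.na(k) && k != "" && !is.na(s) && s != "") good_keys <- c(good_keys, k)
  }
  flags <- logical(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    flags[i] <- variants$variant_key[i] %in% good_keys
  }
  flags
}

naive_multi_hit <- function(variants, gene, patient) {
  hits <- 0L
  for (i in seq_len(nrow(variants))) {
    if (variants$gene[i] == gene && variants$patient_id[i] == patient) hits <- hits + 1L
  }
  hits >= 2L
}

# Deterministic family of tiny cohorts (2-5 patients, 1-10 variants) used for
# oracle-equivalence checks.
make_tiny_cohort <- function(n_patients, n_variants, seed) {
  set.seed(seed)
  ids <- sprintf("T%02d", seq_len(n_patients))
  labels <- data.frame(
    patient_id = ids,
    label = sample(c("responder", "non_responder"), n_patients, replace = TRUE),
    stringsAsFactors = FALSE)
  # force both groups non-empty
  labels$label[1] <- "responder"
  labels$label[n_patients] <- "non_responder"
  keys <- sprintf("chr1:%d:A:G", 100 + seq_len(max(1, n_variants %/% 2)))
  variants <- data.frame(
    patient_id = sample(ids, n_variants, replace = TRUE),
    gene = sample(c("MTRR", "CHAT", "HIF3A"), n_variants, replace = TRUE),
    variant_key = sample(keys, n_variants, replace = TRUE),
    hgvs_label = NA_character_,
    variant_classification = sample(c("missense", "silent", "nonsense"),
                                    n_variants, replace = TRUE),
    variant_type = "SNP",
    snv_class = "C>T",
    zygosity = "het",
    stringsAsFactors = FALSE)
  db <- data.frame(
    variant_key = sample(keys, max(1, length(keys) %/% 2)),
    clinical_significance = "Uncertain significance",
    stringsAsFactors = FALSE)
  list(labels = labels, variants = variants, db = db)
}

# Small, fast simulation settings shared by tests that exercise the whole
# generator without needing the full-size clock.
small_sim <- function(seed, ...) {
  sim_config(seed = seed, clock_cpg_count = 40L, clock_signal_count = 30L,
             clock_extra_cpgs = 5L, background_rate = 4, ...)
}
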