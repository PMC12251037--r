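test_that("sim_config validates counts, SDs and carrier bounds", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(hcy_baseline_sd = -1))
  pv <- default_planted_variants()
  pv$carriers_nonresponder[1] <- 23L
  expect_error(sim_config(planted_variants = pv), "configuration error")
})

test_that("a fixed seed reproduces the dataset byte-identically on disk", {
  cfg <- small_sim(seed = 7)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(generate_cohort(cfg), d1)
  write_cohort(generate_cohort(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # a different seed changes the data
  d3 <- withr::local_tempdir()
  write_cohort(generate_cohort(small_sim(seed = 8)), d3)
  expect_false(identical(readLines(file.path(d1, "cohort.tsv")),
                         readLines(file.path(d3, "cohort.tsv"))))
})

test_that("planted group structure and carrier counts are exact", {
  co <- generate_cohort(small_sim(seed = 11))
  expect_equal(nrow(co$patients), 43)
  expect_equal(sum(co$patients$group_truth == "responder"), 21)
  expect_equal(sum(co$patients$group_truth == "non_responder"), 22)
  r <- co$patients$group_truth == "responder"
  expect_true(all(co$patients$hcy_after[r] < co$patients$hcy_before[r]))
  expect_true(all(co$patients$hcy_after[!r] >= co$patients$hcy_before[!r]))

  labels <- data.frame(patient_id = co$patients$patient_id,
                       label = co$patients$group_truth)
  pv <- default_planted_variants()
  for (k in seq_len(nrow(pv))) {
    keep <- co$variants$hgvs_label == pv$hgvs_label[k] &
      co$variants$gene == pv$gene[k]
    key <- unique(co$variants$variant_key[keep])
    expect_length(key, 1)
    fr <- carrier_frequency(co$variants, labels, variant_key = key)
    expect_equal(fr$carriers_responder, pv$carriers_responder[k])
    expect_equal(fr$carriers_nonresponder, pv$carriers_nonresponder[k])
  }
})

test_that("cohort invariants hold: patients cover variants, betas in range, paired timepoints", {
  co <- generate_cohort(small_sim(seed = 12))
  expect_true(all(co$variants$patient_id %in% co$patients$patient_id))
  expect_true(all(co$beta_before >= 0 & co$beta_before <= 1))
  expect_true(all(co$beta_after >= 0 & co$beta_after <= 1))
  expect_identical(colnames(co$beta_before), co$patients$patient_id)
  expect_identical(colnames(co$beta_after), co$patients$patient_id)
  tp <- table(co$line1$patient_id, co$line1$fraction, co$line1$timepoint)
  expect_true(all(tp == 1))
  expect_true(all(co$line1[, c("cpg1", "cpg2", "cpg3")] >= 0 &
                    co$line1[, c("cpg1", "cpg2", "cpg3")] <= 100))
  expect_equal(co$line1$average,
               (co$line1$cpg1 + co$line1$cpg2 + co$line1$cpg3) / 3,
               tolerance = 1e-9)
  # annotation db covers the planted keys
  pv_keys <- co$variants$variant_key[!is.na(co$variants$hgvs_label) &
                                       co$variants$hgvs_label %in%
                                       default_planted_variants()$hgvs_label]
  expect_true(all(pv_keys %in% co$annotation_db$variant_key))
})

test_that("generated biomarker means converge to the configured means at large n", {
  cfg <- sim_config(n_responders = 500L, n_nonresponders = 500L,
                    planted_variants = NULL, background_rate = 0,
                    cct3_count_mean = 0, cct3_responder_rate = 0,
                    clock_cpg_count = 4L, clock_signal_count = 2L,
                    clock_extra_cpgs = 1L, seed = 13)
  co <- generate_cohort(cfg)
  n <- nrow(co$patients)
  expect_lt(abs(mean(co$patients$hcy_before) - 16.3), 4 * 4.8 / sqrt(n))
  expect_lt(abs(mean(co$patients$cfdna_before) - 9.0), 4 * 4.8 / sqrt(n))
  expect_lt(abs(mean(co$patients$cfdna_after) - 8.1), 4 * 4.9 / sqrt(n))
  expect_lt(abs(mean(relative_change(co$patients$cfdna_before,
                                     co$patients$cfdna_after)) - (-3.3)),
            4 * 20 / sqrt(n))
  # planted cfDNA-HCY correlation has the configured sign and rough size
  expect_gt(cor(co$patients$hcy_before, co$patients$cfdna_before), 0.1)
})

test_that("beta generation is affine in transformed age with planted noise", {
  cfg <- small_sim(seed = 14, noise_sd = 0)
  tm <- make_true_clock_model(cfg)
  ages <- c(20, 41, 62)
  beta <- generate_beta_matrix(ages, tm, 0, seed = 3)
  sig <- names(tm$slopes)[tm$slopes != 0][1]
  expect_equal(beta[sig, 2] - beta[sig, 1],
               tm$slopes[[sig]] * (age_transform(41) - age_transform(20)),
               tolerance = 1e-12)
  # non-whitelist rows carry no age signal: identical ages, different draws
  extra <- setdiff(tm$cpg_ids, tm$whitelist)
  b2 <- generate_beta_matrix(c(30, 30), tm, 0, seed = 3)
  expect_false(isTRUE(all.equal(b2[extra, 1], b2[extra, 2])))
})

test_that("non-responder age deltas follow the planted CCT3 model", {
  co <- generate_cohort(small_sim(seed = 15))
  labels <- data.frame(patient_id = co$patients$patient_id,
                       label = co$patients$group_truth)
  burden <- burden_matrix(co$variants, patients = co$patients$patient_id,
                          panel_genes = unique(default_panel()$gene))
  cct3 <- burden[burden$gene == "CCT3", ]
  nr <- co$truth[co$truth$group_truth == "non_responder", ]
  counts <- cct3$mutation_count[match(nr$patient_id, cct3$patient_id)]
  resid <- nr$true_delta - (-9.214 + 0.394 * counts)
  # residuals have the configured scale and no leftover count dependence
  expect_lt(abs(mean(resid)), 4 * 5.48 / sqrt(nrow(nr)))
  expect_gt(cor(counts, nr$true_delta, method = "spearman"), 0)
})
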