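#' Default planted variants
#'
#' The planted variant set carried by the default simulation: the four
#' non-responder hotspot mutations (HIF3A, TYMS, DNMT3A, PRMT3), the two
#' common MTHFR polymorphisms (C677T, A1298C) at near-equal frequencies in
#' both groups, and one MTRR variant that passes the graph-node rule in both
#' groups (so it draws an edge but is never highlighted). Carrier counts are
#' exact per group; positions are offsets into the synthetic panel regions.
#'
#' @return Data frame with columns `gene`, `hgvs_label`, `offset` (1-based
#'   offset into the gene's panel region), `ref`, `alt`, `classification`,
#'   `carriers_responder`, `carriers_nonresponder`, `clinical_significance`.
#' @export
default_planted_variants <- function() {
  data.frame(
    gene = c("HIF3A", "TYMS", "DNMT3A", "PRMT3", "MTHFR", "MTHFR", "MTRR"),
    hgvs_label = c("n.*1977A > G", "c.*89A > G", "c.178072C > T",
                   "c.993 + 10967G > A", "c.665C > T", "c.1286A > C",
                   "c.66A > G"),
    offset = c(1977L, 1089L, 2072L, 3967L, 665L, 1286L, 66L),
    ref = c("A", "A", "C", "G", "C", "A", "A"),
    alt = c("G", "G", "T", "A", "T", "C", "G"),
    classification = c("missense", "missense", "missense", "missense",
                       "missense", "missense", "missense"),
    carriers_responder = c(1L, 9L, 8L, 7L, 14L, 8L, 12L),
    carriers_nonresponder = c(21L, 18L, 18L, 16L, 14L, 9L, 13L),
    clinical_significance = c("Uncertain significance", "Likely pathogenic",
                              "Uncertain significance", "Uncertain significance",
                              "Pathogenic", "Likely pathogenic",
                              "Uncertain significance"),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Builds a validated configuration for [generate_cohort()]. The defaults are
#' the study conditions of the cohort the pipeline models: 21 responders and
#' 22 non-responders; homocysteine 16.3 +/- 4.8 umol/L at baseline, falling
#' to 11 +/- 2.9 in responders and rising to 19.6 +/- 3.7 in non-responders;
#' folate 46.3 +/- 40 to 81.4 +/- 29.4 nmol/L; cfDNA 9.0 +/- 4.8 to
#' 8.1 +/- 4.9 ng/mL with a mean per-patient relative change of -3.3% and a
#' +0.2375 correlation with homocysteine; LINE-1 shifts of +1.5 / +0.2 /
#' +1.45 percentage points for the cfDNA / granulocyte / mononuclear
#' fractions (a +1.9% relative change on the cfDNA and mononuclear
#' baselines); responder biological-age deltas of -0.5 +/- 8 years and
#' non-responder deltas generated through the CCT3 burden model
#' `delta = -9.214 + 0.394 * count + noise` (mean -5.3 years, about 80%
#' decreasing); and the planted variant set of [default_planted_variants()].
#'
#' @param n_responders,n_nonresponders Group sizes.
#' @param hcy_baseline_mean,hcy_baseline_sd Baseline HCY (umol/L).
#' @param responder_hcy_after_mean,responder_hcy_after_sd Post-supplementation
#'   HCY in responders (umol/L).
#' @param nonresponder_hcy_after_mean,nonresponder_hcy_after_sd Same for
#'   non-responders.
#' @param hcy_pair_cor Within-patient correlation of the baseline and
#'   post-supplementation HCY draws (default 0.5); a correlated pair keeps
#'   the sign-of-change rejection step from distorting the marginal means.
#' @param folate_before_mean,folate_before_sd,folate_after_mean,folate_after_sd
#'   Serum folate (nmol/L).
#' @param cfdna_before_mean,cfdna_before_sd,cfdna_after_mean,cfdna_after_sd
#'   Plasma cfDNA (ng/mL).
#' @param cfdna_relchange_mean,cfdna_relchange_sd Mean and SD of the
#'   per-patient cfDNA relative change, as fractions (default -0.033, 0.2).
#' @param cfdna_hcy_cor Correlation planted between baseline cfDNA and HCY.
#' @param line1_effect Named vector of percentage points added to every CpG
#'   after supplementation, per fraction.
#' @param line1_baseline 3 x 3 matrix of baseline CpG means (fractions x
#'   CpG positions), percentages.
#' @param line1_patient_sd,line1_cpg_sd,line1_within_sd Variance components
#'   of the LINE-1 model: patient-level intercept, per-CpG baseline noise,
#'   and within-patient post-timepoint noise (percentage points).
#' @param line1_hcy_cor_responder Correlation planted between the responder
#'   patient-level LINE-1 intercept and HCY.
#' @param responder_age_delta_mean,responder_age_delta_sd Responder
#'   biological-age change (years).
#' @param cct3_intercept,cct3_slope,cct3_resid_sd Non-responder age-delta
#'   model: `delta = intercept + slope * cct3_count + N(0, resid_sd)`.
#' @param cct3_count_mean,cct3_count_size Negative-binomial parameters of the
#'   non-responder CCT3 mutation count (mean ~9.93, size 2.56 gives SD ~7).
#' @param cct3_responder_rate Poisson mean of the responder CCT3 count.
#' @param planted_variants Data frame as in [default_planted_variants()].
#' @param background_rate Poisson mean of per-patient background variants
#'   spread over the panel.
#' @param clock_cpg_count Whitelist size of the simulated clock (default 308).
#' @param clock_signal_count CpGs with non-zero true slope (default 272).
#' @param clock_extra_cpgs Additional non-whitelist CpGs carried in the beta
#'   matrices (default 46, for 354 rows total).
#' @param noise_sd Beta-scale Gaussian noise SD for the methylation arrays.
#' @param adult_age Age-transform anchor (years).
#' @param seed Integer seed; one seed drives every sub-generator through
#'   fixed streams, so a fixed seed gives byte-identical datasets.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_responders = 21L,
                       n_nonresponders = 22L,
                       hcy_baseline_mean = 16.3, hcy_baseline_sd = 4.8,
                       responder_hcy_after_mean = 11, responder_hcy_after_sd = 2.9,
                       nonresponder_hcy_after_mean = 19.6, nonresponder_hcy_after_sd = 3.7,
                       hcy_pair_cor = 0.5,
                       folate_before_mean = 46.3, folate_before_sd = 40,
                       folate_after_mean = 81.4, folate_after_sd = 29.4,
                       cfdna_before_mean = 9.0, cfdna_before_sd = 4.8,
                       cfdna_after_mean = 8.1, cfdna_after_sd = 4.9,
                       cfdna_relchange_mean = -0.033, cfdna_relchange_sd = 0.2,
                       cfdna_hcy_cor = 0.2375,
                       line1_effect = c(cfDNA = 1.5, granulocyte = 0.2,
                                        mononuclear = 1.45),
                       line1_baseline = rbind(cfDNA = c(85.0, 75.4, 75.9),
                                              granulocyte = c(84.2, 74.5, 74.8),
                                              mononuclear = c(81.4, 74.0, 73.5)),
                       line1_patient_sd = 2.2, line1_cpg_sd = 2.0,
                       line1_within_sd = 1.5,
                       line1_hcy_cor_responder = -0.37,
                       responder_age_delta_mean = -0.5,
                       responder_age_delta_sd = 8,
                       cct3_intercept = -9.214, cct3_slope = 0.394,
                       cct3_resid_sd = 5.48,
                       cct3_count_mean = 9.93, cct3_count_size = 2.56,
                       cct3_responder_rate = 2,
                       planted_variants = default_planted_variants(),
                       background_rate = 12,
                       clock_cpg_count = 308L,
                       clock_signal_count = 272L,
                       clock_extra_cpgs = 46L,
                       noise_sd = 0.02,
                       adult_age = 20,
                       seed = 1L) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_responders >= 0, n_nonresponders >= 0,
              hcy_baseline_sd >= 0, responder_hcy_after_sd >= 0,
              nonresponder_hcy_after_sd >= 0, folate_before_sd >= 0,
              folate_after_sd >= 0, cfdna_before_sd >= 0, cfdna_after_sd >= 0,
              noise_sd >= 0, clock_signal_count <= clock_cpg_count,
              adult_age > 0)
  })
  if (!is.null(cfg$planted_variants) && nrow(cfg$planted_variants)) {
    pv <- cfg$planted_variants
    if (any(pv$carriers_responder > cfg$n_responders) ||
        any(pv$carriers_nonresponder > cfg$n_nonresponders)) {
      stop("configuration error: planted carrier count exceeds group size")
    }
  }
  structure(cfg, class = "sim_config")
}

#' Gene panel and pathway map shipped with the package
#'
#' The shipped 41-gene one-carbon-metabolism panel uses synthetic coordinates
#' (the files are marked `.synthetic.`); users analyzing real data should
#' supply their own BED/TSV. The pathway map assigns the one-carbon genes to
#' the six folic-acid-related pathways used as central graph nodes; a few
#' panel genes are deliberately outside one-carbon metabolism and unmapped.
#'
#' @return `default_panel()`: data frame as from [read_panel_bed()];
#'   `default_pathway_map()`: data frame `gene`, `pathway`.
#' @export
default_panel <- function() {
  read_panel_bed(system.file("extdata", "one_carbon_panel.synthetic.bed",
                             package = "faresponse", mustWork = TRUE))
}

#' @rdname default_panel
#' @export
default_pathway_map <- function() {
  read_tsv(system.file("extdata", "one_carbon_pathways.synthetic.tsv",
                       package = "faresponse", mustWork = TRUE))
}

truncated_normal <- function(n, mean, sd, lower = 0) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  for (i in 1:1000) {
    bad <- x <= lower
    if (!any(bad)) return(x)
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  stop("rejection sampling failed: distribution mass almost entirely below ", lower)
}

#' Generate a synthetic true clock model
#'
#' Draws a linear ground-truth relation between transformed age and the
#' whitelist betas: `clock_signal_count` CpGs get slopes of +/- 0.005-0.02
#' beta units per transformed-age unit around intercepts in (0.25, 0.75); the
#' remaining whitelist CpGs are flat; `clock_extra_cpgs` ids outside the
#' whitelist carry no age signal at all.
#'
#' @param config A [sim_config()] (only the clock fields are used).
#' @param seed Optional override of the derived seed.
#' @return A list of class `true_beta_model` with `cpg_ids`, `whitelist`,
#'   `intercepts`, `slopes`, `adult_age`.
#' @export
make_true_clock_model <- function(config = sim_config(), seed = NULL) {
  if (is.null(seed)) seed <- derive_seed(config$seed, "clock_model")
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  n_wl <- config$clock_cpg_count
  n_sig <- config$clock_signal_count
  n_all <- n_wl + config$clock_extra_cpgs
  ids <- sprintf("cg%07d", seq_len(n_all))
  whitelist <- ids[seq_len(n_wl)]
  slopes <- stats::setNames(numeric(n_all), ids)
  sig <- seq_len(n_sig)
  slopes[sig] <- sample(c(-1, 1), n_sig, replace = TRUE) *
    stats::runif(n_sig, 0.005, 0.02)
  intercepts <- stats::setNames(stats::runif(n_all, 0.25, 0.75), ids)
  structure(list(cpg_ids = ids, whitelist = whitelist,
                 intercepts = intercepts, slopes = slopes,
                 adult_age = config$adult_age),
            class = "true_beta_model")
}

#' Generate a CpG-by-sample beta matrix from a true clock model
#'
#' Every CpG with a non-zero true slope is an affine function of transformed
#' age plus Gaussian noise; flat whitelist CpGs are their intercept plus
#' noise; non-whitelist CpGs are pure uniform noise. Values are clipped to
#' \[0, 1\].
#'
#' @param ages Chronological ages in years (all `>= 0`).
#' @param true_model A [make_true_clock_model()] result.
#' @param noise_sd Beta-scale Gaussian noise SD.
#' @param seed Integer seed.
#' @param sample_ids Optional column names (default `S1...Sn`).
#' @return CpG-by-sample numeric matrix.
#' @export
generate_beta_matrix <- function(ages, true_model, noise_sd, seed,
                                 sample_ids = NULL) {
  if (any(ages < 0)) stop("ages must be non-negative")
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  n <- length(ages)
  ids <- true_model$cpg_ids
  f <- age_transform(ages, true_model$adult_age)
  m <- true_model$intercepts[ids] + outer(true_model$slopes[ids], f)
  in_wl <- ids %in% true_model$whitelist
  m[!in_wl, ] <- stats::runif(sum(!in_wl) * n)
  if (noise_sd > 0) {
    m[in_wl, ] <- m[in_wl, ] + stats::rnorm(sum(in_wl) * n, 0, noise_sd)
  }
  m <- pmin(pmax(m, 0), 1)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%d", seq_len(n))
  dimnames(m) <- list(ids, sample_ids)
  m
}

# -- internal generator stages -------------------------------------------

generate_clinical <- function(config) {
  n_r <- config$n_responders
  n_n <- config$n_nonresponders
  n <- n_r + n_n
  id <- sprintf("P%03d", seq_len(n))
  group <- c(rep("responder", n_r), rep("non_responder", n_n))

  old <- local_seed(derive_seed(config$seed, "cohort"))
  age <- round(truncated_normal(n, 62, 10, lower = 35))
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.7, 0.3))
  restore_seed(old)

  old <- local_seed(derive_seed(config$seed, "hcy"))
  before <- numeric(n)
  after <- numeric(n)
  for (i in seq_len(n)) {
    am <- if (group[i] == "responder") config$responder_hcy_after_mean else
      config$nonresponder_hcy_after_mean
    asd <- if (group[i] == "responder") config$responder_hcy_after_sd else
      config$nonresponder_hcy_after_sd
    # the (before, after) pair is rejected jointly so the planted sign of
    # change holds with the smallest possible distortion of either margin
    for (try in 1:10000) {
      z1 <- stats::rnorm(1)
      z2 <- stats::rnorm(1)
      rho <- config$hcy_pair_cor
      b <- config$hcy_baseline_mean + config$hcy_baseline_sd * z1
      a <- am + asd * (rho * z1 + sqrt(1 - rho^2) * z2)
      if (b <= 0 || a <= 0) next
      ok <- if (group[i] == "responder") a < b else a >= b
      if (ok) break
    }
    if (!ok) stop("rejection sampling failed for the HCY pair of patient ", i)
    before[i] <- b
    after[i] <- a
  }
  restore_seed(old)

  old <- local_seed(derive_seed(config$seed, "folate"))
  fol_b <- truncated_normal(n, config$folate_before_mean, config$folate_before_sd)
  fol_a <- truncated_normal(n, config$folate_after_mean, config$folate_after_sd)
  restore_seed(old)

  old <- local_seed(derive_seed(config$seed, "cfdna"))
  z_h <- (before - config$hcy_baseline_mean) / config$hcy_baseline_sd
  rho_h <- config$cfdna_hcy_cor
  z_b <- rho_h * z_h + sqrt(1 - rho_h^2) * stats::rnorm(n)
  cf_b <- pmax(config$cfdna_before_mean + config$cfdna_before_sd * z_b, 0.2)
  # correlation between baseline and relative change chosen so that both the
  # configured after-mean and the configured mean relative change hold
  rho <- (config$cfdna_after_mean -
            config$cfdna_before_mean * (1 + config$cfdna_relchange_mean)) /
    (config$cfdna_before_sd * config$cfdna_relchange_sd)
  rho <- max(-1, min(1, rho))
  zb_std <- (cf_b - config$cfdna_before_mean) / config$cfdna_before_sd
  r <- config$cfdna_relchange_mean + config$cfdna_relchange_sd *
    (rho * zb_std + sqrt(1 - rho^2) * stats::rnorm(n))
  cf_a <- pmax(cf_b * (1 + r), 0.1)
  restore_seed(old)

  data.frame(patient_id = id, group_truth = group, age_years = age, sex = sex,
             hcy_before = before, hcy_after = after,
             folate_before = fol_b, folate_after = fol_a,
             cfdna_before = cf_b, cfdna_after = cf_a,
             stringsAsFactors = FALSE)
}

generate_line1 <- function(config, patients) {
  old <- local_seed(derive_seed(config$seed, "line1"))
  on.exit(restore_seed(old), add = TRUE)
  n <- nrow(patients)
  z_h <- (patients$hcy_after - mean(patients$hcy_after)) / stats::sd(patients$hcy_after)
  rho <- config$line1_hcy_cor_responder
  u <- ifelse(patients$group_truth == "responder",
              rho * z_h + sqrt(1 - rho^2) * stats::rnorm(n),
              stats::rnorm(n))
  rows <- list()
  for (fr in rownames(config$line1_baseline)) {
    eff <- config$line1_effect[[fr]]
    for (i in seq_len(n)) {
      base <- config$line1_baseline[fr, ] + config$line1_patient_sd * u[i] +
        stats::rnorm(3, 0, config$line1_cpg_sd)
      post <- base + eff + stats::rnorm(3, 0, config$line1_within_sd)
      base <- pmin(pmax(base, 0), 100)
      post <- pmin(pmax(post, 0), 100)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = patients$patient_id[i], fraction = fr,
        timepoint = c("baseline", "post"),
        cpg1 = c(base[1], post[1]), cpg2 = c(base[2], post[2]),
        cpg3 = c(base[3], post[3]), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$average <- average_line1(out$cpg1, out$cpg2, out$cpg3)
  out
}

random_snp_alleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  list(ref = ref, alt = unname(alt))
}

generate_variants <- function(config, patients, panel) {
  old <- local_seed(derive_seed(config$seed, "variants"))
  on.exit(restore_seed(old), add = TRUE)
  resp_ids <- patients$patient_id[patients$group_truth == "responder"]
  nonr_ids <- patients$patient_id[patients$group_truth == "non_responder"]
  rows <- list()
  db <- list()
  region_of <- function(gene) {
    r <- panel[panel$gene == gene, ]
    if (nrow(r) == 0) stop("planted gene not in panel: ", gene)
    r[1, ]
  }

  pv <- config$planted_variants
  if (!is.null(pv)) for (k in seq_len(nrow(pv))) {
    reg <- region_of(pv$gene[k])
    pos <- reg$start0 + pv$offset[k]          # 1-based, inside (start0, end0]
    key <- paste(reg$chrom, pos, pv$ref[k], pv$alt[k], sep = ":")
    carriers <- c(sample(resp_ids, pv$carriers_responder[k]),
                  sample(nonr_ids, pv$carriers_nonresponder[k]))
    for (p in carriers) {
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = p, gene = pv$gene[k], chrom = reg$chrom, pos = pos,
        ref = pv$ref[k], alt = pv$alt[k], variant_key = key,
        hgvs_label = pv$hgvs_label[k],
        variant_classification = pv$classification[k],
        variant_type = "SNP",
        snv_class = snv_class_of(pv$ref[k], pv$alt[k]),
        zygosity = sample(c("het", "hom"), 1, prob = c(0.85, 0.15)),
        stringsAsFactors = FALSE)
    }
    db[[length(db) + 1L]] <- data.frame(
      variant_key = key, clinical_significance = pv$clinical_significance[k],
      stringsAsFactors = FALSE)
  }

  # CCT3 burden: the non-responder counts drive that group's age deltas
  cct3 <- region_of("CCT3")
  counts <- stats::setNames(integer(nrow(patients)), patients$patient_id)
  for (i in seq_len(nrow(patients))) {
    p <- patients$patient_id[i]
    counts[p] <- if (patients$group_truth[i] == "non_responder")
      stats::rnbinom(1, mu = config$cct3_count_mean, size = config$cct3_count_size)
    else stats::rpois(1, config$cct3_responder_rate)
    if (counts[p] > 0) {
      offs <- sample(seq(5000L, 45000L), counts[p])
      al <- random_snp_alleles(counts[p])
      for (j in seq_len(counts[p])) {
        pos <- cct3$start0 + offs[j]
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = p, gene = "CCT3", chrom = cct3$chrom, pos = pos,
          ref = al$ref[j], alt = al$alt[j],
          variant_key = paste(cct3$chrom, pos, al$ref[j], al$alt[j], sep = ":"),
          hgvs_label = sprintf("c.%dN > N", offs[j]),
          variant_classification = sample(c("missense", "silent"), 1,
                                          prob = c(0.6, 0.4)),
          variant_type = "SNP", snv_class = snv_class_of(al$ref[j], al$alt[j]),
          zygosity = "het", stringsAsFactors = FALSE)
      }
    }
  }

  # background variants across the panel; gene weights shape the top lists
  hot_genes <- c(CHAT = 5, MTRR = 5, MTHFD1 = 4, MTHFD1L = 4, PEMT = 3,
                 GART = 3, PLD2 = 3, TBC1D1 = 3, DTHD1 = 3, TYMS = 2)
  w <- stats::setNames(rep(1, nrow(panel)), panel$gene)
  w[names(hot_genes)[names(hot_genes) %in% names(w)]] <-
    hot_genes[names(hot_genes) %in% names(w)]
  cls_pool <- c("missense", "silent", "in_frame_del", "frame_shift_del",
                "nonsense", "splice_site", "in_frame_ins", "frame_shift_ins")
  cls_w <- c(0.52, 0.12, 0.09, 0.08, 0.07, 0.05, 0.04, 0.03)
  sig_pool <- c("Benign", "Likely benign", "Uncertain significance",
                "Likely pathogenic", "Pathogenic")
  for (p in patients$patient_id) {
    k <- stats::rpois(1, config$background_rate)
    if (k == 0) next
    genes <- sample(panel$gene, k, replace = TRUE, prob = w)
    for (g in genes) {
      reg <- region_of(g)
      off <- sample.int(reg$end0 - reg$start0, 1)
      pos <- reg$start0 + off
      cls <- sample(cls_pool, 1, prob = cls_w)
      if (cls %in% c("in_frame_del", "frame_shift_del")) {
        del_len <- if (cls == "in_frame_del") 3L else 1L
        anchor <- sample(c("A", "C", "G", "T"), 1)
        ref <- paste0(anchor, paste(sample(c("A", "C", "G", "T"), del_len,
                                           replace = TRUE), collapse = ""))
        alt <- anchor
        vt <- "DEL"
      } else if (cls %in% c("in_frame_ins", "frame_shift_ins")) {
        ins_len <- if (cls == "in_frame_ins") 3L else 1L
        anchor <- sample(c("A", "C", "G", "T"), 1)
        ref <- anchor
        alt <- paste0(anchor, paste(sample(c("A", "C", "G", "T"), ins_len,
                                           replace = TRUE), collapse = ""))
        vt <- "INS"
      } else {
        al <- random_snp_alleles(1)
        ref <- al$ref
        alt <- al$alt
        vt <- "SNP"
      }
      key <- paste(reg$chrom, pos, ref, alt, sep = ":")
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = p, gene = g, chrom = reg$chrom, pos = pos,
        ref = ref, alt = alt, variant_key = key,
        hgvs_label = sprintf("c.%d%s > %s", off, ref, alt),
        variant_classification = cls, variant_type = vt,
        snv_class = if (vt == "SNP") snv_class_of(ref, alt) else NA_character_,
        zygosity = sample(c("het", "hom"), 1, prob = c(0.85, 0.15)),
        stringsAsFactors = FALSE)
      if (stats::runif(1) < 0.4) {
        db[[length(db) + 1L]] <- data.frame(
          variant_key = key,
          clinical_significance = sample(sig_pool, 1),
          stringsAsFactors = FALSE)
      }
    }
  }
  variants <- do.call(rbind, rows)
  db <- unique(do.call(rbind, db))
  list(variants = variants, annotation_db = db, cct3_counts = counts)
}

generate_age_deltas <- function(config, patients, cct3_counts) {
  old <- local_seed(derive_seed(config$seed, "age_delta"))
  on.exit(restore_seed(old), add = TRUE)
  n <- nrow(patients)
  delta <- numeric(n)
  for (i in seq_len(n)) {
    delta[i] <- if (patients$group_truth[i] == "responder") {
      stats::rnorm(1, config$responder_age_delta_mean, config$responder_age_delta_sd)
    } else {
      config$cct3_intercept +
        config$cct3_slope * cct3_counts[[patients$patient_id[i]]] +
        stats::rnorm(1, 0, config$cct3_resid_sd)
    }
  }
  data.frame(patient_id = patients$patient_id, true_delta = delta,
             stringsAsFactors = FALSE)
}

#' Generate a complete synthetic cohort dataset
#'
#' Produces every input the analysis pipeline consumes: the clinical cohort
#' table (paired HCY, folate, cfDNA), the LINE-1 profiles for three sample
#' fractions, baseline and post-supplementation beta matrices tied to planted
#' biological-age deltas, a MAF-like variant table with exactly the
#' configured carrier counts, and the ClinVar-style annotation table.
#' Group membership is planted (rejection resampling keeps the sign of the
#' HCY change deterministic), so downstream stratification has known truth.
#'
#' @param config A [sim_config()].
#' @param panel Gene panel data frame (default [default_panel()]).
#' @return A list of class `fa_cohort` with elements `patients`, `line1`,
#'   `beta_before`, `beta_after`, `variants`, `annotation_db`, `true_model`,
#'   `truth` (planted group and age delta per patient), and `config`.
#' @export
generate_cohort <- function(config = sim_config(), panel = default_panel()) {
  stopifnot(inherits(config, "sim_config"))
  patients <- generate_clinical(config)
  line1 <- generate_line1(config, patients)
  vg <- generate_variants(config, patients, panel)
  truth <- generate_age_deltas(config, patients, vg$cct3_counts)
  true_model <- make_true_clock_model(config)
  beta_before <- generate_beta_matrix(
    patients$age_years, true_model, config$noise_sd,
    seed = derive_seed(config$seed, "beta"), sample_ids = patients$patient_id)
  beta_after <- generate_beta_matrix(
    pmax(patients$age_years + truth$true_delta, 0), true_model, config$noise_sd,
    seed = derive_seed(config$seed, "beta") + 1L,
    sample_ids = patients$patient_id)
  truth$group_truth <- patients$group_truth
  structure(list(patients = patients, line1 = line1,
                 beta_before = beta_before, beta_after = beta_after,
                 variants = vg$variants, annotation_db = vg$annotation_db,
                 true_model = true_model, truth = truth, config = config),
            class = "fa_cohort")
}

#' Generate a reference training panel for the clock
#'
#' The clock applied to the cohort is trained on external reference samples,
#' not on the study patients; this simulates that reference set from the same
#' ground-truth beta model.
#'
#' @param config A [sim_config()].
#' @param true_model The cohort's `true_model` (default regenerated from
#'   `config`, which gives the identical model).
#' @param n Number of reference samples.
#' @param age_range Uniform age range of the reference samples (years).
#' @return A list with `beta` (CpG-by-sample matrix) and `ages`.
#' @export
generate_training_panel <- function(config = sim_config(),
                                    true_model = make_true_clock_model(config),
                                    n = 200, age_range = c(20, 90)) {
  seed <- derive_seed(config$seed, "training_panel")
  old <- local_seed(seed)
  ages <- stats::runif(n, age_range[1], age_range[2])
  restore_seed(old)
  beta <- generate_beta_matrix(ages, true_model, config$noise_sd,
                               seed = seed + 1L,
                               sample_ids = sprintf("REF%03d", seq_len(n)))
  list(beta = beta, ages = ages)
}

#' @export
print.fa_cohort <- function(x, ...) {
  cat(sprintf("Synthetic FA cohort: %d patients (%d responders / %d non-responders), %d variants, %d CpGs\n",
              nrow(x$patients), sum(x$patients$group_truth == "responder"),
              sum(x$patients$group_truth == "non_responder"),
              nrow(x$variants), nrow(x$beta_before)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes the TSV inputs the pipeline stages read: `cohort.tsv`, `line1.tsv`,
#' `beta_before.tsv`, `beta_after.tsv`, `variants.maf.tsv`,
#' `annotation.tsv`, plus the generator ground truth (`cohort_truth.tsv`)
#' and the configuration as `sim_config.yaml`.
#'
#' @param cohort An `fa_cohort` from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fa_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(cohort$patients, file.path(dir, "cohort.tsv"))
  write_tsv(cohort$line1, file.path(dir, "line1.tsv"))
  write_beta_matrix(cohort$beta_before, file.path(dir, "beta_before.tsv"))
  write_beta_matrix(cohort$beta_after, file.path(dir, "beta_after.tsv"))
  write_variants_maf(cohort$variants, file.path(dir, "variants.maf.tsv"))
  write_tsv(cohort$annotation_db, file.path(dir, "annotation.tsv"))
  write_tsv(cohort$truth, file.path(dir, "cohort_truth.tsv"))
  cfg <- cohort$config
  cfg$line1_baseline <- as.data.frame(cfg$line1_baseline)
  cfg$planted_variants <- as.list(cfg$planted_variants)
  yaml::write_yaml(unclass(cfg), file.path(dir, "sim_config.yaml"))
  invisible(dir)
}
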