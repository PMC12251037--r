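#' Average LINE-1 methylation over the three assayed CpG positions
#'
#' The pyrosequencing assay quantifies three CpG positions of the LINE-1
#' consensus; global methylation is their arithmetic mean. Full precision is
#' retained internally; reporting layers round to one decimal.
#'
#' @param cpg1,cpg2,cpg3 Methylation percentages in \[0, 100\] (vectorized).
#' @return Numeric vector of mean methylation percentages.
#' @examples
#' round(average_line1(85.0, 75.4, 75.9), 1)  # 78.8
#' @export
average_line1 <- function(cpg1, cpg2, cpg3) {
  vals <- cbind(cpg1, cpg2, cpg3)
  if (any(vals < 0 | vals > 100, na.rm = TRUE)) {
    stop("CpG methylation percentages must lie in [0, 100]")
  }
  (cpg1 + cpg2 + cpg3) / 3
}

line1_fractions <- c("cfDNA", "granulocyte", "mononuclear")

#' Per-fraction LINE-1 methylation change analysis
#'
#' For each sample fraction (cfDNA, granulocyte, mononuclear) this compares
#' baseline against post-supplementation three-CpG averages with the
#' normality-gated paired test, reports the mean per-patient relative change,
#' repeats both within each response group, and (when homocysteine levels are
#' supplied) correlates HCY with the LINE-1 average per group, pooling both
#' timepoints. Per-CpG paired comparisons are also produced, unadjusted by
#' default to mirror per-position reporting; `holm = TRUE` adds a
#' Holm-adjusted p across the three CpGs within a fraction/group.
#'
#' @param profiles Data frame of LINE-1 profiles with columns `patient_id`,
#'   `fraction`, `timepoint` (`"baseline"`/`"post"`), `cpg1`, `cpg2`, `cpg3`.
#' @param labels Data frame with `patient_id` and `label` from
#'   [stratify_cohort()] (or NULL to analyze only the pooled cohort).
#' @param hcy Optional data frame `patient_id`, `hcy_before`, `hcy_after` for
#'   the HCY vs LINE-1 correlations.
#' @param alpha Gate for the paired tests.
#' @param holm If TRUE, add Holm-adjusted p-values across the three CpGs.
#' @return A list with `table` (Table-1-shaped long data frame: fraction,
#'   measure, group, baseline/post mean and SD, n, test used, p, optionally
#'   `p_holm`), `relative_change` (per fraction and group: mean, sd, n of
#'   per-patient relative changes of the average), and `hcy_correlation`
#'   (per fraction and group Pearson r and p, or NULL).
#' @export
line1_change_analysis <- function(profiles, labels = NULL, hcy = NULL,
                                  alpha = 0.05, holm = FALSE) {
  stopifnot(is.data.frame(profiles))
  need <- c("patient_id", "fraction", "timepoint", "cpg1", "cpg2", "cpg3")
  miss <- setdiff(need, names(profiles))
  if (length(miss)) stop("profiles is missing columns: ", paste(miss, collapse = ", "))
  profiles$average <- average_line1(profiles$cpg1, profiles$cpg2, profiles$cpg3)

  lab_of <- function(ids) {
    if (is.null(labels)) return(rep(NA_character_, length(ids)))
    labels$label[match(ids, labels$patient_id)]
  }

  table_rows <- list()
  rc_rows <- list()
  cor_rows <- list()
  groups <- c("all", if (!is.null(labels)) c("responder", "non_responder"))

  for (fr in unique(profiles$fraction)) {
    sub <- profiles[profiles$fraction == fr, ]
    base <- sub[sub$timepoint == "baseline", ]
    post <- sub[sub$timepoint == "post", ]
    common <- intersect(base$patient_id, post$patient_id)
    base <- base[match(common, base$patient_id), ]
    post <- post[match(common, post$patient_id), ]
    glab <- lab_of(common)

    for (g in groups) {
      sel <- if (g == "all") rep(TRUE, length(common)) else !is.na(glab) & glab == g
      if (sum(sel) < 3) {
        warning(sprintf("fraction %s, group %s: fewer than 3 complete pairs; skipped",
                        fr, g))
        next
      }
      measures <- c(cpg1 = "cpg1", cpg2 = "cpg2", cpg3 = "cpg3", average = "average")
      pvals <- numeric(0)
      block <- list()
      for (mn in names(measures)) {
        b <- base[[measures[[mn]]]][sel]
        a <- post[[measures[[mn]]]][sel]
        tr <- paired_compare(b, a, alpha)
        sb <- summarize_group(b)
        sa <- summarize_group(a)
        block[[mn]] <- data.frame(
          fraction = fr, measure = mn, group = g,
          baseline_mean = sb$mean, baseline_sd = sb$sd,
          post_mean = sa$mean, post_sd = sa$sd, n = tr$n_pairs,
          test_used = tr$test_used, p_value = tr$p_value,
          stringsAsFactors = FALSE)
        if (mn != "average") pvals[mn] <- tr$p_value
      }
      if (holm) {
        adj <- stats::p.adjust(pvals, method = "holm")
        for (mn in names(adj)) block[[mn]]$p_holm <- adj[[mn]]
        block[["average"]]$p_holm <- NA_real_
      }
      table_rows <- c(table_rows, block)

      rc <- relative_change(base$average[sel], post$average[sel])
      s <- summarize_group(rc)
      rc_rows[[length(rc_rows) + 1L]] <- data.frame(
        fraction = fr, group = g, mean_relative_change_percent = s$mean,
        sd = s$sd, n = s$n, stringsAsFactors = FALSE)

      if (!is.null(hcy)) {
        hb <- hcy$hcy_before[match(common, hcy$patient_id)]
        ha <- hcy$hcy_after[match(common, hcy$patient_id)]
        x <- c(hb[sel], ha[sel])
        y <- c(base$average[sel], post$average[sel])
        ok <- !is.na(x) & !is.na(y)
        if (sum(ok) >= 3 && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0) {
          ct <- correlate(x, y, "pearson")
          cor_rows[[length(cor_rows) + 1L]] <- data.frame(
            fraction = fr, group = g, r = ct$r, p_value = ct$p_value,
            n = ct$n, stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(table = do.call(rbind, table_rows),
       relative_change = do.call(rbind, rc_rows),
       hcy_correlation = if (length(cor_rows)) do.call(rbind, cor_rows) else NULL)
}
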