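#' Per-patient, per-gene mutation burden
#'
#' Counts variant records per (patient, gene), zero-filled over the supplied
#' panel genes and patients so genes with no variants still appear.
#'
#' @param variants Data frame from [read_variants()] (all panel variants,
#'   classified and unclassified alike).
#' @param patients Optional character vector of patient ids to zero-fill
#'   (default: patients seen in `variants`).
#' @param panel_genes Optional character vector of genes to zero-fill
#'   (default: genes seen in `variants`).
#' @return Data frame `patient_id`, `gene`, `mutation_count`.
#' @export
burden_matrix <- function(variants, patients = NULL, panel_genes = NULL) {
  if (is.null(patients)) patients <- sort(unique(variants$patient_id))
  if (is.null(panel_genes)) panel_genes <- sort(unique(variants$gene))
  grid <- expand.grid(patient_id = patients, gene = panel_genes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (nrow(variants)) {
    counts <- stats::aggregate(list(mutation_count = variants$patient_id),
                               by = list(patient_id = variants$patient_id,
                                         gene = variants$gene),
                               FUN = length)
    grid <- merge(grid, counts, by = c("patient_id", "gene"), all.x = TRUE)
  } else {
    grid$mutation_count <- NA_integer_
  }
  grid$mutation_count[is.na(grid$mutation_count)] <- 0L
  grid[order(grid$patient_id, grid$gene), c("patient_id", "gene", "mutation_count")]
}

#' Associate per-gene mutation burden with biological-age change
#'
#' For each gene, within one response group: Spearman rank correlation
#' (two-sided) between the patient's mutation count and the biological-age
#' delta, plus the ordinary least-squares line
#' `delta = intercept + slope * count`. Genes with constant burden in the
#' group are skipped and flagged. Raw p-values are reported unadjusted (the
#' convention followed here); when two or more genes are tested a
#' Benjamini-Hochberg column is always carried, and `adjust = TRUE` promotes
#' it to the significance column.
#'
#' @param burden Data frame from [burden_matrix()].
#' @param deltas Data frame with `patient_id` and `delta` (years, after -
#'   before), e.g. from [cohort_age_deltas()].
#' @param labels Optional data frame `patient_id`, `label`; with `group`,
#'   restricts the analysis to one response group.
#' @param group `"responder"`, `"non_responder"` or NULL for all patients.
#' @param adjust If TRUE report BH-adjusted p as the significance column.
#' @return Data frame `gene`, `spearman_r`, `p_value`, `adjusted_p`,
#'   `intercept`, `slope`, `n`, `skipped_constant`.
#' @export
associate <- function(burden, deltas, labels = NULL, group = NULL,
                      adjust = FALSE) {
  ids <- intersect(unique(burden$patient_id), deltas$patient_id)
  if (!is.null(group)) {
    if (is.null(labels)) stop("labels are required when group is given")
    ids <- intersect(ids, labels$patient_id[!is.na(labels$label) &
                                              labels$label == group])
  }
  if (length(ids) < 3) stop("need at least 3 patients with burden and delta")
  d <- deltas$delta[match(ids, deltas$patient_id)]

  genes <- sort(unique(burden$gene))
  rows <- lapply(genes, function(g) {
    b <- burden[burden$gene == g, ]
    x <- b$mutation_count[match(ids, b$patient_id)]
    x[is.na(x)] <- 0L
    if (length(unique(x)) == 1) {
      return(data.frame(gene = g, spearman_r = NA_real_, p_value = NA_real_,
                        intercept = NA_real_, slope = NA_real_,
                        n = length(ids), skipped_constant = TRUE,
                        stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(x, d, method = "spearman", exact = FALSE)
    fit <- stats::lm(d ~ x)
    data.frame(gene = g, spearman_r = unname(ct$estimate),
               p_value = ct$p.value,
               intercept = unname(stats::coef(fit)[1]),
               slope = unname(stats::coef(fit)[2]),
               n = length(ids), skipped_constant = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  tested <- !out$skipped_constant
  out$adjusted_p <- NA_real_
  if (sum(tested) >= 2) {
    out$adjusted_p[tested] <- stats::p.adjust(out$p_value[tested], method = "BH")
  }
  if (adjust && any(!is.na(out$adjusted_p))) {
    out <- out[order(out$adjusted_p), ]
  } else {
    out <- out[order(out$p_value), ]
  }
  rownames(out) <- NULL
  out[, c("gene", "spearman_r", "p_value", "adjusted_p", "intercept",
          "slope", "n", "skipped_constant")]
}
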