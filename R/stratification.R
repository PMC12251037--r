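#' Classify folic-acid response from paired homocysteine levels
#'
#' A patient is an FA responder when plasma homocysteine (HCY) strictly
#' decreased between baseline and the end of supplementation, and a
#' non-responder when it remained unchanged or increased. Ties therefore go to
#' `non_responder`. Missing values in either timepoint yield `NA` and the
#' patient is excluded from group analyses.
#'
#' @param hcy_before,hcy_after Numeric vectors of paired HCY measurements in
#'   umol/L. Values must be positive where present.
#' @return Character vector with levels `"responder"` / `"non_responder"`,
#'   `NA` where either timepoint is missing.
#' @examples
#' classify_response(c(15.7, 16.7, 15), c(11, 19.6, 15))
#' @export
classify_response <- function(hcy_before, hcy_after) {
  if (length(hcy_before) != length(hcy_after)) {
    stop("hcy_before and hcy_after must have the same length")
  }
  if (any(hcy_before <= 0, na.rm = TRUE) || any(hcy_after <= 0, na.rm = TRUE)) {
    stop("HCY measurements must be positive")
  }
  ifelse(is.na(hcy_before) | is.na(hcy_after), NA_character_,
         ifelse(hcy_after < hcy_before, "responder", "non_responder"))
}

#' Relative change in percent
#'
#' Per-patient relative change of a paired measurement,
#' `100 * (after - before) / before`, signed.
#'
#' @param before,after Numeric vectors; `before` must be non-zero.
#' @return Numeric vector of percent changes.
#' @examples
#' relative_change(10, 11)   # +10
#' relative_change(20, 10)   # -50
#' @export
relative_change <- function(before, after) {
  if (any(before == 0, na.rm = TRUE)) {
    stop("relative change is undefined for a baseline of 0")
  }
  100 * (after - before) / before
}

#' Normality-gated paired comparison
#'
#' Applies the Shapiro-Wilk test to the paired differences; if they are
#' compatible with normality (`p >= alpha`) a paired Student t-test is used,
#' otherwise the Wilcoxon matched-pairs signed-rank test. Pairs with a missing
#' value in either arm are dropped (pairwise deletion). If every difference is
#' zero the comparison is degenerate and reported with `p = 1` and a warning.
#'
#' @param before,after Equal-length numeric vectors of paired measurements.
#' @param alpha Significance criterion used both to gate the normality test and
#'   as the nominal level downstream (default 0.05).
#' @return A list of class `fa_test_result` with elements `statistic`,
#'   `p_value`, `test_used` (`"paired_t"` or `"wilcoxon_signed_rank"`),
#'   `n_pairs`, `normality_p` and `degenerate`.
#' @export
paired_compare <- function(before, after, alpha = 0.05) {
  if (length(before) != length(after)) {
    stop("before and after must be paired vectors of equal length")
  }
  keep <- !is.na(before) & !is.na(after)
  b <- before[keep]
  a <- after[keep]
  n <- length(b)
  if (n < 3) stop("need at least 3 complete pairs, got ", n)
  d <- a - b
  if (all(d == 0)) {
    warning("all paired differences are zero; degenerate comparison")
    return(structure(list(statistic = NA_real_, p_value = 1,
                          test_used = "paired_t", n_pairs = n,
                          normality_p = NA_real_, degenerate = TRUE),
                     class = "fa_test_result"))
  }
  sw <- stats::shapiro.test(d)
  if (sw$p.value >= alpha) {
    ht <- stats::t.test(a, b, paired = TRUE)
    used <- "paired_t"
  } else {
    ht <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = TRUE)
    used <- "wilcoxon_signed_rank"
  }
  structure(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                 test_used = used, n_pairs = n,
                 normality_p = sw$p.value, degenerate = FALSE),
            class = "fa_test_result")
}

#' @export
print.fa_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %d pairs, Shapiro-Wilk p = %.3g)\n",
              x$test_used, x$statistic, x$p_value, x$n_pairs, x$normality_p))
  invisible(x)
}

#' Correlation with two-sided p-value
#'
#' @param x,y Equal-length numeric vectors; pairwise-complete observations are
#'   used and at least 3 are required.
#' @param method `"pearson"` or `"spearman"`.
#' @return A list with `r`, `p_value`, `method` and `n`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) stop("need at least 3 pairwise-complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation is undefined for a zero-variance vector")
  }
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p_value = ct$p.value, method = method,
       n = length(x))
}

#' Mean, sample SD and n of a group of measurements
#'
#' Summaries are reported as mean +/- SD with the sample (n - 1) denominator;
#' a single observation yields SD 0 by convention so one-patient strata still
#' print.
#'
#' @param values Numeric vector, missing values dropped.
#' @return A list with `mean`, `sd` and `n`.
#' @export
summarize_group <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0) stop("cannot summarize an empty group")
  list(mean = mean(values), sd = if (n > 1) stats::sd(values) else 0, n = n)
}

#' Stratify a cohort table and summarize its paired biomarkers
#'
#' Runs the full responder stratification over a cohort data frame: labels
#' every patient, computes the per-patient HCY relative change, and produces
#' paired comparisons of HCY, folate and cfDNA overall and within each
#' response group.
#'
#' @param cohort Data frame with columns `patient_id`, `hcy_before`,
#'   `hcy_after`, `folate_before`, `folate_after`, `cfdna_before`,
#'   `cfdna_after` (extra columns are carried through untouched).
#' @param alpha Significance criterion for the gated paired tests.
#' @return A list with `labels` (data frame `patient_id`, `label`,
#'   `hcy_relative_change_percent`), `group_summary` (long data frame of
#'   mean/sd/n per measurement, timepoint and group) and `tests` (named list
#'   of `fa_test_result`, keys like `"hcy.responder"`, `"cfdna.all"`).
#' @export
stratify_cohort <- function(cohort, alpha = 0.05) {
  stopifnot(is.data.frame(cohort))
  need <- c("patient_id", "hcy_before", "hcy_after")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort is missing columns: ", paste(miss, collapse = ", "))

  label <- classify_response(cohort$hcy_before, cohort$hcy_after)
  labels <- data.frame(
    patient_id = cohort$patient_id,
    label = label,
    hcy_relative_change_percent =
      ifelse(is.na(label), NA_real_,
             relative_change(cohort$hcy_before, cohort$hcy_after)),
    stringsAsFactors = FALSE
  )

  measures <- intersect(c("hcy", "folate", "cfdna"),
                        sub("_before$", "", grep("_before$", names(cohort), value = TRUE)))
  groups <- list(all = rep(TRUE, nrow(cohort)),
                 responder = !is.na(label) & label == "responder",
                 non_responder = !is.na(label) & label == "non_responder")

  tests <- list()
  rows <- list()
  for (m in measures) {
    b <- cohort[[paste0(m, "_before")]]
    a <- cohort[[paste0(m, "_after")]]
    for (g in names(groups)) {
      sel <- groups[[g]]
      complete <- sel & !is.na(b) & !is.na(a)
      if (sum(complete) >= 3) {
        tests[[paste(m, g, sep = ".")]] <- paired_compare(b[sel], a[sel], alpha)
      }
      for (tp in c("before", "after")) {
        v <- if (tp == "before") b[sel] else a[sel]
        if (any(!is.na(v))) {
          s <- summarize_group(v)
          rows[[length(rows) + 1L]] <- data.frame(
            measurement = m, group = g, timepoint = tp,
            mean = s$mean, sd = s$sd, n = s$n, stringsAsFactors = FALSE)
        }
      }
      rc <- relative_change(b[complete], a[complete])
      if (length(rc)) {
        s <- summarize_group(rc)
        rows[[length(rows) + 1L]] <- data.frame(
          measurement = m, group = g, timepoint = "relative_change_percent",
          mean = s$mean, sd = s$sd, n = s$n, stringsAsFactors = FALSE)
      }
    }
  }
  list(labels = labels,
       group_summary = do.call(rbind, rows),
       tests = tests)
}
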