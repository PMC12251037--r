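#' Horvath age transform and its inverse
#'
#' The multi-tissue clock regresses a piecewise-transformed age on CpG betas:
#' logarithmic below the adult-age anchor (fast methylome remodeling during
#' development), linear above it. `age_transform` maps years to the
#' transformed scale; `inverse_age_transform` maps predictions back.
#'
#' @param age Chronological age in years, `>= 0` (vectorized).
#' @param transformed Value on the transformed-age scale (vectorized).
#' @param adult_age Anchor constant in years, default 20.
#' @return Numeric vector.
#' @examples
#' age_transform(20)                 # 0
#' age_transform(41)                 # 1
#' inverse_age_transform(age_transform(63.2))  # 63.2
#' @export
age_transform <- function(age, adult_age = 20) {
  stopifnot(adult_age > 0)
  if (any(age < 0, na.rm = TRUE)) stop("age must be non-negative")
  ifelse(age <= adult_age,
         log((age + 1) / (adult_age + 1)),
         (age - adult_age) / (adult_age + 1))
}

#' @rdname age_transform
#' @export
inverse_age_transform <- function(transformed, adult_age = 20) {
  stopifnot(adult_age > 0)
  ifelse(transformed <= 0,
         exp(transformed) * (adult_age + 1) - 1,
         transformed * (adult_age + 1) + adult_age)
}

#' Construct a clock model object
#'
#' @param whitelist Ordered character vector of CpG ids the clock may use.
#' @param intercept Intercept on the transformed-age scale.
#' @param coefficients Named numeric vector of per-CpG weights; names must be
#'   a subset of (and are re-ordered to) `whitelist`, absent ids get weight 0.
#' @param adult_age Age-transform anchor in years.
#' @param cpg_means Optional named vector of training-set mean betas over the
#'   whitelist, used only for optional mean-imputation at prediction time.
#' @return An object of class `clock_model`.
#' @export
clock_model <- function(whitelist, intercept, coefficients, adult_age = 20,
                        cpg_means = NULL) {
  stopifnot(is.character(whitelist), length(whitelist) > 0, adult_age > 0)
  extra <- setdiff(names(coefficients), whitelist)
  if (length(extra)) stop("coefficients outside the whitelist: ",
                          paste(utils::head(extra, 5), collapse = ", "))
  w <- stats::setNames(numeric(length(whitelist)), whitelist)
  w[names(coefficients)] <- coefficients
  structure(list(whitelist = whitelist, intercept = intercept,
                 coefficients = w, adult_age = adult_age,
                 nonzero_count = sum(w != 0), cpg_means = cpg_means),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("Epigenetic clock: %d whitelist CpGs, %d non-zero weights, adult_age = %g\n",
              length(x$whitelist), x$nonzero_count, x$adult_age))
  invisible(x)
}

#' Retrain a whitelist-filtered epigenetic clock
#'
#' Fits an elastic-net regression of transformed age on the whitelisted CpG
#' betas, the procedure used to adapt the multi-tissue clock to a reduced CpG
#' set: restrict to the CpGs shared across array platforms, then retrain the
#' coefficients. Penalty strength is chosen by internal k-fold
#' cross-validation (fold assignment fixed by `seed`) unless `lambda` is
#' supplied.
#'
#' @param beta CpG-by-sample numeric matrix of methylation beta values in
#'   \[0, 1\]; rownames are CpG ids, colnames sample ids.
#' @param ages Chronological ages (years) for the columns of `beta`.
#' @param whitelist CpG ids the model may use; all must be rows of `beta`.
#' @param alpha Elastic-net mixing parameter (1 = lasso, 0 = ridge);
#'   default 0.5.
#' @param lambda Optional fixed penalty strength; when NULL it is selected as
#'   the cross-validated `lambda.min`.
#' @param nfolds Folds for the internal cross-validation (default 10).
#' @param adult_age Age-transform anchor in years.
#' @param seed Integer seed fixing the fold assignment.
#' @return A [clock_model()].
#' @export
train_filtered_clock <- function(beta, ages, whitelist, alpha = 0.5,
                                 lambda = NULL, nfolds = 10, adult_age = 20,
                                 seed = 1L) {
  stopifnot(is.matrix(beta), length(ages) == ncol(beta))
  missing_cpg <- setdiff(whitelist, rownames(beta))
  if (length(missing_cpg)) {
    stop("whitelist CpGs missing from the beta matrix: ",
         paste(utils::head(missing_cpg, 10), collapse = ", "),
         if (length(missing_cpg) > 10) sprintf(" (+%d more)", length(missing_cpg) - 10))
  }
  if (ncol(beta) < 10) stop("need at least 10 training samples")
  if (stats::sd(ages) == 0) stop("training ages are constant; the clock is unidentifiable")

  x <- t(beta[whitelist, , drop = FALSE])
  y <- age_transform(ages, adult_age)

  # let the penalty path run to near-zero even when the fit saturates
  # (noise-free data would otherwise stop the path early)
  old_ctl <- glmnet::glmnet.control()
  glmnet::glmnet.control(fdev = 0, devmax = 1)
  on.exit(do.call(glmnet::glmnet.control, old_ctl), add = TRUE)

  if (is.null(lambda)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
    foldid <- sample(rep_len(seq_len(nfolds), nrow(x)))
    cv <- glmnet::cv.glmnet(x, y, alpha = alpha, foldid = foldid,
                            lambda.min.ratio = 1e-10, nlambda = 150,
                            thresh = 1e-12, standardize = TRUE)
    lambda <- cv$lambda.min
    fit <- cv$glmnet.fit
  } else {
    # a short decreasing path down to the requested penalty gives a fully
    # converged solution at a single user lambda
    path <- lambda * c(64, 16, 4, 1) + c(1e-3, 1e-4, 1e-5, 0)
    fit <- glmnet::glmnet(x, y, alpha = alpha, standardize = TRUE,
                          lambda = path, thresh = 1e-14, maxit = 1e7)
  }
  co <- as.numeric(stats::coef(fit, s = lambda))
  names(co) <- c("(Intercept)", colnames(x))
  clock_model(whitelist = whitelist, intercept = co[["(Intercept)"]],
              coefficients = co[-1][co[-1] != 0], adult_age = adult_age,
              cpg_means = colMeans(x))
}

#' Predict biological (DNA methylation) age
#'
#' Applies a trained clock to one or more beta profiles:
#' `inverse_age_transform(intercept + sum(w_i * beta_i))` over the whitelist.
#' Rows outside the whitelist are ignored; by default a missing whitelist CpG
#' is an error (set `impute = TRUE` to fall back on training-set means).
#'
#' @param model A [clock_model()].
#' @param beta CpG-by-sample matrix, or a named numeric vector for a single
#'   sample.
#' @param impute If TRUE, missing whitelist CpGs are filled with the model's
#'   stored training means instead of erroring.
#' @return Named numeric vector of predicted ages in years.
#' @export
predict_age <- function(model, beta, impute = FALSE) {
  stopifnot(inherits(model, "clock_model"))
  if (is.vector(beta)) beta <- matrix(beta, ncol = 1, dimnames = list(names(beta), "sample"))
  missing_cpg <- setdiff(model$whitelist, rownames(beta))
  if (length(missing_cpg)) {
    if (!impute || is.null(model$cpg_means)) {
      stop("missing whitelist CpGs: ",
           paste(utils::head(missing_cpg, 10), collapse = ", "),
           if (length(missing_cpg) > 10) sprintf(" (+%d more)", length(missing_cpg) - 10))
    }
    fill <- matrix(model$cpg_means[missing_cpg], nrow = length(missing_cpg),
                   ncol = ncol(beta), dimnames = list(missing_cpg, colnames(beta)))
    beta <- rbind(beta, fill)
  }
  x <- beta[model$whitelist, , drop = FALSE]
  lin <- model$intercept + as.numeric(crossprod(x, model$coefficients))
  stats::setNames(inverse_age_transform(lin, model$adult_age), colnames(beta))
}

#' Per-patient biological-age deltas and group summaries
#'
#' Predicts biological age from the baseline and post-supplementation beta
#' matrices (columns must be the same patients in the same order), forms
#' `delta = after - before` per patient, and summarizes per response group:
#' mean delta, the fraction of patients with strictly decreasing biological
#' age, and the normality-gated paired test of before vs after predictions.
#'
#' @param model A [clock_model()].
#' @param beta_before,beta_after CpG-by-sample matrices with identical
#'   column names (patient ids).
#' @param labels Optional data frame `patient_id`, `label`.
#' @param impute Passed to [predict_age()].
#' @return A list with `deltas` (data frame `patient_id`, `bioage_before`,
#'   `bioage_after`, `delta`) and `group_summary` (per group: mean/sd delta,
#'   n, `fraction_decreasing`, test used and p).
#' @export
cohort_age_deltas <- function(model, beta_before, beta_after, labels = NULL,
                              impute = FALSE) {
  if (is.null(colnames(beta_before)) || is.null(colnames(beta_after)) ||
      !identical(colnames(beta_before), colnames(beta_after))) {
    stop("beta_before and beta_after must have identical sample columns")
  }
  before <- predict_age(model, beta_before, impute)
  after <- predict_age(model, beta_after, impute)
  deltas <- data.frame(patient_id = colnames(beta_before),
                       bioage_before = unname(before),
                       bioage_after = unname(after),
                       delta = unname(after - before),
                       stringsAsFactors = FALSE)
  glab <- if (is.null(labels)) rep(NA_character_, nrow(deltas)) else
    labels$label[match(deltas$patient_id, labels$patient_id)]
  groups <- c("all", if (!is.null(labels)) c("responder", "non_responder"))
  rows <- lapply(groups, function(g) {
    sel <- if (g == "all") rep(TRUE, nrow(deltas)) else !is.na(glab) & glab == g
    if (!any(sel)) return(NULL)
    d <- deltas$delta[sel]
    tr <- if (sum(sel) >= 3) paired_compare(deltas$bioage_before[sel],
                                            deltas$bioage_after[sel]) else NULL
    data.frame(group = g, mean_delta = mean(d),
               sd_delta = if (length(d) > 1) stats::sd(d) else 0,
               n = length(d),
               fraction_decreasing = mean(d < 0),
               test_used = if (is.null(tr)) NA_character_ else tr$test_used,
               p_value = if (is.null(tr)) NA_real_ else tr$p_value,
               stringsAsFactors = FALSE)
  })
  list(deltas = deltas, group_summary = do.call(rbind, rows))
}

#' Serialize / deserialize a clock model as flat TSV
#'
#' The format is a header of comment lines (`#intercept`, `#adult_age`) over a
#' two-column table of `(cpg_id, coefficient)` for the full whitelist
#' (zero-weight CpGs included, preserving order). Numbers are written with 17
#' significant digits so the round-trip is bit-exact. Training means, when
#' present, are stored as a third column.
#'
#' @param model A [clock_model()].
#' @param path File path.
#' @return `write_clock_model` returns `path` invisibly; `read_clock_model`
#'   returns a [clock_model()].
#' @export
write_clock_model <- function(model, path) {
  stopifnot(inherits(model, "clock_model"))
  num <- function(x) sprintf("%.17g", x)
  lines <- c(sprintf("#intercept\t%s", num(model$intercept)),
             sprintf("#adult_age\t%s", num(model$adult_age)),
             if (is.null(model$cpg_means)) "cpg_id\tcoefficient"
             else "cpg_id\tcoefficient\tmean_beta",
             if (is.null(model$cpg_means))
               sprintf("%s\t%s", model$whitelist, num(model$coefficients))
             else
               sprintf("%s\t%s\t%s", model$whitelist, num(model$coefficients),
                       num(model$cpg_means[model$whitelist])))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_clock_model
#' @export
read_clock_model <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  kv <- do.call(rbind, strsplit(sub("^#", "", hdr), "\t"))
  vals <- stats::setNames(as.numeric(kv[, 2]), kv[, 1])
  tab <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                           stringsAsFactors = FALSE)
  clock_model(whitelist = tab$cpg_id,
              intercept = vals[["intercept"]],
              coefficients = stats::setNames(tab$coefficient, tab$cpg_id),
              adult_age = vals[["adult_age"]],
              cpg_means = if ("mean_beta" %in% names(tab))
                stats::setNames(tab$mean_beta, tab$cpg_id) else NULL)
}
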