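# RNG hygiene: functions that take a `seed` argument set it locally and
# restore the caller's generator state on exit.

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Deterministic seed-splitting: one user-facing seed drives every
# sub-generator through fixed named streams, so adding draws to one stream
# never perturbs another. Stays below 2^31 - 1.
derive_seed <- function(seed, stream) {
  streams <- c(cohort = 1L, hcy = 2L, folate = 3L, cfdna = 4L, line1 = 5L,
               clock_model = 6L, beta = 7L, variants = 8L, age_delta = 9L,
               training_panel = 10L, folds = 11L)
  if (!stream %in% names(streams)) stop("unknown seed stream: ", stream)
  (as.integer(seed) %% 1000003L) * 2011L + streams[[stream]] * 7919L
}

# Deterministic TSV writer shared by all stages (fixed number formatting so
# byte-identical reruns hold across platforms with the same locale).
write_tsv <- function(df, path, digits = 10) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]])) {
      df[[j]] <- formatC(df[[j]], digits = digits, format = "g")
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read and write beta matrices as TSV
#'
#' Rows are CpG ids (first column `cpg_id`), columns are sample ids, values
#' are methylation betas in \[0, 1\].
#'
#' @param beta CpG-by-sample numeric matrix.
#' @param path File path.
#' @return `write_beta_matrix` returns `path` invisibly; `read_beta_matrix`
#'   returns the matrix.
#' @export
write_beta_matrix <- function(beta, path) {
  df <- data.frame(cpg_id = rownames(beta),
                   formatC(beta, digits = 10, format = "g"),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("cpg_id", colnames(beta))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_beta_matrix
#' @export
read_beta_matrix <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}
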