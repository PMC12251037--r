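#' Assemble a pipeline configuration
#'
#' Either simulates its inputs (the default: `simulate = TRUE` generates a
#' full synthetic cohort under `seed`) or reads them from files. All
#' thresholds and hyperparameters sit in one place so a run is reproducible
#' from one object; a YAML file with the same field names may be supplied
#' instead.
#'
#' @param simulate If TRUE, generate the inputs with [generate_cohort()];
#'   otherwise the `*_path` fields must point at existing files.
#' @param sim A [sim_config()] used when `simulate = TRUE`.
#' @param cohort_path,line1_path,maf_path,panel_path,annotation_path,beta_before_path,beta_after_path,pathway_path
#'   Input files when `simulate = FALSE` (`panel_path`/`pathway_path` default
#'   to the shipped synthetic panel).
#' @param alpha Significance criterion for the gated paired tests.
#' @param node_threshold,highlight_in,highlight_out Hotspot thresholds in
#'   percent.
#' @param clock_alpha,clock_nfolds Elastic-net mixing and CV folds for the
#'   clock retraining.
#' @param n_train Reference samples simulated to train the clock.
#' @param seed Integer seed driving every stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = TRUE, sim = sim_config(seed = seed),
                            cohort_path = NULL, line1_path = NULL,
                            maf_path = NULL, panel_path = NULL,
                            annotation_path = NULL, beta_before_path = NULL,
                            beta_after_path = NULL, pathway_path = NULL,
                            alpha = 0.05, node_threshold = 50,
                            highlight_in = 70, highlight_out = 50,
                            clock_alpha = 0.5, clock_nfolds = 10,
                            n_train = 200, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(alpha > 0, alpha < 1,
            node_threshold >= 0, node_threshold <= 100,
            highlight_in >= 0, highlight_in <= 100,
            highlight_out >= 0, highlight_out <= 100)
  if (!simulate) {
    needed <- c("cohort_path", "line1_path", "maf_path", "annotation_path",
                "beta_before_path", "beta_after_path")
    for (f in needed) {
      if (is.null(cfg[[f]])) stop("config requires ", f, " when simulate = FALSE")
      if (!file.exists(cfg[[f]])) stop("input file for ", f, " does not exist: ",
                                       cfg[[f]])
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are the arguments of [pipeline_config()]
#'   (`sim:` holds [sim_config()] overrides).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim
  y$sim <- NULL
  if (!is.null(y$seed)) y$seed <- as.integer(y$seed)
  if (!is.null(sim_args)) {
    if (is.null(sim_args$seed) && !is.null(y$seed)) sim_args$seed <- y$seed
    y$sim <- do.call(sim_config, sim_args)
  }
  do.call(pipeline_config, y)
}

log_line <- function(con, ...) {
  msg <- sprintf("%s  %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 paste0(...))
  writeLines(msg, con)
  invisible(msg)
}

run_stage <- function(name, con, expr) {
  tryCatch(expr, error = function(e) {
    log_line(con, "ERROR in stage ", name, ": ", conditionMessage(e))
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional), stratify, LINE-1, clock, variants and
#' association in order, writing every stage's tables under `out_dir` and a
#' plain-text log (`pipeline.log`, one ISO-timestamped line per event).
#' Numeric outputs are deterministic under a fixed seed.
#'
#' @param config A [pipeline_config()] or the path to its YAML form.
#' @param out_dir Output directory.
#' @return A `cohort_report` list: `group_sizes`, `biomarkers` (group
#'   summary and tests from [stratify_cohort()]), `line1`
#'   ([line1_change_analysis()] output), `age` ([cohort_age_deltas()] output
#'   plus the trained model), `hotspots`, `mutation_summaries`,
#'   `association`, and `files` (every table written).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  con <- file(file.path(out_dir, "pipeline.log"), open = "wt")
  on.exit(close(con), add = TRUE)
  log_line(con, "pipeline start, seed = ", config$seed,
           ", package faresponse ", as.character(utils::packageVersion("faresponse")))
  files <- character(0)
  keep <- function(path) { files[[length(files) + 1L]] <<- path; path }

  panel <- run_stage("panel", con, {
    if (is.null(config$panel_path)) default_panel() else read_panel_bed(config$panel_path)
  })
  pathway_map <- if (is.null(config$pathway_path)) default_pathway_map() else
    read_tsv(config$pathway_path)

  if (config$simulate) {
    cohort <- run_stage("simulate", con, generate_cohort(config$sim, panel))
    in_dir <- file.path(out_dir, "inputs")
    write_cohort(cohort, in_dir)
    log_line(con, "simulate: ", nrow(cohort$patients), " patients, ",
             nrow(cohort$variants), " variant records written to ", in_dir)
    patients <- cohort$patients
    line1 <- cohort$line1
    variants_raw <- cohort$variants
    db <- cohort$annotation_db
    beta_before <- cohort$beta_before
    beta_after <- cohort$beta_after
    true_model <- cohort$true_model
  } else {
    patients <- run_stage("read_inputs", con, read_tsv(config$cohort_path))
    line1 <- read_tsv(config$line1_path)
    variants_raw <- read_variants(config$maf_path)
    db <- read_tsv(config$annotation_path)
    beta_before <- read_beta_matrix(config$beta_before_path)
    beta_after <- read_beta_matrix(config$beta_after_path)
    true_model <- NULL
  }

  strat <- run_stage("stratify", con, stratify_cohort(patients, config$alpha))
  write_tsv(strat$labels, keep(file.path(out_dir, "stratification.tsv")))
  write_tsv(strat$group_summary, keep(file.path(out_dir, "group_summary.tsv")))
  n_r <- sum(strat$labels$label == "responder", na.rm = TRUE)
  n_n <- sum(strat$labels$label == "non_responder", na.rm = TRUE)
  log_line(con, "stratify: ", n_r, " responders / ", n_n, " non-responders")

  l1 <- run_stage("line1", con,
                  line1_change_analysis(line1, strat$labels, hcy = patients,
                                        alpha = config$alpha))
  write_tsv(l1$table, keep(file.path(out_dir, "line1_table.tsv")))
  write_tsv(l1$relative_change, keep(file.path(out_dir, "line1_relative_change.tsv")))
  if (!is.null(l1$hcy_correlation)) {
    write_tsv(l1$hcy_correlation, keep(file.path(out_dir, "line1_hcy_correlation.tsv")))
  }
  log_line(con, "line1: ", nrow(l1$table), " table rows over ",
           length(unique(l1$table$fraction)), " fractions")

  age <- run_stage("clock", con, {
    if (config$simulate) {
      panel_train <- generate_training_panel(config$sim, true_model,
                                             n = config$n_train)
      model <- train_filtered_clock(panel_train$beta, panel_train$ages,
                                    whitelist = true_model$whitelist,
                                    alpha = config$clock_alpha,
                                    nfolds = config$clock_nfolds,
                                    adult_age = config$sim$adult_age,
                                    seed = derive_seed(config$seed, "folds"))
    } else {
      model <- train_filtered_clock(beta_before,
                                    patients$age_years,
                                    whitelist = rownames(beta_before),
                                    alpha = config$clock_alpha,
                                    nfolds = config$clock_nfolds,
                                    seed = derive_seed(config$seed, "folds"))
    }
    res <- cohort_age_deltas(model, beta_before, beta_after, strat$labels)
    res$model <- model
    res
  })
  write_clock_model(age$model, keep(file.path(out_dir, "clock_model.tsv")))
  write_tsv(age$deltas, keep(file.path(out_dir, "age_deltas.tsv")))
  write_tsv(age$group_summary, keep(file.path(out_dir, "age_group_summary.tsv")))
  log_line(con, "clock: ", age$model$nonzero_count, " non-zero CpGs, mean delta ",
           sprintf("%.2f", age$group_summary$mean_delta[age$group_summary$group == "all"]),
           " years")

  vres <- run_stage("variants", con, {
    pv <- restrict_to_panel(variants_raw, panel)
    split <- classify_by_annotation(pv, db)
    freqs <- carrier_frequency(pv, strat$labels)
    hot <- call_hotspots(freqs, config$node_threshold, config$highlight_in,
                         config$highlight_out)
    graph <- build_pathway_graph(hot, pathway_map)
    resp_ids <- strat$labels$patient_id[!is.na(strat$labels$label) &
                                          strat$labels$label == "responder"]
    sums <- list(
      responder = summarize_mutations(pv[pv$patient_id %in% resp_ids, ]),
      non_responder = summarize_mutations(pv[!(pv$patient_id %in% resp_ids), ]))
    list(panel_variants = pv, split = split, hotspots = hot, graph = graph,
         summaries = sums)
  })
  write_tsv(vres$split$classified, keep(file.path(out_dir, "variants_classified.tsv")))
  write_tsv(vres$split$unclassified, keep(file.path(out_dir, "variants_unclassified.tsv")))
  write_tsv(vres$hotspots, keep(file.path(out_dir, "hotspots.tsv")))
  for (g in names(vres$summaries)) {
    onc <- vres$summaries[[g]]$oncomatrix
    write_tsv(data.frame(gene = rownames(onc), onc, check.names = FALSE),
              keep(file.path(out_dir, paste0("oncomatrix_", g, ".tsv"))))
  }
  write_pathway_graph(vres$graph,
                      keep(file.path(out_dir, "pathway_graph.graphml")),
                      keep(file.path(out_dir, "pathway_graph.dot")))
  log_line(con, "variants: ", nrow(vres$panel_variants), " on-panel records, ",
           nrow(vres$split$classified), " classified, ",
           sum(vres$hotspots$is_highlighted), " highlighted hotspots")

  assoc <- run_stage("associate", con, {
    burden <- burden_matrix(vres$panel_variants,
                            patients = patients$patient_id,
                            panel_genes = unique(panel$gene))
    list(burden = burden,
         non_responder = associate(burden, age$deltas, strat$labels,
                                   group = "non_responder"),
         responder = associate(burden, age$deltas, strat$labels,
                               group = "responder"))
  })
  write_tsv(assoc$burden, keep(file.path(out_dir, "burden.tsv")))
  write_tsv(assoc$non_responder, keep(file.path(out_dir, "association_non_responder.tsv")))
  write_tsv(assoc$responder, keep(file.path(out_dir, "association_responder.tsv")))
  log_line(con, "associate: ", sum(!assoc$non_responder$skipped_constant),
           " genes tested in non-responders")

  report <- structure(list(
    group_sizes = c(responder = n_r, non_responder = n_n),
    biomarkers = list(summary = strat$group_summary, tests = strat$tests),
    labels = strat$labels,
    line1 = l1,
    age = age,
    hotspots = vres$hotspots,
    mutation_summaries = vres$summaries,
    association = assoc[c("non_responder", "responder")],
    files = files), class = "cohort_report")
  log_line(con, "pipeline done: ", length(files), " tables written")
  report
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Cohort report: %d responders / %d non-responders\n",
              x$group_sizes[["responder"]], x$group_sizes[["non_responder"]]))
  all_row <- x$age$group_summary[x$age$group_summary$group == "all", ]
  cat(sprintf("  mean biological-age delta: %.2f years (%d%% decreasing)\n",
              all_row$mean_delta, round(100 * all_row$fraction_decreasing)))
  cat(sprintf("  highlighted hotspots: %d\n", sum(x$hotspots$is_highlighted)))
  invisible(x)
}
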