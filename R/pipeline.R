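#' @title End-to-end pipeline commands
#' @name pipeline
#' @description Wires the modules into the two-stage pipeline behind a
#'   single entry point with subcommands, mirrored by the command-line
#'   script in \code{inst/cli/drugvnn.R}. Every command writes its resolved
#'   configuration next to its artifacts.
NULL

#' Default experiment configuration
#'
#' All of the pipeline's tunables with their reference values: stage-I
#' label thresholds 1000/1200 days, rare-drug minimum support 5,
#' fingerprint length 2048 and radius 2, attention cutoffs 0.05/0.1/0.2 by
#' depth band and 0.15 for the cohort aggregation.
#'
#' @param out_dir Output directory of the run.
#' @param seed Integer seed.
#' @return Named list of configuration values.
#' @export
default_experiment_config <- function(out_dir = "drugvnn_run", seed = 1L) {
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    inputs = list(
      ontology = NULL, annotations = NULL, expression = NULL,
      clinical = NULL, drugs = NULL
    ),
    generator = list(),          # overrides for generator_config()
    n_bits = 2048L, radius = 2L,
    short_max_days = 1000, long_min_days = 1200,
    min_support = 5L,
    val_fraction = 0.2,
    vnn = list(k_term_neurons = 6L, drug_layer_sizes = c(64L, 32L, 4L),
               head_hidden = 16L),
    train = list(learning_rate = 1e-3, batch_size = 64L,
                 max_epochs = 100L, patience = 10L),
    attention_cutoffs = default_attention_cutoffs(),
    min_avg_attention = 0.15
  )
}

.load_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config) else
      jsonlite::read_json(config, simplifyVector = TRUE)
  }
  base <- default_experiment_config()
  merged <- utils::modifyList(base, config)
  .validate_config(merged)
  merged
}

.validate_config <- function(cfg) {
  problems <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  chk(is.numeric(cfg$min_support) && cfg$min_support >= 1,
      "min_support must be >= 1")
  chk(is.numeric(cfg$n_bits) && cfg$n_bits > 0, "n_bits must be positive")
  chk(is.numeric(cfg$val_fraction) && cfg$val_fraction > 0 &&
        cfg$val_fraction < 1, "val_fraction must be in (0,1)")
  chk(cfg$short_max_days <= cfg$long_min_days,
      "short_max_days must be <= long_min_days")
  chk(all(vapply(cfg$attention_cutoffs, is.numeric, logical(1))),
      "attention_cutoffs must be numeric")
  if (length(problems)) {
    stop("invalid configuration: ", paste(problems, collapse = "; "))
  }
  invisible(cfg)
}

.run_dir <- function(cfg, sub) {
  d <- file.path(cfg$out_dir, sub)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

.log_config <- function(cfg, dir) {
  jsonlite::write_json(cfg, file.path(dir, "config_resolved.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
}

#' Run a pipeline command
#'
#' @param command One of \code{simulate} (write synthetic inputs),
#'   \code{prepare} (cohorts, fingerprints, filtered pairs), \code{train}
#'   (both stages with knowledge transfer), \code{interpret} (attention
#'   reports and aggregation), \code{select} (per-patient optimal drugs and
#'   cohort summary), \code{report} (one text summary), or \code{all}.
#' @param config A configuration list (see
#'   [default_experiment_config()]) or a path to a JSON/YAML file of
#'   overrides.
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(command = c("all", "simulate", "prepare", "train",
                                     "interpret", "select", "report"),
                         config = list()) {
  command <- match.arg(command)
  cfg <- .load_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  .log_config(cfg, cfg$out_dir)
  steps <- if (command == "all") {
    c("simulate", "prepare", "train", "interpret", "select", "report")
  } else command
  for (s in steps) {
    switch(s,
      simulate = .cmd_simulate(cfg),
      prepare = .cmd_prepare(cfg),
      train = .cmd_train(cfg),
      interpret = .cmd_interpret(cfg),
      select = .cmd_select(cfg),
      report = .cmd_report(cfg)
    )
  }
  invisible(cfg$out_dir)
}

.cmd_simulate <- function(cfg) {
  gcfg <- do.call(generator_config,
                  utils::modifyList(list(seed = cfg$seed), cfg$generator))
  ont <- generate_toy_ontology(gcfg)
  coh <- generate_cohort(ont, gcfg)
  d <- .run_dir(cfg, "data")
  write_synthetic_dataset(ont, coh, d)
  message("simulate: wrote synthetic inputs to ", d)
  invisible(d)
}

.resolve_inputs <- function(cfg) {
  d <- file.path(cfg$out_dir, "data")
  defaults <- list(ontology = file.path(d, "ontology.obo"),
                   annotations = file.path(d, "annotations.tsv"),
                   expression = file.path(d, "expression.tsv"),
                   clinical = file.path(d, "clinical.tsv"),
                   drugs = file.path(d, "drugs.tsv"))
  for (nm in names(defaults)) {
    if (is.null(cfg$inputs[[nm]])) cfg$inputs[[nm]] <- defaults[[nm]]
    if (!file.exists(cfg$inputs[[nm]])) {
      stop("missing input file: ", cfg$inputs[[nm]])
    }
  }
  cfg
}

.cmd_prepare <- function(cfg) {
  cfg <- .resolve_inputs(cfg)
  dag <- parse_obo(cfg$inputs$ontology)
  ann <- read_annotations(cfg$inputs$annotations)
  expr <- read_expression(cfg$inputs$expression)
  dag <- annotate_and_prune(dag, ann, rownames(expr))
  validate_ontology(dag)
  clinical <- read_clinical(cfg$inputs$clinical)
  lib <- read_drug_library(cfg$inputs$drugs, cfg$n_bits, cfg$radius)
  d1 <- prepare_training_data(
    expr, clinical, lib, dag, "stage1", cfg$n_bits, cfg$radius,
    cfg$val_fraction, cfg$seed, cfg$min_support,
    short_max_days = cfg$short_max_days, long_min_days = cfg$long_min_days)
  d2 <- prepare_training_data(
    expr, clinical, lib, dag, "stage2", cfg$n_bits, cfg$radius,
    cfg$val_fraction, cfg$seed + 1L, cfg$min_support)
  d <- .run_dir(cfg, "prepared")
  if (!is.null(d2$removed) && nrow(d2$removed)) {
    utils::write.table(d2$removed, file.path(d, "removed_drugs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  saveRDS(list(dag = dag, stage1 = d1, stage2 = d2, lib = lib),
          file.path(d, "prepared.rds"))
  message("prepare: stage1 ", nrow(d1$train$X), "/", nrow(d1$val$X),
          " train/val pairs; stage2 ", nrow(d2$train$X), "/",
          nrow(d2$val$X))
  invisible(d)
}

.cmd_train <- function(cfg) {
  prep <- readRDS(file.path(cfg$out_dir, "prepared", "prepared.rds"))
  vcfg <- do.call(vnn_config,
                  utils::modifyList(
                    list(n_bits = cfg$n_bits, seed = cfg$seed), cfg$vnn))
  tcfg <- do.call(train_config,
                  utils::modifyList(list(seed = cfg$seed), cfg$train))
  s1 <- train_stage1(build_model(prep$dag, vcfg, "stage1"),
                     prep$stage1$train, prep$stage1$val, tcfg)
  s2 <- transfer_and_train_stage2(s1, prep$stage2$train, prep$stage2$val,
                                  tcfg)
  d <- .run_dir(cfg, "models")
  utils::write.table(s1$history, file.path(d, "stage1_history.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(s2$history, file.path(d, "stage2_history.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  saveRDS(list(stage1 = s1, stage2 = s2), file.path(d, "models.rds"))
  message(sprintf(
    "train: stage1 best val accuracy %.3f; stage2 best val Pearson r %.3f",
    s1$best_metric, s2$best_metric))
  invisible(d)
}

.cmd_interpret <- function(cfg) {
  prep <- readRDS(file.path(cfg$out_dir, "prepared", "prepared.rds"))
  fits <- readRDS(file.path(cfg$out_dir, "models", "models.rds"))
  model <- fits$stage2$model
  patients <- unique(prep$stage2$val$pairs$patient_id)
  reports <- lapply(patients, function(p) {
    r <- forward_encoder(model, prep$stage2$std[model$gene_order, p])
    flag_discriminating_terms(r$report, cfg$attention_cutoffs)
  })
  d <- .run_dir(cfg, "interpret")
  per_pat <- do.call(rbind, Map(function(r, p) {
    cbind(patient_id = p, r)
  }, reports, patients))
  utils::write.table(per_pat, file.path(d, "attention_per_patient.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  agg <- aggregate_attention(reports, cfg$min_avg_attention)
  utils::write.table(agg, file.path(d, "attention_aggregated.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message("interpret: ", nrow(agg), " term(s) with mean attention >= ",
          cfg$min_avg_attention)
  invisible(d)
}

.cmd_select <- function(cfg) {
  prep <- readRDS(file.path(cfg$out_dir, "prepared", "prepared.rds"))
  fits <- readRDS(file.path(cfg$out_dir, "models", "models.rds"))
  model <- fits$stage2$model
  # library restricted to drugs retained by the support filter
  kept_drugs <- sort(unique(prep$stage2$pairs$drug))
  lib <- prep$lib
  lib$fingerprints <- lib$fingerprints[kept_drugs, , drop = FALSE]
  vp <- prep$stage2$val$pairs
  first_pair <- vp[!duplicated(vp$patient_id), , drop = FALSE]
  results <- lapply(seq_len(nrow(first_pair)), function(i) {
    select_optimal_drug(
      model, prep$stage2$std[model$gene_order, first_pair$patient_id[i]],
      lib,
      patient_id = first_pair$patient_id[i],
      prescribed_drug = first_pair$drug[i],
      observed_months = exp(first_pair$label[i]))
  })
  summ <- cohort_improvement_stats(results)
  d <- .run_dir(cfg, "select")
  tab <- do.call(rbind, lapply(results, function(r) {
    data.frame(patient_id = r$patient_id, prescribed = r$prescribed_drug,
               observed_months = r$observed_months,
               optimal_drug = r$optimal_drug,
               predicted_optimal_months = r$predicted_optimal_months,
               improved = r$improved,
               relative_improvement = r$relative_improvement)
  }))
  utils::write.table(tab, file.path(d, "drug_selection.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(summ), file.path(d, "improvement_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  message(sprintf(
    "select: %.1f%% of patients have a better in-silico alternative",
    100 * summ$fraction_with_better_alternative))
  invisible(d)
}

.cmd_report <- function(cfg) {
  fits <- readRDS(file.path(cfg$out_dir, "models", "models.rds"))
  summ <- jsonlite::read_json(
    file.path(cfg$out_dir, "select", "improvement_summary.json"))
  lines <- c(
    "# drugvnn run summary", "",
    paste0("seed: ", cfg$seed),
    sprintf("stage1 best validation accuracy: %.4f",
            fits$stage1$best_metric),
    sprintf("stage2 best validation Pearson r: %.4f",
            fits$stage2$best_metric),
    sprintf("fraction with better alternative drug: %.4f",
            summ$fraction_with_better_alternative),
    sprintf("median observed months: %.2f", summ$median_observed_months),
    sprintf("median months under optimal drug: %.2f",
            summ$median_optimal_months))
  writeLines(lines, file.path(cfg$out_dir, "summary.md"))
  message("report: wrote ", file.path(cfg$out_dir, "summary.md"))
  invisible(cfg$out_dir)
}
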