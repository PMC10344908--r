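#' @title End-to-end data preparation and scripted experiments
#' @name experiments
#' @description Convenience wiring from raw inputs to training sets, plus
#'   the two scripted experiments: the rare-drug memorization experiment
#'   (random pair-level split, training to convergence, with and without
#'   the support filter) and the two-stage-versus-single-stage knowledge
#'   transfer ablation on a scarce-label regime.
NULL

#' Prepare stage training sets from raw inputs
#'
#' Standardizes expression, builds the requested stage cohort, expands
#' (patient, drug) pairs, splits, optionally applies the rare-drug filter,
#' and assembles columnar training sets.
#'
#' @param expression FPKM-like genes-by-samples matrix.
#' @param clinical Clinical data frame (see [read_clinical()]).
#' @param drug_library Drug library data frame (name, smiles) or the
#'   result of [read_drug_library()].
#' @param dag Pruned annotated \code{ontology_dag}.
#' @param stage \code{"stage1"} or \code{"stage2"}.
#' @param n_bits,radius Fingerprint settings.
#' @param val_fraction,seed Split settings.
#' @param min_support Rare-drug filter threshold; \code{NULL} disables the
#'   filter.
#' @param split_by \code{"patient"} (leakage-safe default) or \code{"pair"}
#'   (the random data-point split that exposes the memorization effect).
#' @param short_max_days,long_min_days Stage-1 label thresholds.
#' @return List with \code{train}, \code{val} (\code{training_set}s),
#'   \code{pairs}, \code{lib}, \code{std} (standardized matrix),
#'   \code{removed} (filtered drugs).
#' @export
prepare_training_data <- function(expression, clinical, drug_library, dag,
                                  stage = c("stage1", "stage2"),
                                  n_bits = 2048L, radius = 2L,
                                  val_fraction = 0.2, seed = 1L,
                                  min_support = 5L,
                                  split_by = c("patient", "pair"),
                                  short_max_days = 1000,
                                  long_min_days = 1200) {
  stage <- match.arg(stage)
  split_by <- match.arg(split_by)
  std <- if (isTRUE(attr(expression, "standardized"))) expression else
    standardize_expression(expression)
  cohort <- if (stage == "stage1") {
    build_stage1_cohort(clinical, short_max_days, long_min_days)
  } else {
    build_stage2_cohort(clinical)
  }
  lib <- if (is.data.frame(drug_library)) {
    read_drug_library(drug_library, n_bits, radius)
  } else drug_library
  pairs <- expand_patient_drug_pairs(cohort, lib)
  if (split_by == "patient") {
    pairs <- split_cohort(pairs, val_fraction, seed)
  } else {
    pairs <- .with_seed(seed, {
      pairs$fold <- ifelse(stats::runif(nrow(pairs)) < val_fraction,
                           "validation", "train")
      pairs
    })
  }
  removed <- NULL
  if (!is.null(min_support)) {
    flt <- filter_rare_drugs(pairs, min_support)
    pairs <- flt$kept
    removed <- flt$removed
  }
  train <- make_training_set(pairs[pairs$fold == "train", , drop = FALSE],
                             std, lib, dag$genes)
  val <- make_training_set(
    pairs[pairs$fold == "validation", , drop = FALSE], std, lib, dag$genes)
  list(train = train, val = val, pairs = pairs, lib = lib, std = std,
       removed = removed)
}

#' Stage-II training from scratch (no knowledge transfer)
#'
#' Used by the scripted experiments; [transfer_and_train_stage2()] is the
#' two-stage path.
#'
#' @param model A \code{vnn_model} built with \code{stage = "stage2"}.
#' @param train,val \code{training_set}s with log-months labels.
#' @param config A [train_config()].
#' @param checkpoint \code{"best"} restores the best-validation weights,
#'   \code{"final"} keeps the last epoch (the convergence protocol of the
#'   memorization experiment).
#' @return A \code{stage_result}.
#' @export
train_stage2 <- function(model, train, val, config = train_config(),
                         checkpoint = c("best", "final")) {
  stopifnot(inherits(model, "vnn_model"), model$stage == "stage2")
  .train_loop(model, train, val, config, checkpoint = match.arg(checkpoint))
}

#' Default generator settings of the memorization experiment
#' @param seed Integer seed.
#' @return A [generator_config()].
#' @export
memorization_generator_config <- function(seed = 1L) {
  # drug-dominated outcome regime: isolates the drug branch so that what a
  # rare drug's single training example can and cannot teach the network
  # is directly visible in the held-out predictions
  generator_config(n_internal_terms = 12L, max_depth = 3L, branching = 3L,
                   n_genes = 120L, n_patients = 300L, n_drugs = 8L,
                   censoring_rate = 0, noise_sd = 0.5,
                   drug_effect_sd = 1, pathway_effect_sd = 0.05,
                   rare_effect_mult = 0.2,
                   rare_drug_injection = c(3L, 4L, 3L, 4L, 3L, 4L),
                   multi_drug_fraction = 0, seed = seed)
}

#' The rare-drug memorization experiment
#'
#' Reproduces, on synthetic data, the pitfall of training with rarely
#' prescribed drugs: with a random pair-level split and training to
#' convergence, the network memorizes the survival of the one or two
#' training patients carrying a rare drug and reproduces it for held-out
#' patients. The experiment trains a months-to-death model with and without
#' the support filter and reports held-out Pearson r for both arms plus the
#' prediction dispersion of the rare drugs relative to the cohort.
#'
#' Each injected rare drug is forced to carry 1-2 training pairs (the rest
#' of its pairs go to validation); all other pairs are split at random.
#'
#' @param seeds Integer vector; one replicate per seed.
#' @param train_cfg Training configuration (default: 40 epochs to
#'   convergence, no early stop).
#' @param min_support Support filter threshold (default 5).
#' @return Data frame with one row per seed: \code{r_before} (no filter),
#'   \code{r_after} (filtered), \code{collapse_ratio} (pooled within-drug
#'   standard deviation of the rare-drug validation predictions divided by
#'   the standard deviation of all validation predictions).
#' @export
memorization_experiment <- function(seeds = 1:10,
                                    train_cfg = NULL,
                                    min_support = 5L) {
  if (is.null(train_cfg)) {
    # convergence protocol: no early stop. Expression inputs keep the
    # usual noise augmentation (the model should generalize over
    # patients, as the full-scale model does); the drug branch is
    # unregularized — drug memorization is the phenomenon under study
    train_cfg <- train_config(max_epochs = 60L, patience = 60L,
                              batch_size = 32L, weight_decay = 0,
                              input_noise_sd = 1.0, seed = 1L)
  }
  rare_train_support <- c(1L, 2L, 1L, 2L, 1L, 2L)
  out <- lapply(seeds, function(s) {
    gcfg <- memorization_generator_config(seed = s)
    ont <- generate_toy_ontology(gcfg)
    coh <- generate_cohort(ont, gcfg)
    std <- suppressWarnings(standardize_expression(coh$expression))
    cohort2 <- build_stage2_cohort(coh$clinical)
    lib <- read_drug_library(coh$drug_library)
    pairs <- expand_patient_drug_pairs(cohort2, lib)
    rare <- coh$ground_truth$rare_drugs
    pairs <- .with_seed(s, {
      fold <- ifelse(stats::runif(nrow(pairs)) < 0.25,
                     "validation", "train")
      for (i in seq_along(rare)) {
        ridx <- which(pairs$drug == rare[i])
        ridx <- ridx[sample.int(length(ridx))]
        n_tr <- min(rare_train_support[i], length(ridx) - 1L)
        fold[ridx] <- "validation"
        fold[ridx[seq_len(n_tr)]] <- "train"
      }
      pairs$fold <- fold
      pairs
    })
    mk <- function(p) {
      list(train = make_training_set(p[p$fold == "train", , drop = FALSE],
                                     std, lib, ont$dag$genes),
           val = make_training_set(
             p[p$fold == "validation", , drop = FALSE],
             std, lib, ont$dag$genes))
    }
    vcfg <- vnn_config(seed = s)
    sets_all <- mk(pairs)
    fit_all <- train_stage2(build_model(ont$dag, vcfg, "stage2"),
                            sets_all$train, sets_all$val, train_cfg,
                            checkpoint = "final")
    pred_val <- predict_training_set(fit_all$model, sets_all$val)
    r_before <- stats::cor(pred_val, sets_all$val$label)
    is_rare <- sets_all$val$pairs$drug %in% rare
    sd_all <- stats::sd(pred_val)
    # pooled within-drug dispersion of the rare-drug predictions (per-drug
    # standard deviations rest on 2-3 points and are individually noisy)
    within <- unlist(lapply(rare, function(d) {
      p_d <- pred_val[sets_all$val$pairs$drug == d]
      if (length(p_d) >= 2L) p_d - mean(p_d) else NULL
    }))
    n_drugs_used <- sum(vapply(rare, function(d) {
      sum(sets_all$val$pairs$drug == d) >= 2L
    }, logical(1)))
    pooled_sd <- sqrt(sum(within^2) / (length(within) - n_drugs_used))
    flt <- suppressMessages(filter_rare_drugs(pairs, min_support))
    sets_flt <- mk(flt$kept)
    fit_flt <- train_stage2(build_model(ont$dag, vcfg, "stage2"),
                            sets_flt$train, sets_flt$val, train_cfg,
                            checkpoint = "final")
    r_after <- stats::cor(predict_training_set(fit_flt$model, sets_flt$val),
                          sets_flt$val$label)
    data.frame(seed = s, r_before = r_before, r_after = r_after,
               collapse_ratio = pooled_sd / sd_all)
  })
  do.call(rbind, out)
}

#' Default generator settings of the knowledge-transfer ablation
#'
#' A scarce-label regime: heavy censoring leaves few deceased patients for
#' the regression stage, while the binary stage can still draw on censored
#' long-lived patients.
#' @param seed Integer seed.
#' @return A [generator_config()].
#' @export
ablation_generator_config <- function(seed = 1L) {
  generator_config(n_internal_terms = 12L, max_depth = 3L, branching = 3L,
                   n_genes = 120L, n_patients = 1500L, n_drugs = 8L,
                   censoring_rate = 0.9, noise_sd = 0.3,
                   multi_drug_fraction = 0, seed = seed)
}

#' Two-stage versus single-stage training ablation
#'
#' For each seed, trains stage I on the binary vital-status cohort, then
#' stage II twice: with encoder weights transferred from stage I, and from
#' random initialization. Reports held-out Pearson r for both arms.
#'
#' @param seeds Integer vector (default 5 replicates).
#' @param stage1_cfg,stage2_cfg Training configurations.
#' @return Data frame with one row per seed: \code{r_two_stage},
#'   \code{r_single_stage}.
#' @export
two_stage_ablation <- function(seeds = 1:5, stage1_cfg = NULL,
                               stage2_cfg = NULL) {
  if (is.null(stage1_cfg)) {
    stage1_cfg <- train_config(max_epochs = 40L, patience = 8L,
                               batch_size = 32L, seed = 1L)
  }
  if (is.null(stage2_cfg)) {
    stage2_cfg <- train_config(max_epochs = 40L, patience = 8L,
                               batch_size = 32L, seed = 1L)
  }
  out <- lapply(seeds, function(s) {
    gcfg <- ablation_generator_config(seed = s)
    ont <- generate_toy_ontology(gcfg)
    coh <- generate_cohort(ont, gcfg)
    lib <- read_drug_library(coh$drug_library)
    d1 <- suppressMessages(prepare_training_data(
      coh$expression, coh$clinical, lib, ont$dag, "stage1", seed = s))
    d2 <- suppressMessages(prepare_training_data(
      coh$expression, coh$clinical, lib, ont$dag, "stage2", seed = s + 1L))
    vcfg <- vnn_config(seed = s)
    s1 <- train_stage1(build_model(ont$dag, vcfg, "stage1"),
                       d1$train, d1$val, stage1_cfg)
    fit_two <- transfer_and_train_stage2(s1, d2$train, d2$val, stage2_cfg)
    fit_one <- transfer_and_train_stage2(s1, d2$train, d2$val, stage2_cfg,
                                         single_stage = TRUE)
    data.frame(seed = s,
               r_two_stage = evaluate(fit_two$model, d2$val),
               r_single_stage = evaluate(fit_one$model, d2$val))
  })
  do.call(rbind, out)
}
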