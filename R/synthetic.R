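#' @title Synthetic cohort generator with planted ground truth
#' @name synthetic
#' @description Generates a complete set of pipeline inputs — ontology,
#'   gene annotations, FPKM-like expression, clinical table with censoring,
#'   and a drug library of real small-molecule SMILES — with a planted
#'   linear expression-to-survival structure plus additive drug effects, so
#'   that recovery of the signal (and of the planted pathway importances)
#'   is testable end to end without any external download.
NULL

# 20 valid small-molecule SMILES (common approved drugs); the generator
# draws library entries from this panel.
.smiles_panel <- c(
  aspirin      = "CC(=O)Oc1ccccc1C(=O)O",
  caffeine     = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
  ibuprofen    = "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
  paracetamol  = "CC(=O)Nc1ccc(O)cc1",
  naproxen     = "COc1ccc2cc(ccc2c1)C(C)C(=O)O",
  gemcitabine  = "NC1=NC(=O)N(C=C1)C1OC(CO)C(O)C1(F)F",
  fluorouracil = "O=c1[nH]cc(F)c(=O)[nH]1",
  methotrexate = "CN(Cc1cnc2nc(N)nc(N)c2n1)c1ccc(cc1)C(=O)NC(CCC(=O)O)C(=O)O",
  tamoxifen    = "CCC(=C(c1ccccc1)c1ccc(OCCN(C)C)cc1)c1ccccc1",
  imatinib     = "Cc1ccc(NC(=O)c2ccc(CN3CCN(C)CC3)cc2)cc1Nc1nccc(n1)-c1cccnc1",
  erlotinib    = "COCCOc1cc2ncnc(Nc3cccc(c3)C#C)c2cc1OCCOC",
  sorafenib    = "CNC(=O)c1cc(Oc2ccc(NC(=O)Nc3ccc(Cl)c(c3)C(F)(F)F)cc2)ccn1",
  paclitaxel   = "CC1=C2C(C(=O)C3(C(CC4C(C3C(C(C2(C)C)(CC1OC(=O)C(C(c1ccccc1)NC(=O)c1ccccc1)O)O)OC(=O)c1ccccc1)(CO4)OC(C)=O)O)C)OC(C)=O",
  cisplatin_l  = "NCCN", # ethylenediamine stand-in ligand (synthetic panel)
  carboplatin_l = "OC(=O)C1(CCC1)C(=O)O",
  doxorubicin  = "COc1cccc2c1C(=O)c1c(O)c3CC(O)(CC(OC4CC(N)C(O)C(C)O4)c3c(O)c1C2=O)C(C)=O",
  etoposide_c  = "COc1cc(cc(OC)c1O)C1c2cc3OCOc3cc2C(O)C2C1C(=O)OC2",
  tretinoin    = "CC1=C(C(C)(C)CCC1)C=CC(C)=CC=CC(C)=CC(=O)O",
  vorinostat   = "ONC(=O)CCCCCCC(=O)Nc1ccccc1",
  thalidomide  = "O=C1CCC(N2C(=O)c3ccccc3C2=O)C(=O)N1"
)

#' Generator configuration
#'
#' Defaults define the package's reference study conditions: 2000 patients,
#' 300 genes over 30 internal ontology terms, 12 drugs, residual noise
#' standard deviation 0.3 on the log-months scale.
#'
#' @param n_internal_terms Number of ontology terms including the root.
#' @param max_depth Maximum term depth.
#' @param branching Mean branching factor used to spread terms over levels.
#' @param n_genes Number of genes (must be at least the number of leaf
#'   terms).
#' @param n_patients Number of patients.
#' @param n_drugs Number of regular drugs (at most the size of the packaged
#'   20-SMILES panel, including injected rare drugs).
#' @param censoring_rate Probability a patient is reported alive/censored.
#' @param noise_sd Residual SD of log months-to-death.
#' @param drug_effect_sd SD of per-drug additive effects on log months.
#' @param pathway_effect_sd Magnitude of nonzero planted pathway weights
#'   (applied with random sign, so the signal-to-noise ratio is stable
#'   across seeds).
#' @param active_pathway_fraction Fraction of leaf pathways with nonzero
#'   weight (default 0.5; the rest are exactly zero).
#' @param rare_drug_injection Integer vector: each entry adds one extra
#'   drug prescribed to exactly that many patients.
#' @param rare_effect_mult Multiplier on \code{drug_effect_sd} for injected
#'   rare drugs, giving them outlying effects so that memorization is
#'   detectable (default 3).
#' @param multi_drug_fraction Fraction of patients prescribed two drugs
#'   (tandem therapy; their planted effect is the mean of the two).
#' @param baseline_log_months Baseline \eqn{\mu} of log months-to-death
#'   (default \code{log(27)}, a median survival of 27 months).
#' @param seed Integer seed.
#' @return A \code{generator_config} list.
#' @export
generator_config <- function(n_internal_terms = 30L, max_depth = 4L,
                             branching = 3L, n_genes = 300L,
                             n_patients = 2000L, n_drugs = 12L,
                             censoring_rate = 0.6, noise_sd = 0.3,
                             drug_effect_sd = 0.3,
                             pathway_effect_sd = 1,
                             active_pathway_fraction = 0.5,
                             rare_drug_injection = integer(0),
                             rare_effect_mult = 3,
                             multi_drug_fraction = 0.025,
                             baseline_log_months = log(27),
                             seed = 1L) {
  stopifnot(n_internal_terms >= 2, max_depth >= 1, branching >= 1,
            n_genes >= 1, n_patients >= 2, n_drugs >= 1,
            censoring_rate >= 0, censoring_rate <= 1, noise_sd >= 0,
            drug_effect_sd >= 0, pathway_effect_sd >= 0,
            active_pathway_fraction >= 0, active_pathway_fraction <= 1,
            all(rare_drug_injection >= 1))
  if (n_drugs + length(rare_drug_injection) > length(.smiles_panel)) {
    stop("n_drugs + injected rare drugs exceeds the ",
         length(.smiles_panel), "-SMILES panel")
  }
  structure(as.list(environment()), class = "generator_config")
}

#' Generate a toy ontology with gene annotations
#'
#' Builds a random single-rooted DAG (each term has one primary parent at
#' the previous level and, occasionally, a second parent), annotates every
#' gene to exactly one leaf term, and returns the pruned, annotated DAG
#' together with the raw OBO text and annotation table it round-trips
#' through — the generator emits exactly the formats the pipeline consumes.
#'
#' @param config A [generator_config()].
#' @return List with \code{dag} (pruned \code{ontology_dag}),
#'   \code{annotations} (gene_id/term_id data frame), \code{obo_lines}
#'   (character vector of OBO text), \code{gene_list}.
#' @export
generate_toy_ontology <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  .with_seed(config$seed, {
    n <- config$n_internal_terms
    ids <- sprintf("T:%04d", seq_len(n))
    root <- ids[1L]
    # spread terms over levels 1..max_depth with ~branching growth
    level_sizes <- pmax(1L, round(config$branching^(seq_len(config$max_depth))))
    level_sizes <- pmin(level_sizes, n) # cap
    remaining <- n - 1L
    levels <- list()
    i <- 2L
    for (d in seq_len(config$max_depth)) {
      take <- min(level_sizes[d], remaining)
      if (d == config$max_depth) take <- remaining
      if (take <= 0L) break
      levels[[d]] <- ids[i:(i + take - 1L)]
      i <- i + take
      remaining <- remaining - take
    }
    if (remaining > 0L) stop("infeasible config: branching vs depth")
    parents <- stats::setNames(vector("list", n), ids)
    prev <- root
    for (d in seq_along(levels)) {
      for (t in levels[[d]]) {
        parents[[t]] <- sample(prev, 1L)
        # occasional second parent from any strictly shallower level
        if (d >= 2L && stats::runif(1) < 0.2) {
          shallower <- c(root, unlist(levels[seq_len(d - 1L)]))
          extra <- sample(setdiff(shallower, parents[[t]]), 1L)
          parents[[t]] <- c(parents[[t]], extra)
        }
      }
      prev <- levels[[d]]
    }
    obo <- c("format-version: 1.2", "")
    for (t in ids) {
      obo <- c(obo, "[Term]", paste0("id: ", t),
               paste0("name: synthetic term ", t),
               if (!is.null(parents[[t]]))
                 paste0("is_a: ", parents[[t]]), "")
    }
    has_child <- unique(unlist(parents))
    leaves <- setdiff(ids, has_child)
    if (config$n_genes < length(leaves)) {
      stop("n_genes must be at least the number of leaf terms (",
           length(leaves), ")")
    }
    genes <- sprintf("G%04d", seq_len(config$n_genes))
    # round-robin so every leaf receives at least one gene
    gene_term <- leaves[(seq_len(config$n_genes) - 1L) %% length(leaves) + 1L]
    annotations <- data.frame(gene_id = genes, term_id = gene_term,
                              stringsAsFactors = FALSE)
    obo_file <- tempfile(fileext = ".obo")
    on.exit(unlink(obo_file), add = TRUE)
    writeLines(obo, obo_file)
    dag <- parse_obo(obo_file)
    dag <- suppressMessages(annotate_and_prune(dag, annotations, genes))
    list(dag = dag, annotations = annotations, obo_lines = obo,
         gene_list = genes)
  })
}

#' Generate a synthetic cohort over an ontology
#'
#' Expression is lognormal FPKM-like with genes of one leaf pathway sharing
#' a latent factor; the planted outcome is linear in the per-pathway means
#' of the standardized expression plus an additive drug effect:
#' \deqn{\log m = \mu + \sum_p w_p \bar{s}_p + \beta_{drug} + \epsilon}
#' Censored patients are marked alive with a follow-up drawn uniformly
#' below their death time (a lower bound, as in real registries).
#'
#' @param ont Result of [generate_toy_ontology()].
#' @param config The same [generator_config()].
#' @return List with \code{expression} (FPKM genes-by-patients),
#'   \code{clinical} (data frame), \code{drug_library} (name/smiles data
#'   frame), and \code{ground_truth} (planted weights, effects, latent
#'   outcome and the standardized matrix used to generate it).
#' @export
generate_cohort <- function(ont, config) {
  stopifnot(inherits(config, "generator_config"))
  dag <- ont$dag
  .with_seed(config$seed + 1L, {
    n_pat <- config$n_patients
    genes <- ont$gene_list
    patients <- sprintf("P%05d", seq_len(n_pat))
    pathways <- dag$terms[vapply(dag$terms,
                                 function(t) length(dag$gene_annotations[[t]]) > 0L,
                                 logical(1))]
    # correlated expression: shared latent factor per pathway
    lambda <- 0.8
    Z <- matrix(stats::rnorm(length(genes) * n_pat), length(genes), n_pat,
                dimnames = list(genes, patients))
    Fp <- matrix(stats::rnorm(length(pathways) * n_pat), length(pathways),
                 n_pat, dimnames = list(pathways, patients))
    for (p in pathways) {
      gs <- dag$gene_annotations[[p]]
      Z[gs, ] <- lambda * matrix(Fp[p, ], length(gs), n_pat, byrow = TRUE) +
        sqrt(1 - lambda^2) * Z[gs, , drop = FALSE]
    }
    mu_g <- stats::runif(length(genes), 0, 3)
    fpkm <- exp(mu_g + 0.5 * Z)
    S <- standardize_expression(fpkm)
    path_means <- t(vapply(pathways, function(p) {
      colMeans(S[dag$gene_annotations[[p]], , drop = FALSE])
    }, numeric(n_pat))) # pathways x patients
    if (length(pathways) == 1L) {
      path_means <- matrix(path_means, nrow = 1L,
                           dimnames = list(pathways, patients))
    }
    n_active <- round(length(pathways) * config$active_pathway_fraction)
    w <- stats::setNames(numeric(length(pathways)), pathways)
    active <- sample(pathways, n_active)
    # fixed magnitude, random sign: keeps the planted signal-to-noise ratio
    # stable across seeds (Gaussian weights make it vary several-fold)
    w[active] <- config$pathway_effect_sd *
      sample(c(-1, 1), n_active, replace = TRUE)
    # drug library: regular drugs then injected rare drugs, from the panel
    n_rare <- length(config$rare_drug_injection)
    panel_names <- names(.smiles_panel)
    reg_drugs <- panel_names[seq_len(config$n_drugs)]
    rare_drugs <- if (n_rare)
      panel_names[config$n_drugs + seq_len(n_rare)] else character(0)
    all_drugs <- c(reg_drugs, rare_drugs)
    drug_library <- data.frame(name = all_drugs,
                               smiles = unname(.smiles_panel[all_drugs]),
                               stringsAsFactors = FALSE)
    # injected rare drugs carry strongly adverse effects (emulating
    # salvage-line compounds with much shorter survival); the far-low-tail
    # outcomes are what a memorizing network reproduces verbatim
    beta <- stats::setNames(
      c(stats::rnorm(length(reg_drugs), 0, config$drug_effect_sd),
        -config$rare_effect_mult * config$drug_effect_sd *
          stats::runif(n_rare, 0.8, 1.2)),
      all_drugs)
    # prescription frequencies: mildly skewed across regular drugs
    freq <- (1 / sqrt(seq_along(reg_drugs)))
    assigned <- sample(reg_drugs, n_pat, replace = TRUE,
                       prob = freq / sum(freq))
    drug_list <- as.list(assigned)
    # inject rare drugs: reassign exactly the requested supports
    perm <- sample.int(n_pat)
    cursor <- 1L
    for (r in seq_len(n_rare)) {
      take <- config$rare_drug_injection[r]
      sel <- perm[cursor:(cursor + take - 1L)]
      cursor <- cursor + take
      for (i in sel) drug_list[[i]] <- rare_drugs[r]
    }
    # tandem therapy: a second regular drug for a small fraction
    n_multi <- round(config$multi_drug_fraction * n_pat)
    if (n_multi > 0L && length(reg_drugs) >= 2L) {
      multi_sel <- perm[cursor:min(cursor + n_multi - 1L, n_pat)]
      for (i in multi_sel) {
        second <- sample(setdiff(reg_drugs, drug_list[[i]]), 1L)
        drug_list[[i]] <- c(drug_list[[i]], second)
      }
    }
    beta_eff <- vapply(drug_list, function(d) mean(beta[d]), numeric(1))
    log_months <- config$baseline_log_months +
      drop(w %*% path_means) + beta_eff +
      stats::rnorm(n_pat, 0, config$noise_sd)
    days <- pmax(1, round(exp(log_months) * DAYS_PER_MONTH))
    censored <- stats::runif(n_pat) < config$censoring_rate
    followup <- ifelse(censored,
                       floor(stats::runif(n_pat) * days), NA_real_)
    clinical <- data.frame(
      patient_id = patients,
      vital_status = ifelse(censored, "alive_or_censored", "deceased"),
      days_to_death = ifelse(censored, NA_real_, days),
      days_to_last_followup = followup,
      drugs = vapply(drug_list, paste, character(1), collapse = ";"),
      stringsAsFactors = FALSE
    )
    ground_truth <- list(
      baseline = config$baseline_log_months,
      pathway_weights = w,
      drug_effects = beta,
      noise_sd = config$noise_sd,
      log_months_true = stats::setNames(log_months, patients),
      pathway_means = path_means,
      standardized = S,
      rare_drugs = rare_drugs,
      formula = "log_months = baseline + sum_p w_p * mean_p(standardized expr) + mean(beta[drugs]) + N(0, noise_sd)"
    )
    list(expression = fpkm, clinical = clinical,
         drug_library = drug_library, ground_truth = ground_truth)
  })
}

#' Write a synthetic dataset to pipeline input files
#'
#' Emits ontology.obo, annotations.tsv, expression.tsv, clinical.tsv,
#' drugs.tsv and ground_truth.json under \code{dir}.
#'
#' @param ont Result of [generate_toy_ontology()].
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_synthetic_dataset <- function(ont, cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(ont$obo_lines, file.path(dir, "ontology.obo"))
  utils::write.table(ont$annotations, file.path(dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  expr <- data.frame(gene_id = rownames(cohort$expression),
                     cohort$expression, check.names = FALSE)
  utils::write.table(expr, file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(cohort$drug_library, file.path(dir, "drugs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gt <- cohort$ground_truth
  jsonlite::write_json(
    list(baseline = gt$baseline,
         pathway_weights = as.list(gt$pathway_weights),
         drug_effects = as.list(gt$drug_effects),
         noise_sd = gt$noise_sd, rare_drugs = gt$rare_drugs,
         formula = gt$formula),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an expression TSV written by [write_synthetic_dataset()]
#' @param path TSV with a \code{gene_id} column and one column per sample.
#' @return Numeric genes-by-samples matrix.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}
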