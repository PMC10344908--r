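test_that("toy ontology generation is deterministic and valid", {
  gcfg <- small_gen_config()
  o1 <- generate_toy_ontology(gcfg)
  o2 <- generate_toy_ontology(gcfg)
  expect_identical(o1$obo_lines, o2$obo_lines)
  expect_identical(o1$dag$child_edges, o2$dag$child_edges)
  expect_true(validate_ontology(o1$dag))
  # every gene annotated at least once
  expect_setequal(unique(o1$annotations$gene_id), o1$gene_list)
})

test_that("max_depth 1 yields a star graph", {
  gcfg <- generator_config(n_internal_terms = 5L, max_depth = 1L,
                           branching = 4L, n_genes = 8L, n_patients = 4L,
                           seed = 2L)
  dag <- generate_toy_ontology(gcfg)$dag
  expect_identical(length(dag$child_edges[[dag$root]]), 4L)
  expect_true(all(unlist(dag$depth[setdiff(dag$terms, dag$root)]) == 1L))
})

test_that("generated clinical rows satisfy the record invariants; zero \
censoring means all deceased", {
  gcfg <- small_gen_config(censoring_rate = 0)
  ont <- generate_toy_ontology(gcfg)
  coh <- generate_cohort(ont, gcfg)
  expect_true(all(coh$clinical$vital_status == "deceased"))
  expect_true(all(!is.na(coh$clinical$days_to_death)))
  expect_true(all(coh$expression >= 0)) # FPKM-like
})

test_that("empirical censoring fraction is within 3 SE of the rate", {
  gcfg <- generator_config(n_internal_terms = 8L, max_depth = 2L,
                           branching = 3L, n_genes = 40L,
                           n_patients = 800L, n_drugs = 5L,
                           censoring_rate = 0.4, seed = 21L)
  ont <- generate_toy_ontology(gcfg)
  coh <- generate_cohort(ont, gcfg)
  frac <- mean(coh$clinical$vital_status == "alive_or_censored")
  se <- sqrt(0.4 * 0.6 / 800)
  expect_lt(abs(frac - 0.4), 3 * se)
  # censored follow-up is a lower bound below the latent death time
  cens <- coh$clinical[coh$clinical$vital_status == "alive_or_censored", ]
  expect_true(all(!is.na(cens$days_to_last_followup)))
})

test_that("noiseless single-pathway, single-drug data admit exact linear \
recovery of the planted weights", {
  gcfg <- generator_config(n_internal_terms = 2L, max_depth = 1L,
                           branching = 1L, n_genes = 10L,
                           n_patients = 60L, n_drugs = 1L,
                           censoring_rate = 0, noise_sd = 0,
                           multi_drug_fraction = 0, seed = 5L)
  ont <- generate_toy_ontology(gcfg)
  coh <- generate_cohort(ont, gcfg)
  gt <- coh$ground_truth
  expect_length(gt$pathway_weights, 1L)
  m_p <- drop(gt$pathway_means)
  y <- unname(gt$log_months_true)
  fit <- stats::lm(y ~ m_p)
  expect_equal(unname(stats::coef(fit)[2L]),
               unname(gt$pathway_weights[1L]), tolerance = 1e-6)
  expect_equal(unname(stats::coef(fit)[1L]),
               gt$baseline + unname(gt$drug_effects[1L]), tolerance = 1e-6)
})

test_that("rare drug injection creates exactly the requested supports", {
  gcfg <- small_gen_config(rare_drug_injection = c(1L, 2L))
  ont <- generate_toy_ontology(gcfg)
  coh <- generate_cohort(ont, gcfg)
  rare <- coh$ground_truth$rare_drugs
  expect_length(rare, 2L)
  counts <- vapply(rare, function(d) {
    sum(vapply(strsplit(coh$clinical$drugs, ";"),
               function(x) d %in% x, logical(1)))
  }, numeric(1))
  expect_identical(unname(counts), c(1, 2))
  expect_true(all(rare %in% coh$drug_library$name))
})

test_that("generator files round-trip through the pipeline readers", {
  gcfg <- small_gen_config()
  ont <- generate_toy_ontology(gcfg)
  coh <- generate_cohort(ont, gcfg)
  d <- tempfile("synthdata")
  on.exit(unlink(d, recursive = TRUE))
  write_synthetic_dataset(ont, coh, d)
  dag <- parse_obo(file.path(d, "ontology.obo"))
  ann <- read_annotations(file.path(d, "annotations.tsv"))
  expr <- read_expression(file.path(d, "expression.tsv"))
  clin <- read_clinical(file.path(d, "clinical.tsv"))
  dag <- suppressMessages(annotate_and_prune(dag, ann, rownames(expr)))
  expect_identical(sort(dag$terms), sort(ont$dag$terms))
  expect_identical(dag$genes, ont$dag$genes)
  expect_equal(unname(expr), unname(coh$expression), tolerance = 1e-6)
  expect_identical(clin$patient_id, coh$clinical$patient_id)
})

test_that("labels derived from generated clinical data track the planted \
outcome", {
  ds <- small_dataset()
  c2 <- suppressWarnings(build_stage2_cohort(ds$coh$clinical))
  gt_lm <- ds$coh$ground_truth$log_months_true[c2$patient_id]
  # rounding days to integers perturbs labels only slightly
  expect_gt(stats::cor(c2$label, gt_lm), 0.999)
})

test_that("planted pathways attract higher attention than zero-weight \
pathways after training", {
  act_all <- c()
  inact_all <- c()
  for (s in 1:5) {
    gcfg <- generator_config(n_internal_terms = 14L, max_depth = 2L,
                             branching = 4L, n_genes = 72L,
                             n_patients = 600L, n_drugs = 5L,
                             censoring_rate = 0, multi_drug_fraction = 0,
                             seed = s)
    ont <- generate_toy_ontology(gcfg)
    coh <- generate_cohort(ont, gcfg)
    lib <- read_drug_library(coh$drug_library, n_bits = 256L)
    d2 <- suppressMessages(prepare_training_data(
      coh$expression, coh$clinical, lib, ont$dag, "stage2",
      n_bits = 256L, seed = s, min_support = NULL))
    vcfg <- vnn_config(k_term_neurons = 4L,
                       drug_layer_sizes = c(16L, 8L, 3L),
                       n_bits = 256L, head_hidden = 8L, seed = s)
    fit <- train_stage2(build_model(ont$dag, vcfg, "stage2"),
                        d2$train, d2$val,
                        train_config(max_epochs = 50L, patience = 50L,
                                     batch_size = 32L,
                                     input_noise_sd = 1.0, seed = s))
    w <- coh$ground_truth$pathway_weights
    active <- names(w)[w != 0]
    inactive <- names(w)[w == 0]
    pats <- unique(d2$val$pairs$patient_id)
    att <- sapply(pats, function(p) {
      r <- forward_encoder(fit$model,
                           d2$std[fit$model$gene_order, p])$report
      stats::setNames(r$weight, r$term)[c(active, inactive)]
    })
    m <- rowMeans(att)
    act_all <- c(act_all, m[active])
    inact_all <- c(inact_all, m[inactive])
  }
  wt <- suppressWarnings(
    stats::wilcox.test(act_all, inact_all, alternative = "greater"))
  expect_lt(wt$p.value, 0.05)
})
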