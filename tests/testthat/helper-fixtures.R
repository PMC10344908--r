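# Shared fixtures, generated in code. Heavy objects are memoized so that
# test files can reuse them without repeated generation.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# a 5-term DAG: root R with children A, B; A with child C; B and C share
# child D (multi-parent); genes attached at C, D, and B
write_fixture_obo <- function(path) {
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: T:R", "name: root", "",
    "[Term]", "id: T:A", "name: a", "is_a: T:R", "",
    "[Term]", "id: T:B", "name: b", "is_a: T:R", "",
    "[Term]", "id: T:C", "name: c", "is_a: T:A", "",
    "[Term]", "id: T:D", "name: d", "is_a: T:B", "is_a: T:C", ""
  ), path)
  path
}

fixture_annotations <- function() {
  data.frame(
    gene_id = c("g1", "g2", "g3", "g4", "g5"),
    term_id = c("T:C", "T:D", "T:D", "T:B", "T:C"),
    stringsAsFactors = FALSE
  )
}

fixture_dag <- function() {
  memo("dag5", {
    obo <- tempfile(fileext = ".obo")
    on.exit(unlink(obo))
    write_fixture_obo(obo)
    dag <- parse_obo(obo)
    suppressMessages(annotate_and_prune(dag, fixture_annotations(),
                                        paste0("g", 1:5)))
  })
}

# small generated dataset shared by vnn / train / interpret tests
small_gen_config <- function(seed = 7L, ...) {
  args <- utils::modifyList(
    list(n_internal_terms = 8L, max_depth = 2L, branching = 3L,
         n_genes = 40L, n_patients = 150L, n_drugs = 5L,
         censoring_rate = 0.3, multi_drug_fraction = 0, seed = seed),
    list(...))
  do.call(generator_config, args)
}

small_dataset <- function() {
  memo("small_ds", {
    gcfg <- small_gen_config()
    ont <- generate_toy_ontology(gcfg)
    coh <- generate_cohort(ont, gcfg)
    lib <- read_drug_library(coh$drug_library, n_bits = 256L)
    list(gcfg = gcfg, ont = ont, coh = coh, lib = lib)
  })
}

small_vnn_config <- function(seed = 3L) {
  vnn_config(k_term_neurons = 4L, drug_layer_sizes = c(16L, 8L, 3L),
             n_bits = 256L, head_hidden = 8L, seed = seed)
}

# clinical table covering all stage-1 / stage-2 label cases
fixture_clinical <- function() {
  data.frame(
    patient_id = paste0("P", 1:8),
    vital_status = c("deceased", "deceased", "deceased", "deceased",
                     "alive_or_censored", "alive_or_censored",
                     "alive_or_censored", "deceased"),
    days_to_death = c(999, 1250, 1100, 500, NA, NA, NA, 0),
    days_to_last_followup = c(NA, NA, NA, NA, 1201, 800, 1200, NA),
    drugs = c("d1", "d1;d2", "d1", "d2", "d1", "d2", "d1", "d2"),
    stringsAsFactors = FALSE
  )
}

fp_oracle_script <- function() {
  p <- system.file("tools", "fp_oracle.py", package = "drugvnn")
  if (!nzchar(p)) p <- file.path("..", "..", "inst", "tools", "fp_oracle.py")
  normalizePath(p)
}
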