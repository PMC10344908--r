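test_that("standardization gives per-gene mean 0 / population SD 1", {
  set.seed(1)
  m <- matrix(rexp(50), 5, 10,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  s <- standardize_expression(m)
  expect_lt(max(abs(rowMeans(s))), 1e-6)
  expect_lt(max(abs(sqrt(rowMeans(s^2)) - 1)), 1e-6)
  expect_equal(unname(s["g1", 1:3]),
               unname((m["g1", 1:3] - mean(m["g1", ])) /
                        sqrt(mean((m["g1", ] - mean(m["g1", ]))^2))))
  # z-score example: [1,2,3] -> +-1.2247
  z <- standardize_expression(matrix(c(1, 2, 3), 1, 3,
                                     dimnames = list("g", NULL)))
  expect_equal(unname(z[1, ]), c(-1.224745, 0, 1.224745), tolerance = 1e-6)
})

test_that("constant genes standardize to zero with a warning; double \
standardization and empty input are errors", {
  m <- matrix(c(5, 5, 5, 1, 2, 3), 2, 3, byrow = TRUE,
              dimnames = list(c("gc", "gv"), NULL))
  expect_warning(s <- standardize_expression(m), "constant")
  expect_identical(unname(s["gc", ]), c(0, 0, 0))
  expect_error(standardize_expression(s), "already standardized")
  expect_error(standardize_expression(matrix(numeric(0), 0, 0)), "empty")
})

test_that("stage-1 labels follow the 1000/1200-day thresholds", {
  c1 <- build_stage1_cohort(fixture_clinical())
  lab <- stats::setNames(c1$label, c1$patient_id)
  expect_identical(lab[["P1"]], 0L)  # deceased at 999
  expect_identical(lab[["P2"]], 1L)  # deceased at 1250
  expect_false("P3" %in% names(lab)) # deceased at 1100: gap
  expect_identical(lab[["P4"]], 0L)  # deceased at 500
  expect_identical(lab[["P5"]], 1L)  # censored, follow-up 1201
  expect_false("P6" %in% names(lab)) # censored, follow-up 800
  expect_false("P7" %in% names(lab)) # follow-up exactly 1200: strict >
  expect_identical(attr(c1, "excluded"), 3L)
  expect_warning(build_stage1_cohort(fixture_clinical()[0, ]), "empty")
})

test_that("no patient with gap lower bound is ever labeled", {
  set.seed(42)
  rec <- data.frame(
    patient_id = sprintf("P%03d", 1:200),
    vital_status = sample(c("deceased", "alive_or_censored"), 200, TRUE),
    days_to_death = sample(1:2000, 200, TRUE),
    days_to_last_followup = sample(1:2000, 200, TRUE),
    drugs = "d"
  )
  rec$days_to_death[rec$vital_status != "deceased"] <- NA
  rec$days_to_last_followup[rec$vital_status == "deceased"] <- NA
  c1 <- build_stage1_cohort(rec)
  lb <- ifelse(is.na(rec$days_to_death), rec$days_to_last_followup,
               rec$days_to_death)
  gap <- rec$patient_id[lb >= 1000 & lb <= 1200]
  expect_length(intersect(c1$patient_id, gap), 0L)
  expect_length(intersect(c1$patient_id[c1$label == 0],
                          c1$patient_id[c1$label == 1]), 0L)
})

test_that("clinical invariant violations name the patient", {
  bad <- fixture_clinical()
  bad$days_to_death[1] <- NA
  expect_error(build_stage1_cohort(bad), "P1")
})

test_that("stage-2 cohort keeps exactly deceased patients with positive days", {
  expect_warning(c2 <- build_stage2_cohort(fixture_clinical()), "zero days")
  expect_setequal(c2$patient_id, c("P1", "P2", "P3", "P4"))
  p1 <- c2[c2$patient_id == "P1", ]
  expect_equal(p1$label, log(999 / 30.4375))
})

test_that("day/log-month conversion and round trip", {
  expect_equal(days_to_log_months(30.4375), 0)
  expect_equal(days_to_log_months(913.125), log(30))
  d <- c(1, 37, 913.125, 5000)
  expect_equal(log_months_to_days(days_to_log_months(d)), d,
               tolerance = 1e-9)
  expect_error(days_to_log_months(0), "positive")
  expect_error(days_to_log_months(-5), "positive")
})

test_that("pair expansion: multi-drug patients share an expression vector, \
unknown drugs are dropped and counted", {
  cohort <- data.frame(patient_id = c("A", "B", "C"),
                       label = c(0, 1, 1),
                       drugs = c("d1;d2", "unknown_drug", "d1"))
  lib <- list(table = data.frame(name = c("d1", "d2"),
                                 smiles = c("C", "CC")))
  pairs <- NULL
  expect_message(pairs <- expand_patient_drug_pairs(cohort, lib), "dropped")
  expect_identical(nrow(pairs), 3L)
  expect_identical(pairs$drug[pairs$patient_id == "A"], c("d1", "d2"))
  expect_false("B" %in% pairs$patient_id)
  expect_identical(attr(pairs, "dropped_pairs"), 1L)
  # every cohort patient with >= 1 matched drug contributes >= 1 example
  expect_setequal(unique(pairs$patient_id), c("A", "C"))
})

test_that("patient-level split is deterministic, disjoint and stratified", {
  set.seed(99)
  pairs <- data.frame(
    patient_id = rep(sprintf("P%02d", 1:30), each = 2),
    drug = "d",
    label = rep(rep(c(0, 1), c(15, 15)), each = 2)
  )
  s1 <- split_cohort(pairs, 0.2, seed = 4L)
  s2 <- split_cohort(pairs, 0.2, seed = 4L)
  expect_identical(s1, s2)
  tr_p <- unique(s1$patient_id[s1$fold == "train"])
  va_p <- unique(s1$patient_id[s1$fold == "validation"])
  expect_length(intersect(tr_p, va_p), 0L)
  expect_length(va_p, 6L)
  # stratification: 3 validation patients per class (15 * 0.2)
  lab_of <- s1$label[match(va_p, s1$patient_id)]
  expect_identical(sum(lab_of == 0), 3L)
  expect_error(split_cohort(pairs, 1.5), "val_fraction")
  expect_error(split_cohort(pairs[1:2, ], 0.2), "2 distinct")
})

test_that("clinical TSV round-trips through read_clinical", {
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f))
  utils::write.table(fixture_clinical(), f, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  back <- read_clinical(f)
  expect_identical(back$patient_id, fixture_clinical()$patient_id)
  expect_identical(back$days_to_death, fixture_clinical()$days_to_death)
  expect_error(read_clinical(data.frame(patient_id = "x")), "columns")
})
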