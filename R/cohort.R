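#' @title Cohort construction: labels, standardization, pairs, splits
#' @name cohort
#' @description Turns the clinical table, expression matrix and drug library
#'   into training examples (expression vector, drug fingerprint, label).
#'   Stage I uses censoring-aware binary vital-status labels; stage II uses
#'   log months-to-death of deceased patients only.
NULL

DAYS_PER_MONTH <- 365.25 / 12 # 30.4375

#' Convert days to log months-to-death
#' @param days Positive survival time in days.
#' @return \code{log(days / 30.4375)} (natural log).
#' @export
days_to_log_months <- function(days) {
  if (any(!is.finite(days)) || any(days <= 0)) {
    stop("days must be positive")
  }
  log(days / DAYS_PER_MONTH)
}

#' Inverse of [days_to_log_months()]
#' @param log_months Log months-to-death.
#' @return Days.
#' @export
log_months_to_days <- function(log_months) {
  exp(log_months) * DAYS_PER_MONTH
}

#' Per-gene z-score standardization of an expression matrix
#'
#' Each gene row is centered and scaled by its population standard
#' deviation across samples. Constant genes are set to all-zero (with a
#' warning) rather than dropped, keeping the encoder input dimension stable
#' across cohorts. Standardizing an already standardized matrix is an error.
#'
#' @param m Numeric genes-by-samples matrix (FPKM-like, nonnegative), with
#'   gene ids as row names and sample ids as column names.
#' @return The standardized matrix with attribute \code{standardized = TRUE}.
#' @export
standardize_expression <- function(m) {
  if (!is.matrix(m) || !nrow(m) || !ncol(m)) stop("empty expression matrix")
  if (isTRUE(attr(m, "standardized"))) {
    stop("expression matrix is already standardized")
  }
  mu <- rowMeans(m)
  centered <- m - mu
  sd_pop <- sqrt(rowMeans(centered^2))
  const <- sd_pop < 1e-12
  if (any(const)) {
    warning(sum(const), " constant gene(s) standardized to zero: ",
            paste(utils::head(rownames(m)[const], 5L), collapse = ", "))
    sd_pop[const] <- 1
    centered[const, ] <- 0
  }
  out <- centered / sd_pop
  attr(out, "standardized") <- TRUE
  out
}

#' Read a clinical table
#'
#' @param path TSV with columns \code{patient_id}, \code{vital_status}
#'   (\code{deceased} or \code{alive_or_censored}), \code{days_to_death},
#'   \code{days_to_last_followup} (empty/NA when absent), and \code{drugs}
#'   (semicolon-separated drug names); or a data frame with those columns.
#' @return Data frame with those columns, \code{drugs} kept as a string.
#' @export
read_clinical <- function(path) {
  df <- if (is.data.frame(path)) path else
    utils::read.delim(path, stringsAsFactors = FALSE,
                      na.strings = c("NA", ""))
  need <- c("patient_id", "vital_status", "days_to_death",
            "days_to_last_followup", "drugs")
  if (!all(need %in% names(df))) {
    stop("clinical table must have columns: ", paste(need, collapse = ", "))
  }
  df$days_to_death <- as.numeric(df$days_to_death)
  df$days_to_last_followup <- as.numeric(df$days_to_last_followup)
  df
}

.check_clinical_invariants <- function(records) {
  dead <- records$vital_status == "deceased"
  bad <- which(dead & is.na(records$days_to_death))
  if (length(bad)) {
    stop("deceased patient without days_to_death: ",
         records$patient_id[bad[1L]])
  }
  bad <- which(!dead & is.na(records$days_to_last_followup))
  if (length(bad)) {
    stop("censored patient without days_to_last_followup: ",
         records$patient_id[bad[1L]])
  }
  invisible(TRUE)
}

#' Build the stage-I binary vital-status cohort
#'
#' Short-lived (\code{y = 0}): deceased with days-to-death strictly below
#' \code{short_max_days}. Long-lived (\code{y = 1}): survival lower bound
#' (days-to-death or days-to-last-follow-up) strictly above
#' \code{long_min_days}, which admits censored patients. Patients in the
#' gap are excluded.
#'
#' @param records Clinical data frame (see [read_clinical()]).
#' @param short_max_days Upper day bound for the short-lived class
#'   (default 1000).
#' @param long_min_days Lower day bound for the long-lived class
#'   (default 1200).
#' @return Data frame \code{patient_id}, \code{label} (0/1), \code{drugs};
#'   exclusion counts attached as attribute \code{excluded}.
#' @export
build_stage1_cohort <- function(records, short_max_days = 1000,
                                long_min_days = 1200) {
  stopifnot(short_max_days <= long_min_days)
  if (!nrow(records)) {
    warning("empty clinical record list")
    return(data.frame(patient_id = character(0), label = integer(0),
                      drugs = character(0)))
  }
  .check_clinical_invariants(records)
  dead <- records$vital_status == "deceased"
  lower_bound <- ifelse(dead, records$days_to_death,
                        records$days_to_last_followup)
  y0 <- dead & records$days_to_death < short_max_days
  y1 <- lower_bound > long_min_days
  keep <- y0 | y1
  out <- data.frame(patient_id = records$patient_id[keep],
                    label = as.integer(y1[keep]),
                    drugs = records$drugs[keep],
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- sum(!keep)
  out
}

#' Build the stage-II months-to-death regression cohort
#'
#' Only deceased patients with an exact positive days-to-death enter;
#' labels are natural-log months-to-death.
#'
#' @param records Clinical data frame (see [read_clinical()]).
#' @return Data frame \code{patient_id}, \code{label} (log months),
#'   \code{drugs}.
#' @export
build_stage2_cohort <- function(records) {
  if (!nrow(records)) {
    return(data.frame(patient_id = character(0), label = numeric(0),
                      drugs = character(0)))
  }
  .check_clinical_invariants(records)
  dead <- records$vital_status == "deceased"
  zero_day <- dead & records$days_to_death <= 0
  if (any(zero_day)) {
    warning(sum(zero_day), " deceased patient(s) with zero days-to-death ",
            "excluded")
  }
  keep <- dead & records$days_to_death > 0
  data.frame(patient_id = records$patient_id[keep],
             label = days_to_log_months(records$days_to_death[keep]),
             drugs = records$drugs[keep],
             stringsAsFactors = FALSE)
}

#' Expand patients into (patient, drug) training pairs
#'
#' A patient prescribed several drugs (tandem or combination therapy)
#' contributes one data point per drug, all sharing the same transcriptome.
#' Drugs absent from the library are dropped and counted.
#'
#' @param cohort Labeled cohort from [build_stage1_cohort()] or
#'   [build_stage2_cohort()].
#' @param drug_library Result of [read_drug_library()] (or its
#'   \code{table}).
#' @return Data frame \code{patient_id}, \code{drug}, \code{label};
#'   attribute \code{dropped_pairs} counts pairs lost to missing drugs.
#' @export
expand_patient_drug_pairs <- function(cohort, drug_library) {
  lib <- if (is.data.frame(drug_library)) drug_library else
    drug_library$table
  known <- lib$name
  rows <- vector("list", nrow(cohort))
  dropped <- 0L
  for (i in seq_len(nrow(cohort))) {
    drugs <- strsplit(cohort$drugs[i], ";", fixed = TRUE)[[1L]]
    drugs <- trimws(drugs[nzchar(trimws(drugs))])
    in_lib <- drugs %in% known
    dropped <- dropped + sum(!in_lib)
    if (any(in_lib)) {
      rows[[i]] <- data.frame(patient_id = cohort$patient_id[i],
                              drug = drugs[in_lib],
                              label = cohort$label[i],
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(patient_id = character(0), drug = character(0),
                      label = numeric(0))
  }
  if (dropped) {
    message(dropped, " (patient, drug) pair(s) dropped: drug not in library")
  }
  attr(out, "dropped_pairs") <- dropped
  rownames(out) <- NULL
  out
}

#' Patient-level stratified train/validation split
#'
#' All pairs of a patient land in the same fold, preventing transcriptome
#' leakage across folds. Stratification is by label for binary cohorts and
#' by label quartile for continuous ones; the split is deterministic given
#' the seed (the global RNG state is restored on exit).
#'
#' @param pairs Pair data frame from [expand_patient_drug_pairs()].
#' @param val_fraction Fraction of patients in the validation fold,
#'   in (0, 1); default 0.2.
#' @param seed Integer seed.
#' @return \code{pairs} with an added \code{fold} column
#'   (\code{"train"}/\code{"validation"}).
#' @export
split_cohort <- function(pairs, val_fraction = 0.2, seed = 1L) {
  if (!is.numeric(val_fraction) || val_fraction <= 0 || val_fraction >= 1) {
    stop("val_fraction must be in (0, 1)")
  }
  patients <- unique(pairs$patient_id)
  if (length(patients) < 2L) stop("need at least 2 distinct patients")
  # patient-level label (identical across a patient's pairs)
  lab <- pairs$label[match(patients, pairs$patient_id)]
  strata <- if (all(lab %in% c(0, 1))) {
    factor(lab)
  } else {
    cut(lab, breaks = unique(stats::quantile(lab, probs = seq(0, 1, 0.25))),
        include.lowest = TRUE)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  val_patients <- character(0)
  for (s in levels(strata)) {
    ps <- patients[strata == s]
    n_val <- round(length(ps) * val_fraction)
    if (length(ps) >= 2L && n_val == 0L) n_val <- 1L
    val_patients <- c(val_patients, sample(ps, n_val))
  }
  pairs$fold <- ifelse(pairs$patient_id %in% val_patients,
                       "validation", "train")
  pairs
}

#' Assemble a training set from pairs, expression and fingerprints
#'
#' Columnar layout consumed by the network: standardized expression rows
#' and fingerprint rows per pair, plus the label vector.
#'
#' @param pairs Pair data frame (with or without a \code{fold} column).
#' @param expression Standardized genes-by-samples matrix.
#' @param drug_library Result of [read_drug_library()].
#' @param gene_order Character vector fixing the gene order expected by the
#'   encoder (the pruned DAG's annotated genes).
#' @return A \code{training_set}: list with \code{X} (pairs-by-genes),
#'   \code{FP} (pairs-by-bits), \code{label}, \code{pairs}.
#' @export
make_training_set <- function(pairs, expression, drug_library, gene_order) {
  if (!isTRUE(attr(expression, "standardized"))) {
    stop("expression must be standardized first")
  }
  missing_genes <- setdiff(gene_order, rownames(expression))
  if (length(missing_genes)) {
    stop("expression matrix lacks gene(s): ",
         paste(utils::head(missing_genes, 5L), collapse = ", "))
  }
  missing_pat <- setdiff(pairs$patient_id, colnames(expression))
  if (length(missing_pat)) {
    stop("expression matrix lacks patient(s): ",
         paste(utils::head(missing_pat, 5L), collapse = ", "))
  }
  X <- t(expression[gene_order, pairs$patient_id, drop = FALSE])
  FP <- drug_library$fingerprints[pairs$drug, , drop = FALSE]
  structure(list(X = X, FP = FP, label = pairs$label, pairs = pairs),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat("training_set:", nrow(x$X), "pairs,", ncol(x$X), "genes,",
      ncol(x$FP), "fingerprint bits\n")
  invisible(x)
}

# subset a training_set by row index
subset_training_set <- function(ts, idx) {
  structure(list(X = ts$X[idx, , drop = FALSE],
                 FP = ts$FP[idx, , drop = FALSE],
                 label = ts$label[idx],
                 pairs = ts$pairs[idx, , drop = FALSE]),
            class = "training_set")
}
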