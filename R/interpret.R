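#' @title Attention interpretation and in-silico optimal drug selection
#' @name interpret
#' @description Flags the most discriminating ontology terms from attention
#'   weights with depth-banded cutoffs, aggregates attention across
#'   patients, exhaustively scores every library drug per patient to find
#'   the optimal one, and summarizes cohort-level improvement statistics.
NULL

#' Default depth-banded attention cutoffs
#'
#' Terms at depth 0-1 are flagged above 0.05, depth-2 terms above 0.1, and
#' depth-3-and-deeper terms above 0.2 (all strict inequalities). Shallow
#' terms have many siblings competing for softmax mass, hence the lower
#' cutoff.
#' @return Named list with \code{shallow}, \code{mid}, \code{deep}.
#' @export
default_attention_cutoffs <- function() {
  list(shallow = 0.05, mid = 0.1, deep = 0.2)
}

.cutoff_for_depth <- function(depth, cutoffs) {
  ifelse(depth <= 1L, cutoffs$shallow,
         ifelse(depth == 2L, cutoffs$mid, cutoffs$deep))
}

#' Flag the most discriminating terms in an attention report
#'
#' @param report Attention report data frame from [forward_encoder()]
#'   (columns \code{term}, \code{depth}, \code{weight}, ...).
#' @param cutoffs Depth-banded cutoffs, see [default_attention_cutoffs()].
#' @return The report with a logical \code{most_discriminating} column;
#'   flag = weight strictly above the cutoff of the term's depth band.
#' @export
flag_discriminating_terms <- function(report,
                                      cutoffs = default_attention_cutoffs()) {
  stopifnot(all(c("term", "depth", "weight") %in% names(report)))
  if (anyNA(report$depth)) stop("missing depth in attention report")
  cut <- .cutoff_for_depth(report$depth, cutoffs)
  report$most_discriminating <- !is.na(report$weight) & report$weight > cut
  report
}

#' Aggregate attention weights across patients
#'
#' @param reports List of attention reports (one per patient).
#' @param min_avg Minimum mean attention weight to keep a term
#'   (inclusive, default 0.15).
#' @return Data frame \code{term}, \code{depth}, \code{mean_weight},
#'   \code{n_patients} (reports in which the term carries a weight),
#'   sorted by decreasing mean weight (ties by term id).
#' @export
aggregate_attention <- function(reports, min_avg = 0.15) {
  if (!length(reports)) stop("need at least one attention report")
  all_r <- do.call(rbind, reports)
  all_r <- all_r[!is.na(all_r$weight), , drop = FALSE]
  agg <- stats::aggregate(weight ~ term + depth, data = all_r, FUN = mean)
  cnt <- stats::aggregate(weight ~ term, data = all_r, FUN = length)
  names(agg)[names(agg) == "weight"] <- "mean_weight"
  agg$n_patients <- cnt$weight[match(agg$term, cnt$term)]
  agg <- agg[agg$mean_weight >= min_avg, , drop = FALSE]
  agg <- agg[order(-agg$mean_weight, agg$term), , drop = FALSE]
  rownames(agg) <- NULL
  agg[, c("term", "depth", "mean_weight", "n_patients")]
}

#' Exhaustive in-silico optimal drug selection for one patient
#'
#' Scores every drug in the (rare-drug-filtered) library with the stage-II
#' model, back-transforms predictions from log months to months, and
#' selects the drug with the longest predicted survival; ties break
#' lexicographically by drug name.
#'
#' @param model A stage-II \code{vnn_model}.
#' @param expression Standardized expression vector for the patient.
#' @param drug_library Result of [read_drug_library()], restricted to
#'   retained drugs.
#' @param patient_id,prescribed_drug,observed_months Optional metadata; if
#'   observed months are given, improvement statistics are filled in.
#' @return A \code{drug_selection_result}: list with \code{patient_id},
#'   \code{prescribed_drug}, \code{observed_months}, \code{predicted}
#'   (named months vector over the whole library), \code{optimal_drug},
#'   \code{predicted_optimal_months}, \code{improved},
#'   \code{relative_improvement}.
#' @export
select_optimal_drug <- function(model, expression, drug_library,
                                patient_id = NA_character_,
                                prescribed_drug = NA_character_,
                                observed_months = NA_real_) {
  stopifnot(inherits(model, "vnn_model"))
  if (model$stage != "stage2") stop("optimal drug selection needs a stage2 model")
  fps <- drug_library$fingerprints
  if (is.null(fps) || !nrow(fps)) stop("empty drug library")
  X <- .coerce_expression_row(model, expression)
  Xrep <- X[rep(1L, nrow(fps)), , drop = FALSE]
  pred_log <- vnn_forward(model, Xrep, fps, training = FALSE)$pred
  months <- stats::setNames(exp(pred_log), rownames(fps))
  months <- months[order(names(months))] # lexicographic tie-break
  optimal <- names(months)[which.max(months)]
  res <- list(patient_id = patient_id,
              prescribed_drug = prescribed_drug,
              observed_months = observed_months,
              predicted = months,
              optimal_drug = optimal,
              predicted_optimal_months = unname(months[optimal]),
              improved = NA,
              relative_improvement = NA_real_)
  if (!is.na(observed_months)) {
    res$improved <- !is.na(prescribed_drug) && optimal != prescribed_drug &&
      res$predicted_optimal_months > observed_months
    res$relative_improvement <-
      (res$predicted_optimal_months - observed_months) / observed_months
  }
  structure(res, class = "drug_selection_result")
}

#' @export
print.drug_selection_result <- function(x, ...) {
  cat("drug_selection_result:", x$patient_id, "optimal", x$optimal_drug,
      sprintf("(%.1f months predicted)", x$predicted_optimal_months), "\n")
  invisible(x)
}

#' Cohort-level improvement statistics of in-silico drug selection
#'
#' @param results List of \code{drug_selection_result}s with observed
#'   months.
#' @param rel_threshold Relative-improvement threshold (default 0.05).
#' @return A list (\code{cohort_improvement_summary}):
#'   \code{fraction_with_better_alternative} (optimal differs from the
#'   prescription and predicts longer survival than observed),
#'   \code{median_observed_months}, \code{median_optimal_months} (median of
#'   the per-patient best of observed and predicted-optimal),
#'   \code{fraction_relative_improvement_ge_threshold},
#'   \code{max_fold_change}, \code{n_patients}.
#' @export
cohort_improvement_stats <- function(results, rel_threshold = 0.05) {
  obs <- vapply(results, function(r) r$observed_months, numeric(1))
  opt <- vapply(results, function(r) r$predicted_optimal_months, numeric(1))
  pres <- vapply(results, function(r) r$prescribed_drug, character(1))
  optd <- vapply(results, function(r) r$optimal_drug, character(1))
  bad <- is.na(obs) | obs <= 0
  if (any(bad)) {
    warning(sum(bad), " result(s) without positive observed months excluded")
    obs <- obs[!bad]; opt <- opt[!bad]; pres <- pres[!bad]; optd <- optd[!bad]
  }
  if (!length(obs)) stop("no usable drug selection results")
  better <- optd != pres & opt > obs
  rel <- (opt - obs) / obs
  structure(list(
    fraction_with_better_alternative = mean(better),
    median_observed_months = stats::median(obs),
    median_optimal_months = stats::median(pmax(obs, opt)),
    fraction_relative_improvement_ge_threshold =
      mean(better & rel >= rel_threshold),
    max_fold_change = max(opt / obs),
    n_patients = length(obs)
  ), class = "cohort_improvement_summary")
}

#' @export
print.cohort_improvement_summary <- function(x, ...) {
  cat(sprintf(
    paste0("cohort improvement: %.1f%% with better alternative; median ",
           "months %.1f -> %.1f; %.1f%% improve >= threshold; max fold ",
           "change %.2f (n = %d)\n"),
    100 * x$fraction_with_better_alternative, x$median_observed_months,
    x$median_optimal_months,
    100 * x$fraction_relative_improvement_ge_threshold,
    x$max_fold_change, x$n_patients))
  invisible(x)
}

#' Most similar patients by transcriptome cosine similarity
#'
#' Samples are normalized to unit vectors; the query patient is excluded
#' from its own ranking.
#'
#' @param expr Genes-by-samples expression matrix (standardized or raw).
#' @param patient_id Query sample id (must be a column).
#' @param n Number of neighbors to return.
#' @return Data frame \code{patient_id}, \code{similarity}, ranked by
#'   decreasing cosine similarity.
#' @export
nearest_patients <- function(expr, patient_id, n) {
  if (!patient_id %in% colnames(expr)) {
    stop("patient ", patient_id, " not in expression matrix")
  }
  if (ncol(expr) - 1L < n) stop("need at least n other patients")
  norms <- sqrt(colSums(expr^2))
  if (any(norms < 1e-12)) {
    stop("zero-norm expression vector for sample ",
         colnames(expr)[which(norms < 1e-12)[1L]])
  }
  unit <- sweep(expr, 2L, norms, "/")
  sims <- drop(crossprod(unit[, patient_id], unit))
  sims <- sims[names(sims) != patient_id]
  ord <- order(-sims, names(sims))
  data.frame(patient_id = names(sims)[ord][seq_len(n)],
             similarity = unname(sims[ord][seq_len(n)]),
             stringsAsFactors = FALSE)
}
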