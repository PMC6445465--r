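#' Drop a block or named variables from a cohort
#'
#' @param cohort a `cohort_matrix`.
#' @param block block name to remove, or `NULL`.
#' @param variables variable names to remove, or `NULL`.
#' @return A reduced `cohort_matrix` with a matching reduced schema.
#' @export
subset_cohort <- function(cohort, block = NULL, variables = NULL) {
  schema <- schema_drop(cohort$schema, block = block, variables = variables)
  keep <- schema_variables(schema)
  new_cohort_matrix(cohort$values[, keep, drop = FALSE],
                    cohort$missing_mask[, keep, drop = FALSE],
                    schema, true_labels = cohort$true_labels,
                    patient_ids = cohort$patient_ids)
}

rerun_without <- function(cohort, block = NULL, variables = NULL,
                          baseline, n_reps, n_triplet, master_seed,
                          first_layer_size, schedule, target_k) {
  red <- subset_cohort(cohort, block = block, variables = variables)
  z <- preprocess(red)
  rep <- stability_protocol(z, method = "som", target_k = target_k,
                            n_reps = n_reps, n_triplet = n_triplet,
                            master_seed = master_seed,
                            first_layer_size = first_layer_size,
                            schedule = schedule)
  lab <- align_labels(baseline$final_labels, rep$final_labels)
  100 * mean(lab != baseline$final_labels)
}

#' Leave-one-test-out feature importance
#'
#' For each of the schema's test blocks, the block's columns are removed,
#' the full preprocessing and stable clustering procedure is re-run under
#' the identical seed policy (so differences reflect the removed columns,
#' not RNG drift), the result is aligned to the full-matrix baseline, and
#' the percentage of patients whose cluster changed is reported. Requires
#' a stable baseline.
#'
#' @param cohort the full `cohort_matrix`.
#' @param baseline a stable `stability_report` from the full matrix.
#' @param n_reps,n_triplet,master_seed,first_layer_size,schedule the exact
#'   clustering configuration used for the baseline.
#' @return data.frame (`level`, `removed`, `percent_reclassified`), sorted
#'   descending by percentage.
#' @export
leave_one_test_out <- function(cohort, baseline, n_reps = 100L,
                               n_triplet = 3L, master_seed = 0L,
                               first_layer_size = NULL, schedule = NULL) {
  stopifnot(inherits(baseline, "stability_report"))
  if (!baseline$stable) {
    stop("baseline clustering is not stable; importance analysis refused",
         call. = FALSE)
  }
  blocks <- names(cohort$schema$blocks)
  pct <- vapply(blocks, function(b) {
    rerun_without(cohort, block = b, baseline = baseline,
                  n_reps = n_reps, n_triplet = n_triplet,
                  master_seed = master_seed,
                  first_layer_size = first_layer_size, schedule = schedule,
                  target_k = length(unique(baseline$final_labels)))
  }, numeric(1))
  out <- data.frame(level = "test", removed = blocks,
                    percent_reclassified = pct, row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(-out$percent_reclassified, out$removed), , drop = FALSE]
}

#' Gated leave-one-variable-out importance within one block
#'
#' Only admissible for a block whose whole-block removal reclassified at
#' least 20% of patients (the gate); each of the block's variables is then
#' removed singly with the same mechanics as [leave_one_test_out()].
#'
#' @param cohort the full `cohort_matrix`.
#' @param block block name (must pass the gate).
#' @param test_results output of [leave_one_test_out()].
#' @param baseline the stable full-matrix `stability_report`.
#' @param gate minimum test-level percentage required (default 20).
#' @inheritParams leave_one_test_out
#' @return data.frame (`level`, `removed`, `percent_reclassified`), sorted
#'   descending.
#' @export
leave_one_variable_out <- function(cohort, block, test_results, baseline,
                                   n_reps = 100L, n_triplet = 3L,
                                   master_seed = 0L, first_layer_size = NULL,
                                   schedule = NULL, gate = 20) {
  stopifnot(inherits(baseline, "stability_report"))
  if (!baseline$stable) {
    stop("baseline clustering is not stable; importance analysis refused",
         call. = FALSE)
  }
  row <- test_results[test_results$removed == block, ]
  if (nrow(row) != 1L) stop("block '", block, "' not in test results",
                            call. = FALSE)
  if (row$percent_reclassified < gate) {
    stop(sprintf(
      "block '%s' reclassified only %.1f%% at test level (< %g%% gate)",
      block, row$percent_reclassified, gate), call. = FALSE)
  }
  vars <- cohort$schema$blocks[[block]]
  pct <- vapply(vars, function(v) {
    rerun_without(cohort, variables = v, baseline = baseline,
                  n_reps = n_reps, n_triplet = n_triplet,
                  master_seed = master_seed,
                  first_layer_size = first_layer_size, schedule = schedule,
                  target_k = length(unique(baseline$final_labels)))
  }, numeric(1))
  out <- data.frame(level = "variable", removed = vars,
                    percent_reclassified = pct, row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(-out$percent_reclassified, out$removed), , drop = FALSE]
}
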