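#' End-to-end pipeline configuration
#'
#' Numeric defaults follow the study protocol: 500 cluster-evaluation
#' repetitions, 100 consensus repetitions taken 3 times, 20 + 50 training
#' epochs, a 10% stability threshold and a 20% variable-level gate.
#' `reduced = TRUE` scales the repetition counts down (50 evaluation reps,
#' 20 x 3 consensus) for desk-scale runs without touching any scientific
#' default.
#'
#' @param k_range candidate cluster counts.
#' @param n_eval_reps criterion-vote repetitions.
#' @param n_consensus_reps consensus repetitions per protocol block.
#' @param n_triplet protocol repetitions.
#' @param criteria validity criteria to vote with.
#' @param schedule a [som_schedule()] or `NULL` for defaults.
#' @param candidate_sizes list of `(rows, cols)` pairs or `NULL` for
#'   [default_candidate_sizes()].
#' @param master_seed integer master seed; all stage seeds derive from it.
#' @param alpha base significance level before Bonferroni correction.
#' @param stability_threshold discordance fraction below which a result is
#'   stable.
#' @param importance_gate test-level percentage gating variable-level
#'   importance.
#' @param reduced logical; use desk-scale repetition counts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(k_range = 2:10, n_eval_reps = 500L,
                            n_consensus_reps = 100L, n_triplet = 3L,
                            criteria = c("CH", "SI", "Gap", "DB"),
                            schedule = NULL, candidate_sizes = NULL,
                            master_seed = 1L, alpha = 0.05,
                            stability_threshold = 0.10,
                            importance_gate = 20, reduced = FALSE) {
  if (reduced) {
    n_eval_reps <- min(n_eval_reps, 50L)
    n_consensus_reps <- min(n_consensus_reps, 20L)
  }
  structure(
    list(k_range = k_range, n_eval_reps = as.integer(n_eval_reps),
         n_consensus_reps = as.integer(n_consensus_reps),
         n_triplet = as.integer(n_triplet), criteria = criteria,
         schedule = schedule, candidate_sizes = candidate_sizes,
         master_seed = as.integer(master_seed), alpha = alpha,
         stability_threshold = stability_threshold,
         importance_gate = importance_gate, reduced = reduced),
    class = "pipeline_config"
  )
}

#' Choose the cluster count from a set of criterion votes
#'
#' The modal `k` among the decisive criteria (strict-majority votes);
#' falls back to the Calinski-Harabasz mode with a warning when no
#' criterion reaches a majority.
#'
#' @param votes named list of `criterion_vote` objects (must include
#'   `"CH"`).
#' @return Integer cluster count.
#' @export
choose_k <- function(votes) {
  decisive <- Filter(function(v) v$decisive, votes)
  if (length(decisive) == 0L) {
    warning("no criterion vote was decisive; falling back to the CH mode",
            call. = FALSE)
    return(votes[["CH"]]$mode_k)
  }
  ks <- vapply(decisive, function(v) v$mode_k, integer(1))
  tab <- table(ks)
  as.integer(names(tab)[which.max(tab)])
}

#' Run the full phenotyping pipeline on one cohort
#'
#' Preprocesses the cohort (median imputation, z-scores), votes on the
#' cluster count, sizes the first map layer by QE/TE rank-sum, runs the
#' SOM-stack and k-means stability protocols, reports their overlap, and —
#' only when the SOM outcome is stable — runs the leave-one-out importance
#' analyses and the group/symptom statistics.
#'
#' @param cohort a `cohort_matrix`.
#' @param symptoms optional `symptom_table`.
#' @param config a [pipeline_config()].
#' @param do_importance logical; the importance stage re-runs the full
#'   consensus once per removal and dominates runtime.
#' @return A `run_report` list (see elements in the source); fully
#'   regenerable from the cohort and `master_seed`.
#' @export
run_pipeline <- function(cohort, symptoms = NULL, config = pipeline_config(),
                         do_importance = TRUE) {
  z <- preprocess(cohort)
  votes <- run_criterion_votes(z, config$k_range, config$n_eval_reps,
                               config$criteria,
                               seed = config$master_seed + 11L)
  k <- choose_k(votes)
  sizing <- select_map_size(z, config$candidate_sizes, config$schedule,
                            seed = config$master_seed + 23L)
  som <- stability_protocol(z, "som", target_k = k,
                            n_reps = config$n_consensus_reps,
                            n_triplet = config$n_triplet,
                            master_seed = config$master_seed,
                            first_layer_size = sizing$size,
                            schedule = config$schedule,
                            stability_threshold = config$stability_threshold)
  km <- stability_protocol(z, "kmeans", target_k = k,
                           n_reps = config$n_consensus_reps,
                           n_triplet = config$n_triplet,
                           master_seed = config$master_seed + 500000L,
                           stability_threshold = config$stability_threshold)
  overlap <- method_overlap(som$final_labels, km$final_labels)

  importance <- NULL
  stats_out <- NULL
  # the consensus mode can collapse below k groups on clusterless data
  # (every run isolating a different small set); downstream analyses need
  # all k groups represented
  som_degenerate <- length(unique(som$final_labels)) < k
  if (som$stable && !som_degenerate) {
    if (do_importance) {
      tests <- leave_one_test_out(cohort, som,
                                  n_reps = config$n_consensus_reps,
                                  n_triplet = config$n_triplet,
                                  master_seed = config$master_seed,
                                  first_layer_size = sizing$size,
                                  schedule = config$schedule)
      gated <- tests$removed[tests$percent_reclassified >=
                               config$importance_gate]
      vars <- lapply(gated, function(b) {
        leave_one_variable_out(cohort, b, tests, som,
                               n_reps = config$n_consensus_reps,
                               n_triplet = config$n_triplet,
                               master_seed = config$master_seed,
                               first_layer_size = sizing$size,
                               schedule = config$schedule,
                               gate = config$importance_gate)
      })
      importance <- list(tests = tests,
                         variables = do.call(rbind, vars))
    }
    alpha_c <- bonferroni_alpha(config$alpha, cohort$schema$total_variables)
    comparison <- compare_groups(cohort, z, som$final_labels, alpha_c)
    pca <- run_pca(z)
    contrast <- if (!is.null(symptoms)) {
      symptom_contrast(symptoms, som$final_labels)
    }
    stats_out <- list(comparison = comparison, pca = pca,
                      symptom_contrast = contrast,
                      alpha_corrected = alpha_c)
  }

  structure(
    list(votes = votes, chosen_k = k, map_sizing = sizing,
         som = som, kmeans = km, overlap = overlap,
         som_degenerate = som_degenerate,
         importance = importance, stats = stats_out,
         config = config,
         true_label_ari = if (!is.null(cohort$true_labels)) {
           adjusted_rand_index(som$final_labels, cohort$true_labels)
         }),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  chosen k: %d; first layer %dx%d (qe-based)\n",
              x$chosen_k, x$map_sizing$size[1], x$map_sizing$size[2]))
  cat(sprintf("  SOM:     %5.1f%% discordant -> %s%s\n",
              100 * x$som$instability,
              if (x$som$stable) "stable" else "not stable",
              if (isTRUE(x$som_degenerate))
                " (consensus mode collapsed below k groups)" else ""))
  cat(sprintf("  k-means: %5.1f%% discordant -> %s\n",
              100 * x$kmeans$instability,
              if (x$kmeans$stable) "stable" else "not stable"))
  cat(sprintf("  method overlap: %.0f%%\n",
              100 * x$overlap$overlap_fraction))
  if (!is.null(x$true_label_ari)) {
    cat(sprintf("  ARI vs true groups: %.3f\n", x$true_label_ari))
  }
  invisible(x)
}

#' Write the final labels as CSV
#' @param report a `run_report` (or `stability_report`).
#' @param path output CSV path.
#' @param patient_ids optional ids; defaults to `P001`, ...
#' @return `path`, invisibly.
#' @export
write_labels_csv <- function(report, path, patient_ids = NULL) {
  labels <- if (inherits(report, "run_report")) report$som$final_labels
  else report$final_labels
  if (is.null(patient_ids)) {
    patient_ids <- sprintf("P%03d", seq_along(labels))
  }
  utils::write.csv(data.frame(patient_id = patient_ids, label = labels),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize the main report quantities as JSON
#' @param report a `run_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  payload <- list(
    chosen_k = report$chosen_k,
    votes = lapply(report$votes, function(v) {
      list(mode_k = v$mode_k, mode_fraction = v$mode_fraction,
           decisive = v$decisive)
    }),
    first_layer = report$map_sizing$size,
    som = list(instability = report$som$instability,
               stable = report$som$stable,
               group_sizes = as.integer(table(report$som$final_labels))),
    kmeans = list(instability = report$kmeans$instability,
                  stable = report$kmeans$stable),
    overlap_fraction = report$overlap$overlap_fraction,
    true_label_ari = report$true_label_ari,
    master_seed = report$config$master_seed
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
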