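#!/usr/bin/env Rscript
# Cluster both cohorts with the stacked multi-layer SOM and the k-means
# reference, each under the study protocol (mode of 100 repetitions, taken
# three times; stable if < 10% of patients move between the three), then
# compare the two methods.
suppressPackageStartupMessages(library(vestisom))

seed <- if (length(a <- commandArgs(TRUE))) as.integer(a[[1]]) else 1L
dir.create("results", showWarnings = FALSE)

for (scenario in c("default", "blockwide")) {
  cohort <- read_cohort(file.path("results",
                                  sprintf("cohort_%s.csv", scenario)))
  z <- preprocess(cohort)
  k <- as.integer(readLines(file.path("results",
                                      sprintf("chosen_k_%s.txt", scenario))))

  sizing <- select_map_size(z, seed = seed + 23L)
  cat(sprintf("[%s] first layer sized %dx%d by QE/TE rank-sum:\n",
              scenario, sizing$size[1], sizing$size[2]))
  print(round(sizing$table, 4))

  som <- stability_protocol(z, "som", target_k = k, n_reps = 100L,
                            n_triplet = 3L, master_seed = seed,
                            first_layer_size = sizing$size)
  km <- stability_protocol(z, "kmeans", target_k = k, n_reps = 100L,
                           n_triplet = 3L, master_seed = seed + 500000L)
  print(som); print(km)

  ov <- method_overlap(som$final_labels, km$final_labels)
  ari <- adjusted_rand_index(som$final_labels, cohort$true_labels)
  cat(sprintf("  SOM cluster sizes: %s | overlap with k-means: %.0f%% | ARI vs latent groups: %.2f\n",
              paste(table(som$final_labels), collapse = "/"),
              100 * ov$overlap_fraction, ari))

  write_labels_csv(som, file.path("results",
                                  sprintf("labels_som_%s.csv", scenario)),
                   cohort$patient_ids)
  write_labels_csv(km, file.path("results",
                                 sprintf("labels_kmeans_%s.csv", scenario)),
                   cohort$patient_ids)
  jsonlite::write_json(
    list(scenario = scenario, chosen_k = k,
         first_layer = sizing$size,
         som = list(instability = som$instability, stable = som$stable,
                    sizes = as.integer(table(som$final_labels))),
         kmeans = list(instability = km$instability, stable = km$stable),
         overlap_fraction = ov$overlap_fraction,
         ari_vs_latent = ari, master_seed = seed),
    file.path("results", sprintf("stability_%s.json", scenario)),
    auto_unbox = TRUE, digits = NA)

  # representative first-layer map for the U-matrix export
  map <- som_train(som_init(sizing$size[1], sizing$size[2], z,
                            seed = seed + 1018L), z)
  write_grid_tsv(u_matrix(map),
                 file.path("results", sprintf("umatrix_%s.tsv", scenario)))
  cat(sprintf("  first-layer map: qe = %.3f, te = %.3f; U-matrix written\n",
              map$qe, map$te))
}
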