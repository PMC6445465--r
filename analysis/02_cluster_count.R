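#!/usr/bin/env Rscript
# How many clusters do the internal validity criteria recommend?
# 100 repetitions per criterion (each repetition re-clusters by k-means
# from a fresh random start for every candidate k in 2..10); a criterion
# is decisive when one k collects a strict majority of repetitions.
suppressPackageStartupMessages(library(vestisom))

seed <- if (length(a <- commandArgs(TRUE))) as.integer(a[[1]]) else 1L
dir.create("results", showWarnings = FALSE)

for (scenario in c("default", "blockwide")) {
  cohort <- read_cohort(file.path("results",
                                  sprintf("cohort_%s.csv", scenario)))
  z <- preprocess(cohort)
  votes <- run_criterion_votes(z, 2:10, n_reps = 100L,
                                          criteria = c("CH", "SI", "Gap", "DB"),
                                          seed = seed + 11L)
  cat(sprintf("[%s cohort]\n", scenario))
  for (v in votes) {
    cat("  "); print(v)
    write_vote_json(v, file.path("results",
                                 sprintf("vote_%s_%s.json", scenario,
                                         v$criterion)))
  }
  k <- choose_k(votes)
  cat(sprintf("  -> chosen number of clusters: %d\n", k))
  writeLines(as.character(k),
             file.path("results", sprintf("chosen_k_%s.txt", scenario)))
}
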