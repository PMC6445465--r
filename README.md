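# vestisom

Unsupervised phenotyping of concussion patients from wide balance and
vestibular diagnostic batteries, for researchers who want to know whether
a patient matrix — here 96 patients × 53 variables across 8 test blocks
(SOT posturography, static/dynamic visual acuity, video head impulse,
VEMPs, subjective visual vertical, caloric irrigation, fundus
photography, plus sex/age/days since injury) — contains data-driven
patient subgroups, and which tests drive them.

The pipeline is a stacked, multi-layer **batch self-organizing map**:

* one layer is a sheet-shaped hexagonal lattice whose codebook trains by
  the batch rule with an Epanechnikov neighbourhood
  `max(0, 1 − (d/r)²)`, in a rough phase (20 epochs, wide radius) and a
  fine phase (50 epochs, narrow radius); map size is chosen by jointly
  minimizing the quantization error (mean distance to the best-matching
  unit) and the topographic error (fraction of patients whose two nearest
  units are not lattice neighbours);
* each patient's best-matching-unit codebook feeds a strictly smaller
  next layer, until the occupied nodes of the last layer equal the target
  number of clusters;
* the number of clusters comes from a mode-with-majority vote of repeated
  internal validity criteria (Calinski–Harabasz, silhouette, gap,
  Davies–Bouldin) over fresh k-means starts;
* runs are repeated 100×, aligned, and reduced to per-patient modal
  labels; three such consensus rounds must agree on >90% of patients for
  the result to count as **stable** — only then do the leave-one-test-out
  / gated leave-one-variable-out importance analyses and the phenotype
  statistics (Mann–Whitney U with tie-corrected Z and exact small-sample
  path, η² = Z²/N effect sizes, Bonferroni correction, chi-squared/Fisher
  symptom contrasts, varimax-rotated PCA) run.

Because no patient-level data are public, the package ships a first-class
synthetic cohort generator (`generate_cohort()`) that emulates the
battery: two latent groups of 38/58, group separation on the caloric
maximal slow-phase-velocity summaries, the SOT composite and the DVA
acuities (σ = IQR/1.349 around reported medians), 0.85% missingness
(sentinel 9999), occasional 5σ outliers, and a 12-item symptom table with
group-specific prevalences.

## Worked example

```r
library(vestisom)

sim <- generate_cohort(sim_config(effect_spec = blockwide_effect_spec(),
                                  seed = 1))
z   <- preprocess(sim$cohort)          # median-impute, then z-score

vote_best_k(z, 2:10, n_reps = 100, criterion = "CH", seed = 12)
#> <criterion_vote> CH: mode k = 2 (97% of 100 reps), decisive

rep <- stability_protocol(z, "som", target_k = 2, n_reps = 100,
                          n_triplet = 3, master_seed = 1,
                          first_layer_size = c(8, 6))
rep
#> <stability_report> som, 3x100 reps: 0/96 discordant (0.0%) -> stable
table(rep$final_labels)
#>  1  2
#> 57 39
adjusted_rand_index(rep$final_labels, sim$cohort$true_labels)
#> [1] 0.958
```

The vote recommends two clusters; the three-round consensus is stable
(no patient changes groups across the three rounds); the recovered split
(57/39) matches the generator's latent groups almost perfectly.
Removing one test block at a time and re-running the whole consensus
(`leave_one_test_out()`) then shows the clustering hangs on the caloric
block — 37.5% of patients reclassify without it, versus at most 3.1% for
any other block — and `compare_groups()` reports the phenotype contrast
(median [IQR] on the raw scale, Mann–Whitney p, η²) at the
Bonferroni-corrected threshold 0.05/53 ≈ 9.4×10⁻⁴.

This example uses the signal-rich `blockwide_effect_spec()` scenario, in
which the whole caloric block responds to the group difference. Under the
stricter default scenario (`default_effect_spec()`: only the six headline
variables separate the groups, everything else independent noise) the
latent structure is below the detection threshold at n = 96 — the
consensus typically collapses to a degenerate single group and the
importance stage refuses its own gate. The methods vignette
(`vignettes/som-phenotyping.Rmd`) derives why, and what that implies for
batteries with this sample-to-feature ratio.

## The analysis workflow

Numbered drivers under `analysis/` run the study end to end on both
scenarios and write tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R     # cohorts + symptom tables (CSV)
Rscript analysis/02_cluster_count.R       # criterion votes (JSON)
Rscript analysis/03_clustering.R          # SOM + k-means stability, labels, U-matrix
Rscript analysis/04_feature_importance.R  # leave-one-out tables (TSV)
Rscript analysis/05_group_statistics.R    # phenotype contrasts, PCA, symptoms
```

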