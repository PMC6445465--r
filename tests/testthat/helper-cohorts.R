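# Shared fixture builders; everything is generated in code at test time.

# Two Gaussian blobs separated by `sep` standard deviations on every feature.
make_blobs <- function(n1 = 25, n2 = 35, p = 5, sep = 10, seed = 1) {
  g <- rep(1:2, c(n1, n2))
  x <- vestisom:::with_seed(seed, {
    matrix(stats::rnorm((n1 + n2) * p), n1 + n2, p) + sep * (g - 1)
  })
  list(x = x, z = scale(x), g = g)
}

# A 3-block cohort (one strongly separating block, two pure-noise blocks)
# small enough for repeated stability runs in tests.
toy_schema <- function() {
  new_feature_schema(list(
    EffectA = c("ea_1", "ea_2", "ea_3"),
    NoiseB = c("nb_1", "nb_2", "nb_3"),
    NoiseC = c("nc_1", "nc_2", "nc_3")
  ))
}

toy_effect_spec <- function(sep = 8) {
  data.frame(variable = c("ea_1", "ea_2", "ea_3"),
             median_1 = c(0, 0, 0), iqr_1 = c(1.349, 1.349, 1.349),
             median_2 = rep(sep, 3), iqr_2 = c(1.349, 1.349, 1.349),
             stringsAsFactors = FALSE)
}

toy_cohort <- function(seed = 1, n = 40, groups = c(16L, 24L), sep = 8,
                       missing_rate = 0, outlier_rate = 0) {
  cfg <- sim_config(n_patients = n, group_sizes = groups,
                    effect_spec = toy_effect_spec(sep),
                    missing_rate = missing_rate,
                    outlier_rate = outlier_rate, seed = seed)
  generate_cohort(cfg, schema = toy_schema())
}

# Wrap a plain matrix as a zmatrix-like object where handy.
as_z <- function(m) structure(list(values = m), class = "zmatrix")
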