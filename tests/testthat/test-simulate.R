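test_that("default cohort matches the study's shape and is reproducible", {
  cfg <- sim_config(seed = 7L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$cohort$values, b$cohort$values)
  expect_identical(a$cohort$missing_mask, b$cohort$missing_mask)
  expect_identical(a$symptoms$presence, b$symptoms$presence)

  expect_identical(dim(a$cohort$values), c(96L, 53L))
  expect_identical(sum(a$cohort$true_labels == 1L), 38L)
  expect_identical(sum(a$cohort$true_labels == 2L), 58L)
  expect_false(any(a$cohort$values[!a$cohort$missing_mask] == 9999))
  expect_identical(colnames(a$cohort$values),
                   schema_variables(default_schema()))
  expect_identical(colnames(a$symptoms$presence),
                   default_symptom_prevalence()$symptom)
})

test_that("missing_rate = 0 yields a clean mask and config is validated", {
  sim <- generate_cohort(sim_config(missing_rate = 0, seed = 3L))
  expect_false(any(sim$cohort$missing_mask))
  expect_error(sim_config(group_sizes = c(40L, 58L)), "summing")
  expect_error(sim_config(missing_rate = 1), "\\[0, 1\\)")
  expect_error(sim_config(outlier_rate = -0.1), "\\[0, 1\\)")
})

test_that("large cohorts recover the configured group medians within 5%", {
  cfg <- sim_config(n_patients = 2000L, group_sizes = c(792L, 1208L),
                    missing_rate = 0, outlier_rate = 0, seed = 11L)
  sim <- generate_cohort(cfg)
  g <- sim$cohort$true_labels
  eff <- default_effect_spec()
  for (i in seq_len(nrow(eff))) {
    v <- eff$variable[i]
    m1 <- median(sim$cohort$values[g == 1L, v])
    m2 <- median(sim$cohort$values[g == 2L, v])
    expect_lt(abs(m1 - eff$median_1[i]), 0.05 * max(abs(eff$median_1[i]), 1))
    expect_lt(abs(m2 - eff$median_2[i]), 0.05 * max(abs(eff$median_2[i]), 1))
  }
})

test_that("effect_scale = 0 removes the group separation", {
  cfg <- sim_config(n_patients = 2000L, group_sizes = c(792L, 1208L),
                    effect_scale = 0, missing_rate = 0, outlier_rate = 0,
                    seed = 5L)
  sim <- generate_cohort(cfg)
  g <- sim$cohort$true_labels
  v <- sim$cohort$values[, "caloric_mSPV_sum"]
  # both groups share the size-weighted centre of the two medians
  expect_lt(abs(median(v[g == 1L]) - median(v[g == 2L])), 1.5)
})

test_that("simulated symptom prevalences recover their configured values", {
  cfg <- sim_config(n_patients = 2000L, group_sizes = c(792L, 1208L),
                    symptom_missing_rate = 0, seed = 13L)
  sim <- generate_cohort(cfg)
  g <- sim$cohort$true_labels
  sp <- default_symptom_prevalence()
  for (k in seq_len(nrow(sp))) {
    for (grp in 1:2) {
      p0 <- if (grp == 1) sp$prev_1[k] else sp$prev_2[k]
      n_g <- sum(g == grp)
      obs <- mean(sim$symptoms$presence[g == grp, k])
      se <- sqrt(max(p0 * (1 - p0), 1e-12) / n_g)
      expect_lte(abs(obs - p0), max(3 * se, 1e-9))
    }
  }
})

test_that("inject_missing hits the expected rate and never empties a column", {
  sim <- generate_cohort(sim_config(missing_rate = 0, seed = 2L))
  expect_identical(inject_missing(sim$cohort, 0, seed = 1L), sim$cohort)
  expect_error(inject_missing(sim$cohort, 1, seed = 1L), "\\[0, 1\\)")

  # expected masked count 96*53*0.0085 = 43.25 per seed; the mean over
  # seeds must sit within 4 standard errors of the binomial expectation
  counts <- vapply(1:50, function(s) {
    sum(inject_missing(sim$cohort, 0.0085, seed = s)$missing_mask)
  }, numeric(1))
  n_cells <- 96 * 53
  expected <- n_cells * 0.0085
  se <- sqrt(n_cells * 0.0085 * (1 - 0.0085) / 50)
  expect_lt(abs(mean(counts) - expected), 4 * se)

  # 2x2 matrix at rate 0.5: the column guard must always leave one entry
  tiny <- new_cohort_matrix(matrix(1:4, 2, 2), matrix(FALSE, 2, 2),
                            new_feature_schema(list(A = c("v1", "v2"))))
  for (s in 1:300) {
    m <- inject_missing(tiny, 0.5, seed = s)$missing_mask
    expect_true(all(colSums(m) < 2))
  }
})

test_that("outlier injection perturbs single cells at the configured rate", {
  base <- generate_cohort(sim_config(outlier_rate = 0, missing_rate = 0,
                                     seed = 21L))
  # same seed, outliers on: the draws differ only by the added shifts plus
  # the RNG stream consumed by the outlier machinery
  loud <- generate_cohort(sim_config(outlier_rate = 0.5, missing_rate = 0,
                                     seed = 21L))
  z <- preprocess(loud$cohort)
  expect_gt(max(abs(z$values)), 4)  # 5-sigma shifts survive z-scoring
  expect_false(identical(base$cohort$values, loud$cohort$values))
})

test_that("cohort CSV round-trips through the 9999 sentinel", {
  sim <- generate_cohort(sim_config(seed = 17L))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(c(path, paste0(path, ".json"))), add = TRUE)
  write_cohort(sim$cohort, path)
  back <- read_cohort(path)
  expect_identical(back$missing_mask, sim$cohort$missing_mask)
  expect_equal(back$values[!back$missing_mask],
               sim$cohort$values[!sim$cohort$missing_mask], tolerance = 1e-12)
  expect_identical(back$true_labels, sim$cohort$true_labels)

  sy <- tempfile(fileext = ".csv")
  on.exit(unlink(sy), add = TRUE)
  write_symptoms(sim$symptoms, sy)
  back_s <- read_symptoms(sy)
  expect_equal(back_s$presence, sim$symptoms$presence, ignore_attr = TRUE)
})
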