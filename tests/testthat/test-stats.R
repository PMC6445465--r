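test_that("PCA explains collinear data with one component", {
  set.seed(40)
  t <- rnorm(50)
  z <- scale(cbind(t, t))
  p <- run_pca(as_z(z), rotation = "none")
  expect_equal(p$explained_fraction[1], 1, tolerance = 1e-12)
  expect_identical(p$n_retained, 1L)
  expect_equal(sum(p$explained_fraction), 1, tolerance = 1e-12)
})

test_that("PCA reconstructs the input and keeps orthonormal loadings", {
  sim <- generate_cohort(sim_config(seed = 41L))
  z <- preprocess(sim$cohort)
  p <- run_pca(z)
  expect_equal(sum(p$explained_fraction), 1, tolerance = 1e-10)
  expect_true(all(diff(p$explained_fraction) <= 1e-12))
  # unrotated loadings are orthonormal
  expect_equal(crossprod(p$unrotated_loadings),
               diag(ncol(p$unrotated_loadings)),
               tolerance = 1e-8, ignore_attr = TRUE)
  # all-component scores times loadings reconstruct the standardized data
  rec <- p$all_scores %*% t(p$unrotated_loadings)
  expect_equal(rec, z$values, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("varimax rotation separates independent variable blocks", {
  set.seed(42)
  n <- 400
  f1 <- rnorm(n); f2 <- rnorm(n)
  x <- cbind(f1 + 0.33 * rnorm(n), f1 + 0.33 * rnorm(n),
             f2 + 0.33 * rnorm(n), f2 + 0.33 * rnorm(n))
  p <- run_pca(as_z(scale(x)), cum_var = 0.8)
  expect_identical(p$n_retained, 2L)
  L <- abs(p$loadings)
  main <- apply(L, 1L, max)
  cross <- apply(L, 1L, min)
  expect_true(all(main > 0.9))
  expect_true(all(cross < 0.1))
  # rotation preserves each variable's communality over retained components
  sdev <- sqrt(p$explained_fraction[1:2] * ncol(x))
  unrot <- sweep(p$unrotated_loadings[, 1:2], 2L, sdev, "*")
  expect_equal(rowSums(p$loadings^2), rowSums(unrot^2), tolerance = 1e-8)
})

test_that("Mann-Whitney matches the enumerated toy example and identities", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)        # 2 * 1/20 under full enumeration
  expect_identical(r$method, "exact")

  same <- mann_whitney(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$Z, 0)
  expect_equal(same$p, 1)

  set.seed(43)
  a <- rnorm(20); b <- rnorm(25)
  ua <- mann_whitney(a, b)$U
  ub <- mann_whitney(b, a)$U
  expect_equal(ua + ub, 20 * 25)
  expect_error(mann_whitney(numeric(0), b), "non-empty")
})

test_that("Mann-Whitney agrees with wilcox.test on U and normal p", {
  set.seed(44)
  for (i in 1:5) {
    a <- round(rnorm(18), 1)  # rounding induces ties
    b <- round(rnorm(22, 0.3), 1)
    mine <- mann_whitney(a, b)
    ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE,
                                        correct = FALSE))
    expect_equal(mine$U, unname(ref$statistic))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("exact and normal p-values agree within the calibrated bound", {
  set.seed(45)
  worst <- 0
  for (i in 1:200) {
    a <- rnorm(6); b <- rnorm(6)
    e <- mann_whitney(a, b)
    worst <- max(worst, abs(e$p - 2 * pnorm(-abs(e$Z))))
  }
  expect_lt(worst, 0.08)
})

test_that("eta squared and Bonferroni thresholds follow their formulas", {
  expect_equal(as.numeric(eta_squared(3, 100)), 0.09)
  expect_equal(as.numeric(eta_squared(0, 50)), 0)
  expect_equal(as.numeric(eta_squared(sqrt(96), 96)), 1)
  expect_identical(attr(eta_squared(6, 96), "band"), "medium")
  expect_error(eta_squared(1, 0), "positive")

  expect_equal(bonferroni_alpha(0.05, 50), 0.001)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.05, 53), 0.05 / 53)
  expect_error(bonferroni_alpha(0.05, 0), "at least 1")
})

test_that("group comparison flags the strong effect variables only", {
  sim <- generate_cohort(sim_config(seed = 46L, missing_rate = 0,
                                    outlier_rate = 0))
  z <- preprocess(sim$cohort)
  cmp <- compare_groups(sim$cohort, z, sim$cohort$true_labels)
  sig <- cmp$variable[cmp$significant]
  # the three caloric mSPV variables and the SOT composite carry the
  # largest standardized shifts and must reach the corrected threshold
  expect_true(all(c("caloric_mSPV_sum", "caloric_mSPV_30",
                    "caloric_mSPV_44", "sot_cs") %in% sig))
  noise_vars <- setdiff(cmp$variable, default_effect_spec()$variable)
  expect_lte(sum(noise_vars %in% sig), 1)  # expected false flags < 1
  # descriptives stay on the raw scale
  row <- cmp[cmp$variable == "caloric_mSPV_sum", ]
  expect_lt(abs(row$median_1 - 27.6), 6)
  expect_lt(abs(row$median_2 - 50.95), 9)
  expect_true(all(cmp$eta_squared >= 0 & cmp$eta_squared <= 1))
})

test_that("identical groups yield no significance and zero effect sizes", {
  sim <- generate_cohort(sim_config(n_patients = 20L,
                                    group_sizes = c(10L, 10L),
                                    missing_rate = 0, outlier_rate = 0,
                                    seed = 47L))
  dup <- sim$cohort
  dup$values <- rbind(dup$values[1:10, ], dup$values[1:10, ])
  dup$missing_mask <- matrix(FALSE, 20, 53)
  dimnames(dup$missing_mask) <- dimnames(dup$values)
  z <- preprocess(dup)
  cmp <- compare_groups(dup, z, rep(1:2, each = 10))
  expect_false(any(cmp$significant))
  expect_true(all(cmp$eta_squared == 0))
})

test_that("symptom contrast applies the test switch and the 10-point band", {
  pres <- cbind(
    all_or_none = c(rep(TRUE, 10), rep(FALSE, 8)),
    balanced = rep(c(TRUE, FALSE), 9),
    empty = rep(NA, 18)
  )
  st <- structure(list(symptoms = colnames(pres), presence = pres),
                  class = "symptom_table")
  labels <- rep(1:2, c(10, 8))
  expect_warning(out <- symptom_contrast(st, labels), "zero responses")
  expect_identical(nrow(out), 2L)

  # perfect separation with expected cells below 5: the Fisher branch,
  # checked against direct hypergeometric enumeration
  sep <- out[out$symptom == "all_or_none", ]
  expect_identical(sep$test, "fisher")
  expect_equal(sep$p, fisher_oracle(matrix(c(10, 0, 0, 8), 2, 2)),
               tolerance = 1e-12)
  expect_identical(sep$band, "more in group 1")

  bal <- out[out$symptom == "balanced", ]
  expect_identical(bal$band, "similar")

  # larger balanced tables use the chi-squared branch
  set.seed(48)
  big <- structure(list(
    symptoms = "s",
    presence = matrix(rep(c(TRUE, FALSE), c(60, 60))[sample(120)], 120, 1,
                      dimnames = list(NULL, "s"))),
    class = "symptom_table")
  out2 <- symptom_contrast(big, rep(1:2, each = 60))
  expect_identical(out2$test, "chi-squared")
})

test_that("group frequencies near the configured prevalences band correctly", {
  sim <- generate_cohort(sim_config(n_patients = 2000L,
                                    group_sizes = c(792L, 1208L),
                                    symptom_missing_rate = 0, seed = 49L))
  out <- symptom_contrast(sim$symptoms, sim$cohort$true_labels)
  head_row <- out[out$symptom == "headache", ]
  expect_identical(head_row$band, "more in group 1")  # 76% vs 59%
  conc <- out[out$symptom == "difficulty_concentrating", ]
  expect_identical(conc$band, "similar")
})
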