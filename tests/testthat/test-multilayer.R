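test_that("seeded Lloyd k-means finds the optimal small bipartition", {
  x <- matrix(c(0, 0.1, 10, 10.1), 4, 1)
  # brute-force oracle over all 7 bipartitions
  best_ss <- Inf; best_part <- NULL
  for (code in 1:7) {
    part <- as.integer(intToBits(code)[1:4]) + 1L
    if (length(unique(part)) < 2L) next
    ss <- sum(vapply(1:2, function(cl) {
      pts <- x[part == cl, , drop = FALSE]
      sum(sweep(pts, 2, colMeans(pts))^2)
    }, numeric(1)))
    if (ss < best_ss) { best_ss <- ss; best_part <- part }
  }
  for (s in 1:5) {
    got <- lloyd_kmeans(x, 2, seed = s)
    expect_equal(adjusted_rand_index(got, best_part), 1)
  }
  expect_error(lloyd_kmeans(x, 4, seed = 1), "smaller")
})

test_that("k-means output is a Lloyd fixed point and duplicates co-cluster", {
  set.seed(20)
  x <- matrix(rnorm(30 * 3), 30, 3)
  labels <- lloyd_kmeans(x, 3, seed = 2)
  cen <- t(vapply(1:3, function(j) colMeans(x[labels == j, , drop = FALSE]),
                  numeric(3)))
  d2 <- as.matrix(dist(rbind(x, cen)))[1:30, 31:33]
  expect_true(all(labels == apply(d2, 1L, which.min)))

  dup <- rbind(x[1:10, ], x[1:10, ])
  lab <- lloyd_kmeans(dup, 2, seed = 3)
  expect_identical(lab[1:10], lab[11:20])
})

test_that("label alignment undoes permutations, by exhaustive search", {
  expect_identical(align_labels(c(1, 1, 2, 2), c(2, 2, 1, 1)), c(1, 1, 2, 2))
  expect_identical(align_labels(c(1, 1, 2, 2), c(1, 1, 2, 2)), c(1, 1, 2, 2))
  expect_identical(align_labels(c(1, 1, 2, 2, 3, 3), c(3, 3, 1, 1, 2, 2)),
                   c(1, 1, 2, 2, 3, 3))
  expect_error(align_labels(1:3, 1:4), "length")
  # candidate with fewer clusters maps into the reference id space
  expect_identical(align_labels(c(1, 1, 2, 3), c(7, 7, 9, 9)),
                   c(1, 1, 2, 2))
})

test_that("consensus mode is the columnwise majority with ties to 1", {
  runs <- rbind(c(1, 1, 2), c(1, 2, 2), c(1, 1, 2))
  ens <- structure(list(aligned_runs = runs), class = "run_ensemble")
  expect_identical(consensus_mode(ens), c(1L, 1L, 2L))
  one <- structure(list(aligned_runs = runs[1, , drop = FALSE]),
                   class = "run_ensemble")
  expect_identical(consensus_mode(one), c(1L, 1L, 2L))
  tie <- structure(list(aligned_runs = rbind(c(1, 2), c(2, 1))),
                   class = "run_ensemble")
  expect_identical(consensus_mode(tie), c(1L, 1L))
})

test_that("consensus is invariant to run order and to id permutations", {
  blobs <- make_blobs(n1 = 15, n2 = 20, p = 3, sep = 6, seed = 30)
  ens <- run_consensus(blobs$z, "kmeans", 2, n_reps = 10, seed_base = 40)
  # every aligned run is a pure relabeling of its raw run
  for (r in 1:10) {
    expect_equal(adjusted_rand_index(ens$runs[r, ], ens$aligned_runs[r, ]), 1)
  }
  shuffled <- ens
  perm <- c(7, 3, 1, 10, 2, 9, 4, 8, 5, 6)
  shuffled$aligned_runs <- ens$aligned_runs[perm, ]
  expect_identical(consensus_mode(shuffled), ens$mode_labels)

  # flipping ids in a subset of aligned runs then re-aligning changes nothing
  flipped <- ens$runs
  flipped[c(2, 5), ] <- 3L - flipped[c(2, 5), ]
  realigned <- flipped
  for (r in 2:10) realigned[r, ] <- align_labels(flipped[1, ], flipped[r, ])
  expect_equal(adjusted_rand_index(
    apply(realigned, 2, function(col) as.integer(names(which.max(table(col))))),
    ens$mode_labels), 1)
})

test_that("the layer stack recovers well-separated groups exactly", {
  blobs <- make_blobs(n1 = 25, n2 = 35, p = 5, sep = 10, seed = 31)
  st <- train_stack(blobs$z, 2, first_layer_size = c(6, 5), seed = 3)
  expect_equal(adjusted_rand_index(st$final_labels, blobs$g), 1)
  nodes <- vapply(st$sizes, prod, numeric(1))
  expect_true(all(diff(nodes) < 0))  # strictly shrinking layers
  expect_identical(length(unique(st$final_labels)), 2L)
})

test_that("degenerate input raises a stack error rather than crashing", {
  x <- matrix(1, 20, 4)
  expect_error(train_stack(x, 2, first_layer_size = c(2, 2), seed = 1),
               "collapsed|clusters")
  expect_error(train_stack(matrix(rnorm(40), 20, 2), 5,
                           first_layer_size = c(2, 2), seed = 1),
               "at least")
})

test_that("stability protocol is consistent and stable on separated data", {
  blobs <- make_blobs(n1 = 20, n2 = 28, p = 4, sep = 10, seed = 33)
  rep <- stability_protocol(blobs$z, "som", 2, n_reps = 5, n_triplet = 3,
                            master_seed = 9, first_layer_size = c(5, 4))
  expect_identical(rep$n_discordant, 0L)
  expect_true(rep$stable)
  expect_equal(adjusted_rand_index(rep$final_labels, blobs$g), 1)
  expect_identical(rep$stable, rep$instability < 0.10)
  # determinism of the whole protocol under the master seed
  rep2 <- stability_protocol(blobs$z, "som", 2, n_reps = 5, n_triplet = 3,
                             master_seed = 9, first_layer_size = c(5, 4))
  expect_identical(rep2$final_labels, rep$final_labels)
})

test_that("method overlap counts identically labelled patients", {
  a <- rep(1:2, c(40, 60))
  expect_equal(method_overlap(a, a)$overlap_fraction, 1)
  expect_equal(method_overlap(a, c(a[1:76], 3 - a[77:100]))$overlap_fraction,
               0.76)
  expect_equal(method_overlap(a, 3 - a)$overlap_fraction, 1)  # absorbed
  expect_error(method_overlap(a, a[-1]), "length")
  cc <- method_overlap(a, a)$cross_counts
  expect_identical(as.integer(diag(cc)), c(40L, 60L))
})

test_that("adjusted Rand index agrees with the mclust reference", {
  set.seed(21)
  for (i in 1:5) {
    a <- sample(1:3, 40, replace = TRUE)
    b <- sample(1:3, 40, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})
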