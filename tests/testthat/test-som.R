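sub_lattice_schedule <- function(epochs) {
  som_schedule(rough_epochs = epochs, fine_epochs = 0L,
               rough_radius = c(0.4, 0.4))
}

test_that("hexagonal lattice geometry has unit-distance neighbours", {
  pos <- hex_positions(8, 6)
  expect_identical(nrow(pos), 48L)
  d <- as.matrix(dist(pos))
  nn <- apply(d + diag(Inf, 48), 1L, min)
  expect_equal(unname(nn), rep(1, 48), tolerance = 1e-12)
  # interior nodes of a hexagonal lattice have exactly 6 unit neighbours
  counts <- rowSums(abs(d - 1) < 1e-9)
  expect_identical(max(counts), 6)
  expect_equal(unname(pos[7, "y"]), sqrt(3) / 2)  # second row pitch
})

test_that("Epanechnikov neighbourhood has the right shape and support", {
  expect_equal(ep_neighbourhood(0, 2), 1)
  expect_equal(ep_neighbourhood(2, 2), 0)
  expect_equal(ep_neighbourhood(1, 2), 0.75)
  expect_equal(ep_neighbourhood(5, 2), 0)
  expect_error(ep_neighbourhood(1, 0), "positive")
})

test_that("map initialization is seeded and range-bounded", {
  set.seed(99)
  x <- matrix(rnorm(30), 10, 3)
  a <- som_init(2, 2, x, seed = 5)
  b <- som_init(2, 2, x, seed = 5)
  expect_identical(a$codebook, b$codebook)
  expect_true(all(a$codebook >= rep(apply(x, 2, min), each = 4)))
  expect_true(all(a$codebook <= rep(apply(x, 2, max), each = 4)))

  const <- matrix(2, 6, 2)
  expect_true(all(som_init(1, 2, const, seed = 1)$codebook == 2))
  expect_error(som_init(1, 1, x), "at least 2 nodes")
  expect_error(som_train(som_init(2, 2, x, 1), x[, 1:2]), "dimension")
})

test_that("sub-lattice-radius batch epochs coincide with Lloyd iterations", {
  set.seed(7)
  x <- matrix(rnorm(10 * 3), 10, 3)
  map0 <- som_init(2, 3, x, seed = 2)
  centroids <- map0$codebook
  for (epochs in 1:4) {
    trained <- som_train(map0, x, sub_lattice_schedule(epochs))
    oracle <- map0$codebook
    for (e in seq_len(epochs)) oracle <- lloyd_oracle_step(oracle, x)
    expect_equal(trained$codebook, oracle, tolerance = 1e-12)
  }
})

test_that("QE is non-increasing over epochs at sub-lattice radius", {
  set.seed(8)
  x <- matrix(rnorm(40 * 4), 40, 4)
  map <- som_train(som_init(3, 3, x, seed = 3), x, sub_lattice_schedule(15))
  qe <- map$training_log$qe
  expect_true(all(diff(qe) <= 1e-12))
})

test_that("a map whose codebook equals the data is a fixed point", {
  set.seed(9)
  x <- matrix(rnorm(6 * 2), 6, 2)
  map <- som_init(2, 3, x, seed = 1)
  map$codebook <- x  # one datum per node
  trained <- som_train(map, x, sub_lattice_schedule(3))
  expect_equal(trained$codebook, x, tolerance = 1e-12)
  expect_equal(trained$qe, 0)
})

test_that("a 1x2 map under the default schedule finds two blob means", {
  blobs <- make_blobs(n1 = 40, n2 = 40, p = 3, sep = 8, seed = 11)
  map <- som_train(som_init(1, 2, blobs$x, seed = 4), blobs$x)
  m1 <- colMeans(blobs$x[blobs$g == 1, ])
  m2 <- colMeans(blobs$x[blobs$g == 2, ])
  got <- map$codebook[order(map$codebook[, 1]), ]
  expect_equal(got[1, ], m1, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(got[2, ], m2, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(topographic_error(map, blobs$x), 0)  # forced by geometry
})

test_that("BMU lookup breaks ties toward the lowest node index", {
  x <- matrix(c(0, 0, 1, 1, 5, 5), 3, 2, byrow = TRUE)
  map <- som_init(1, 3, x, seed = 1)
  map$codebook <- x
  b <- som_bmu(map, x[3, ])
  expect_identical(b$bmu, 3L)
  # equidistant between nodes 1 and 2
  mid <- som_bmu(map, c(0.5, 0.5))
  expect_identical(mid$bmu, 1L)
  two <- som_init(1, 2, x[, 1, drop = FALSE], seed = 1)
  bt <- som_bmu(two, matrix(0.3))
  expect_setequal(c(bt$bmu, bt$second), c(1L, 2L))
})

test_that("quantization and topographic errors behave on edge cases", {
  x1 <- matrix(c(0, 2), 2, 1)
  map <- som_init(1, 2, x1, seed = 1)
  map$codebook <- matrix(c(1, 1), 2, 1)
  expect_equal(quantization_error(map, x1), 1)

  map$codebook <- x1
  expect_equal(quantization_error(map, x1), 0)
})

test_that("the U-matrix reflects codebook distances to lattice neighbours", {
  x <- matrix(rnorm(20), 10, 2)
  map <- som_init(2, 2, x, seed = 6)
  map$codebook <- matrix(3, 4, 2)
  expect_equal(u_matrix(map), matrix(0, 2, 2))

  m2 <- som_init(1, 2, x[, 1, drop = FALSE], seed = 1)
  m2$codebook <- matrix(c(0, 7), 2, 1)
  expect_equal(u_matrix(m2), matrix(c(7, 7), 1, 2))

  trained <- som_train(som_init(3, 3, x, seed = 2), x)
  expect_true(all(u_matrix(trained) >= 0))
})

test_that("lattice-preserving symmetries leave QE, TE and U-values alike", {
  set.seed(12)
  x <- matrix(rnorm(30 * 3), 30, 3)
  map <- som_train(som_init(5, 4, x, seed = 7), x)
  # vertical flip preserves row parity (odd row count), hence the lattice
  perm <- as.vector(t(apply(matrix(seq_len(20), 5, 4, byrow = TRUE),
                            2L, rev)))
  flipped <- map
  flipped$codebook <- map$codebook[perm, ]
  expect_equal(quantization_error(flipped, x), quantization_error(map, x))
  expect_equal(topographic_error(flipped, x), topographic_error(map, x))
  expect_equal(sort(as.vector(u_matrix(flipped))),
               sort(as.vector(u_matrix(map))), tolerance = 1e-12)
})

test_that("map-size selection minimizes the QE/TE rank sum", {
  set.seed(13)
  x <- matrix(rnorm(50 * 4), 50, 4)
  one <- select_map_size(x, candidates = list(c(3, 3)), seed = 1)
  expect_identical(one$size, c(3, 3))

  sel_a <- select_map_size(x, candidates = list(c(2, 2), c(4, 4), c(5, 4)),
                           seed = 2)
  sel_b <- select_map_size(x, candidates = list(c(2, 2), c(4, 4), c(5, 4)),
                           seed = 2)
  expect_identical(sel_a$size, sel_b$size)  # deterministic under the seed
  # the chosen size is never strictly dominated on both errors
  tab <- sel_a$table
  best <- tab[tab$rows == sel_a$size[1] & tab$cols == sel_a$size[2], ]
  expect_false(any(tab$qe < best$qe & tab$te < best$te))
  expect_error(select_map_size(x, candidates = list()), "empty")
})
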