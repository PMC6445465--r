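#' Hexagonal sheet lattice coordinates
#'
#' Offset hexagonal geometry: odd rows are shifted half a unit to the
#' right and the row pitch is `sqrt(3)/2`, so every pair of adjacent nodes
#' sits at unit distance in the embedded plane. Nodes are ordered row-major.
#'
#' @param n_rows,n_cols grid dimensions.
#' @return Matrix (`n_rows * n_cols` x 2) of x/y coordinates.
#' @export
hex_positions <- function(n_rows, n_cols) {
  r <- rep(seq_len(n_rows) - 1L, each = n_cols)
  c <- rep(seq_len(n_cols) - 1L, times = n_rows)
  cbind(x = c + 0.5 * (r %% 2L), y = r * sqrt(3) / 2)
}

#' Epanechnikov neighbourhood kernel
#'
#' `max(0, 1 - (d/radius)^2)`: weight 1 at the winning node, falling to 0
#' at lattice distance `radius`.
#'
#' @param lattice_distance non-negative distance(s) on the lattice.
#' @param radius positive neighbourhood radius.
#' @return Weight(s) in `[0, 1]`.
#' @export
ep_neighbourhood <- function(lattice_distance, radius) {
  if (radius <= 0) stop("`radius` must be positive", call. = FALSE)
  pmax(0, 1 - (lattice_distance / radius)^2)
}

#' Initialize a self-organizing map
#'
#' Codebook rows are drawn uniformly within each feature's observed data
#' range (a constant feature pins its codebook column to that constant).
#' Deterministic given the seed.
#'
#' @param n_rows,n_cols map dimensions (at least 2 nodes in total).
#' @param data numeric matrix or `zmatrix` supplying feature ranges.
#' @param seed integer.
#' @return A `som_map` with untrained codebook (`qe`/`te` are `NA`).
#' @export
som_init <- function(n_rows, n_cols, data, seed = 1L) {
  x <- as_values(data)
  n_nodes <- n_rows * n_cols
  if (n_rows < 1L || n_cols < 1L || n_nodes < 2L) {
    stop("map must have at least 2 nodes", call. = FALSE)
  }
  lo <- apply(x, 2L, min)
  hi <- apply(x, 2L, max)
  codebook <- with_seed(seed, {
    matrix(stats::runif(n_nodes * ncol(x), rep(lo, each = n_nodes),
                        rep(hi, each = n_nodes)),
           n_nodes, ncol(x))
  })
  colnames(codebook) <- colnames(x)
  pos <- hex_positions(n_rows, n_cols)
  nd <- sqrt(cross_dist2(pos, pos))
  structure(
    list(n_rows = n_rows, n_cols = n_cols, node_positions = pos,
         node_dist = nd, codebook = codebook,
         qe = NA_real_, te = NA_real_, training_log = NULL),
    class = "som_map"
  )
}

#' Two-phase batch training schedule
#'
#' Rough phase (default 20 epochs) with a wide shrinking neighbourhood,
#' then a fine-tuning phase (default 50 epochs) with a narrow one. `NULL`
#' radii are resolved against the map at training time: rough from
#' `max(n_rows, n_cols)/4` (at least 1) down to 1, fine from 1 down to 0.5.
#'
#' @param rough_epochs,fine_epochs phase lengths in epochs.
#' @param rough_radius,fine_radius length-2 `(start, end)` radii or `NULL`.
#' @return A `som_schedule` list.
#' @export
som_schedule <- function(rough_epochs = 20L, fine_epochs = 50L,
                         rough_radius = NULL, fine_radius = c(1, 0.5)) {
  structure(
    list(rough_epochs = as.integer(rough_epochs),
         fine_epochs = as.integer(fine_epochs),
         rough_radius = rough_radius, fine_radius = fine_radius),
    class = "som_schedule"
  )
}

resolve_schedule <- function(schedule, map) {
  if (is.null(schedule)) schedule <- som_schedule()
  rough <- schedule$rough_radius
  # floor the start radius at 1.5: at radius <= 1 the Epanechnikov kernel
  # gives zero weight to lattice neighbours (unit spacing), leaving small
  # maps with no topological interaction at all
  if (is.null(rough)) rough <- c(max(1.5, max(map$n_rows, map$n_cols) / 4), 1)
  fine <- schedule$fine_radius
  if (is.null(fine)) fine <- c(1, 0.5)
  bounds <- c(
    if (schedule$rough_epochs > 0) c(rough[1], rough[2]),
    if (schedule$fine_epochs > 0) c(fine[1], fine[2])
  )
  if (length(bounds) == 0L) stop("schedule has no epochs", call. = FALSE)
  if (is.unsorted(rev(bounds)) || bounds[length(bounds)] < 0) {
    stop("radii must satisfy rough.start >= rough.end >= fine.start >= fine.end >= 0",
         call. = FALSE)
  }
  c(
    if (schedule$rough_epochs > 0)
      seq(rough[1], rough[2], length.out = schedule$rough_epochs),
    if (schedule$fine_epochs > 0)
      seq(fine[1], fine[2], length.out = schedule$fine_epochs)
  )
}

#' Batch-train a self-organizing map
#'
#' Per epoch: every datum is assigned to its best-matching unit (nearest
#' codebook row, Euclidean, ties to the lowest node index) and every
#' codebook row is replaced by the neighbourhood-weighted mean of all data,
#' the weights being the Epanechnikov kernel of the lattice distance
#' between the datum's BMU and the node at the epoch's radius. The radius
#' interpolates linearly within each phase. Nodes receiving zero total
#' weight keep their codebook row. Quantization and topographic errors are
#' recorded on the trained map.
#'
#' @param map a `som_map` from [som_init()].
#' @param data numeric matrix or `zmatrix`.
#' @param schedule a [som_schedule()] or `NULL` for defaults.
#' @return The trained `som_map` (with `qe`, `te`, `training_log`).
#' @export
som_train <- function(map, data, schedule = NULL) {
  x <- as_values(data)
  if (nrow(x) == 0L) stop("cannot train on empty data", call. = FALSE)
  if (ncol(x) != ncol(map$codebook)) {
    stop("feature dimension mismatch between map and data", call. = FALSE)
  }
  radii <- resolve_schedule(schedule, map)
  codebook <- map$codebook
  log_qe <- numeric(length(radii))
  for (e in seq_along(radii)) {
    d2 <- cross_dist2(x, codebook)
    bmu <- row_which_min(d2)
    log_qe[e] <- mean(sqrt(d2[cbind(seq_len(nrow(x)), bmu)]))
    radius <- max(radii[e], 1e-12)
    h <- 1 - (map$node_dist / radius)^2
    h[h < 0] <- 0
    w <- h[bmu, , drop = FALSE]              # n x n_nodes
    denom <- colSums(w)
    numer <- crossprod(w, x)                 # n_nodes x p
    upd <- denom > 0
    codebook[upd, ] <- numer[upd, , drop = FALSE] / denom[upd]
  }
  map$codebook <- codebook
  map$training_log <- data.frame(epoch = seq_along(radii), radius = radii,
                                 qe = log_qe)
  map$qe <- quantization_error(map, x)
  map$te <- if (nrow(map$codebook) >= 2L) topographic_error(map, x) else NA_real_
  map
}

#' Best-matching units
#'
#' Nearest and second-nearest codebook rows for each datum, Euclidean
#' distance, ties broken toward the lowest node index.
#'
#' @param map a `som_map`.
#' @param x numeric matrix (or single vector) of data.
#' @return list with integer vectors `bmu` and `second` (the latter `NA`
#'   on single-node maps).
#' @export
som_bmu <- function(map, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as_values(x)
  d2 <- cross_dist2(x, map$codebook)
  first <- row_which_min(d2)
  second <- rep(NA_integer_, nrow(x))
  if (ncol(d2) >= 2L) {
    d2[cbind(seq_len(nrow(x)), first)] <- Inf
    second <- row_which_min(d2)
  }
  list(bmu = first, second = second)
}

#' Quantization error
#'
#' Mean Euclidean distance from each datum to its best-matching unit, in
#' the (z-score) units of the training data.
#'
#' @param map a `som_map`.
#' @param data numeric matrix or `zmatrix`.
#' @return Non-negative scalar.
#' @export
quantization_error <- function(map, data) {
  x <- as_values(data)
  d2 <- cross_dist2(x, map$codebook)
  mean(sqrt(apply(d2, 1L, min)))
}

#' Topographic error
#'
#' Fraction of data whose first and second best-matching units are not
#' adjacent on the hexagonal lattice.
#'
#' @param map a `som_map` with at least 2 nodes.
#' @param data numeric matrix or `zmatrix`.
#' @return Fraction in `[0, 1]`.
#' @export
topographic_error <- function(map, data) {
  if (nrow(map$codebook) < 2L) {
    stop("topographic error needs at least 2 nodes", call. = FALSE)
  }
  b <- som_bmu(map, data)
  adj <- map$node_dist <= 1 + 1e-9 & map$node_dist > 0
  mean(!adj[cbind(b$bmu, b$second)])
}

#' Unified distance matrix
#'
#' Per node, the mean Euclidean codebook distance to its lattice
#' neighbours; high values mark cluster boundaries on the map.
#'
#' @param map a `som_map`.
#' @return Numeric `n_rows` x `n_cols` grid (row-major node order).
#' @export
u_matrix <- function(map) {
  cd <- sqrt(cross_dist2(map$codebook, map$codebook))
  adj <- map$node_dist <= 1 + 1e-9 & map$node_dist > 0
  u <- vapply(seq_len(nrow(cd)), function(i) mean(cd[i, adj[i, ]]),
              numeric(1))
  matrix(u, map$n_rows, map$n_cols, byrow = TRUE)
}

#' Write a U-matrix (or any numeric grid) as TSV
#' @param grid numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grid_tsv <- function(grid, path) {
  utils::write.table(grid, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Candidate map sizes around the `5 * sqrt(n)` heuristic
#' @param n number of observations.
#' @return list of `(rows, cols)` integer pairs.
#' @export
default_candidate_sizes <- function(n) {
  units <- 5 * sqrt(n)
  lapply(c(0.75, 1, 1.25), function(f) {
    u <- round(units * f)
    rows <- max(2L, round(sqrt(u * 4 / 3)))
    cols <- max(2L, round(u / rows))
    c(rows, cols)
  })
}

#' Default first-layer map size for a cohort of n patients
#' @param n number of observations.
#' @return `(rows, cols)` integer pair.
#' @export
default_map_size <- function(n) {
  default_candidate_sizes(n)[[2L]]
}

#' Select the map size minimizing quantization and topographic errors
#'
#' Trains one map per candidate size and returns the candidate with the
#' lowest sum of QE rank and TE rank; ties break toward fewer nodes. The
#' full `(size, qe, te)` table is attached for logging.
#'
#' @param data numeric matrix or `zmatrix`.
#' @param candidates list of `(rows, cols)` pairs; defaults to
#'   [default_candidate_sizes()].
#' @param schedule a [som_schedule()] or `NULL`.
#' @param seed integer.
#' @return list with `size` (chosen pair) and `table` (data.frame of
#'   rows, cols, qe, te, rank_sum).
#' @export
select_map_size <- function(data, candidates = NULL, schedule = NULL,
                            seed = 1L) {
  x <- as_values(data)
  if (is.null(candidates)) candidates <- default_candidate_sizes(nrow(x))
  if (length(candidates) == 0L) stop("empty candidate list", call. = FALSE)
  res <- lapply(seq_along(candidates), function(i) {
    sz <- candidates[[i]]
    m <- som_train(som_init(sz[1], sz[2], x, seed = seed + i), x, schedule)
    c(rows = sz[1], cols = sz[2], qe = m$qe, te = m$te)
  })
  tab <- as.data.frame(do.call(rbind, res))
  tab$rank_sum <- rank(tab$qe, ties.method = "min") +
    rank(tab$te, ties.method = "min")
  nodes <- tab$rows * tab$cols
  ord <- order(tab$rank_sum, nodes)
  best <- tab[ord[1L], ]
  list(size = c(best$rows, best$cols), table = tab)
}

#' @export
print.som_map <- function(x, ...) {
  cat(sprintf("<som_map> %dx%d hexagonal sheet, %d features%s\n",
              x$n_rows, x$n_cols, ncol(x$codebook),
              if (!is.na(x$qe)) sprintf("; qe = %.4f, te = %.4f", x$qe, x$te)
              else " (untrained)"))
  invisible(x)
}
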