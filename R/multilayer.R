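#' Lloyd k-means with seeded random initialization
#'
#' Centroids start at `k` distinct data rows chosen at random; assignment
#' uses squared Euclidean distance (ties to the lowest centroid index);
#' iteration stops when assignments are fixed or after `iter_max` rounds.
#' An emptied cluster is re-seeded at the point farthest from its current
#' centroid. Deterministic given the seed.
#'
#' @param x numeric matrix or `zmatrix`.
#' @param k number of clusters, `2 <= k < n`.
#' @param seed integer.
#' @param iter_max maximum Lloyd iterations.
#' @return Integer label vector in `1..k`.
#' @export
lloyd_kmeans <- function(x, k, seed = 1L, iter_max = 300L) {
  x <- as_values(x)
  n <- nrow(x)
  if (k >= n) stop("`k` must be smaller than the number of observations",
                   call. = FALSE)
  if (k < 2L) stop("`k` must be at least 2", call. = FALSE)
  centroids <- with_seed(seed, x[sample.int(n, k), , drop = FALSE])
  labels <- integer(n)
  for (iter in seq_len(iter_max)) {
    d2 <- cross_dist2(x, centroids)
    new_labels <- row_which_min(d2)
    # re-seed emptied clusters at the farthest point from its assignment
    for (j in which(tabulate(new_labels, k) == 0L)) {
      far <- which.max(d2[cbind(seq_len(n), new_labels)])
      centroids[j, ] <- x[far, ]
      new_labels[far] <- j
    }
    if (identical(new_labels, labels)) break
    labels <- new_labels
    for (j in seq_len(k)) {
      centroids[j, ] <- colMeans(x[labels == j, , drop = FALSE])
    }
  }
  labels
}

# Next layer size: total nodes roughly halved, aspect ratio kept close to
# the parent's, never below 2x2 until the terminal 1 x target_k fallback.
shrink_size <- function(prev, target_k) {
  nodes <- prev[1] * prev[2]
  if (nodes <= 4L) return(c(1L, as.integer(target_k)))
  tgt <- max(ceiling(nodes / 2), 4L, target_k)
  aspect <- prev[1] / prev[2]
  best <- NULL; best_score <- Inf
  for (r in 2:tgt) {
    cl <- max(2L, round(tgt / r))
    if (r * cl >= nodes) next
    if (r * cl < target_k) next
    score <- abs(r * cl - tgt) + 0.25 * abs(log((r / cl) / aspect))
    if (score < best_score) { best_score <- score; best <- c(r, cl) }
  }
  if (is.null(best)) c(1L, as.integer(target_k)) else as.integer(best)
}

# Distinct occupied nodes of a trained map, merging occupied nodes whose
# codebook rows coincide (converged duplicates). Returns per-patient
# cluster ids 1..m in node-index order.
occupied_clusters <- function(map, bmu, tol = 1e-8) {
  occ <- sort(unique(bmu))
  reps <- integer(0)  # representative node per merged group
  group_of <- integer(length(occ))
  for (i in seq_along(occ)) {
    assigned <- FALSE
    for (g in seq_along(reps)) {
      if (sqrt(sum((map$codebook[occ[i], ] - map$codebook[reps[g], ])^2)) < tol) {
        group_of[i] <- g; assigned <- TRUE; break
      }
    }
    if (!assigned) { reps <- c(reps, occ[i]); group_of[i] <- length(reps) }
  }
  group_of[match(bmu, occ)]
}

#' Train a stacked multi-layer self-organizing map
#'
#' Layer 1 is trained on the standardized data; each patient's
#' representation for layer `l + 1` is the codebook vector of their
#' best-matching unit at layer `l`, so every layer still holds one row per
#' patient. Layer sizes shrink by roughly halving the node count (minimum
#' 2x2, with a terminal `1 x target_k` layer as last resort). Layers are
#' appended until the distinct occupied final-layer nodes (after merging
#' nodes with coinciding codebooks) equal `target_k`, or `max_layers` is
#' reached — the latter is an error, not a silent truncation.
#'
#' @param data numeric matrix or `zmatrix`.
#' @param target_k desired number of clusters.
#' @param first_layer_size `(rows, cols)` pair; `NULL` uses
#'   [default_map_size()] of the cohort size.
#' @param schedule a [som_schedule()] or `NULL`.
#' @param seed integer; layer `l` initializes with `seed + 17 * l`.
#' @param max_layers stack depth cap.
#' @return A `layer_stack`: trained `layers`, per-layer `bmu_paths`
#'   (n x n_layers), `final_labels` in `1..target_k`, `sizes`, `target_k`.
#' @export
train_stack <- function(data, target_k = 2L, first_layer_size = NULL,
                        schedule = NULL, seed = 1L, max_layers = 8L) {
  x <- as_values(data)
  n <- nrow(x)
  if (is.null(first_layer_size)) first_layer_size <- default_map_size(n)
  if (prod(first_layer_size) < target_k) {
    stop("first layer must have at least `target_k` nodes", call. = FALSE)
  }
  layers <- list()
  sizes <- list(as.integer(first_layer_size))
  bmu_paths <- matrix(NA_integer_, n, 0L)
  input <- x
  repeat {
    l <- length(layers) + 1L
    sz <- sizes[[l]]
    map <- som_train(som_init(sz[1], sz[2], input, seed = seed + 17L * l),
                     input, schedule)
    bmu <- som_bmu(map, input)$bmu
    layers[[l]] <- map
    bmu_paths <- cbind(bmu_paths, bmu)
    clusters <- occupied_clusters(map, bmu)
    m <- max(clusters)
    if (m == target_k) {
      return(structure(
        list(layers = layers, bmu_paths = bmu_paths,
             final_labels = clusters, sizes = sizes, target_k = target_k),
        class = "layer_stack"
      ))
    }
    if (m < target_k) {
      stop(sprintf(
        "stack collapsed to %d occupied node group(s) before reaching %d clusters",
        m, target_k), call. = FALSE)
    }
    if (l >= max_layers) {
      stop(sprintf("could not reach %d clusters within %d layers (at %d)",
                   target_k, max_layers, m), call. = FALSE)
    }
    sizes[[l + 1L]] <- shrink_size(sz, target_k)
    input <- map$codebook[bmu, , drop = FALSE]
  }
}

#' @export
print.layer_stack <- function(x, ...) {
  szs <- vapply(x$sizes, function(s) sprintf("%dx%d", s[1], s[2]), "")
  cat(sprintf("<layer_stack> %d layers (%s) -> %d clusters over %d patients\n",
              length(x$layers), paste(szs, collapse = " > "),
              x$target_k, nrow(x$bmu_paths)))
  invisible(x)
}

all_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    rest <- all_permutations(v[-i])
    out <- c(out, lapply(rest, function(r) c(v[i], r)))
  }
  out
}

#' Align one labelling to another by optimal label permutation
#'
#' Finds the relabeling of `candidate` (an injective mapping of its cluster
#' ids into the reference's) that maximizes per-item agreement with
#' `reference`, by exhaustive search over assignments (guarded to at most
#' 8 clusters).
#'
#' @param reference,candidate equal-length label vectors; `candidate` may
#'   use at most as many distinct ids as `reference`.
#' @return `candidate` relabelled into the reference's id space.
#' @export
align_labels <- function(reference, candidate) {
  if (length(reference) != length(candidate)) {
    stop("label vectors differ in length", call. = FALSE)
  }
  ur <- sort(unique(reference))
  uc <- sort(unique(candidate))
  # target id space: the reference's ids, extended with fresh ids when the
  # candidate has more clusters (a degenerate reference must still accept
  # an alignment; surplus candidate clusters keep distinct ids)
  targets <- ur
  while (length(targets) < length(uc)) {
    targets <- c(targets, max(targets) + 1L)
  }
  if (length(targets) > 8L) {
    stop("alignment supports at most 8 clusters", call. = FALSE)
  }
  best <- candidate; best_agree <- -1L
  for (perm in all_permutations(targets)) {
    mapping <- perm[seq_along(uc)]
    mapped <- mapping[match(candidate, uc)]
    agree <- sum(mapped == reference)
    if (agree > best_agree) { best_agree <- agree; best <- mapped }
  }
  best
}

#' Repeated clustering runs aligned to a common label space
#'
#' Runs the chosen method `n_reps` times (repetition `r` uses seed
#' `seed_base + r`), aligns every run to the first, and records the
#' per-patient modal label.
#'
#' @param data numeric matrix or `zmatrix`.
#' @param method `"som"` (stacked multi-layer map) or `"kmeans"`.
#' @param target_k number of clusters.
#' @param n_reps repetitions (the study protocol uses 100).
#' @param seed_base integer.
#' @param first_layer_size,schedule forwarded to [train_stack()].
#' @return A `run_ensemble`: `runs`, `aligned_runs` (both
#'   `n_reps` x n), `mode_labels`, `method`, `n_reps`.
#' @export
run_consensus <- function(data, method = c("som", "kmeans"), target_k = 2L,
                          n_reps = 100L, seed_base = 0L,
                          first_layer_size = NULL, schedule = NULL) {
  method <- match.arg(method)
  x <- as_values(data)
  runs <- matrix(NA_integer_, n_reps, nrow(x))
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    s <- seed_base + r
    runs[r, ] <- if (method == "som") {
      # a run whose stack cannot reach target_k contributes a degenerate
      # single-cluster labelling; the consensus mode outvotes it
      tryCatch(
        train_stack(x, target_k, first_layer_size, schedule,
                    seed = s)$final_labels,
        error = function(e) { n_failed <<- n_failed + 1L; rep(1L, nrow(x)) }
      )
    } else {
      lloyd_kmeans(x, target_k, seed = s)
    }
  }
  aligned <- runs
  for (r in seq_len(n_reps)[-1L]) {
    aligned[r, ] <- align_labels(runs[1L, ], runs[r, ])
  }
  structure(
    list(method = method, runs = runs, aligned_runs = aligned,
         mode_labels = label_mode(aligned), n_reps = n_reps,
         n_failed = n_failed),
    class = "run_ensemble"
  )
}

#' Per-patient modal label of an aligned ensemble
#' @param ensemble a `run_ensemble`.
#' @return Integer label vector (ties to the smaller label id).
#' @export
consensus_mode <- function(ensemble) {
  label_mode(ensemble$aligned_runs)
}

#' Three-repetition stability protocol
#'
#' Runs the `n_reps`-repetition consensus `n_triplet` times with disjoint
#' derived seed blocks (repetition `r` of block `t` uses
#' `master_seed + 1000 * t + r`), aligns the consensus vectors, and counts
#' patients not identically labelled across the blocks. The outcome is
#' stable when that fraction is below 10%; the final labels are the
#' columnwise mode of the aligned consensus vectors.
#'
#' @param data numeric matrix or `zmatrix`.
#' @param method `"som"` or `"kmeans"`.
#' @param target_k number of clusters.
#' @param n_reps consensus repetitions per block (study protocol: 100).
#' @param n_triplet number of protocol repetitions (study protocol: 3).
#' @param master_seed integer.
#' @param first_layer_size,schedule forwarded to [train_stack()].
#' @param stability_threshold discordance fraction below which the outcome
#'   counts as stable.
#' @return A `stability_report`: `consensus_triplet` (aligned matrix),
#'   `n_discordant`, `instability`, `stable`, `final_labels`, `method`.
#' @export
stability_protocol <- function(data, method = c("som", "kmeans"),
                               target_k = 2L, n_reps = 100L, n_triplet = 3L,
                               master_seed = 0L, first_layer_size = NULL,
                               schedule = NULL, stability_threshold = 0.10) {
  method <- match.arg(method)
  x <- as_values(data)
  modes <- matrix(NA_integer_, n_triplet, nrow(x))
  for (t in seq_len(n_triplet)) {
    ens <- run_consensus(x, method, target_k, n_reps,
                         seed_base = master_seed + 1000L * t,
                         first_layer_size = first_layer_size,
                         schedule = schedule)
    modes[t, ] <- ens$mode_labels
  }
  for (t in seq_len(n_triplet)[-1L]) {
    modes[t, ] <- align_labels(modes[1L, ], modes[t, ])
  }
  n_discordant <- sum(apply(modes, 2L, function(col) length(unique(col)) > 1L))
  instability <- n_discordant / nrow(x)
  structure(
    list(method = method, consensus_triplet = modes,
         n_discordant = n_discordant, instability = instability,
         stable = instability < stability_threshold,
         final_labels = label_mode(modes),
         n_reps = n_reps, n_triplet = n_triplet,
         master_seed = master_seed),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(
    "<stability_report> %s, %dx%d reps: %d/%d discordant (%.1f%%) -> %s\n",
    x$method, x$n_triplet, x$n_reps, x$n_discordant,
    ncol(x$consensus_triplet), 100 * x$instability,
    if (x$stable) "stable" else "NOT stable"))
  invisible(x)
}

#' Overlap between two clusterings of the same patients
#'
#' Aligns `labels_b` to `labels_a` and reports the fraction of identically
#' labelled patients plus the k x k cross-tabulation.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return list with `overlap_fraction` and `cross_counts` (table).
#' @export
method_overlap <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors differ in length", call. = FALSE)
  }
  b <- align_labels(labels_a, labels_b)
  list(overlap_fraction = mean(labels_a == b),
       cross_counts = table(a = labels_a, b = b))
}
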