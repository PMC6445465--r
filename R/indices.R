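#' Internal cluster validity index
#'
#' Evaluates one of four internal criteria for a given labelling of
#' standardized data:
#' \describe{
#'   \item{CH}{Calinski-Harabasz: `(B/(k-1)) / (W/(n-k))` with B/W the
#'     between/within cluster sums of squares. Higher is better.}
#'   \item{SI}{mean silhouette width under Euclidean distance. Higher is
#'     better; singleton clusters are rejected.}
#'   \item{Gap}{gap statistic: mean log within-dispersion of `B` uniform
#'     reference sets (over each feature's observed range, re-clustered by
#'     k-means) minus the log within-dispersion of the labelling. Higher is
#'     better; stochastic, controlled by `seed`.}
#'   \item{DB}{Davies-Bouldin: mean over clusters of the worst
#'     `(scatter_i + scatter_j) / centroid_distance`. Lower is better.}
#' }
#'
#' @param x numeric matrix (observations x features) or a `zmatrix`.
#' @param labels integer cluster ids, at least two non-empty clusters.
#' @param criterion one of `"CH"`, `"SI"`, `"Gap"`, `"DB"`.
#' @param B number of uniform reference sets for the gap statistic.
#' @param seed integer seed for the gap reference draws.
#' @return A single numeric score.
#' @export
internal_index <- function(x, labels, criterion = c("CH", "SI", "Gap", "DB"),
                           B = 10L, seed = 1L) {
  criterion <- match.arg(criterion)
  x <- as_values(x)
  labels <- as.integer(labels)
  ids <- sort(unique(labels))
  k <- length(ids)
  n <- nrow(x)
  if (k < 2L) stop("need at least 2 non-empty clusters", call. = FALSE)
  if (n <= k) stop("need more observations than clusters", call. = FALSE)
  switch(criterion,
         CH = index_ch(x, labels, ids),
         SI = index_si(x, labels, ids),
         DB = index_db(x, labels, ids),
         Gap = index_gap(x, labels, ids, B = B, seed = seed))
}

as_values <- function(x) {
  if (inherits(x, "zmatrix")) x$values else as.matrix(x)
}

cluster_centroids <- function(x, labels, ids) {
  do.call(rbind, lapply(ids, function(i) {
    colMeans(x[labels == i, , drop = FALSE])
  }))
}

index_ch <- function(x, labels, ids) {
  n <- nrow(x); k <- length(ids)
  grand <- colMeans(x)
  cent <- cluster_centroids(x, labels, ids)
  sizes <- as.numeric(table(factor(labels, levels = ids)))
  between <- sum(sizes * rowSums(sweep(cent, 2L, grand, "-")^2))
  within <- sum((x - cent[match(labels, ids), , drop = FALSE])^2)
  (between / (k - 1)) / (within / (n - k))
}

index_si <- function(x, labels, ids) {
  sizes <- table(factor(labels, levels = ids))
  if (any(sizes < 2L)) stop("silhouette requires no singleton clusters",
                            call. = FALSE)
  d <- as.matrix(stats::dist(x))
  n <- nrow(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- sum(d[i, own]) / (sum(own) - 1L)
    b <- min(vapply(ids[ids != labels[i]], function(cl) {
      mean(d[i, labels == cl])
    }, numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

index_db <- function(x, labels, ids) {
  cent <- cluster_centroids(x, labels, ids)
  k <- length(ids)
  scatter <- vapply(seq_len(k), function(i) {
    pts <- x[labels == ids[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(pts, 2L, cent[i, ], "-")^2)))
  }, numeric(1))
  m <- sqrt(cross_dist2(cent, cent))
  r <- numeric(k)
  for (i in seq_len(k)) {
    ratios <- (scatter[i] + scatter[-i]) / m[i, -i]
    r[i] <- max(ratios)
  }
  mean(r)
}

within_dispersion <- function(x, labels, ids) {
  cent <- cluster_centroids(x, labels, ids)
  sum((x - cent[match(labels, ids), , drop = FALSE])^2)
}

index_gap <- function(x, labels, ids, B = 10L, seed = 1L) {
  k <- length(ids)
  w_obs <- within_dispersion(x, labels, ids)
  lo <- apply(x, 2L, min)
  hi <- apply(x, 2L, max)
  ref_logw <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      ref <- matrix(stats::runif(length(x), rep(lo, each = nrow(x)),
                                 rep(hi, each = nrow(x))),
                    nrow(x), ncol(x))
      rl <- lloyd_kmeans(ref, k,
                         seed = sample.int(.Machine$integer.max - 1L, 1L))
      log(within_dispersion(ref, rl, sort(unique(rl))))
    }, numeric(1))
  })
  mean(ref_logw) - log(w_obs)
}

#' Vote on the number of clusters by repeated criterion evaluation
#'
#' Per repetition, the data are clustered by k-means (one fresh random
#' start) for every candidate `k` and the criterion-best `k` is recorded;
#' ties break toward the smaller `k`. The vote is decisive when the modal
#' `k` holds a strict majority of repetitions.
#'
#' @param x numeric matrix or `zmatrix`.
#' @param k_range candidate cluster counts, a subset of `2:(n-1)`.
#' @param n_reps repetitions (the study protocol uses 500).
#' @param criterion one of `"CH"`, `"SI"`, `"Gap"`, `"DB"`.
#' @param seed integer master seed.
#' @param B gap-statistic reference sets per repetition.
#' @return A `criterion_vote` object: votes per `k`, `mode_k`,
#'   `mode_fraction`, `decisive`.
#' @export
vote_best_k <- function(x, k_range = 2:10, n_reps = 500L,
                        criterion = c("CH", "SI", "Gap", "DB"),
                        seed = 1L, B = 10L) {
  criterion <- match.arg(criterion)
  votes <- run_criterion_votes(x, k_range, n_reps, criterion, seed, B)[[1L]]
  votes
}

#' Vote with several criteria over shared k-means repetitions
#'
#' Like [vote_best_k()], but each repetition clusters the data once per
#' candidate `k` and scores every requested criterion on the same
#' labellings, so a four-criterion vote costs one criterion's clustering
#' work.
#'
#' @inheritParams vote_best_k
#' @param criteria criteria to evaluate.
#' @return Named list of `criterion_vote` objects.
#' @export
run_criterion_votes <- function(x, k_range, n_reps,
                                criteria = c("CH", "SI", "Gap", "DB"),
                                seed = 1L, B = 10L) {
  x <- as_values(x)
  if (n_reps < 1L) stop("`n_reps` must be at least 1", call. = FALSE)
  if (any(k_range < 2L) || any(k_range >= nrow(x))) {
    stop("`k_range` must lie within 2..(n-1)", call. = FALSE)
  }
  best <- matrix(NA_integer_, n_reps, length(criteria),
                 dimnames = list(NULL, criteria))
  for (r in seq_len(n_reps)) {
    scores <- matrix(NA_real_, length(k_range), length(criteria),
                     dimnames = list(k_range, criteria))
    for (ki in seq_along(k_range)) {
      k <- k_range[ki]
      ksd <- seed + 7919L * r + k
      labels <- lloyd_kmeans(x, k, seed = ksd)
      for (cr in criteria) {
        scores[ki, cr] <- tryCatch(
          internal_index(x, labels, cr, B = B, seed = ksd + 13L),
          error = function(e) NA_real_)
      }
    }
    for (cr in criteria) {
      sc <- scores[, cr]
      if (cr == "DB") sc <- -sc
      if (all(is.na(sc))) next
      best[r, cr] <- k_range[which.max(sc)]  # first max = smaller k on ties
    }
  }
  out <- lapply(criteria, function(cr) {
    b <- best[, cr]
    b <- b[!is.na(b)]
    votes <- table(factor(b, levels = k_range))
    mode_k <- as.integer(names(votes)[which.max(votes)])
    mode_fraction <- max(votes) / n_reps
    structure(
      list(criterion = cr, votes = votes, mode_k = mode_k,
           mode_fraction = as.numeric(mode_fraction),
           decisive = mode_fraction > 0.5, n_reps = n_reps),
      class = "criterion_vote"
    )
  })
  names(out) <- criteria
  out
}

#' @export
print.criterion_vote <- function(x, ...) {
  cat(sprintf("<criterion_vote> %s: mode k = %d (%.0f%% of %d reps)%s\n",
              x$criterion, x$mode_k, 100 * x$mode_fraction, x$n_reps,
              if (x$decisive) ", decisive" else ", not decisive"))
  invisible(x)
}

#' Export a criterion vote as JSON
#' @param vote a `criterion_vote`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vote_json <- function(vote, path) {
  jsonlite::write_json(
    list(criterion = vote$criterion,
         votes = as.list(stats::setNames(as.integer(vote$votes),
                                         names(vote$votes))),
         mode_k = vote$mode_k, mode_fraction = vote$mode_fraction,
         decisive = vote$decisive),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
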