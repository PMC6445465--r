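# Independent oracles, written as plain loops/enumerations that share no
# code with the package implementation.

# One Lloyd iteration from given centroids: nearest-centroid assignment
# (ties to the lowest index), centroid = mean of assigned points, empty
# centroids stay put. This is what a batch SOM epoch reduces to when the
# neighbourhood radius lies below the unit lattice distance.
lloyd_oracle_step <- function(centroids, x) {
  n <- nrow(x); k <- nrow(centroids)
  assign <- integer(n)
  for (i in seq_len(n)) {
    d <- vapply(seq_len(k), function(j) sum((x[i, ] - centroids[j, ])^2),
                numeric(1))
    assign[i] <- which.min(d)
  }
  out <- centroids
  for (j in seq_len(k)) {
    if (any(assign == j)) out[j, ] <- colMeans(x[assign == j, , drop = FALSE])
  }
  out
}

# Calinski-Harabasz by direct evaluation of its defining sums.
bf_ch <- function(x, labels) {
  ids <- sort(unique(labels)); k <- length(ids); n <- nrow(x)
  grand <- colMeans(x)
  between <- 0; within <- 0
  for (cl in ids) {
    pts <- x[labels == cl, , drop = FALSE]
    cen <- colMeans(pts)
    between <- between + nrow(pts) * sum((cen - grand)^2)
    for (r in seq_len(nrow(pts))) within <- within + sum((pts[r, ] - cen)^2)
  }
  (between / (k - 1)) / (within / (n - k))
}

# Davies-Bouldin by direct evaluation.
bf_db <- function(x, labels) {
  ids <- sort(unique(labels)); k <- length(ids)
  cen <- lapply(ids, function(cl) colMeans(x[labels == cl, , drop = FALSE]))
  sc <- vapply(seq_len(k), function(i) {
    pts <- x[labels == ids[i], , drop = FALSE]
    mean(apply(pts, 1L, function(r) sqrt(sum((r - cen[[i]])^2))))
  }, numeric(1))
  mean(vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) {
      (sc[i] + sc[j]) / sqrt(sum((cen[[i]] - cen[[j]])^2))
    }, numeric(1)))
  }, numeric(1)))
}

# Mann-Whitney U by pair counting (half credit for ties) and its exact
# two-sided p by complete enumeration of all group assignments.
u_pairs <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

mwu_exact_oracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  u0 <- u_pairs(a, b)
  idx <- utils::combn(n, na)
  us <- apply(idx, 2L, function(ii) u_pairs(pooled[ii], pooled[-ii]))
  list(U = u0,
       p = min(1, 2 * min(mean(us <= u0 + 1e-9), mean(us >= u0 - 1e-9))))
}

# Fisher's exact two-sided p for a 2x2 table by enumeration over all
# tables with the observed margins, summing those no more probable than
# the observed one.
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  prob <- vapply(xs, function(x) {
    choose(c1, x) * choose(n - c1, r1 - x) / choose(n, r1)
  }, numeric(1))
  obs <- prob[match(tab[1, 1], xs)]
  sum(prob[prob <= obs * (1 + 1e-7)])
}
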