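#' @keywords internal
"_PACKAGE"

# Run `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so no global state leaks.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Squared Euclidean cross-distances between rows of a (n x p) and b (m x p).
cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# Row-wise index of the minimum, ties broken toward the lowest index.
row_which_min <- function(d2) {
  max.col(-d2, ties.method = "first")
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items,
#' invariant to label permutation. Used to score recovery of known groups
#' on synthetic cohorts.
#'
#' @param a,b integer or factor label vectors of equal length.
#' @return A number in (-1, 1]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length", call. = FALSE)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Columnwise mode with ties broken toward the smallest label id.
label_mode <- function(mat) {
  apply(mat, 2L, function(col) {
    tab <- table(col)
    as.integer(names(tab)[which.max(tab)])
  })
}
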