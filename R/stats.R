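# Kaiser's pairwise-angle varimax with row normalization. The closed-form
# planar angle (tan 4*phi) escapes the symmetric stationary points where
# SVD-update implementations stall on block-structured loadings.
varimax_kaiser <- function(L, normalize = TRUE, eps = 1e-10,
                           max_iter = 200L) {
  p <- nrow(L); m <- ncol(L)
  if (m < 2L) return(list(loadings = L, rotmat = diag(m)))
  h <- if (normalize) sqrt(rowSums(L^2)) else rep(1, p)
  h[h == 0] <- 1
  A <- L / h
  R <- diag(m)
  crit <- function(A) sum(apply(A^2, 2L, function(cc) mean(cc^2) - mean(cc)^2))
  old <- crit(A)
  for (it in seq_len(max_iter)) {
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      x <- A[, i]; y <- A[, j]
      u <- x^2 - y^2; v <- 2 * x * y
      num <- 2 * (p * sum(u * v) - sum(u) * sum(v))
      den <- p * sum(u^2 - v^2) - (sum(u)^2 - sum(v)^2)
      phi <- atan2(num, den) / 4
      if (abs(phi) < 1e-12) next
      G <- diag(m); G[i, i] <- cos(phi); G[j, j] <- cos(phi)
      G[i, j] <- -sin(phi); G[j, i] <- sin(phi)
      A <- A %*% G; R <- R %*% G
    }
    new <- crit(A)
    if (new - old < eps) break
    old <- new
  }
  list(loadings = A * h, rotmat = R)
}

#' Principal component analysis with varimax rotation
#'
#' Eigendecomposition of the standardized matrix (so of the raw
#' correlation structure); components are retained by cumulative explained
#' variance and the retained orthonormal loadings are varimax-rotated.
#' Scores are reported for the retained (rotated) components.
#'
#' @param z a `zmatrix` or standardized numeric matrix.
#' @param rotation `"varimax"` or `"none"`.
#' @param cum_var retain the smallest number of components whose
#'   cumulative explained-variance fraction reaches this value.
#' @return A `pca_result`: `loadings` (rotated, variables x retained),
#'   `unrotated_loadings` (all components), `explained_fraction` (all),
#'   `scores` (patients x retained), `n_retained`, `rotation`.
#' @export
run_pca <- function(z, rotation = c("varimax", "none"), cum_var = 0.8) {
  rotation <- match.arg(rotation)
  x <- as_values(z)
  if (nrow(x) < 2L) stop("need more than one observation", call. = FALSE)
  p <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  ev <- p$sdev^2
  if (sum(ev) <= 0) stop("degenerate (rank-0) matrix", call. = FALSE)
  frac <- ev / sum(ev)
  m <- which(cumsum(frac) >= cum_var)[1L]
  if (is.na(m)) m <- length(frac)
  # component loadings in the factor-analytic convention (eigenvector times
  # component sd = variable-component correlation for standardized input);
  # this is the matrix rotation programs rotate
  sdev <- p$sdev[seq_len(m)]
  load <- sweep(p$rotation[, seq_len(m), drop = FALSE], 2L, sdev, "*")
  scores <- sweep(p$x[, seq_len(m), drop = FALSE], 2L,
                  ifelse(sdev > 0, sdev, 1), "/")
  if (rotation == "varimax" && m > 1L) {
    vm <- varimax_kaiser(load)
    rot <- vm$rotmat
    load <- vm$loadings
    scores <- scores %*% rot
    colnames(load) <- colnames(scores) <- paste0("RC", seq_len(m))
  }
  structure(
    list(loadings = load, unrotated_loadings = p$rotation,
         explained_fraction = frac, scores = scores,
         all_scores = p$x, n_retained = m, rotation = rotation),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf(
    "<pca_result> %d of %d components retained (%.1f%% variance), %s rotation\n",
    x$n_retained, length(x$explained_fraction),
    100 * sum(x$explained_fraction[seq_len(x$n_retained)]), x$rotation))
  invisible(x)
}

#' Mann-Whitney U test with tie-corrected Z and small-sample exact path
#'
#' U is computed from midrank sums; Z uses the normal approximation with
#' tie-corrected variance and no continuity correction. When
#' `n_a + n_b <= exact_max` the two-sided p-value is computed by exact
#' enumeration of all group assignments of the pooled sample
#' (`p = min(1, 2 * min(P(U <= u), P(U >= u)))`); otherwise the normal
#' approximation is used.
#'
#' @param a,b non-empty numeric samples.
#' @param exact_max pooled-size threshold for the exact path.
#' @return list with `U` (first sample), `Z`, `p`, `method`.
#' @export
mann_whitney <- function(a, b, exact_max = 12L) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  rk <- rank(pooled)
  u <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  ties <- table(pooled)
  mu <- na * nb / 2
  v <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- if (v > 0) (u - mu) / sqrt(v) else 0
  if (n <= exact_max) {
    combs <- utils::combn(n, na)
    us <- apply(combs, 2L, function(idx) sum(rk[idx]) - na * (na + 1) / 2)
    p <- min(1, 2 * min(mean(us <= u + 1e-9), mean(us >= u - 1e-9)))
    method <- "exact"
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(U = u, Z = z, p = p, method = method)
}

#' Eta-squared effect size from a normal-approximation Z
#'
#' `eta^2 = Z^2 / N`. Interpretation bands: > 0.1 small, > 0.3 medium,
#' > 0.5 large.
#'
#' @param Z normal-approximation statistic.
#' @param N total sample size, positive.
#' @return Effect size with attribute `band`.
#' @export
eta_squared <- function(Z, N) {
  if (N <= 0) stop("`N` must be positive", call. = FALSE)
  e <- Z^2 / N
  band <- if (e > 0.5) "large" else if (e > 0.3) "medium" else if (e > 0.1) "small" else "negligible"
  structure(e, band = band)
}

#' Bonferroni-corrected significance threshold
#' @param base_alpha family-wise level (default 0.05).
#' @param m number of comparisons, at least 1.
#' @return `base_alpha / m`.
#' @export
bonferroni_alpha <- function(base_alpha = 0.05, m) {
  if (m < 1) stop("`m` must be at least 1", call. = FALSE)
  base_alpha / m
}

#' Per-variable nonparametric comparison of two patient groups
#'
#' Descriptives (median and IQR per group) are reported on the raw
#' measurement scale for clinical readability, restricted to observed
#' (non-masked) values; the Mann-Whitney test runs on the standardized
#' values; the effect size is `eta^2 = Z^2 / N`. Rows are sorted with
#' significant variables first, then by p-value.
#'
#' @param cohort the raw-scale `cohort_matrix`.
#' @param zdata the matching `zmatrix`.
#' @param labels two-group label vector (values 1 and 2), each non-empty.
#' @param alpha_corrected significance threshold (e.g.
#'   [bonferroni_alpha()]).
#' @return data.frame with one row per variable: group medians/IQRs, `U`,
#'   `Z`, `p`, `eta_squared`, `significant`.
#' @export
compare_groups <- function(cohort, zdata, labels,
                           alpha_corrected = bonferroni_alpha(0.05, 53)) {
  ids <- sort(unique(labels))
  if (length(ids) != 2L) stop("exactly two groups required", call. = FALSE)
  if (any(table(labels) == 0L)) stop("a group is empty", call. = FALSE)
  vars <- schema_variables(cohort$schema)
  n <- length(labels)
  rows <- lapply(vars, function(v) {
    raw <- cohort$values[, v]
    obs <- !cohort$missing_mask[, v]
    g1 <- raw[obs & labels == ids[1]]
    g2 <- raw[obs & labels == ids[2]]
    zt <- mann_whitney(zdata$values[labels == ids[1], v],
                       zdata$values[labels == ids[2], v])
    e2 <- eta_squared(zt$Z, n)
    data.frame(variable = v,
               median_1 = stats::median(g1), iqr_1 = stats::IQR(g1),
               median_2 = stats::median(g2), iqr_2 = stats::IQR(g2),
               U = zt$U, Z = zt$Z, p = zt$p,
               eta_squared = as.numeric(e2),
               significant = zt$p < alpha_corrected,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$significant, out$p), , drop = FALSE]
}

#' Symptom frequency contrast between two groups
#'
#' Per symptom: presence frequencies per group over non-missing responses;
#' a chi-squared test on the 2 x 2 presence-by-group table, switching to
#' Fisher's exact test when any expected cell count falls below 5; and a
#' band by the 10-percentage-point rule (`more in group 1` / `more in
#' group 2` / `similar`). Symptoms with no responses at all are excluded
#' with a warning; degenerate tables (a symptom uniformly present or
#' absent) get `p = 1`.
#'
#' @param symptoms a `symptom_table`.
#' @param labels two-group label vector aligned with its rows.
#' @return data.frame: `symptom`, `freq_1`, `freq_2` (percent), `test`,
#'   `p`, `band`.
#' @export
symptom_contrast <- function(symptoms, labels) {
  ids <- sort(unique(labels))
  if (length(ids) != 2L) stop("exactly two groups required", call. = FALSE)
  pres <- symptoms$presence
  rows <- list()
  for (k in seq_along(symptoms$symptoms)) {
    resp <- pres[, k]
    keep <- !is.na(resp)
    if (!any(keep)) {
      warning("symptom '", symptoms$symptoms[k],
              "' has zero responses; excluded", call. = FALSE)
      next
    }
    g <- labels[keep]; r <- resp[keep]
    f1 <- mean(r[g == ids[1]])
    f2 <- mean(r[g == ids[2]])
    tab <- table(factor(r, levels = c(FALSE, TRUE)),
                 factor(g, levels = ids))
    if (any(rowSums(tab) == 0L)) {
      test <- "none"; p <- 1
    } else {
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        test <- "fisher"
        p <- stats::fisher.test(tab)$p.value
      } else {
        test <- "chi-squared"
        p <- stats::chisq.test(tab, correct = FALSE)$p.value
      }
    }
    diff <- 100 * (f1 - f2)
    band <- if (diff >= 10) "more in group 1"
    else if (diff <= -10) "more in group 2"
    else "similar"
    rows[[length(rows) + 1L]] <- data.frame(
      symptom = symptoms$symptoms[k],
      freq_1 = 100 * f1, freq_2 = 100 * f2,
      test = test, p = p, band = band, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
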