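#' Read a cohort CSV with the 9999 missing sentinel
#'
#' Parses a patient-by-variable CSV whose header must match the schema's
#' variable names in order. Every cell equal to 9999 is converted to an
#' entry of the missing mask; any other non-numeric cell is a parse error
#' naming its row and column. If a `<path>.json` sidecar written by
#' [write_cohort()] exists, patient ids and true labels are recovered
#' from it.
#'
#' @param path CSV path.
#' @param schema expected `feature_schema`; defaults to [default_schema()].
#' @return A `cohort_matrix`.
#' @export
read_cohort <- function(path, schema = default_schema()) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (!identical(colnames(df), schema_variables(schema))) {
    stop("CSV header does not match schema variables", call. = FALSE)
  }
  n <- nrow(df)
  vals <- matrix(NA_real_, n, ncol(df))
  mask <- matrix(FALSE, n, ncol(df))
  for (j in seq_len(ncol(df))) {
    raw <- trimws(df[[j]])
    miss <- raw == "9999"
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!miss & is.na(num))
    if (length(bad)) {
      stop(sprintf("non-numeric cell at row %d, column '%s': '%s'",
                   bad[1], colnames(df)[j], raw[bad[1]]), call. = FALSE)
    }
    num[miss] <- 0  # placeholder under the mask; never read back
    vals[, j] <- num
    mask[, j] <- miss
  }
  ids <- NULL; labels <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    ids <- meta$patient_ids
    if (!is.null(meta$true_labels) && length(meta$true_labels)) {
      labels <- as.integer(meta$true_labels)
    }
  }
  new_cohort_matrix(vals, mask, schema, true_labels = labels,
                    patient_ids = ids)
}

#' Replace missing entries by column medians
#'
#' Each masked cell is filled with the median of its column's observed
#' values (even counts use the midpoint of the two central order
#' statistics); observed cells are untouched and the returned mask is all
#' `FALSE`. A fully missing column is an error.
#'
#' @param cohort a `cohort_matrix`.
#' @return The imputed `cohort_matrix`.
#' @export
impute_median <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_matrix"))
  vals <- cohort$values
  mask <- cohort$missing_mask
  for (j in seq_len(ncol(vals))) {
    mj <- mask[, j]
    if (all(mj)) {
      stop("column '", colnames(vals)[j], "' is fully missing; cannot impute",
           call. = FALSE)
    }
    if (any(mj)) vals[mj, j] <- stats::median(vals[!mj, j])
  }
  cohort$values <- vals
  cohort$missing_mask[] <- FALSE
  cohort
}

#' Standardize an imputed cohort to z-scores
#'
#' Column-wise centring and scaling by the sample standard deviation
#' (n - 1 denominator). Constant columns are mapped to all-zero with a
#' warning rather than dropped, so column bookkeeping against the schema
#' stays intact. Raw-scale column medians, means and SDs are retained for
#' reporting on the measurement scale.
#'
#' @param cohort a fully imputed `cohort_matrix` (no masked cells).
#' @return A `zmatrix` object.
#' @export
zscore <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_matrix"))
  if (any(cohort$missing_mask)) {
    stop("cohort has missing entries; run impute_median() first",
         call. = FALSE)
  }
  vals <- cohort$values
  mu <- colMeans(vals)
  sd <- apply(vals, 2L, stats::sd)
  const <- sd == 0 | !is.finite(sd)
  if (any(const)) {
    warning("constant column(s) standardized to zero: ",
            paste(colnames(vals)[const], collapse = ", "), call. = FALSE)
  }
  z <- sweep(vals, 2L, mu, "-")
  z <- sweep(z, 2L, ifelse(const, 1, sd), "/")
  z[, const] <- 0
  structure(
    list(values = z,
         column_medians = apply(vals, 2L, stats::median),
         column_means = mu, column_sds = sd,
         schema = cohort$schema),
    class = "zmatrix"
  )
}

#' Impute and standardize in the study's order
#'
#' Convenience pipeline: median imputation first, then z-scoring.
#'
#' @param cohort a `cohort_matrix` (may contain masked cells).
#' @return A `zmatrix`.
#' @export
preprocess <- function(cohort) {
  zscore(impute_median(cohort))
}

#' Write a standardized matrix as TSV
#' @param z a `zmatrix`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_zmatrix <- function(z, path) {
  utils::write.table(as.data.frame(z$values), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.zmatrix <- function(x, ...) {
  cat("<zmatrix> ", nrow(x$values), " patients x ", ncol(x$values),
      " standardized variables\n", sep = "")
  invisible(x)
}
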