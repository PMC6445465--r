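#' Default group-separating effect specification
#'
#' Per-group medians and IQRs (raw measurement scale) for the six variables
#' that separate the two latent phenotypes in the default simulated cohort:
#' the caloric maximal slow-phase velocity summaries, the SOT composite
#' score, and static/dynamic visual acuity (LogMAR). Group 1 is the
#' vestibular-impaired phenotype (lower caloric responses, lower SOT
#' composite, worse acuity). The bitherrmal 30-degree mSPV for group 2 is
#' taken as a magnitude (13.30 deg/s); see the methods vignette for the
#' sign convention.
#'
#' @return data.frame with columns `variable`, `median_1`, `iqr_1`,
#'   `median_2`, `iqr_2`.
#' @export
default_effect_spec <- function() {
  data.frame(
    variable = c("sot_cs", "dva_dynamic", "dva_static",
                 "caloric_mSPV_30", "caloric_mSPV_44", "caloric_mSPV_sum"),
    median_1 = c(69.00, 0.38, -0.03, 7.25, 7.30, 27.60),
    iqr_1    = c(22.30, 0.84, 0.33, 6.70, 6.20, 18.20),
    median_2 = c(79.00, 0.20, -0.14, 13.30, 12.35, 50.95),
    iqr_2    = c(10.50, 0.20, 0.12, 10.00, 9.50, 31.00),
    stringsAsFactors = FALSE
  )
}

#' Default null (non-separating) variable specification
#'
#' Median/IQR pairs on plausible raw clinical scales for every schema
#' variable that does not separate the groups: VHIT gains near 1 with small
#' spread, SVV angles near 0 degrees, caloric latencies/durations in
#' seconds, and so on. The varied raw scales exercise the z-scoring step.
#' `gen_sex` is a 0/1 code drawn as Bernoulli (about 19% female, code 1).
#'
#' @param schema a `feature_schema`; defaults to [default_schema()].
#' @return data.frame with columns `variable`, `median`, `iqr`, `type`
#'   (`"gaussian"` or `"binary"`; for binary rows `median` holds the
#'   success probability).
#' @export
default_null_spec <- function(schema = default_schema()) {
  defaults <- c(
    sot_som = "90,8", sot_vis = "85,10", sot_vest = "70,15", sot_pref = "95,6",
    dva_loss = "0.25,0.30", dva_velocity = "120,40",
    dva_static_left = "-0.10,0.20", dva_static_right = "-0.10,0.20",
    dva_dynamic_left = "0.25,0.30", dva_dynamic_right = "0.25,0.30",
    hit_gain_lh = "0.95,0.12", hit_gain_rh = "0.96,0.12",
    hit_gain_la = "0.90,0.15", hit_gain_ra = "0.91,0.15",
    hit_gain_lp = "0.88,0.16", hit_gain_rp = "0.89,0.16",
    hit_asymmetry = "5,6", hit_saccade_overt = "10,15",
    hit_saccade_covert = "8,12",
    cvemp_asymmetry = "15,20", ovemp_asymmetry = "12,18",
    vemp_latency = "14,2",
    svv_static_mean = "0,2", svv_static_sd = "1.5,1",
    svv_dyn_cw_mean = "2,3", svv_dyn_cw_sd = "2,1.5",
    svv_dyn_ccw_mean = "-2,3", svv_dyn_ccw_sd = "2,1.5",
    svv_tilt_left_mean = "-2.5,3", svv_tilt_left_sd = "2,1.5",
    svv_tilt_right_mean = "2.5,3", svv_tilt_right_sd = "2,1.5",
    svv_offset = "0.5,1.5",
    caloric_index_30 = "10,12", caloric_index_44 = "10,12",
    caloric_asym_diff = "8,10", caloric_dominancy = "10,14",
    caloric_latency_30 = "60,20", caloric_latency_44 = "60,20",
    caloric_duration_30 = "90,30", caloric_duration_44 = "90,30",
    fundus_torsion_left = "6,5", fundus_torsion_right = "6,5",
    fundus_torsion_asym = "2,4",
    gen_age = "25,11", gen_days_since_injury = "52,140"
  )
  vars <- setdiff(schema_variables(schema), default_effect_spec()$variable)
  med <- iqr <- numeric(length(vars))
  type <- rep("gaussian", length(vars))
  for (i in seq_along(vars)) {
    v <- vars[i]
    if (v == "gen_sex") {
      med[i] <- 0.187; iqr[i] <- NA_real_; type[i] <- "binary"
    } else if (v %in% names(defaults)) {
      mi <- as.numeric(strsplit(defaults[[v]], ",")[[1]])
      med[i] <- mi[1]; iqr[i] <- mi[2]
    } else {
      med[i] <- 0; iqr[i] <- 1.349
    }
  }
  data.frame(variable = vars, median = med, iqr = iqr, type = type,
             stringsAsFactors = FALSE)
}

#' Block-wide caloric effect specification (signal-rich scenario)
#'
#' Extends [default_effect_spec()] so that every caloric variable carries
#' the group difference, not only the three mSPV summaries: each remaining
#' caloric variable's group medians sit symmetrically around its null
#' median at `+/- shift_iqr/2` of its IQR (per-variable standardized shift
#' of about 2). This emulates a battery whose caloric block responds as a
#' whole to reduced vestibular reflectivity — the regime in which a
#' quantization-based clustering pipeline can actually resolve the
#' phenotypes. The tightly specified [default_effect_spec()] scenario
#' (only the six headline variables informative) is statistically
#' unresolvable at n = 96; see the methods vignette.
#'
#' @param shift_iqr total between-group shift in units of each variable's
#'   IQR (default 1.5).
#' @param schema a `feature_schema`; defaults to [default_schema()].
#' @return data.frame in the [default_effect_spec()] format.
#' @export
blockwide_effect_spec <- function(shift_iqr = 1.5, schema = default_schema()) {
  base <- default_effect_spec()
  null_spec <- default_null_spec(schema)
  extra_vars <- setdiff(schema$blocks$Caloric, base$variable)
  rows <- null_spec[match(extra_vars, null_spec$variable), ]
  extra <- data.frame(
    variable = rows$variable,
    median_1 = rows$median - shift_iqr * rows$iqr / 2,
    iqr_1 = rows$iqr,
    median_2 = rows$median + shift_iqr * rows$iqr / 2,
    iqr_2 = rows$iqr,
    stringsAsFactors = FALSE
  )
  rbind(base, extra)
}

#' Default per-group symptom prevalences
#'
#' Twelve-item concussion symptom inventory prevalences. Items with a
#' between-group difference (headache, blurred vision, balance problems,
#' sensitivity to light, dizziness) carry distinct group probabilities;
#' the remaining items are common to both groups.
#'
#' @return data.frame with columns `symptom`, `prev_1`, `prev_2`.
#' @export
default_symptom_prevalence <- function() {
  data.frame(
    symptom = c("headache", "dizziness", "neck_pain",
                "difficulty_concentrating", "blurred_vision",
                "sensitivity_to_light", "balance_problems",
                "feeling_confused", "coordination_problems", "nausea",
                "difficulty_remembering", "feeling_slowed_down"),
    prev_1 = c(0.76, 0.45, 0.38, 0.39, 0.39, 0.27, 0.27,
               0.05, 0.04, 0.05, 0.01, 0.00),
    prev_2 = c(0.59, 0.51, 0.38, 0.39, 0.24, 0.18, 0.15,
               0.05, 0.04, 0.05, 0.01, 0.00),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic cohort generator. Defaults emulate
#' the study cohort: 96 patients in two latent groups of 38 and 58,
#' group separation on the caloric mSPV / SOT composite / DVA variables,
#' 0.85% missingness, occasional 5-sigma outliers, and group-specific
#' symptom prevalences.
#'
#' @param n_patients cohort size.
#' @param group_sizes two counts summing to `n_patients` (group 1, group 2).
#' @param effect_spec data.frame as [default_effect_spec()].
#' @param null_spec data.frame as [default_null_spec()].
#' @param effect_scale multiplier on all group-median differences; 1 keeps
#'   the configured separations, 0 collapses the cohort to a single
#'   population (a null cohort).
#' @param missing_rate fraction of cells masked at random, in `[0, 1)`.
#' @param outlier_rate per-patient probability of one 5-sigma shifted
#'   variable.
#' @param symptom_prevalence data.frame as [default_symptom_prevalence()].
#' @param symptom_missing_rate fraction of symptom responses missing.
#' @param seed integer; the generator is fully reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 96L,
                       group_sizes = c(38L, 58L),
                       effect_spec = default_effect_spec(),
                       null_spec = NULL,
                       effect_scale = 1,
                       missing_rate = 0.0085,
                       outlier_rate = 0.05,
                       symptom_prevalence = default_symptom_prevalence(),
                       symptom_missing_rate = 0.173,
                       seed = 1L) {
  if (length(group_sizes) != 2L || sum(group_sizes) != n_patients) {
    stop("`group_sizes` must be two counts summing to `n_patients`",
         call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("`missing_rate` must lie in [0, 1)", call. = FALSE)
  }
  if (outlier_rate < 0 || outlier_rate >= 1) {
    stop("`outlier_rate` must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(n_patients = as.integer(n_patients),
         group_sizes = as.integer(group_sizes),
         effect_spec = effect_spec, null_spec = null_spec,
         effect_scale = effect_scale,
         missing_rate = missing_rate, outlier_rate = outlier_rate,
         symptom_prevalence = symptom_prevalence,
         symptom_missing_rate = symptom_missing_rate,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Construct a cohort matrix
#'
#' @param values numeric matrix, patients x variables, raw scale.
#' @param missing_mask logical matrix of the same shape (`TRUE` = missing).
#' @param schema the `feature_schema` describing the columns.
#' @param true_labels optional integer group ids (synthetic cohorts only).
#' @param patient_ids optional character ids; defaults to `P001`, ...
#' @return A `cohort_matrix` object.
#' @export
new_cohort_matrix <- function(values, missing_mask, schema,
                              true_labels = NULL, patient_ids = NULL) {
  if (!all(dim(values) == dim(missing_mask))) {
    stop("values and missing_mask must have identical dimensions",
         call. = FALSE)
  }
  if (ncol(values) != schema$total_variables) {
    stop("column count does not match schema", call. = FALSE)
  }
  if (any(values[!missing_mask] == 9999, na.rm = TRUE)) {
    stop("sentinel 9999 present in observed cells; ingest via read_cohort()",
         call. = FALSE)
  }
  if (is.null(patient_ids)) {
    patient_ids <- sprintf("P%03d", seq_len(nrow(values)))
  }
  colnames(values) <- schema_variables(schema)
  rownames(values) <- patient_ids
  dimnames(missing_mask) <- dimnames(values)
  structure(
    list(values = values, missing_mask = missing_mask, schema = schema,
         true_labels = true_labels, patient_ids = patient_ids),
    class = "cohort_matrix"
  )
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat("<cohort_matrix> ", nrow(x$values), " patients x ", ncol(x$values),
      " variables; ", sum(x$missing_mask), " missing cells",
      if (!is.null(x$true_labels)) " (synthetic, labelled)", "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic cohort and symptom table
#'
#' Draws a patient-by-variable matrix with two latent groups: Gaussian
#' within-group distributions whose medians/IQRs follow the effect
#' specification on the separating variables and a shared null distribution
#' elsewhere (sigma = IQR/1.349). Outliers, uniform missingness and a
#' per-group Bernoulli symptom table are then layered on. Bit-identical
#' output for identical config and seed.
#'
#' @param config a [sim_config()].
#' @param schema a `feature_schema`; defaults to [default_schema()].
#' @return list with elements `cohort` (a `cohort_matrix` carrying
#'   `true_labels`) and `symptoms` (a `symptom_table`).
#' @export
generate_cohort <- function(config, schema = default_schema()) {
  stopifnot(inherits(config, "sim_config"))
  null_spec <- config$null_spec
  if (is.null(null_spec)) null_spec <- default_null_spec(schema)
  vars <- schema_variables(schema)
  eff <- config$effect_spec
  missing_eff <- setdiff(eff$variable, vars)
  if (length(missing_eff)) {
    stop("effect variables not in schema: ",
         paste(missing_eff, collapse = ", "), call. = FALSE)
  }
  n <- config$n_patients
  g <- rep.int(c(1L, 2L), config$group_sizes)
  sds <- numeric(length(vars))
  names(sds) <- vars

  values <- with_seed(config$seed, {
    m <- matrix(0, n, length(vars))
    for (j in seq_along(vars)) {
      v <- vars[j]
      if (v %in% eff$variable) {
        e <- eff[eff$variable == v, ]
        # collapse toward the size-weighted centre when effect_scale != 1
        ctr <- sum(c(e$median_1, e$median_2) * config$group_sizes) / n
        m1 <- ctr + config$effect_scale * (e$median_1 - ctr)
        m2 <- ctr + config$effect_scale * (e$median_2 - ctr)
        s1 <- e$iqr_1 / 1.349
        s2 <- e$iqr_2 / 1.349
        m[g == 1L, j] <- stats::rnorm(config$group_sizes[1], m1, s1)
        m[g == 2L, j] <- stats::rnorm(config$group_sizes[2], m2, s2)
        sds[j] <- sqrt((s1^2 + s2^2) / 2)
      } else {
        sp <- null_spec[null_spec$variable == v, ]
        if (nrow(sp) != 1L) stop("no null spec for variable ", v, call. = FALSE)
        if (sp$type == "binary") {
          m[, j] <- stats::rbinom(n, 1L, sp$median)
          sds[j] <- NA_real_  # never outlier-shifted
        } else {
          s <- sp$iqr / 1.349
          m[, j] <- stats::rnorm(n, sp$median, s)
          sds[j] <- s
        }
      }
    }
    # occasional outliers: one variable per affected patient shifted 5 sigma
    hit <- stats::runif(n) < config$outlier_rate
    shiftable <- which(!is.na(sds))
    for (i in which(hit)) {
      j <- sample(shiftable, 1L)
      m[i, j] <- m[i, j] + sample(c(-5, 5), 1L) * sds[j]
    }
    m
  })

  cohort <- new_cohort_matrix(values,
                              matrix(FALSE, n, length(vars)),
                              schema, true_labels = g)
  if (config$missing_rate > 0) {
    cohort <- inject_missing(cohort, config$missing_rate,
                             seed = config$seed + 101L)
  }
  symptoms <- generate_symptoms(config, g)
  list(cohort = cohort, symptoms = symptoms)
}

generate_symptoms <- function(config, groups) {
  sp <- config$symptom_prevalence
  n <- length(groups)
  with_seed(config$seed + 202L, {
    pres <- matrix(NA, n, nrow(sp),
                   dimnames = list(sprintf("P%03d", seq_len(n)), sp$symptom))
    for (k in seq_len(nrow(sp))) {
      p <- ifelse(groups == 1L, sp$prev_1[k], sp$prev_2[k])
      pres[, k] <- stats::rbinom(n, 1L, p) == 1L
    }
    if (config$symptom_missing_rate > 0) {
      drop <- matrix(stats::runif(n * nrow(sp)) < config$symptom_missing_rate,
                     n, nrow(sp))
      pres[drop] <- NA
    }
    structure(list(symptoms = sp$symptom, presence = pres),
              class = "symptom_table")
  })
}

#' Mask a random fraction of cells
#'
#' Marks cells missing uniformly at random at the given expected rate,
#' without ever masking an entire column (one random entry of a fully
#' masked column is re-exposed). Deterministic given the seed; a rate of 0
#' returns the input untouched.
#'
#' @param cohort a `cohort_matrix`.
#' @param rate expected masked fraction, in `[0, 1)`.
#' @param seed integer.
#' @return The cohort with an updated `missing_mask`.
#' @export
inject_missing <- function(cohort, rate, seed) {
  stopifnot(inherits(cohort, "cohort_matrix"))
  if (rate < 0 || rate >= 1) stop("`rate` must lie in [0, 1)", call. = FALSE)
  if (rate == 0) return(cohort)
  dims <- dim(cohort$values)
  mask <- with_seed(seed, {
    m <- matrix(stats::runif(prod(dims)) < rate, dims[1], dims[2])
    full <- which(colSums(m) == dims[1])
    for (j in full) m[sample.int(dims[1], 1L), j] <- FALSE
    m
  })
  cohort$missing_mask <- cohort$missing_mask | mask
  dimnames(cohort$missing_mask) <- dimnames(cohort$values)
  cohort
}

#' Write a cohort to CSV with the 9999 missing sentinel
#'
#' @param cohort a `cohort_matrix`.
#' @param path output CSV path.
#' @param sidecar write `<path>.json` with schema blocks, patient ids and
#'   (if present) true labels.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, sidecar = TRUE) {
  vals <- cohort$values
  vals[cohort$missing_mask] <- 9999
  df <- as.data.frame(vals)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (sidecar) {
    jsonlite::write_json(
      list(blocks = cohort$schema$blocks,
           patient_ids = cohort$patient_ids,
           true_labels = cohort$true_labels),
      paste0(path, ".json"), auto_unbox = FALSE, digits = NA
    )
  }
  invisible(path)
}

#' Write a symptom table to CSV (9999 = missing response)
#' @param symptoms a `symptom_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_symptoms <- function(symptoms, path) {
  m <- ifelse(is.na(symptoms$presence), 9999L, as.integer(symptoms$presence))
  utils::write.csv(as.data.frame(m), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a symptom table written by [write_symptoms()]
#' @param path CSV path.
#' @return A `symptom_table`.
#' @export
read_symptoms <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df)
  pres <- m == 1L
  pres[m == 9999L] <- NA
  structure(list(symptoms = colnames(m), presence = pres),
            class = "symptom_table")
}
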