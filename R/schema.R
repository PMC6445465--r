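#' Default balance/vestibular feature schema
#'
#' The canonical 8-block, 53-variable layout of the diagnostic battery:
#' sensory organization test (SOT, 5 variables), dynamic visual acuity
#' (DVA, 8), video head impulse test (VHIT, 9), vestibular-evoked myogenic
#' potentials (VEMPs, 3), subjective visual vertical (SVV, 11), caloric
#' irrigation (11), fundus photography (3) and general epidemiological
#' variables (sex, age, days since injury; 3). Variable names are schematic
#' stand-ins with the field's usual abbreviations (mSPV = maximal slow-phase
#' velocity, cs = composite score, LogMAR acuity scales).
#'
#' @return A `feature_schema` object: a named list of character vectors
#'   (one per block) with attribute `total_variables`.
#' @examples
#' sc <- default_schema()
#' sc$total_variables            # 53
#' lengths(sc$blocks)[["Caloric"]] # 11
#' @export
default_schema <- function() {
  blocks <- list(
    SOT = c("sot_cs", "sot_som", "sot_vis", "sot_vest", "sot_pref"),
    DVA = c("dva_static", "dva_dynamic", "dva_loss", "dva_velocity",
            "dva_static_left", "dva_static_right",
            "dva_dynamic_left", "dva_dynamic_right"),
    VHIT = c("hit_gain_lh", "hit_gain_rh", "hit_gain_la", "hit_gain_ra",
             "hit_gain_lp", "hit_gain_rp", "hit_asymmetry",
             "hit_saccade_overt", "hit_saccade_covert"),
    VEMPs = c("cvemp_asymmetry", "ovemp_asymmetry", "vemp_latency"),
    SVV = c("svv_static_mean", "svv_static_sd",
            "svv_dyn_cw_mean", "svv_dyn_cw_sd",
            "svv_dyn_ccw_mean", "svv_dyn_ccw_sd",
            "svv_tilt_left_mean", "svv_tilt_left_sd",
            "svv_tilt_right_mean", "svv_tilt_right_sd",
            "svv_offset"),
    Caloric = c("caloric_mSPV_30", "caloric_mSPV_44", "caloric_mSPV_sum",
                "caloric_index_30", "caloric_index_44",
                "caloric_asym_diff", "caloric_dominancy",
                "caloric_latency_30", "caloric_latency_44",
                "caloric_duration_30", "caloric_duration_44"),
    Fundus = c("fundus_torsion_left", "fundus_torsion_right",
               "fundus_torsion_asym"),
    General = c("gen_sex", "gen_age", "gen_days_since_injury")
  )
  new_feature_schema(blocks)
}

#' Construct a feature schema
#'
#' @param blocks named list of character vectors, one entry per test block,
#'   in battery order. Variable names must be unique across blocks.
#' @return A `feature_schema` object.
#' @export
new_feature_schema <- function(blocks) {
  stopifnot(is.list(blocks), length(blocks) >= 1L, !is.null(names(blocks)))
  vars <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(vars)) {
    stop("variable names must be unique across blocks", call. = FALSE)
  }
  structure(
    list(blocks = blocks, total_variables = length(vars)),
    class = "feature_schema"
  )
}

#' All variable names of a schema, in block order
#' @param schema a `feature_schema`.
#' @return Character vector of length `schema$total_variables`.
#' @export
schema_variables <- function(schema) {
  unlist(schema$blocks, use.names = FALSE)
}

#' Block membership of each variable
#' @param schema a `feature_schema`.
#' @return Named character vector mapping variable name to block name.
#' @export
schema_block_of <- function(schema) {
  out <- rep(names(schema$blocks), lengths(schema$blocks))
  names(out) <- schema_variables(schema)
  out
}

#' Drop one block (or named variables) from a schema
#' @param schema a `feature_schema`.
#' @param block block name to remove, or `NULL`.
#' @param variables variable names to remove, or `NULL`.
#' @return A smaller `feature_schema`.
#' @export
schema_drop <- function(schema, block = NULL, variables = NULL) {
  blocks <- schema$blocks
  if (!is.null(block)) {
    if (!block %in% names(blocks)) stop("unknown block: ", block, call. = FALSE)
    blocks[[block]] <- NULL
  }
  if (!is.null(variables)) {
    blocks <- lapply(blocks, setdiff, y = variables)
    blocks <- blocks[lengths(blocks) > 0L]
  }
  new_feature_schema(blocks)
}

#' @export
print.feature_schema <- function(x, ...) {
  cat("<feature_schema> ", x$total_variables, " variables in ",
      length(x$blocks), " blocks\n", sep = "")
  for (b in names(x$blocks)) {
    cat(sprintf("  %-8s %2d: %s\n", b, length(x$blocks[[b]]),
                paste(x$blocks[[b]], collapse = ", ")))
  }
  invisible(x)
}
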