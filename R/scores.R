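# Integrated behavioral z-scores: each raw ethogram variable is normalized
# against the pooled cohort (all strains together as reference group), sign
# aligned so that larger means more of the named dimension, and averaged
# into one integrated score per dimension per mouse per trial.

#' Default dimension specification
#'
#' Maps every raw behavioral variable to its dimension (avoidance,
#' exploration, locomotion) with the direction in which it enters the
#' integrated score: latency-type and inverse-direction variables are
#' sign-flipped so a higher integrated score always means more of the
#' dimension (more avoidance, more exploration, more locomotion). For
#' avoidance this puts board entries and percentage time on board at -1 and
#' latency to first board entry at +1. User-overridable.
#'
#' @return data.frame with columns `variable`, `dimension`, `sign`.
#' @export
dimension_spec_default <- function() {
  reg <- behavioral_variable_registry()
  data.frame(variable = reg$variable, dimension = reg$dimension,
             sign = reg$sign, stringsAsFactors = FALSE)
}

validate_dimension_spec <- function(spec) {
  stopifnot(is.data.frame(spec),
            all(c("variable", "dimension", "sign") %in% names(spec)))
  if (anyDuplicated(spec$variable)) {
    stop_bt("each variable must appear in exactly one dimension")
  }
  if (!all(spec$sign %in% c(-1, 1))) stop_bt("signs must be +1 or -1")
  spec
}

#' Pooled-reference z-score normalization
#'
#' Centers and scales a single variable's values against the pooled cohort
#' (sample SD, denominator n - 1). The output has mean 0 and SD 1 over the
#' reference.
#'
#' @param values numeric vector of one variable across the pooled cohort.
#' @param variable name used in error messages.
#' @return numeric z-score vector.
#' @export
zscore_normalize <- function(values, variable = "variable") {
  if (length(values) < 2L) stop_bt("need at least 2 observations to normalize '",
                                   variable, "'")
  if (anyNA(values)) stop_bt("missing values in '", variable, "'")
  s <- sd(values)
  if (s == 0) stop_bt("degenerate variable '", variable,
                      "': zero reference SD")
  (values - mean(values)) / s
}

#' Integrate member-variable z-scores into one dimension score
#'
#' The integrated score for a mouse x trial is the mean over member
#' variables of `sign(variable) * z(variable)`.
#'
#' @param z_table long data.frame with columns `mouse_id`, `trial`,
#'   `variable`, `z`.
#' @param spec data.frame with columns `variable`, `sign` for the members of
#'   one dimension.
#' @return data.frame `mouse_id`, `trial`, `score`, one row per mouse x trial.
#' @export
integrate_dimension <- function(z_table, spec) {
  stopifnot(all(c("mouse_id", "trial", "variable", "z") %in% names(z_table)),
            all(c("variable", "sign") %in% names(spec)))
  z_table <- z_table[z_table$variable %in% spec$variable, ]
  cells <- unique(z_table[, c("mouse_id", "trial")])
  have <- table(z_table$mouse_id, z_table$trial)
  expected <- merge(cells, spec["variable"], by = NULL)
  missing <- merge(expected, z_table, all.x = TRUE,
                   by = c("mouse_id", "trial", "variable"))
  missing <- missing[is.na(missing$z), c("mouse_id", "trial", "variable")]
  if (nrow(missing) > 0L) {
    ex <- head(missing, 5L)
    stop_bt("missing member variable(s): ",
            paste(sprintf("(%s, trial %s, %s)", ex$mouse_id, ex$trial,
                          ex$variable), collapse = ", "),
            if (nrow(missing) > 5L) sprintf(" and %d more", nrow(missing) - 5L))
  }
  sgn <- setNames(spec$sign, spec$variable)
  z_table$signed <- sgn[z_table$variable] * z_table$z
  out <- aggregate(signed ~ mouse_id + trial, data = z_table, FUN = mean)
  names(out)[names(out) == "signed"] <- "score"
  out[order(out$mouse_id, out$trial), ]
}

#' Compute integrated dimension scores from a raw observation table
#'
#' Normalizes every variable against the pooled cohort, applies the
#' dimension specification's sign map, and averages members into one
#' integrated z-score per dimension per mouse per trial.
#'
#' @param raw long-format raw observation table (`mouse_id`, `trial`,
#'   `variable`, `value`, plus covariates).
#' @param spec a dimension specification, default [dimension_spec_default()].
#' @return a `DimensionScores` data.frame: `mouse_id`, `trial`,
#'   `avoidance_z`, `exploration_z`, `locomotion_z`.
#' @export
compute_dimension_scores <- function(raw, spec = dimension_spec_default()) {
  spec <- validate_dimension_spec(spec)
  stopifnot(all(c("mouse_id", "trial", "variable", "value") %in% names(raw)))
  if (anyDuplicated(raw[, c("mouse_id", "trial", "variable")])) {
    stop_bt("(mouse, trial, variable) rows must be unique")
  }
  z_table <- raw[, c("mouse_id", "trial", "variable")]
  z_table$z <- NA_real_
  for (v in unique(raw$variable)) {
    idx <- raw$variable == v
    z_table$z[idx] <- zscore_normalize(raw$value[idx], v)
  }
  out <- NULL
  for (d in unique(spec$dimension)) {
    dint <- integrate_dimension(z_table, spec[spec$dimension == d, ])
    names(dint)[names(dint) == "score"] <- paste0(d, "_z")
    out <- if (is.null(out)) dint else merge(out, dint,
                                             by = c("mouse_id", "trial"))
  }
  out <- out[order(out$mouse_id, out$trial), ]
  rownames(out) <- NULL
  out
}
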