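# Confounder removal: per behavioral dimension, a mixed model with strain
# and experimenter as fixed factors, crossed random intercepts for mouse,
# test group and test order, CAR(1) within-mouse correlation across the
# equally spaced trials, and a separate residual variance per stratum
# (default: strain). Trial is deliberately excluded so the residual
# trajectories keep the across-trial habituation signal for clustering.
# Residuals are conditional standardized Pearson residuals:
# (observed - fixed - predicted random intercepts) divided by the
# model-implied SD sqrt(sd_ar1^2 + stratum residual variance); the CAR(1)
# component is retained in the residual because it carries the
# trial-to-trial structure.

#' Specification of the residualization model
#'
#' @param transforms named character vector giving the response
#'   transformation per dimension ([transform_dimension()] kinds). Defaults
#'   to log-shift for avoidance, sqrt-shift for exploration and rank for
#'   locomotion.
#' @param fixed character vector of fixed factors.
#' @param random character vector of random-intercept factors.
#' @param car1 logical, include a CAR(1) within-mouse correlation across
#'   trials.
#' @param var_stratum factor name receiving its own residual variance per
#'   level, or `NULL` for a single variance.
#' @return an object of class `residual_model_spec`.
#' @export
residual_model_spec <- function(transforms = c(avoidance = "log-shift",
                                               exploration = "sqrt-shift",
                                               locomotion = "rank"),
                                fixed = c("strain", "experimenter"),
                                random = c("mouse_id", "test_group",
                                           "test_order"),
                                car1 = TRUE,
                                var_stratum = "strain") {
  if ("trial" %in% c(fixed, random)) {
    stop_bt("'trial' must never enter the residualization model")
  }
  stopifnot(all(names(transforms) %in% DIMENSIONS))
  spec <- list(transforms = transforms, fixed = fixed, random = random,
               car1 = isTRUE(car1), var_stratum = var_stratum)
  class(spec) <- "residual_model_spec"
  spec
}

# error early, naming the aliased factor, if the fixed design is singular
check_fixed_rank <- function(data, fixed) {
  mm <- model.matrix(as.formula(paste("~", paste(fixed, collapse = " + "))),
                     data = data)
  q <- qr(mm)
  if (q$rank < ncol(mm)) {
    aliased <- colnames(mm)[q$pivot[(q$rank + 1L):ncol(mm)]]
    stop_bt("singular design: aliased term(s) ", paste(aliased, collapse = ", "))
  }
  invisible(TRUE)
}

fit_one_dimension <- function(data, spec) {
  check_fixed_rank(data, spec$fixed)
  fixed_rhs <- paste(spec$fixed, collapse = " + ")
  use_mixed <- length(spec$random) > 0L || spec$car1
  fallbacks <- character(0)

  if (!use_mixed && is.null(spec$var_stratum)) {
    fit <- lm(as.formula(paste("y ~", fixed_rhs)), data = data)
    sig <- sqrt(sum(resid(fit)^2) / fit$df.residual)
    return(list(residuals = resid(fit) / sig, method = "ols",
                phi = 0, converged = TRUE, fallbacks = fallbacks, fit = fit))
  }

  build_formula <- function(car1) {
    re <- if (length(spec$random) > 0L) {
      paste(sprintf("(1 | %s)", spec$random), collapse = " + ")
    }
    ar <- if (car1) "ar1(trial_f + 0 | mouse_id)"
    as.formula(paste("y ~", paste(c(fixed_rhs, re, ar), collapse = " + ")))
  }
  dispf <- if (!is.null(spec$var_stratum)) {
    as.formula(paste("~", spec$var_stratum))
  } else ~1

  # Accept a fit when its point estimates are finite and usable. A
  # non-positive-definite Hessian with a variance component at the zero
  # boundary is expected here: the latent type structure is deliberately
  # not modelled, and nuisance variances can be truly zero. Such fits give
  # stable point estimates and residuals; they are accepted with a note.
  try_fit <- function(car1) {
    fit <- tryCatch(
      suppressWarnings(glmmTMB::glmmTMB(build_formula(car1),
                                        dispformula = dispf,
                                        data = data, REML = TRUE)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    est_ok <- all(is.finite(glmmTMB::fixef(fit)$cond)) &&
      all(is.finite(predict(fit, re.form = NA))) &&
      all(is.finite(predict(fit, type = "disp"))) &&
      all(predict(fit, type = "disp") > 0)
    if (!est_ok) return(NULL)
    attr(fit, "clean_convergence") <-
      isTRUE(fit$sdr$pdHess) && fit$fit$convergence == 0
    fit
  }

  fit <- if (spec$car1) try_fit(TRUE)
  car1_used <- spec$car1
  if (is.null(fit)) {
    if (spec$car1) fallbacks <- c(fallbacks, "car1 dropped (phi = 0)")
    fit <- try_fit(FALSE)
    car1_used <- FALSE
  }
  if (!is.null(fit) && !isTRUE(attr(fit, "clean_convergence"))) {
    fallbacks <- c(fallbacks,
                   "accepted at variance boundary (non-positive-definite Hessian)")
  }
  if (is.null(fit)) {
    fallbacks <- c(fallbacks, "random effects dropped (fixed-effects-only fit)")
    ols <- lm(as.formula(paste("y ~", fixed_rhs)), data = data)
    sig <- sqrt(sum(resid(ols)^2) / ols$df.residual)
    return(list(residuals = resid(ols) / sig, method = "ols-fallback",
                phi = 0, converged = FALSE, fallbacks = fallbacks, fit = ols))
  }

  # conditional prediction: fixed effects + random intercept BLUPs only
  # (warnings about the BLUP covariance are irrelevant: only point
  # estimates are used)
  pred <- predict(fit, re.form = NA)
  re <- suppressWarnings(glmmTMB::ranef(fit)$cond)
  for (g in spec$random) {
    blup <- re[[g]]
    if (!is.null(blup) && "(Intercept)" %in% colnames(blup)) {
      pred <- pred + blup[as.character(data[[g]]), "(Intercept)"]
    }
  }
  raw_resid <- data$y - pred

  # model-implied SD: ar1 process + per-stratum residual
  disp_sd <- predict(fit, type = "disp")
  vc <- glmmTMB::VarCorr(fit)$cond
  sd_ar1 <- 0
  for (nm in names(vc)) {
    if (nrow(vc[[nm]]) == N_TRIALS) sd_ar1 <- attr(vc[[nm]], "stddev")[1]
  }
  phi <- 0
  if (car1_used && sd_ar1 > 0) {
    for (nm in names(vc)) {
      if (nrow(vc[[nm]]) == N_TRIALS) {
        cr <- attr(vc[[nm]], "correlation")
        phi <- cr[1, 2]
      }
    }
  }
  total_sd <- sqrt(sd_ar1^2 + disp_sd^2)
  list(residuals = raw_resid / total_sd, method = "glmmTMB",
       phi = unname(phi),
       converged = isTRUE(attr(fit, "clean_convergence")),
       fallbacks = fallbacks, fit = fit)
}

#' Fit the residualization model and return standardized residual trajectories
#'
#' @param scores a `DimensionScores` data.frame (`mouse_id`, `trial`,
#'   `avoidance_z`, `exploration_z`, `locomotion_z`).
#' @param covariates per-mouse covariate table with `mouse_id` and the
#'   factors named in `spec` (e.g. the `truth` element of a simulated
#'   cohort).
#' @param spec a [residual_model_spec()].
#' @return object of class `residual_trajectories`: a list with
#'   `residuals` (long data.frame `mouse_id`, `trial`, `dimension`,
#'   `residual`), and per-dimension `models` metadata (method, CAR(1) phi,
#'   convergence, fallbacks). Residuals are conditional on the predicted
#'   random intercepts; this choice is recorded in the metadata.
#' @export
fit_residual_model <- function(scores, covariates,
                               spec = residual_model_spec()) {
  stopifnot(inherits(spec, "residual_model_spec"))
  need <- c("mouse_id", "trial", paste0(DIMENSIONS, "_z"))
  stopifnot(all(need %in% names(scores)))
  trials_per_mouse <- table(scores$mouse_id)
  if (any(trials_per_mouse != N_TRIALS)) {
    stop_bt("every mouse must have exactly ", N_TRIALS, " trials")
  }
  data <- merge(scores, covariates, by = "mouse_id", sort = FALSE)
  data <- data[order(data$mouse_id, data$trial), ]
  for (f in unique(c(spec$fixed, spec$random, spec$var_stratum))) {
    if (!f %in% names(data)) stop_bt("covariate '", f, "' not found")
    data[[f]] <- factor(data[[f]])
  }
  data$trial_f <- factor(data$trial, levels = 1:N_TRIALS)

  out <- NULL
  models <- list()
  for (d in DIMENSIONS) {
    dd <- data
    kind <- spec$transforms[[d]] %||% "none"
    dd$y <- transform_dimension(dd[[paste0(d, "_z")]], kind)
    fitted <- fit_one_dimension(dd, spec)
    models[[d]] <- fitted[c("method", "phi", "converged", "fallbacks")]
    models[[d]]$transform <- kind
    out <- rbind(out, data.frame(
      mouse_id = dd$mouse_id, trial = dd$trial, dimension = d,
      residual = fitted$residuals, stringsAsFactors = FALSE))
  }
  if (any(!is.finite(out$residual))) stop_bt("non-finite residuals produced")
  res <- list(residuals = out, models = models,
              standardization = "conditional")
  class(res) <- "residual_trajectories"
  res
}

#' @export
print.residual_trajectories <- function(x, ...) {
  cat("Standardized Pearson residual trajectories (conditional)\n")
  for (d in names(x$models)) {
    m <- x$models[[d]]
    cat(sprintf("  %-12s %-10s transform=%-10s phi=%.3f%s\n", d, m$method,
                m$transform, m$phi,
                if (length(m$fallbacks)) paste0(" [", paste(m$fallbacks,
                                                            collapse = "; "),
                                                "]") else ""))
  }
  invisible(x)
}

#' Reshape residual trajectories into a clustering matrix
#'
#' @param x a `residual_trajectories` object or its long `residuals`
#'   data.frame.
#' @return numeric matrix, one row per mouse, `5 trials x 3 dimensions = 15`
#'   columns named `dimension.trial`, with a `traj_dim` attribute.
#' @export
trajectory_matrix <- function(x) {
  df <- if (inherits(x, "residual_trajectories")) x$residuals else x
  stopifnot(all(c("mouse_id", "trial", "dimension", "residual") %in% names(df)))
  mice <- sort(unique(df$mouse_id))
  cols <- as.vector(outer(1:N_TRIALS, DIMENSIONS,
                          function(t, d) paste(d, t, sep = ".")))
  mat <- matrix(NA_real_, nrow = length(mice), ncol = length(cols),
                dimnames = list(mice, cols))
  key <- paste(df$dimension, df$trial, sep = ".")
  for (j in cols) {
    sub <- df[key == j, ]
    mat[sub$mouse_id, j] <- sub$residual
  }
  if (anyNA(mat)) stop_bt("incomplete trajectories: each mouse needs 5 trials x 3 dimensions")
  attr(mat, "traj_dim") <- c(trials = N_TRIALS, dimensions = 3L)
  mat
}
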