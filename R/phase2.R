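# Phase-2 factorial analysis: linear mixed models of the single-trial
# integrated z-scores with treatment, strain, (pool,) experimenter and all
# their interactions as fixed effects and a random block (test-day)
# intercept; partial eta squared with noncentral-F confidence intervals,
# Dunn-Sidak corrected estimated-marginal-mean contrasts with Cohen's d,
# and a balanced-vs-unbalanced divergence report.

#' Dunn-Sidak familywise alpha adjustment
#'
#' Per-test level `1 - (1 - alpha)^(1/m)` controlling the familywise error
#' over `m` comparisons.
#'
#' @param alpha familywise level in (0, 1).
#' @param m number of comparisons, `>= 1`.
#' @return adjusted per-test alpha.
#' @export
dunn_sidak <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop_bt("alpha must lie in (0, 1)")
  }
  if (!is.numeric(m) || m < 1) stop_bt("m must be >= 1")
  1 - (1 - alpha)^(1 / m)
}

#' Partial eta squared with a noncentral-F confidence interval
#'
#' `SS_effect / (SS_effect + SS_error)`, with a 95% CI obtained by
#' inverting the noncentral-F distribution of the observed F statistic, and
#' an interpretation band (small <= 0.03 < medium < 0.10 <= large < 0.20 <=
#' very large).
#'
#' @param ss_effect,ss_error sums of squares (`>= 0`, not both zero).
#' @param df_effect,df_error degrees of freedom.
#' @param conf_level confidence level.
#' @return list with `value`, `ci` (length 2), `band`.
#' @export
partial_eta_squared <- function(ss_effect, ss_error, df_effect, df_error,
                                conf_level = 0.95) {
  if (ss_effect < 0 || ss_error < 0) stop_bt("sums of squares must be >= 0")
  if (ss_effect == 0 && ss_error == 0) stop_bt("both sums of squares are zero")
  value <- ss_effect / (ss_effect + ss_error)
  if (ss_error == 0) {
    return(list(value = 1, ci = c(NA_real_, 1), band = eta_band(1)))
  }
  f <- (ss_effect / df_effect) / (ss_error / df_error)
  ci <- pes_ci_from_f(f, df_effect, df_error, conf_level)
  list(value = value, ci = ci, band = eta_band(value))
}

eta_band <- function(eta) {
  ifelse(eta <= 0.03, "small",
         ifelse(eta < 0.10, "medium",
                ifelse(eta < 0.20, "large", "very large")))
}

# CI for partial eta^2 by noncentral-F inversion of the observed F
pes_ci_from_f <- function(f, df1, df2, conf_level = 0.95) {
  a <- (1 - conf_level) / 2
  eta_of <- function(ncp) ncp / (ncp + df1 + df2 + 1)
  bound <- function(p_target) {
    # ncp such that pf(f, df1, df2, ncp) == p_target
    if (pf(f, df1, df2, 0) < p_target) return(0)
    hi <- max(10, 2 * f * df1)
    while (pf(f, df1, df2, hi) > p_target) hi <- hi * 2
    uniroot(function(ncp) pf(f, df1, df2, ncp) - p_target,
            c(0, hi), tol = 1e-8)$root
  }
  c(eta_of(bound(1 - a)), eta_of(bound(a)))
}

check_cells <- function(data, factors) {
  tab <- table(interaction(data[factors], drop = FALSE))
  empty <- names(tab)[tab == 0]
  if (length(empty) > 0L) {
    stop_bt("empty design cell(s): ", paste(head(empty, 6), collapse = ", "),
            if (length(empty) > 6) sprintf(" and %d more", length(empty) - 6))
  }
}

#' Fit the phase-2 factorial mixed model for every behavioral dimension
#'
#' For each dimension the (optionally transformed) integrated z-score is
#' modelled with all fixed factors and all their interactions plus a random
#' block intercept; F tests use the between-within denominator-df
#' convention of `nlme::lme`. Each fixed term is reported with partial eta
#' squared, its noncentral-F confidence interval and a band label.
#'
#' @param responses per-mouse data.frame with the dimension score columns
#'   (`avoidance_z`, ...), the fixed factors and `block`.
#' @param fixed character vector of fixed factor names.
#' @param random name of the random blocking factor.
#' @param transforms response transformation per dimension (default:
#'   log-shift for exploration, rank for locomotion).
#' @param dimensions behavioral dimensions to fit (default all three).
#' @return object of class `factorial_fit`: per dimension an `anova` table
#'   of `AnovaRow`s (effect, F, dfs, p, partial eta squared + CI + band)
#'   and the fitted model.
#' @export
fit_factorial_model <- function(responses,
                                fixed = c("treatment", "strain", "pool",
                                          "experimenter"),
                                random = "block",
                                transforms = c(avoidance = "none",
                                               exploration = "log-shift",
                                               locomotion = "rank"),
                                dimensions = DIMENSIONS) {
  for (f in c(fixed, random)) {
    if (!f %in% names(responses)) stop_bt("factor '", f, "' not found")
    responses[[f]] <- factor(responses[[f]])
  }
  check_cells(responses, fixed)
  check_fixed_rank(responses, paste(fixed, collapse = " * "))
  out <- list()
  for (d in dimensions) {
    dd <- responses
    dd$y <- transform_dimension(dd[[paste0(d, "_z")]],
                                transforms[[d]] %||% "none")
    form <- as.formula(paste("y ~", paste(fixed, collapse = " * ")))
    fit <- nlme::lme(form, random = as.formula(paste("~ 1 |", random)),
                     data = dd,
                     control = nlme::lmeControl(opt = "optim",
                                                returnObject = TRUE))
    an <- anova(fit)
    rows <- rownames(an) != "(Intercept)"
    tab <- data.frame(effect = rownames(an)[rows],
                      numDF = an$numDF[rows], denDF = an$denDF[rows],
                      F = an$`F-value`[rows], p = an$`p-value`[rows],
                      row.names = NULL, stringsAsFactors = FALSE)
    pes <- lapply(seq_len(nrow(tab)), function(i) {
      eta <- tab$F[i] * tab$numDF[i] / (tab$F[i] * tab$numDF[i] + tab$denDF[i])
      ci <- pes_ci_from_f(tab$F[i], tab$numDF[i], tab$denDF[i])
      list(value = eta, ci = ci)
    })
    tab$eta_p2 <- vapply(pes, `[[`, numeric(1), "value")
    tab$eta_lower <- vapply(pes, function(p) p$ci[1], numeric(1))
    tab$eta_upper <- vapply(pes, function(p) p$ci[2], numeric(1))
    tab$band <- eta_band(tab$eta_p2)
    out[[d]] <- list(anova = tab, model = fit,
                     transform = transforms[[d]] %||% "none")
  }
  class(out) <- "factorial_fit"
  out
}

#' @export
print.factorial_fit <- function(x, ...) {
  for (d in names(x)) {
    cat(sprintf("== %s (transform: %s) ==\n", d, x[[d]]$transform))
    print(x[[d]]$anova, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Estimated-marginal-mean contrasts with Dunn-Sidak control and Cohen's d
#'
#' Pairwise contrasts of estimated marginal means from a fitted mixed
#' model, tested against the Dunn-Sidak adjusted per-test alpha for a
#' family of `m` comparisons; Cohen's d standardizes the estimate by the
#' model residual SD.
#'
#' @param model a fitted `nlme::lme` model (e.g. from
#'   [fit_factorial_model()], element `model`).
#' @param specs emmeans specification, e.g. `~ strain` or
#'   `~ treatment | strain`.
#' @param m family size; defaults to the number of contrasts produced.
#' @param alpha familywise level.
#' @param data the data used to fit the model (required by emmeans for lme
#'   fits in some call contexts).
#' @return data.frame of `ContrastRow`s: contrast, estimate, SE, df,
#'   statistic, p, adjusted alpha, significance, Cohen's d with CI, band.
#' @export
emm_contrasts <- function(model, specs, m = NULL, alpha = 0.05, data = NULL) {
  emm <- tryCatch(
    suppressMessages(
      if (is.null(data)) emmeans::emmeans(model, specs)
      else emmeans::emmeans(model, specs, data = data)),
    error = function(e) stop_bt("emmeans failed: ", conditionMessage(e)))
  contr <- emmeans::contrast(emm, "pairwise", adjust = "none")
  n_contr <- nrow(as.data.frame(summary(contr)))
  m <- m %||% n_contr
  summarize_contrasts(contr, model, dunn_sidak(alpha, m))
}

#' Classify term-level divergence between balanced and unbalanced analyses
#'
#' For every model term, compares significance at level `alpha` between the
#' pool analyses: significant in both, in neither, only in the unbalanced
#' pool (`augmented` -- response-type variation inflating an apparent
#' effect) or only in the balanced pool (`unmasked` -- type variation
#' hiding a real effect that matching reveals).
#'
#' @param balanced,unbalanced `AnovaRow` tables over the same terms
#'   (data.frames with `effect` and `p`), or `factorial_fit` elements.
#' @param alpha significance level.
#' @return data.frame: effect, p in each pool, classification.
#' @export
compare_pools <- function(balanced, unbalanced, alpha = 0.05) {
  tab_of <- function(x) if (is.data.frame(x)) x else x$anova
  b <- tab_of(balanced); u <- tab_of(unbalanced)
  if (!setequal(b$effect, u$effect)) {
    stop_bt("term sets differ between the two analyses")
  }
  u <- u[match(b$effect, u$effect), ]
  sig_b <- b$p < alpha
  sig_u <- u$p < alpha
  cls <- ifelse(sig_b & sig_u, "both",
                ifelse(!sig_b & !sig_u, "neither",
                       ifelse(sig_u, "augmented", "unmasked")))
  data.frame(effect = b$effect, p_balanced = b$p, p_unbalanced = u$p,
             classification = cls, stringsAsFactors = FALSE)
}
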