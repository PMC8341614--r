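# Cluster characterization: per behavioral dimension, a linear mixed model
# of the integrated z-scores with cluster, trial and their interaction as
# fixed effects and a random intercept + trial slope per mouse; estimated
# marginal mean contrasts between clusters within trial and between trials
# 1 and 5 within cluster, with Cohen's d on the model residual SD scale.

#' Characterize clusters on each behavioral dimension
#'
#' @param scores `DimensionScores` data.frame over 5 trials.
#' @param labels named cluster label vector (or a `cluster_solution`).
#' @param transforms response transformation per dimension; the default rank
#'   transforms locomotion and leaves the other dimensions untransformed.
#' @param alpha familywise level for the post hoc families.
#' @return list of class `cluster_characterization`, one element per
#'   dimension with `anova` (F tests for cluster, trial, cluster x trial),
#'   `cluster_by_trial` and `trial1_vs_5` contrast tables (estimate, SE, t,
#'   p, Cohen's d with CI and Wahlsten band), and the fitted model.
#' @export
characterize_clusters <- function(scores, labels,
                                  transforms = c(avoidance = "none",
                                                 exploration = "none",
                                                 locomotion = "rank"),
                                  alpha = 0.05) {
  labels <- solution_labels(labels)
  stopifnot(!is.null(names(labels)))
  if (length(unique(labels)) < 2L) stop_bt("need two or more clusters")
  sizes <- table(labels)
  singleton <- names(sizes)[sizes == 1L]
  data0 <- scores[scores$mouse_id %in% names(labels), ]
  if (!all(table(data0$mouse_id) == N_TRIALS)) {
    stop_bt("every mouse must have exactly ", N_TRIALS, " trials")
  }
  out <- list()
  for (d in DIMENSIONS) {
    dd <- data.frame(
      mouse_id = data0$mouse_id,
      y = transform_dimension(data0[[paste0(d, "_z")]],
                              transforms[[d]] %||% "none"),
      cluster = factor(labels[data0$mouse_id]),
      trial_f = factor(data0$trial, levels = 1:N_TRIALS),
      trial_num = data0$trial)
    fit <- nlme::lme(y ~ cluster * trial_f,
                     random = ~ trial_num | mouse_id, data = dd,
                     control = nlme::lmeControl(opt = "optim",
                                                returnObject = TRUE))
    an <- anova(fit)
    an <- data.frame(effect = rownames(an), numDF = an$numDF,
                     denDF = an$denDF, F = an$`F-value`,
                     p = an$`p-value`, row.names = NULL)
    an <- an[an$effect != "(Intercept)", ]
    res <- list(anova = an, model = fit, transform = transforms[[d]] %||% "none")
    if (length(singleton) > 0L) {
      res$contrasts_skipped <- paste("singleton cluster(s):",
                                     paste(singleton, collapse = ", "))
    } else {
      emm_ct <- suppressMessages(
        emmeans::emmeans(fit, ~ cluster | trial_f, data = dd))
      ct <- summarize_contrasts(emmeans::contrast(emm_ct, "pairwise",
                                                  adjust = "none"),
                                fit, dunn_sidak(alpha, 2))
      emm_tr <- suppressMessages(
        emmeans::emmeans(fit, ~ trial_f | cluster, data = dd))
      t15 <- emmeans::contrast(
        emm_tr, list(`trial1 - trial5` = c(1, 0, 0, 0, -1)), adjust = "none")
      tt <- summarize_contrasts(t15, fit, dunn_sidak(alpha, 2))
      res$cluster_by_trial <- ct
      res$trial1_vs_5 <- tt
    }
    out[[d]] <- res
  }
  class(out) <- "cluster_characterization"
  out
}

# emmGrid contrasts -> ContrastRow table with Cohen's d on residual-SD scale
summarize_contrasts <- function(contr, fit, adj_alpha) {
  s <- as.data.frame(summary(contr))
  sig <- stats::sigma(fit)
  byc <- setdiff(names(s), c("contrast", "estimate", "SE", "df", "t.ratio",
                             "z.ratio", "p.value"))
  stat <- if ("t.ratio" %in% names(s)) s$t.ratio else s$z.ratio
  desc <- s$contrast
  for (b in byc) desc <- paste0(desc, " | ", b, "=", s[[b]])
  d <- s$estimate / sig
  half <- qt(0.975, s$df) * s$SE / sig
  data.frame(
    contrast = desc, estimate = s$estimate, SE = s$SE, df = s$df,
    statistic = stat, p = s$p.value, adj_alpha = adj_alpha,
    significant = s$p.value < adj_alpha,
    cohens_d = d, d_lower = d - half, d_upper = d + half,
    band = wahlsten_band(d), stringsAsFactors = FALSE)
}

#' Interpretation band for Cohen's d (neurobehavioral cut-offs)
#'
#' Bands at |d| cut points 0.5, 1.0 and 1.5: small, medium, large, very
#' large.
#'
#' @param d numeric vector of standardized mean differences.
#' @return character vector of band labels.
#' @export
wahlsten_band <- function(d) {
  a <- abs(d)
  ifelse(a < 0.5, "small",
         ifelse(a < 1.0, "medium",
                ifelse(a < 1.5, "large", "very large")))
}
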