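# End-to-end pipeline: simulate -> score -> residualize -> cluster ->
# stability -> design -> phase-2 simulate -> analyze -> compare, with one
# config, deterministic derived stage seeds, CSV outputs and a YAML
# manifest (seeds, files, checksums, warnings).

#' Pipeline configuration
#'
#' @param synthetic a [synthetic_config()]; its `seed` is overridden by the
#'   derived stage seed.
#' @param dimension_spec dimension specification for the scoring stage.
#' @param residual_spec a [residual_model_spec()].
#' @param k_min,k_max candidate cluster numbers.
#' @param n_restarts k-means restarts per k.
#' @param gap_B reference sets for the gap statistic.
#' @param boot_B bootstrap samples for the stability stage.
#' @param boot_restarts restarts per bootstrap re-clustering.
#' @param alpha significance level for phase-2 analyses.
#' @param stages character vector of stages to run (dependencies are
#'   checked).
#' @param master_seed master seed; every stage derives its own stream from
#'   it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            dimension_spec = dimension_spec_default(),
                            residual_spec = residual_model_spec(),
                            k_min = 2L, k_max = 6L, n_restarts = 100L,
                            gap_B = 25L, boot_B = 200L, boot_restarts = 50L,
                            alpha = 0.05,
                            stages = c("simulate", "score", "residualize",
                                       "cluster", "stability", "design",
                                       "phase2", "analyze", "compare"),
                            master_seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

PIPELINE_DEPS <- list(
  score = "simulate", residualize = "simulate", cluster = "residualize",
  stability = "cluster", design = c("simulate", "cluster"),
  phase2 = "design", analyze = "phase2", compare = "analyze")

#' Run the full response-type pipeline
#'
#' Executes the enabled stages in order, writes every stage's tabular
#' output as CSV under `out_dir`, and returns (and writes) a manifest with
#' derived seeds, output files, md5 checksums, collected warnings and the
#' headline results. Identical config and master seed reproduce identical
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return the manifest, invisibly (class `pipeline_manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("btrun")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- config$stages
  for (s in stages) {
    miss <- setdiff(PIPELINE_DEPS[[s]], stages)
    if (length(miss) > 0L) {
      stop_bt("stage '", s, "' requires disabled stage(s): ",
              paste(miss, collapse = ", "))
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(master_seed = config$master_seed, stages = list(),
                   warnings = character(0))
  seeds <- sapply(c("simulate", "cluster", "stability", "design", "phase2"),
                  function(s) derive_seed(config$master_seed, s))
  manifest$stage_seeds <- as.list(seeds)
  env <- new.env()

  emit <- function(stage, name, df) {
    path <- file.path(out_dir, paste0(name, ".csv"))
    write.csv(df, path, row.names = FALSE)
    rec <- manifest$stages[[stage]] %||% list(files = character(0))
    rec$files <- c(rec$files, path)
    rec$checksums <- c(rec$checksums %||% character(0),
                       setNames(unname(tools::md5sum(path)), basename(path)))
    manifest$stages[[stage]] <<- rec
    path
  }

  run_stage <- function(stage, fun) {
    if (!stage %in% stages) return(invisible(NULL))
    withCallingHandlers(
      tryCatch(fun(), error = function(e) {
        writeLines(paste("FAILED at stage:", stage, "-", conditionMessage(e)),
                   file.path(out_dir, "FAILED"))
        stop_bt("pipeline failed at stage '", stage, "': ",
                conditionMessage(e))
      }),
      warning = function(w) {
        manifest$warnings <<- c(manifest$warnings,
                                paste0(stage, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }

  run_stage("simulate", function() {
    cfg <- config$synthetic
    cfg$seed <- seeds[["simulate"]]
    env$cohort <- simulate_phase1_cohort(cfg)
    env$sim_config <- cfg
    emit("simulate", "raw_observations", env$cohort$raw)
    emit("simulate", "cohort_truth", env$cohort$truth)
    emit("simulate", "latent_scores", env$cohort$scores)
    message(sprintf("[simulate] %d mice (seed %d)", nrow(env$cohort$truth),
                    seeds[["simulate"]]))
  })
  run_stage("score", function() {
    env$scores <- compute_dimension_scores(env$cohort$raw,
                                           config$dimension_spec)
    emit("score", "dimension_scores", env$scores)
    message("[score] integrated z-scores computed from raw variables")
  })
  run_stage("residualize", function() {
    src <- env$scores %||% env$cohort$scores
    env$residuals <- fit_residual_model(src, env$cohort$truth,
                                        config$residual_spec)
    emit("residualize", "residual_trajectories", env$residuals$residuals)
    for (d in names(env$residuals$models)) {
      fb <- env$residuals$models[[d]]$fallbacks
      if (length(fb) > 0L) {
        manifest$warnings <<- c(manifest$warnings,
                                paste0("residualize/", d, ": ",
                                       paste(fb, collapse = "; ")))
      }
    }
    message("[residualize] standardized Pearson residual trajectories ready")
  })
  run_stage("cluster", function() {
    traj <- trajectory_matrix(env$residuals)
    env$gap <- gap_statistic(traj, k_max = config$k_max, B = config$gap_B,
                             seed = seeds[["cluster"]])
    sols <- lapply(config$k_min:config$k_max, function(k) {
      kmeans_longitudinal(traj, k, n_restarts = config$n_restarts,
                          seed = seeds[["cluster"]])
    })
    sel <- select_k_cvi(sols)
    env$solution <- sols[[which(config$k_min:config$k_max == sel$k_selected)]]
    env$k_selected <- sel$k_selected
    manifest$stages$cluster$k_selected <<- sel$k_selected
    manifest$stages$cluster$one_cluster_verdict <<- env$gap$one_cluster
    manifest$stages$cluster$cvi_note <<-
      "k selected by plain majority vote of Calinski-Harabasz, Davies-Bouldin and Ray-Turi"
    emit("cluster", "cluster_assignments",
         data.frame(mouse_id = names(env$solution$labels),
                    cluster = as.integer(env$solution$labels)))
    emit("cluster", "cvi_table", sel$cvi_table)
    emit("cluster", "gap_table", env$gap$table)
    message(sprintf("[cluster] k_selected = %d (one-cluster verdict: %s)",
                    sel$k_selected, env$gap$one_cluster))
  })
  run_stage("stability", function() {
    traj <- trajectory_matrix(env$residuals)
    env$stability <- bootstrap_stability(traj, env$solution,
                                         B = config$boot_B,
                                         seed = seeds[["stability"]],
                                         n_restarts = config$boot_restarts)
    emit("stability", "jaccard_per_mouse", env$stability$per_mouse)
    emit("stability", "jaccard_per_cluster", env$stability$per_cluster)
    message(sprintf("[stability] per-cluster Jaccard: %s",
                    paste(sprintf("%.3f", env$stability$per_cluster$jaccard),
                          collapse = ", ")))
  })
  run_stage("design", function() {
    mice <- env$cohort$truth
    # response type from the clustering, mapped to A/B by majority truth label
    labels <- env$solution$labels[mice$mouse_id]
    mice$latent_type <- majority_type_map(labels, mice$latent_type)
    env$design <- build_default_design(mice, seed = seeds[["design"]])
    emit("design", "design_table", as.data.frame(env$design))
    message(sprintf("[design] %d pairs / %d mice", nrow(env$design),
                    2L * nrow(env$design)))
  })
  run_stage("phase2", function() {
    env$phase2 <- simulate_phase2_responses(env$design, env$sim_config,
                                            seed = seeds[["phase2"]])
    emit("phase2", "phase2_responses", env$phase2)
    message("[phase2] single-trial responses simulated")
  })
  run_stage("analyze", function() {
    env$fit_all <- fit_factorial_model(env$phase2)
    env$fit_bal <- fit_factorial_model(
      env$phase2[env$phase2$pool == "balanced", ],
      fixed = c("treatment", "strain", "experimenter"))
    env$fit_unb <- fit_factorial_model(
      env$phase2[env$phase2$pool == "unbalanced", ],
      fixed = c("treatment", "strain", "experimenter"))
    for (d in DIMENSIONS) {
      emit("analyze", paste0("anova_combined_", d), env$fit_all[[d]]$anova)
      emit("analyze", paste0("anova_balanced_", d), env$fit_bal[[d]]$anova)
      emit("analyze", paste0("anova_unbalanced_", d), env$fit_unb[[d]]$anova)
    }
    message("[analyze] factorial models fitted (combined + per pool)")
  })
  run_stage("compare", function() {
    cmp <- lapply(DIMENSIONS, function(d) {
      cbind(dimension = d,
            compare_pools(env$fit_bal[[d]], env$fit_unb[[d]],
                          alpha = config$alpha))
    })
    env$divergence <- do.call(rbind, cmp)
    emit("compare", "pool_divergence", env$divergence)
    message("[compare] balanced vs unbalanced divergence report written")
  })

  manifest$out_dir <- out_dir
  manifest$k_selected <- env$k_selected
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  manifest$results <- as.list(env)
  class(manifest) <- "pipeline_manifest"
  invisible(manifest)
}

# map cluster labels to the A/B vocabulary by majority overlap with a
# reference type vector (used when handing cluster output to the designer)
majority_type_map <- function(labels, reference_types) {
  out <- character(length(labels))
  for (cl in unique(labels)) {
    idx <- labels == cl
    tab <- table(reference_types[idx])
    out[idx] <- names(tab)[which.max(tab)]
  }
  out
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat("Pipeline run:", x$out_dir, "\n")
  cat("  master seed:", x$master_seed, "\n")
  if (!is.null(x$k_selected)) cat("  k selected:", x$k_selected, "\n")
  cat("  stages:", paste(names(x$stages), collapse = ", "), "\n")
  if (length(x$warnings) > 0L) {
    cat("  warnings:\n"); for (w in x$warnings) cat("   -", w, "\n")
  }
  invisible(x)
}
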