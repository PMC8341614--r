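# Shared fixtures, built once per test run. The default cohort and its
# residualization are reused by several files because the mixed-model fits
# are the slow step.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

default_cohort <- function() {
  cached("cohort", function() simulate_phase1_cohort(synthetic_config()))
}

default_residuals <- function() {
  cached("residuals", function() {
    fit_residual_model(default_cohort()$scores, default_cohort()$truth)
  })
}

default_traj <- function() {
  cached("traj", function() trajectory_matrix(default_residuals()))
}

# two well-separated gaussian blobs of 15-column trajectories
two_blob_traj <- function(n_per = 4L, sep = 10, sd = 1, seed = 1L) {
  set.seed(seed)
  x <- rbind(
    matrix(rnorm(n_per * 15, 0, sd), ncol = 15),
    matrix(rnorm(n_per * 15, sep, sd), ncol = 15))
  rownames(x) <- sprintf("M%02d", seq_len(2L * n_per))
  x
}

# exhaustive-minimum within-cluster SS over all 2-cluster label vectors
brute_force_best_bipartition <- function(x) {
  n <- nrow(x)
  best_ss <- Inf
  best_labels <- NULL
  for (code in 0:(2^n - 1)) {
    labels <- as.integer(intToBits(code))[seq_len(n)] + 1L
    if (length(unique(labels)) < 2L) next
    ss <- 0
    for (j in 1:2) {
      sub <- x[labels == j, , drop = FALSE]
      ss <- ss + sum(sweep(sub, 2, colMeans(sub))^2)
    }
    if (ss < best_ss) {
      best_ss <- ss
      best_labels <- labels
    }
  }
  list(ss = best_ss, labels = best_labels)
}

# minimum total within-pair weight difference over all perfect matchings
brute_force_min_pairing <- function(weights) {
  n <- length(weights)
  stopifnot(n %% 2 == 0)
  rec <- function(idx) {
    if (length(idx) == 0) return(0)
    i <- idx[1]
    best <- Inf
    for (j in idx[-1]) {
      best <- min(best, abs(weights[i] - weights[j]) +
                    rec(setdiff(idx, c(i, j))))
    }
    best
  }
  rec(seq_len(n))
}
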