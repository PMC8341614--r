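# Multivariate longitudinal k-means: joint clustering of the 5-trial x
# 3-dimension residual trajectories under the Frobenius (joint Euclidean)
# distance, with many random restarts, gap-statistic screening against a
# uniform reference, and k selection by a majority vote of cluster validity
# indices (Calinski-Harabasz, Davies-Bouldin, Ray-Turi).

#' Distance between two trajectories
#'
#' Euclidean distance over all 15 (trial, dimension) entries, i.e. the
#' Frobenius norm of the difference of the two 5 x 3 matrices.
#'
#' @param a,b numeric 5 x 3 matrices (or length-15 vectors).
#' @return non-negative scalar.
#' @export
traj_distance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop_bt("shape mismatch between trajectories")
  if (anyNA(a) || anyNA(b)) stop_bt("trajectories must be finite")
  sqrt(sum((a - b)^2))
}

# squared distances of every row of x to every row of centers
dist2_matrix <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") -
    2 * tcrossprod(x, centers)
  d2[d2 < 0] <- 0
  d2
}

within_ss <- function(x, labels, centers) {
  sum((x - centers[labels, , drop = FALSE])^2)
}

lloyd_once <- function(x, k, max_iter) {
  n <- nrow(x)
  centers <- x[sample.int(n, k), , drop = FALSE]
  labels <- rep(1L, n)
  prev_ss <- Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- dist2_matrix(x, centers)
    new_labels <- max.col(-d2, ties.method = "first")
    # repair empty clusters by reseeding from the farthest point
    for (j in seq_len(k)) {
      if (!any(new_labels == j)) {
        far <- which.max(d2[cbind(seq_len(n), new_labels)])
        centers[j, ] <- x[far, ]
        new_labels[far] <- j
      }
    }
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(x[new_labels == j, , drop = FALSE])
    }
    ss <- within_ss(x, new_labels, centers)
    if (ss > prev_ss + 1e-8) {
      stop_bt("internal error: within-cluster SS increased during Lloyd iteration")
    }
    if (identical(new_labels, labels) || iter >= max_iter) {
      labels <- new_labels
      break
    }
    labels <- new_labels
    prev_ss <- ss
  }
  list(labels = labels, centers = centers,
       ss = within_ss(x, labels, centers), iterations = iter)
}

#' Multi-restart k-means over joint behavioral trajectories
#'
#' Lloyd iterations under [traj_distance()] until assignments stabilize (or
#' an iteration cap is hit), repeated over `n_restarts` random
#' initializations (k distinct trajectories sampled without replacement,
#' one derived RNG stream per (k, restart)); the solution with the smallest
#' total within-cluster sum of squares is retained.
#'
#' @param trajectories numeric matrix, one row per mouse (see
#'   [trajectory_matrix()]).
#' @param k number of clusters, `>= 2`.
#' @param n_restarts number of random restarts.
#' @param seed integer seed; restart streams are derived from it.
#' @param max_iter Lloyd iteration cap per restart.
#' @return object of class `cluster_solution`: `k`, named `labels`,
#'   `centers` (k x 15), `tot_withinss`, per-restart `restart_ss` and
#'   `iterations`, and the three `cvi` values.
#' @export
kmeans_longitudinal <- function(trajectories, k, n_restarts = 100L,
                                seed = 1L, max_iter = 100L) {
  x <- as.matrix(trajectories)
  n <- nrow(x)
  if (k < 2L) stop_bt("k must be >= 2")
  if (k > n) stop_bt("k exceeds the number of trajectories")
  if (n_restarts < 1L) stop_bt("n_restarts must be >= 1")
  best <- NULL
  restart_ss <- numeric(n_restarts)
  iterations <- integer(n_restarts)
  for (r in seq_len(n_restarts)) {
    set.seed(derive_seed(seed, sprintf("kmeans/k=%d/restart=%d", k, r)))
    sol <- lloyd_once(x, k, max_iter)
    restart_ss[r] <- sol$ss
    iterations[r] <- sol$iterations
    if (is.null(best) || sol$ss < best$ss) best <- sol
  }
  labels <- setNames(best$labels, rownames(x))
  out <- list(k = k, labels = labels, centers = best$centers,
              tot_withinss = best$ss, restart_ss = restart_ss,
              iterations = iterations, n_restarts = n_restarts,
              cvi = cluster_validity_indices(x, best$labels, best$centers))
  class(out) <- "cluster_solution"
  out
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("Trajectory k-means solution: k = %d, n = %d, within-SS = %.3f\n",
              x$k, length(x$labels), x$tot_withinss))
  print(table(cluster = x$labels))
  cat(sprintf("  CVI: CH = %.2f, DB = %.3f, RT = %.3f (%d restarts)\n",
              x$cvi["calinski_harabasz"], x$cvi["davies_bouldin"],
              x$cvi["ray_turi"], x$n_restarts))
  invisible(x)
}

#' Cluster centers as trial x dimension trajectories
#'
#' @param solution a `cluster_solution`.
#' @return array `k x 5 x 3` (cluster x trial x dimension).
#' @export
center_trajectories <- function(solution) {
  k <- solution$k
  arr <- array(NA_real_, dim = c(k, N_TRIALS, 3L),
               dimnames = list(cluster = seq_len(k), trial = 1:N_TRIALS,
                               dimension = DIMENSIONS))
  for (d in seq_along(DIMENSIONS)) {
    cols <- paste(DIMENSIONS[d], 1:N_TRIALS, sep = ".")
    idx <- if (!is.null(colnames(solution$centers))) cols
           else (d - 1L) * N_TRIALS + 1:N_TRIALS
    arr[, , d] <- solution$centers[, idx, drop = FALSE]
  }
  arr
}

#' Cluster validity indices of a partition
#'
#' Calinski-Harabasz (maximize), Davies-Bouldin (minimize) and Ray-Turi
#' (minimize), computed with the joint trajectory distance.
#'
#' @param x trajectory matrix.
#' @param labels integer cluster labels.
#' @param centers optional precomputed centers.
#' @return named numeric vector.
#' @export
cluster_validity_indices <- function(x, labels, centers = NULL) {
  x <- as.matrix(x)
  k <- length(unique(labels))
  n <- nrow(x)
  if (is.null(centers)) {
    centers <- t(sapply(sort(unique(labels)), function(j) {
      colMeans(x[labels == j, , drop = FALSE])
    }))
  }
  sizes <- as.integer(table(factor(labels, levels = seq_len(k))))
  grand <- colMeans(x)
  W <- within_ss(x, labels, centers)
  B <- sum(sizes * rowSums(sweep(centers, 2, grand)^2))
  ch <- if (k > 1L && W > 0) (B / (k - 1)) / (W / (n - k)) else Inf

  # mean (unsquared) distance to own centroid, per cluster
  s <- sapply(seq_len(k), function(j) {
    mean(sqrt(rowSums(sweep(x[labels == j, , drop = FALSE], 2,
                            centers[j, ])^2)))
  })
  m <- as.matrix(stats::dist(centers))
  db <- mean(sapply(seq_len(k), function(i) {
    max(((s[i] + s[-i]) / m[i, -i]))
  }))
  rt <- (W / n) / min(m[upper.tri(m)]^2)
  c(calinski_harabasz = ch, davies_bouldin = db, ray_turi = rt)
}

#' Gap statistic for the number of clusters
#'
#' Compares observed within-cluster dispersion to B uniform reference data
#' sets drawn over each feature's observed range:
#' `gap(k) = mean_b log W*_k - log W_k`. The one-cluster verdict applies
#' the one-standard-error rule: the data are best left unpartitioned iff
#' `gap(1) >= gap(2) - SE(2)`.
#'
#' @param trajectories trajectory matrix.
#' @param k_max largest k evaluated.
#' @param B number of reference data sets (`>= 10`).
#' @param seed integer seed.
#' @param n_restarts restarts per k-means run inside the statistic.
#' @return object of class `gap_result`: data.frame `k`, `logW`,
#'   `E_logW`, `gap`, `se`, and `one_cluster` verdict.
#' @export
gap_statistic <- function(trajectories, k_max = 6L, B = 50L, seed = 1L,
                          n_restarts = 25L) {
  x <- as.matrix(trajectories)
  if (B < 10L) stop_bt("B must be >= 10")
  if (max(dist2_matrix(x, x[1, , drop = FALSE])) == 0) {
    stop_bt("degenerate data: all trajectories identical")
  }
  n <- nrow(x)
  wk <- function(y, k, seed) {
    if (k == 1L) sum(sweep(y, 2, colMeans(y))^2)
    else kmeans_longitudinal(y, k, n_restarts = n_restarts,
                             seed = seed)$tot_withinss
  }
  logW <- sapply(1:k_max, function(k) log(wk(x, k, derive_seed(seed,
    paste0("gap/obs/k=", k)))))
  lo <- apply(x, 2, min); hi <- apply(x, 2, max)
  logWstar <- matrix(NA_real_, nrow = B, ncol = k_max)
  for (b in seq_len(B)) {
    set.seed(derive_seed(seed, paste0("gap/ref/", b)))
    ref <- sapply(seq_along(lo), function(j) runif(n, lo[j], hi[j]))
    for (k in 1:k_max) {
      logWstar[b, k] <- log(wk(ref, k, derive_seed(seed,
        sprintf("gap/ref/%d/k=%d", b, k))))
    }
  }
  gap <- colMeans(logWstar) - logW
  se <- apply(logWstar, 2, sd) * sqrt(1 + 1 / B)
  tab <- data.frame(k = 1:k_max, logW = logW, E_logW = colMeans(logWstar),
                    gap = gap, se = se)
  out <- list(table = tab, one_cluster = gap[1] >= gap[2] - se[2], B = B)
  class(out) <- "gap_result"
  out
}

#' @export
print.gap_result <- function(x, ...) {
  cat(sprintf("Gap statistic (B = %d reference sets)\n", x$B))
  print(x$table, row.names = FALSE, digits = 4)
  cat(if (x$one_cluster) "Verdict: data best represented by a single cluster\n"
      else "Verdict: cluster structure present (more than one cluster)\n")
  invisible(x)
}

#' Select the number of clusters by a CVI majority vote
#'
#' Each index votes for its optimal k (maximum for Calinski-Harabasz,
#' minimum for Davies-Bouldin and Ray-Turi); the k with the most votes
#' wins, ties broken toward the smallest k.
#'
#' @param solutions list of `cluster_solution` objects for k = 2..k_max.
#' @return list: `k_selected`, per-index `votes`, and the `cvi_table`.
#' @export
select_k_cvi <- function(solutions) {
  if (length(solutions) < 2L) stop_bt("need solutions for at least 2 values of k")
  ks <- as.integer(vapply(solutions, function(s) s$k, numeric(1)))
  if (anyDuplicated(ks)) stop_bt("duplicate k among solutions")
  cvi <- t(vapply(solutions, function(s) s$cvi, numeric(3)))
  rownames(cvi) <- ks
  votes <- c(
    calinski_harabasz = ks[which.max(cvi[, "calinski_harabasz"])],
    davies_bouldin = ks[which.min(cvi[, "davies_bouldin"])],
    ray_turi = ks[which.min(cvi[, "ray_turi"])])
  counts <- table(votes)
  winners <- as.integer(names(counts)[counts == max(counts)])
  list(k_selected = min(winners), votes = votes,
       cvi_table = data.frame(k = ks, cvi, row.names = NULL))
}
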