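# Bootstrap cluster stability: resample mice with replacement, re-cluster,
# align labels to the base solution, and compute per-mouse and per-cluster
# Jaccard indices (number of times a mouse lands in its base cluster over
# the number of bootstrap samples evaluated for it).

solution_labels <- function(x) {
  if (inherits(x, "cluster_solution")) x$labels
  else if (is.numeric(x) || is.integer(x)) x
  else stop_bt("expected a cluster_solution or a label vector")
}

#' Align candidate cluster labels to a reference solution
#'
#' Finds the label permutation maximizing the total overlap of shared
#' individuals between matched clusters (optimal assignment on the k x k
#' contingency table, by exhaustive search over permutations; k is small).
#'
#' @param reference,candidate `cluster_solution` objects or named label
#'   vectors.
#' @return integer vector `perm` with `perm[j]` = reference label matched to
#'   candidate label `j`.
#' @export
align_cluster_labels <- function(reference, candidate) {
  ref <- solution_labels(reference)
  cand <- solution_labels(candidate)
  shared <- intersect(names(ref), names(cand))
  if (length(shared) == 0L) stop_bt("no shared individuals between solutions")
  k_ref <- max(ref)
  k_cand <- max(cand)
  k <- max(k_ref, k_cand)
  tab <- matrix(0L, nrow = k, ncol = k)
  for (id in shared) tab[ref[[id]], cand[[id]]] <- tab[ref[[id]], cand[[id]]] + 1L
  best <- NULL; best_overlap <- -1L
  for (p in permutations(k)) {
    ov <- sum(tab[cbind(p, seq_len(k))])
    if (ov > best_overlap) { best_overlap <- ov; best <- p }
  }
  perm <- best[seq_len(k_cand)]
  perm[perm > k_ref] <- NA_integer_ # extra candidate clusters are unmatched
  perm
}

#' Bootstrap Jaccard stability of a clustering solution
#'
#' Draws `B` samples of n mice with replacement (a mouse can occur several
#' times in one sample), re-runs the longitudinal k-means at the base k,
#' aligns labels to the base solution, and records for every mouse present
#' whether it landed in its base cluster. The primary per-mouse Jaccard
#' index divides by the number of bootstrap samples that contain the mouse
#' (multiplicity ignored); the raw-B convention (dividing by all `B`
#' samples) is reported alongside. Per-cluster indices average the
#' per-mouse values over the cluster's members.
#'
#' @param trajectories trajectory matrix the base solution was fitted on.
#' @param base a `cluster_solution` on these trajectories.
#' @param B number of bootstrap samples.
#' @param seed integer seed.
#' @param n_restarts restarts per bootstrap re-clustering.
#' @return object of class `stability_report`: `per_mouse` (mouse_id,
#'   base_cluster, inclusion_count, draw_count with multiplicity,
#'   times_same, jaccard, jaccard_raw_b), `per_cluster` (cluster, mean
#'   Jaccard under both conventions), `B`.
#' @export
bootstrap_stability <- function(trajectories, base, B = 200L, seed = 1L,
                                n_restarts = 50L) {
  stopifnot(inherits(base, "cluster_solution"))
  if (B < 1L) stop_bt("B must be >= 1")
  x <- as.matrix(trajectories)
  n <- nrow(x)
  ids <- rownames(x)
  if (!setequal(ids, names(base$labels))) {
    stop_bt("base solution must be fitted on the same trajectories")
  }
  k <- base$k
  incl <- setNames(integer(n), ids)
  same <- setNames(integer(n), ids)
  draws <- setNames(integer(n), ids) # with multiplicity; sums to B * n
  for (b in seq_len(B)) {
    set.seed(derive_seed(seed, paste0("boot/draw/", b)))
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(idx)) < k) {
      stop_bt("bootstrap sample ", b, " has fewer than k distinct individuals")
    }
    xb <- x[idx, , drop = FALSE]
    rownames(xb) <- sprintf("r%d", seq_len(n))
    sol <- kmeans_longitudinal(xb, k, n_restarts = n_restarts,
                               seed = derive_seed(seed, paste0("boot/fit/", b)))
    # contingency over rows: base label of the drawn mouse vs candidate label
    row_base <- base$labels[ids[idx]]
    tab_labels <- setNames(sol$labels, NULL)
    cand_named <- setNames(tab_labels, sprintf("row%d", seq_len(n)))
    ref_named <- setNames(as.integer(row_base), sprintf("row%d", seq_len(n)))
    perm <- align_cluster_labels(ref_named, cand_named)
    aligned <- perm[tab_labels]
    tab_idx <- table(idx)
    draws[ids[as.integer(names(tab_idx))]] <-
      draws[ids[as.integer(names(tab_idx))]] + as.integer(tab_idx)
    first_row <- match(unique(idx), idx)
    for (fr in first_row) {
      id <- ids[idx[fr]]
      incl[id] <- incl[id] + 1L
      if (!is.na(aligned[fr]) && aligned[fr] == base$labels[[id]]) {
        same[id] <- same[id] + 1L
      }
    }
  }
  per_mouse <- data.frame(
    mouse_id = ids,
    base_cluster = as.integer(base$labels[ids]),
    inclusion_count = as.integer(incl),
    draw_count = as.integer(draws),
    times_same = as.integer(same),
    jaccard = ifelse(incl > 0, same / incl, NA_real_),
    jaccard_raw_b = same / B,
    stringsAsFactors = FALSE)
  per_cluster <- aggregate(cbind(jaccard, jaccard_raw_b) ~ base_cluster,
                           data = per_mouse, FUN = mean, na.rm = TRUE)
  names(per_cluster)[1] <- "cluster"
  out <- list(per_mouse = per_mouse, per_cluster = per_cluster, B = B)
  class(out) <- "stability_report"
  out
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Bootstrap cluster stability (B = %d samples)\n", x$B))
  cat("Per-cluster mean Jaccard (inclusion-based; raw-B alongside):\n")
  print(x$per_cluster, row.names = FALSE, digits = 3)
  invisible(x)
}
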