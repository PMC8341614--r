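# Longitudinal k-means, gap statistic and CVI-based k selection, with
# brute-force enumeration oracles on tiny instances and stats::kmeans as an
# independent cross-check.

test_that("trajectory distance is the Frobenius norm of the difference", {
  a <- matrix(rnorm(15), 5, 3)
  expect_equal(traj_distance(a, a), 0)
  b <- matrix(rnorm(15), 5, 3)
  expect_equal(traj_distance(a, b), traj_distance(b, a))
  expect_equal(traj_distance(a, a - 2), sqrt(60)) # all 15 entries differ by 2
  expect_error(traj_distance(a, matrix(0, 5, 2)), "shape")
})

test_that("n = k distinct trajectories each get their own cluster", {
  x <- two_blob_traj(n_per = 2, sep = 4, seed = 3)
  sol <- kmeans_longitudinal(x, k = 4, n_restarts = 5, seed = 1)
  expect_equal(sol$tot_withinss, 0)
  expect_equal(sort(unique(as.integer(sol$labels))), 1:4)
  expect_error(kmeans_longitudinal(x, k = 5, n_restarts = 1, seed = 1),
               "exceeds")
  expect_error(kmeans_longitudinal(x, k = 1, n_restarts = 1, seed = 1), ">= 2")
})

test_that("k-means attains the exhaustive-enumeration optimum on tiny instances", {
  # the canonical two-blob case ...
  x <- two_blob_traj(n_per = 4, sep = 10, seed = 5)
  oracle <- brute_force_best_bipartition(x)
  sol <- kmeans_longitudinal(x, k = 2, n_restarts = 20, seed = 2)
  expect_equal(sol$tot_withinss, oracle$ss, tolerance = 1e-8)
  expect_equal(length(unique(paste(sol$labels, oracle$labels))), 2L)
  # ... and unstructured small instances (many restarts: the optimum's
  # Lloyd basin can be small when there is no real cluster structure)
  for (s in 1:4) {
    set.seed(100 + s)
    n <- sample(6:9, 1)
    y <- matrix(rnorm(n * 15), ncol = 15,
                dimnames = list(sprintf("m%02d", 1:n), NULL))
    oracle <- brute_force_best_bipartition(y)
    sol <- kmeans_longitudinal(y, k = 2, n_restarts = 400, seed = s)
    expect_equal(sol$tot_withinss, oracle$ss, tolerance = 1e-8)
  }
})

test_that("best-of-restarts SS is non-increasing in the number of restarts
           and matches stats::kmeans", {
  set.seed(77)
  x <- matrix(rnorm(60 * 15), ncol = 15,
              dimnames = list(sprintf("m%02d", 1:60), NULL))
  sol <- kmeans_longitudinal(x, k = 3, n_restarts = 40, seed = 9)
  prefix_best <- cummin(sol$restart_ss)
  expect_true(all(diff(prefix_best) <= 0))
  expect_equal(sol$tot_withinss, min(sol$restart_ss))
  # independent implementation cross-check
  km <- stats::kmeans(x, centers = 3, nstart = 50, iter.max = 100)
  expect_lt(abs(sol$tot_withinss - km$tot.withinss) / km$tot.withinss, 0.02)
})

test_that("gap statistic separates one blob from two and matches the SS identity", {
  one <- two_blob_traj(n_per = 15, sep = 0, sd = 1, seed = 11)
  g1 <- gap_statistic(one, k_max = 3, B = 10, seed = 1, n_restarts = 10)
  expect_true(g1$one_cluster)
  two <- two_blob_traj(n_per = 15, sep = 10, sd = 1, seed = 12)
  g2 <- gap_statistic(two, k_max = 3, B = 10, seed = 1, n_restarts = 10)
  expect_false(g2$one_cluster)
  # definitional identity: logW at k=2 equals the brute-force within-SS of
  # the best retained labeling
  sol <- kmeans_longitudinal(two, 2, n_restarts = 10,
                             seed = derive_seed(1, "gap/obs/k=2"))
  manual <- sum(vapply(1:2, function(j) {
    sub <- two[sol$labels == j, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }, numeric(1)))
  expect_equal(g2$table$logW[2], log(manual), tolerance = 1e-8)
  expect_error(gap_statistic(matrix(1, 10, 15), k_max = 2, B = 10, seed = 1),
               "degenerate")
  expect_error(gap_statistic(two, k_max = 3, B = 5, seed = 1), "B must be")
})

test_that("CVI vote follows majority with ties toward the smallest k", {
  fake <- function(k, ch, db, rt) {
    structure(list(k = k, cvi = c(calinski_harabasz = ch, davies_bouldin = db,
                                  ray_turi = rt)),
              class = "cluster_solution")
  }
  # unanimous
  sols <- list(fake(2, 10, 0.5, 0.5), fake(3, 5, 1, 1), fake(4, 2, 2, 2))
  expect_equal(select_k_cvi(sols)$k_selected, 2)
  # 2-1 majority for k = 2
  sols <- list(fake(2, 10, 0.5, 1), fake(3, 5, 1, 0.5), fake(4, 2, 2, 2))
  expect_equal(select_k_cvi(sols)$k_selected, 2)
  # three-way tie resolves to the smallest k
  sols <- list(fake(2, 1, 0.5, 1), fake(3, 5, 1, 0.5), fake(4, 10, 2, 2))
  expect_equal(select_k_cvi(sols)$k_selected, 2)
  expect_error(select_k_cvi(sols[1]), "at least 2")
})

test_that("cluster characterization detects opposite habituation patterns", {
  co <- default_cohort()
  labels <- setNames(ifelse(co$truth$latent_type == "A", 1L, 2L),
                     co$truth$mouse_id)
  ch <- characterize_clusters(co$scores, labels)
  for (d in c("avoidance", "exploration", "locomotion")) {
    inter <- ch[[d]]$anova
    expect_lt(inter$p[inter$effect == "cluster:trial_f"], 1e-4)
  }
  t15 <- ch$avoidance$trial1_vs_5
  est <- setNames(t15$estimate, t15$contrast)
  # type A avoidance rises (trial1 - trial5 < 0), type B falls
  expect_lt(est[grepl("cluster=1", names(est))], 0)
  expect_gt(est[grepl("cluster=2", names(est))], 0)
  expect_true(all(t15$band %in% c("small", "medium", "large", "very large")))
})

test_that("contrasts between identical groups give zero estimate and d", {
  set.seed(5)
  base <- rnorm(40, 0, 0.3)
  sc <- data.frame(
    mouse_id = rep(sprintf("m%02d", 1:40), each = 5),
    trial = rep(1:5, 40),
    avoidance_z = rep(base, each = 5) + rnorm(200, 0, 0.5))
  sc$exploration_z <- sc$avoidance_z
  sc$locomotion_z <- sc$avoidance_z
  # alternating labeling of one homogeneous population: the two "clusters"
  # are identical in law, so contrasts should hover around zero
  labels <- setNames(rep(c(1L, 2L), 20), sprintf("m%02d", 1:40))
  ch <- characterize_clusters(sc, labels,
                              transforms = c(avoidance = "none",
                                             exploration = "none",
                                             locomotion = "none"))
  ct <- ch$avoidance$cluster_by_trial
  expect_lt(abs(mean(ct$cohens_d)), 0.75)
  expect_true(all(ct$p > 1e-4))
})
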