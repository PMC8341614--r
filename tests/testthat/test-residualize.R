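# Residualization: OLS oracle for the degenerate spec, confounder removal
# with signal preservation, per-stratum calibration on a well-specified
# cohort, and input validation.

zero_offsets <- function() {
  list(
    strain = matrix(0, 3, 3, dimnames = list(c("C", "B6N", "129S2"),
                                             c("avoidance", "exploration",
                                               "locomotion"))),
    experimenter = matrix(0, 2, 3, dimnames = list(c("E1", "E2"),
                                                   c("avoidance", "exploration",
                                                     "locomotion"))))
}

test_that("with no random effects, no CAR(1) and equal weights the residuals
           equal OLS standardized residuals", {
  co <- default_cohort()
  spec <- residual_model_spec(
    transforms = c(avoidance = "none", exploration = "none",
                   locomotion = "none"),
    random = character(0), car1 = FALSE, var_stratum = NULL)
  res <- fit_residual_model(co$scores, co$truth, spec)
  # closed-form OLS oracle on the same design matrix
  data <- merge(co$scores, co$truth, by = "mouse_id")
  data <- data[order(data$mouse_id, data$trial), ]
  X <- model.matrix(~ strain + experimenter, data)
  y <- data$avoidance_z
  beta <- solve(crossprod(X), crossprod(X, y))
  r <- y - X %*% beta
  sigma <- sqrt(sum(r^2) / (length(y) - ncol(X)))
  got <- res$residuals[res$residuals$dimension == "avoidance", ]
  got <- got[order(got$mouse_id, got$trial), ]
  expect_equal(got$residual, as.vector(r / sigma), tolerance = 1e-10)
  expect_equal(res$models$avoidance$method, "ols")
})

test_that("a response orthogonal to the fixed factors is returned centered
           and variance-scaled", {
  co <- default_cohort()
  data <- merge(co$scores, co$truth, by = "mouse_id")
  data <- data[order(data$mouse_id, data$trial), ]
  set.seed(12)
  y0 <- rnorm(nrow(data))
  y <- resid(lm(y0 ~ strain + experimenter, data)) # nothing left to remove
  sc <- co$scores[order(co$scores$mouse_id, co$scores$trial), ]
  sc$avoidance_z <- y
  spec <- residual_model_spec(
    transforms = c(avoidance = "none", exploration = "none",
                   locomotion = "none"),
    random = character(0), car1 = FALSE, var_stratum = NULL)
  res <- fit_residual_model(sc, co$truth, spec)
  got <- res$residuals[res$residuals$dimension == "avoidance", ]
  got <- got[order(got$mouse_id, got$trial), ]
  expect_equal(cor(got$residual, y), 1, tolerance = 1e-10)
  expect_lt(abs(mean(got$residual)), 1e-10)
})

test_that("residualization removes an injected experimenter offset while
           preserving the type trajectory separation", {
  off <- zero_offsets()$experimenter
  off["E1", "avoidance"] <- 1
  cfg <- synthetic_config(experimenter_offsets = off, seed = 21L)
  co <- simulate_phase1_cohort(cfg)
  res <- fit_residual_model(co$scores, co$truth)
  av <- res$residuals[res$residuals$dimension == "avoidance", ]
  av <- merge(av, co$truth[, c("mouse_id", "experimenter", "latent_type")])
  # raw scores carry the full +1 z offset ...
  raw <- merge(co$scores, co$truth[, c("mouse_id", "experimenter")])
  raw_delta <- diff(tapply(raw$avoidance_z, raw$experimenter, mean))
  expect_gt(abs(raw_delta), 0.8)
  # ... the residuals do not (up to the sampling error of the estimated
  # experimenter coefficient)
  resid_delta <- diff(tapply(av$residual, av$experimenter, mean))
  expect_lt(abs(resid_delta), 0.25)
  expect_lt(abs(resid_delta), abs(raw_delta) / 3)
  # trial-to-trial type separation is retained: opposite avoidance slopes
  slope <- function(type) {
    sub <- av[av$latent_type == type, ]
    mean(sub$residual[sub$trial == 5]) - mean(sub$residual[sub$trial == 1])
  }
  expect_gt(slope("A") - slope("B"), 1)
})

test_that("standardized residuals have per-stratum SD near 1 when the model
           is well specified", {
  zo <- zero_offsets()
  cfg <- synthetic_config(strain_type_probs = c(C = 0, B6N = 0, `129S2` = 0),
                          seed = 31L)
  co <- simulate_phase1_cohort(cfg)
  res <- fit_residual_model(co$scores, co$truth)
  dat <- merge(res$residuals, co$truth[, c("mouse_id", "strain")])
  for (d in c("avoidance", "exploration", "locomotion")) {
    sds <- tapply(dat$residual[dat$dimension == d],
                  dat$strain[dat$dimension == d], sd)
    expect_true(all(abs(sds - 1) < 0.2),
                info = paste(d, paste(round(sds, 3), collapse = " ")))
  }
})

test_that("residual model validates its inputs", {
  co <- default_cohort()
  expect_error(residual_model_spec(fixed = c("strain", "trial")), "trial")
  # aliased fixed factor is named
  tr <- co$truth
  tr$experimenter <- as.character(tr$strain)
  expect_error(fit_residual_model(co$scores, tr), "aliased")
  # incomplete trajectories
  expect_error(fit_residual_model(co$scores[-1, ], co$truth), "exactly 5")
})

test_that("between-type separation is not reduced by residualization", {
  co <- default_cohort()
  res <- default_residuals()
  sep <- function(mat, types) {
    d <- sqrt(sum((colMeans(mat[types == "A", , drop = FALSE]) -
                     colMeans(mat[types == "B", , drop = FALSE]))^2))
    spread <- mean(c(apply(mat[types == "A", , drop = FALSE], 2, sd),
                     apply(mat[types == "B", , drop = FALSE], 2, sd)))
    d / spread
  }
  types <- setNames(co$truth$latent_type, co$truth$mouse_id)
  raw_long <- data.frame(
    mouse_id = rep(co$scores$mouse_id, 3),
    trial = rep(co$scores$trial, 3),
    dimension = rep(c("avoidance", "exploration", "locomotion"),
                    each = nrow(co$scores)),
    residual = c(co$scores$avoidance_z, co$scores$exploration_z,
                 co$scores$locomotion_z))
  raw_mat <- trajectory_matrix(raw_long)
  res_mat <- default_traj()
  expect_gte(sep(res_mat, types[rownames(res_mat)]),
             sep(raw_mat, types[rownames(raw_mat)]))
})
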