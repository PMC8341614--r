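# Synthetic cohort generator: cohort composition, degenerate noise-free
# behavior, mixture and autocorrelation calibration, determinism.

test_that("default cohort reproduces the study composition", {
  co <- default_cohort()
  expect_equal(nrow(co$truth), 179L)
  expect_equal(as.integer(table(co$truth$strain)), c(59L, 60L, 60L))
  expect_false(anyDuplicated(co$truth$mouse_id) > 0)
  expect_equal(nrow(co$scores), 179L * 5L)
  # raw table: one row per mouse x trial x variable, within bounds
  reg <- behavioral_variable_registry()
  expect_equal(nrow(co$raw), 179L * 5L * nrow(reg))
  expect_false(anyDuplicated(co$raw[, c("mouse_id", "trial", "variable")]) > 0)
  lat <- co$raw[grepl("latency", co$raw$variable), "value"]
  expect_true(all(lat >= 0 & lat <= 300))
  pct <- co$raw[co$raw$variable == "pct_time_on_board", "value"]
  expect_true(all(pct >= 0 & pct <= 100))
  # weekly batches of 30 (10/strain); the short strain ends with a partial week
  wk <- table(co$truth$test_group, co$truth$strain)
  expect_true(all(wk[1:5, ] == 10))
})

test_that("noise-free cohort reproduces the type mean trajectories exactly", {
  cfg <- synthetic_config(
    strain_offsets = matrix(0, 3, 3,
                            dimnames = list(c("C", "B6N", "129S2"),
                                            c("avoidance", "exploration",
                                              "locomotion"))),
    experimenter_offsets = matrix(0, 2, 3,
                                  dimnames = list(c("E1", "E2"),
                                                  c("avoidance", "exploration",
                                                    "locomotion"))),
    sd_individual = 0, sd_noise = 0, seed = 4L)
  co <- simulate_phase1_cohort(cfg)
  for (i in c(1L, 90L, 179L)) {
    m <- co$truth[i, ]
    sc <- co$scores[co$scores$mouse_id == m$mouse_id, ]
    expect_equal(sc$avoidance_z,
                 unname(cfg$type_mean_trajectories[, "avoidance", m$latent_type]))
    expect_equal(sc$locomotion_z,
                 unname(cfg$type_mean_trajectories[, "locomotion", m$latent_type]))
  }
})

test_that("strain type mixture matches the binomial expectation", {
  # independent oracle: brute-force binomial simulation of 59 draws at 0.881
  set.seed(101)
  oracle <- mean(rbinom(10000L, 59L, 0.881))
  counts <- vapply(1:100, function(s) {
    co <- simulate_phase1_cohort(synthetic_config(seed = 1000L + s))
    sum(co$truth$strain == "C" & co$truth$latent_type == "B")
  }, numeric(1))
  # binomial SD 2.49 -> SE of the 100-cohort mean ~ 0.25
  expect_lt(abs(mean(counts) - oracle), 1.0)
  expect_lt(abs(oracle - 59 * 0.881), 0.1)
})

test_that("lag-1 autocorrelation of the noise converges to car1_phi", {
  zero3 <- function(rn) matrix(0, length(rn), 3,
                               dimnames = list(rn, c("avoidance", "exploration",
                                                     "locomotion")))
  cfg <- synthetic_config(
    strain_type_probs = c(C = 0, B6N = 0, `129S2` = 0),
    strain_offsets = zero3(c("C", "B6N", "129S2")),
    experimenter_offsets = zero3(c("E1", "E2")),
    sd_individual = 0, car1_phi = 0.4, seed = 7L)
  co <- simulate_phase1_cohort(cfg)
  noise <- co$scores$avoidance_z -
    rep(cfg$type_mean_trajectories[, "avoidance", "A"], 179)
  by_mouse <- matrix(noise, nrow = 5)
  lag1 <- cor(as.vector(by_mouse[1:4, ]), as.vector(by_mouse[2:5, ]))
  expect_lt(abs(lag1 - 0.4), 3.5 / sqrt(4 * 179)) # ~3.5 SE of a correlation
  # stationary variance normalized to sd_noise^2
  expect_lt(abs(sd(noise) - cfg$sd_noise), 0.03)
})

test_that("generation is bit-identical under a fixed seed and validates input", {
  a <- simulate_phase1_cohort(synthetic_config(seed = 33L))
  b <- simulate_phase1_cohort(synthetic_config(seed = 33L))
  expect_identical(a$raw, b$raw)
  expect_identical(a$truth, b$truth)
  expect_error(synthetic_config(n_per_strain = c(C = 0L, B6N = 2L, `129S2` = 2L)),
               "non-positive")
  expect_error(synthetic_config(car1_phi = 1), "phi")
  expect_error(
    synthetic_config(type_mean_trajectories = array(0, c(4, 3, 2))),
    "malformed")
})

test_that("phase-2 responses: exact treatment effect in the noise-free case", {
  co <- default_cohort()
  design <- build_default_design(co$truth, seed = 5L)
  zero3 <- function(rn) matrix(0, length(rn), 3,
                               dimnames = list(rn, c("avoidance", "exploration",
                                                     "locomotion")))
  cfg <- synthetic_config(
    strain_offsets = zero3(c("C", "B6N", "129S2")),
    experimenter_offsets = zero3(c("E1", "E2")),
    sd_individual = 0, sd_noise = 0,
    treatment_effect = c(avoidance = 0.3, exploration = -0.6,
                         locomotion = -0.8))
  p2 <- simulate_phase2_responses(design, cfg, seed = 6L)
  tr <- p2[p2$treatment == "dexmedetomidine", ]
  cc <- p2[p2$treatment == "saline", ]
  cc <- cc[match(tr$pair_id, cc$pair_id), ]
  same_type <- tr$latent_type == cc$latent_type
  expect_true(any(same_type))
  expect_equal(tr$locomotion_z[same_type] - cc$locomotion_z[same_type],
               rep(-0.8, sum(same_type)))
  expect_equal(tr$avoidance_z[same_type] - cc$avoidance_z[same_type],
               rep(0.3, sum(same_type)))
})

test_that("phase-2 fitter recovers an injected treatment coefficient", {
  co <- default_cohort()
  cfg <- synthetic_config(treatment_effect = c(avoidance = 0, exploration = 0,
                                               locomotion = -0.8))
  est <- vapply(1:100, function(s) {
    # a fresh randomization each replicate: a single fixed design carries a
    # fixed chance type imbalance between treatment arms
    design <- build_default_design(co$truth, seed = 3000L + s)
    p2 <- simulate_phase2_responses(design, cfg, seed = 2000L + s)
    fit <- fit_factorial_model(p2, dimensions = "locomotion",
                               transforms = c(locomotion = "none"))
    emm <- emmeans::emmeans(fit$locomotion$model, ~treatment, data = p2)
    s <- as.data.frame(summary(emmeans::contrast(emm, "pairwise")))
    s$estimate[1] # dexmedetomidine - saline
  }, numeric(1))
  expect_lt(abs(mean(est) - (-0.8)), 0.06)
})
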