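# Synthetic cohort generator: two latent response types (A/B) with
# strain-specific mixture proportions, nuisance (strain, experimenter,
# individual) offsets and CAR(1) within-mouse noise, plus raw ethogram
# variables emitted consistently with the latent dimension scores.

#' Registry of raw behavioral variables emitted by the generator
#'
#' One row per ethogram variable of the modified Hole Board: its behavioral
#' dimension, measurement kind (count, latency in seconds capped at 300, or
#' percentage), the direction in which it loads on the dimension (`sign`),
#' and the affine parameters used to derive it from the latent dimension
#' score (`base + sign * scale * latent + noise`).
#'
#' @return a data.frame with columns `variable`, `dimension`, `kind`,
#'   `sign`, `base`, `scale`.
#' @export
behavioral_variable_registry <- function() {
  reg <- rbind(
    data.frame(
      variable = c("board_entries", "latency_first_board_entry",
                   "pct_time_on_board"),
      dimension = "avoidance",
      kind = c("count", "latency", "percent"),
      sign = c(-1, 1, -1),
      base = c(12, 80, 20),
      scale = c(4, 60, 8)
    ),
    data.frame(
      variable = c("rearings_box", "latency_first_rearing_box",
                   "rearings_board", "latency_first_rearing_board",
                   "hole_explorations", "latency_first_hole_exploration",
                   "hole_visits", "latency_first_hole_visit"),
      dimension = "exploration",
      kind = rep(c("count", "latency"), 4),
      sign = rep(c(1, -1), 4),
      base = c(25, 60, 10, 120, 15, 90, 8, 130),
      scale = c(8, 40, 4, 60, 5, 50, 3, 60)
    ),
    data.frame(
      variable = c("line_crossings", "latency_first_line_crossing"),
      dimension = "locomotion",
      kind = c("count", "latency"),
      sign = c(1, -1),
      base = c(60, 30),
      scale = c(20, 25)
    )
  )
  rownames(reg) <- NULL
  reg
}

default_type_trajectories <- function() {
  traj <- array(
    NA_real_,
    dim = c(N_TRIALS, 3L, 2L),
    dimnames = list(trial = 1:N_TRIALS, dimension = DIMENSIONS,
                    type = c("A", "B"))
  )
  # type A: avoidance rises, exploration stays low, locomotion declines
  traj[, "avoidance", "A"]   <- seq(-0.5, 0.5, length.out = N_TRIALS)
  traj[, "exploration", "A"] <- rep(-0.3, N_TRIALS)
  traj[, "locomotion", "A"]  <- seq(0.3, -0.3, length.out = N_TRIALS)
  # type B: avoidance habituates, exploration and locomotion ramp up
  traj[, "avoidance", "B"]   <- seq(0.5, -0.5, length.out = N_TRIALS)
  traj[, "exploration", "B"] <- seq(-0.5, 0.5, length.out = N_TRIALS)
  traj[, "locomotion", "B"]  <- seq(-0.5, 0.5, length.out = N_TRIALS)
  traj
}

#' Configuration of the synthetic cohort generator
#'
#' Encodes the study conditions the generator emulates: three inbred strains
#' (BALB/c `C` n = 59, C57BL/6 `B6N` n = 60, 129S2 n = 60), five modified
#' Hole Board trials, two latent response types with strain-specific mixture
#' proportions, additive strain and experimenter offsets, a between-mouse
#' random intercept, CAR(1) trial-to-trial noise, and a single-trial
#' phase-2 test with an activity-suppressing treatment effect.
#'
#' @param n_per_strain named integer vector of cohort sizes per strain.
#' @param strain_type_probs named numeric vector, per-strain probability
#'   that a mouse is latent type B (type A otherwise).
#' @param type_mean_trajectories numeric array `5 x 3 x 2`
#'   (trial x dimension x type) of mean integrated z-scores.
#' @param strain_offsets numeric matrix strains x dimensions, additive shift
#'   in z units.
#' @param experimenter_offsets numeric matrix experimenters x dimensions.
#' @param sd_individual between-mouse random-intercept SD (z units).
#' @param sd_noise stationary SD of the CAR(1) residual process (z units).
#' @param car1_phi trial-to-trial correlation of the noise, `|phi| < 1`.
#' @param treatment_effect named numeric vector, additive phase-2 shift per
#'   dimension for treated mice (z units).
#' @param type_offsets_phase2 named numeric vector, additive phase-2 shift
#'   per dimension for type-B mice relative to type A (z units).
#' @param weight_mean_sd numeric matrix strains x 2 (`mean`, `sd`) of body
#'   weight in grams.
#' @param seed integer RNG seed recorded with every output.
#' @return an object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_per_strain = c(C = 59L, B6N = 60L, `129S2` = 60L),
                             strain_type_probs = c(C = 0.881, B6N = 0.300,
                                                   `129S2` = 0.100),
                             type_mean_trajectories = default_type_trajectories(),
                             strain_offsets = NULL,
                             experimenter_offsets = NULL,
                             sd_individual = 0.3,
                             sd_noise = 0.3,
                             car1_phi = 0.4,
                             treatment_effect = c(avoidance = 0.3,
                                                  exploration = -0.6,
                                                  locomotion = -0.8),
                             type_offsets_phase2 = c(avoidance = -1,
                                                     exploration = 1,
                                                     locomotion = 1),
                             weight_mean_sd = NULL,
                             seed = 1L) {
  strains <- names(n_per_strain)
  if (is.null(strains) || any(!nzchar(strains))) {
    stop_bt("n_per_strain must be a named vector of strain sizes")
  }
  if (any(n_per_strain <= 0)) stop_bt("non-positive cohort size in n_per_strain")
  if (!all(strains %in% names(strain_type_probs))) {
    stop_bt("strain_type_probs must name every strain")
  }
  if (any(strain_type_probs < 0 | strain_type_probs > 1)) {
    stop_bt("strain_type_probs must lie in [0, 1]")
  }
  if (!is.array(type_mean_trajectories) ||
      !identical(dim(type_mean_trajectories), c(N_TRIALS, 3L, 2L))) {
    stop_bt("malformed trajectory matrix: type_mean_trajectories must be 5 x 3 x 2")
  }
  if (sd_individual < 0 || sd_noise < 0) stop_bt("SDs must be >= 0")
  if (abs(car1_phi) >= 1) stop_bt("car1_phi must satisfy |phi| < 1")
  if (is.null(strain_offsets)) {
    strain_offsets <- matrix(
      c( 0.3, -0.2, -0.2,   # C: avoidant, less active
        -0.1,  0.3,  0.5,   # B6N: exploratory, high locomotion
         0.0, -0.2, -0.3),  # 129S2: low locomotion
      nrow = length(strains), ncol = 3L, byrow = TRUE,
      dimnames = list(strains, DIMENSIONS)
    )[seq_along(strains), , drop = FALSE]
  }
  if (is.null(experimenter_offsets)) {
    experimenter_offsets <- matrix(
      c(0.2, -0.2, 0,
        0.0,  0.0, 0),
      nrow = 2L, byrow = TRUE,
      dimnames = list(c("E1", "E2"), DIMENSIONS)
    )
  }
  if (is.null(weight_mean_sd)) {
    weight_mean_sd <- matrix(
      c(20.4, 1.5,
        21.0, 1.5,
        24.1, 2.0),
      nrow = length(strains), ncol = 2L, byrow = TRUE,
      dimnames = list(strains, c("mean", "sd"))
    )[seq_along(strains), , drop = FALSE]
  }
  cfg <- list(
    n_per_strain = n_per_strain,
    strain_type_probs = strain_type_probs[strains],
    type_mean_trajectories = type_mean_trajectories,
    strain_offsets = strain_offsets,
    experimenter_offsets = experimenter_offsets,
    sd_individual = sd_individual,
    sd_noise = sd_noise,
    car1_phi = car1_phi,
    treatment_effect = treatment_effect,
    type_offsets_phase2 = type_offsets_phase2,
    weight_mean_sd = weight_mean_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "synthetic_config"
  cfg
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat("  strains:", paste(sprintf("%s (n=%d)", names(x$n_per_strain),
                                  x$n_per_strain), collapse = ", "), "\n")
  cat("  P(type B):", paste(sprintf("%s=%.3f", names(x$strain_type_probs),
                                    x$strain_type_probs), collapse = ", "), "\n")
  cat(sprintf("  sd_individual=%.2f sd_noise=%.2f car1_phi=%.2f seed=%d\n",
              x$sd_individual, x$sd_noise, x$car1_phi, x$seed))
  invisible(x)
}

# CAR(1) noise, stationary variance sd^2, generated recursively across trials
car1_noise <- function(n_trials, phi, sd) {
  e <- numeric(n_trials)
  e[1] <- rnorm(1, 0, sd)
  if (n_trials > 1) {
    innov_sd <- sd * sqrt(1 - phi^2)
    for (t in 2:n_trials) e[t] <- phi * e[t - 1] + rnorm(1, 0, innov_sd)
  }
  e
}

# weekly batches of 30 (10/strain); returns test_group and test_order columns
assign_batches <- function(truth) {
  strains <- unique(truth$strain)
  per_week <- 10L
  truth$test_group <- NA_integer_
  for (s in strains) {
    idx <- sample(which(truth$strain == s)) # randomize within strain
    truth$test_group[idx] <- ((seq_along(idx) - 1L) %/% per_week) + 1L
  }
  truth$test_order <- NA_integer_
  for (g in unique(truth$test_group)) {
    idx <- which(truth$test_group == g)
    truth$test_order[idx] <- sample(seq_along(idx)) # randomized across strains
  }
  truth
}

# two experimenters, stratified by strain within each weekly batch
assign_experimenters <- function(truth) {
  truth$experimenter <- NA_character_
  for (g in unique(truth$test_group)) {
    for (s in unique(truth$strain)) {
      idx <- which(truth$test_group == g & truth$strain == s)
      half <- ceiling(length(idx) / 2)
      pick <- sample(idx, half)
      truth$experimenter[pick] <- "E1"
      truth$experimenter[setdiff(idx, pick)] <- "E2"
    }
  }
  truth
}

#' Simulate a phase-1 characterization cohort
#'
#' Draws a cohort with latent response types per strain mixture proportions,
#' builds each mouse's 5-trial integrated z-score trajectory on the three
#' behavioral dimensions (type mean + strain offset + experimenter offset +
#' individual intercept + CAR(1) noise), and additionally emits the raw
#' ethogram variables as affine-plus-noise functions of the latent scores
#' (counts rounded and non-negative, latencies capped at 300 s, percentages
#' clamped to `[0, 100]`).
#'
#' @param config a [synthetic_config()].
#' @return a list of class `phase1_cohort` with elements
#'   \describe{
#'     \item{raw}{long-format raw observation table: one row per
#'       mouse x trial x variable with covariates.}
#'     \item{scores}{latent dimension scores: `mouse_id`, `trial`,
#'       `avoidance_z`, `exploration_z`, `locomotion_z`.}
#'     \item{truth}{per-mouse ground truth: strain, experimenter, test
#'       group/order, body weight, `latent_type` (A/B).}
#'   }
#' @export
simulate_phase1_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  strains <- names(config$n_per_strain)
  n_total <- sum(config$n_per_strain)

  truth <- data.frame(
    mouse_id = sprintf("M%03d", seq_len(n_total)),
    strain = factor(rep(strains, config$n_per_strain), levels = strains),
    stringsAsFactors = FALSE
  )
  truth$latent_type <- ifelse(
    rbinom(n_total, 1L, config$strain_type_probs[as.character(truth$strain)]) == 1L,
    "B", "A")
  truth$body_weight_g <- rnorm(
    n_total,
    mean = config$weight_mean_sd[as.character(truth$strain), "mean"],
    sd = config$weight_mean_sd[as.character(truth$strain), "sd"])
  truth <- assign_batches(truth)
  truth <- assign_experimenters(truth)
  truth <- truth[, c("mouse_id", "strain", "experimenter", "test_group",
                     "test_order", "body_weight_g", "latent_type")]

  # latent dimension score trajectories
  scores <- expand.grid(trial = 1:N_TRIALS, mouse_id = truth$mouse_id,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  scores <- scores[, c("mouse_id", "trial")]
  lat <- matrix(NA_real_, nrow = nrow(scores), ncol = 3L,
                dimnames = list(NULL, DIMENSIONS))
  for (i in seq_len(n_total)) {
    m <- truth[i, ]
    rows <- (i - 1L) * N_TRIALS + 1:N_TRIALS
    b <- rnorm(3L, 0, config$sd_individual)
    for (d in seq_along(DIMENSIONS)) {
      mu <- config$type_mean_trajectories[, d, m$latent_type] +
        config$strain_offsets[as.character(m$strain), d] +
        config$experimenter_offsets[m$experimenter, d] + b[d]
      lat[rows, d] <- mu + car1_noise(N_TRIALS, config$car1_phi, config$sd_noise)
    }
  }
  scores$avoidance_z <- lat[, "avoidance"]
  scores$exploration_z <- lat[, "exploration"]
  scores$locomotion_z <- lat[, "locomotion"]

  raw <- emit_raw_variables(scores, truth)

  out <- list(raw = raw, scores = scores, truth = truth, config = config)
  class(out) <- "phase1_cohort"
  out
}

#' @export
print.phase1_cohort <- function(x, ...) {
  cat(sprintf("Phase-1 synthetic cohort: %d mice, %d trials, %d raw variables\n",
              nrow(x$truth), N_TRIALS,
              length(unique(x$raw$variable))))
  print(table(strain = x$truth$strain, type = x$truth$latent_type))
  invisible(x)
}

# raw Table-1-style variables as affine-plus-noise images of the latent scores
emit_raw_variables <- function(scores, truth) {
  reg <- behavioral_variable_registry()
  n <- nrow(scores)
  lat <- as.matrix(scores[, paste0(DIMENSIONS, "_z")])
  colnames(lat) <- DIMENSIONS
  pieces <- vector("list", nrow(reg))
  for (v in seq_len(nrow(reg))) {
    r <- reg[v, ]
    value <- r$base + r$sign * r$scale * lat[, r$dimension] +
      rnorm(n, 0, 0.15 * r$scale)
    value <- switch(r$kind,
      count = pmax(0, round(value)),
      latency = pmin(300, pmax(0, value)),
      percent = pmin(100, pmax(0, value)))
    pieces[[v]] <- data.frame(
      mouse_id = scores$mouse_id, trial = scores$trial,
      variable = r$variable, value = value, stringsAsFactors = FALSE)
  }
  raw <- do.call(rbind, pieces)
  raw <- merge(raw,
               truth[, c("mouse_id", "strain", "experimenter", "test_group",
                         "test_order")],
               by = "mouse_id", sort = FALSE)
  raw <- raw[order(raw$mouse_id, raw$trial, raw$variable), ]
  rownames(raw) <- NULL
  raw
}

#' Simulate single-trial phase-2 responses under a matched-pair design
#'
#' One modified Hole Board trial per enrolled mouse:
#' `score = strain offset + type offset + experimenter offset +
#' treatment effect * 1(treated) + individual intercept + noise`,
#' per behavioral dimension.
#'
#' @param design a `design_table` from [build_block_design()].
#' @param config a [synthetic_config()]; `treatment_effect` and
#'   `type_offsets_phase2` parameterize the treatment and response-type
#'   shifts.
#' @param seed optional integer; defaults to `config$seed + 1`.
#' @return a data.frame with one row per mouse: design covariates,
#'   `treatment` (`dexmedetomidine`/`saline`) and the three dimension
#'   scores.
#' @export
simulate_phase2_responses <- function(design, config = synthetic_config(),
                                      seed = NULL) {
  stopifnot(inherits(design, "design_table"))
  mice <- design_mice(design)
  if (any(is.na(mice$treatment))) stop_bt("design rows missing treatment")
  if (any(is.na(mice$latent_type))) stop_bt("design rows missing response type")
  set.seed(seed %||% (config$seed + 1L))
  mice <- mice[order(mice$mouse_id), ]
  n <- nrow(mice)
  for (d in DIMENSIONS) {
    mu <- config$strain_offsets[as.character(mice$strain), d] +
      config$experimenter_offsets[as.character(mice$experimenter), d] +
      config$type_offsets_phase2[[d]] * (mice$latent_type == "B") +
      config$treatment_effect[[d]] * (mice$treatment == "dexmedetomidine")
    mice[[paste0(d, "_z")]] <- mu + rnorm(n, 0, config$sd_individual) +
      rnorm(n, 0, config$sd_noise)
  }
  rownames(mice) <- NULL
  mice
}
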