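# Constructed confounding scenarios for studying how response-type
# variation distorts a factorial experiment. Parameters were fixed a priori
# by power analysis (see the methods vignette) and use an equal 50/50 type
# mixture so the mechanism is not entangled with strain-specific mixtures.

#' Scenario: treatment confounded with response type in unbalanced pairs
#'
#' A generator configuration with zero true treatment effect and a strong
#' response-type shift on exploration and locomotion. Combined with
#' [confound_treatment_with_type()], the unbalanced pool acquires a
#' spurious treatment effect (type variation "augments" the result), while
#' type-matched balanced pairs cannot be confounded.
#'
#' @param seed integer seed.
#' @return a [synthetic_config()].
#' @export
scenario_config_augmented <- function(seed = 1L) {
  synthetic_config(
    strain_type_probs = c(C = 0.5, B6N = 0.5, `129S2` = 0.5),
    sd_individual = 0.2, sd_noise = 0.4,
    treatment_effect = c(avoidance = 0, exploration = 0, locomotion = 0),
    type_offsets_phase2 = c(avoidance = 0, exploration = 2, locomotion = 2),
    seed = seed)
}

#' Force treatment onto the type-B member of mixed unbalanced pairs
#'
#' Rewrites the treatment assignment of a design so that in every
#' mixed-type unbalanced pair the type-B mouse receives the active
#' treatment; same-type and balanced pairs keep their randomized
#' assignment. This deterministically confounds treatment with response
#' type exactly where matching did not prevent it.
#'
#' @param design a `design_table`.
#' @return the modified `design_table`.
#' @export
confound_treatment_with_type <- function(design) {
  stopifnot(inherits(design, "design_table"))
  swap <- design$pool == "unbalanced" & design$pair_type == "mixed" &
    design$type_treated != "B"
  tmp_id <- design$mouse_id_treated[swap]
  design$mouse_id_treated[swap] <- design$mouse_id_control[swap]
  design$mouse_id_control[swap] <- tmp_id
  tmp_w <- design$weight_treated[swap]
  design$weight_treated[swap] <- design$weight_control[swap]
  design$weight_control[swap] <- tmp_w
  tmp_t <- design$type_treated[swap]
  design$type_treated[swap] <- design$type_control[swap]
  design$type_control[swap] <- tmp_t
  design
}

#' Scenario: experimenter effect masked by response-type variation
#'
#' A generator configuration with a real experimenter offset on avoidance
#' and a large response-type variance on the same dimension. Because the
#' design builder distributes balanced pairs evenly by type across
#' experimenters, the balanced analysis detects the experimenter effect
#' more reliably than the unbalanced one, where random type imbalance
#' between experimenters adds noise to the contrast ("unmasking").
#'
#' @param seed integer seed.
#' @return a [synthetic_config()].
#' @export
scenario_config_masked <- function(seed = 1L) {
  exp_off <- matrix(c(1.2, 0, 0,
                      0.0, 0, 0), nrow = 2L, byrow = TRUE,
                    dimnames = list(c("E1", "E2"), DIMENSIONS))
  synthetic_config(
    strain_type_probs = c(C = 0.5, B6N = 0.5, `129S2` = 0.5),
    experimenter_offsets = exp_off,
    sd_individual = 0, sd_noise = 0.4,
    treatment_effect = c(avoidance = 0, exploration = 0, locomotion = 0),
    type_offsets_phase2 = c(avoidance = 2.4, exploration = 0, locomotion = 0),
    seed = seed)
}
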