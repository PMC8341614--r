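# Phase-2 design builder: weight-matched pairs (the balanced pool
# additionally matched on response type), random within-pair treatment
# assignment, and a complete randomized block layout with one pair per
# (block x experimenter x strain x pool) cell.

#' Match mice into weight-matched pairs within a strain
#'
#' Balanced pool: within strain x response type, mice are sorted by body
#' weight and paired adjacently, so both members share the response type.
#' Unbalanced pool: candidate mice are drawn at random (seeded) from the
#' strain, sorted by weight and paired adjacently ignoring type. Adjacent
#' pairing on the weight-sorted list is deterministic and near-optimal for
#' the total within-pair weight difference.
#'
#' @param mice per-mouse table with `mouse_id`, `strain`, `body_weight_g`
#'   and `latent_type` (e.g. a cohort `truth` table).
#' @param pool `"balanced"` or `"unbalanced"`.
#' @param strain strain to draw from.
#' @param n_pairs number of pairs requested.
#' @param seed integer seed (used for the unbalanced random draw).
#' @param exclude mouse ids already used and unavailable.
#' @return data.frame, one row per pair: ids, weights, types, pool, strain,
#'   `pair_type` (shared type or `"mixed"`), `weight_diff` in grams.
#' @export
match_pairs <- function(mice, pool = c("balanced", "unbalanced"), strain,
                        n_pairs, seed = 1L, exclude = character(0)) {
  pool <- match.arg(pool)
  cand <- mice[mice$strain == strain & !(mice$mouse_id %in% exclude), ]
  if (pool == "balanced") {
    pairs <- NULL
    for (ty in sort(unique(cand$latent_type))) {
      sub <- cand[cand$latent_type == ty, ]
      sub <- sub[order(sub$body_weight_g), ]
      n_here <- floor(nrow(sub) / 2)
      if (n_here == 0L) next
      i1 <- seq(1L, by = 2L, length.out = n_here)
      pairs <- rbind(pairs, data.frame(
        mouse_id_1 = sub$mouse_id[i1], mouse_id_2 = sub$mouse_id[i1 + 1L],
        weight_1 = sub$body_weight_g[i1], weight_2 = sub$body_weight_g[i1 + 1L],
        type_1 = ty, type_2 = ty, stringsAsFactors = FALSE))
    }
    if (is.null(pairs) || nrow(pairs) < n_pairs) {
      stop_bt("insufficient eligible mice of strain ", strain,
              " for ", n_pairs, " balanced pairs (", nrow(pairs) %||% 0,
              " feasible)")
    }
    # keep the n_pairs tightest pairs (smallest within-pair weight difference)
    pairs$weight_diff <- abs(pairs$weight_1 - pairs$weight_2)
    pairs <- pairs[order(pairs$weight_diff), ][seq_len(n_pairs), ]
  } else {
    if (nrow(cand) < 2L * n_pairs) {
      stop_bt("insufficient eligible mice of strain ", strain, " for ",
              n_pairs, " unbalanced pairs (", nrow(cand), " available)")
    }
    set.seed(derive_seed(seed, paste0("match/", strain, "/unbalanced")))
    sub <- cand[sample.int(nrow(cand), 2L * n_pairs), ]
    sub <- sub[order(sub$body_weight_g), ]
    i1 <- seq(1L, by = 2L, length.out = n_pairs)
    pairs <- data.frame(
      mouse_id_1 = sub$mouse_id[i1], mouse_id_2 = sub$mouse_id[i1 + 1L],
      weight_1 = sub$body_weight_g[i1], weight_2 = sub$body_weight_g[i1 + 1L],
      type_1 = sub$latent_type[i1], type_2 = sub$latent_type[i1 + 1L],
      stringsAsFactors = FALSE)
    pairs$weight_diff <- abs(pairs$weight_1 - pairs$weight_2)
  }
  pairs$pool <- pool
  pairs$strain <- strain
  pairs$pair_type <- ifelse(pairs$type_1 == pairs$type_2, pairs$type_1, "mixed")
  rownames(pairs) <- NULL
  pairs
}

#' Build the complete randomized block design for phase 2
#'
#' Takes 8 balanced and 8 unbalanced pairs per strain and allocates them so
#' that every (block x experimenter x strain x pool) cell holds exactly one
#' pair (4 blocks x 2 experimenters x 3 strains x 2 pools = 48 pairs, 96
#' mice). Treatment (dexmedetomidine vs saline) is assigned by a fair coin
#' within each pair; within each block and experimenter, the test order
#' alternates balanced and unbalanced pairs. Balanced pairs of a strain are
#' dealt across experimenters by response type so each experimenter's
#' balanced type composition is as even as the pool permits.
#'
#' @param pairs data.frame of pairs from [match_pairs()] (stacked pools and
#'   strains).
#' @param mice per-mouse table used to recover covariates for enrolled mice.
#' @param seed integer seed.
#' @param n_blocks number of blocks (test days).
#' @param experimenters experimenter labels.
#' @return object of class `design_table`: one row per pair with `pair_id`,
#'   `pool`, `strain`, `experimenter`, `block`, `test_slot`, treated and
#'   control mouse ids, weights, types and `weight_diff`.
#' @export
build_block_design <- function(pairs, mice, seed = 1L, n_blocks = 4L,
                               experimenters = c("E1", "E2")) {
  strains <- unique(as.character(pairs$strain))
  per_cell <- n_blocks * length(experimenters)
  for (s in strains) {
    for (p in c("balanced", "unbalanced")) {
      got <- sum(pairs$strain == s & pairs$pool == p)
      if (got != per_cell) {
        stop_bt("cell-count infeasibility: need ", per_cell, " ", p,
                " pairs of strain ", s, ", got ", got)
      }
    }
  }
  dup <- unlist(pairs[, c("mouse_id_1", "mouse_id_2")])
  if (anyDuplicated(dup)) stop_bt("a mouse appears in more than one pair")

  cells <- expand.grid(experimenter = experimenters, block = seq_len(n_blocks),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  alloc <- NULL
  for (s in strains) {
    for (p in c("balanced", "unbalanced")) {
      sub <- pairs[pairs$strain == s & pairs$pool == p, ]
      if (p == "balanced") {
        # deal types alternately across experimenters for an even composition
        sub <- sub[order(sub$pair_type, sub$weight_diff), ]
        exp_seq <- rep(experimenters, length.out = nrow(sub))
        sub$experimenter <- exp_seq
        set.seed(derive_seed(seed, paste0("alloc/", s, "/", p)))
        sub$block <- NA_integer_
        for (e in experimenters) {
          idx <- which(sub$experimenter == e)
          sub$block[idx] <- sample(seq_len(n_blocks))
        }
      } else {
        set.seed(derive_seed(seed, paste0("alloc/", s, "/", p)))
        ord <- sample.int(nrow(sub))
        sub$experimenter <- cells$experimenter[ord]
        sub$block <- cells$block[ord]
      }
      alloc <- rbind(alloc, sub)
    }
  }

  # fair-coin treatment within pair
  set.seed(derive_seed(seed, "treatment"))
  flip <- rbinom(nrow(alloc), 1L, 0.5) == 1L
  alloc$mouse_id_treated <- ifelse(flip, alloc$mouse_id_1, alloc$mouse_id_2)
  alloc$mouse_id_control <- ifelse(flip, alloc$mouse_id_2, alloc$mouse_id_1)
  alloc$weight_treated <- ifelse(flip, alloc$weight_1, alloc$weight_2)
  alloc$weight_control <- ifelse(flip, alloc$weight_2, alloc$weight_1)
  alloc$type_treated <- ifelse(flip, alloc$type_1, alloc$type_2)
  alloc$type_control <- ifelse(flip, alloc$type_2, alloc$type_1)

  # test order within (block, experimenter): alternate balanced/unbalanced,
  # strain order randomized
  alloc$test_slot <- NA_integer_
  set.seed(derive_seed(seed, "slots"))
  for (b in seq_len(n_blocks)) {
    for (e in experimenters) {
      idx_bal <- which(alloc$block == b & alloc$experimenter == e &
                         alloc$pool == "balanced")
      idx_unb <- which(alloc$block == b & alloc$experimenter == e &
                         alloc$pool == "unbalanced")
      idx_bal <- sample(idx_bal)
      idx_unb <- sample(idx_unb)
      slots <- integer(length(idx_bal) + length(idx_unb))
      slots[seq(1L, by = 2L, length.out = length(idx_bal))] <- idx_bal
      slots[seq(2L, by = 2L, length.out = length(idx_unb))] <- idx_unb
      alloc$test_slot[slots] <- seq_along(slots)
    }
  }

  alloc$pair_id <- sprintf("P%02d", seq_len(nrow(alloc)))
  keep <- c("pair_id", "pool", "strain", "experimenter", "block", "test_slot",
            "mouse_id_treated", "mouse_id_control", "weight_treated",
            "weight_control", "type_treated", "type_control", "pair_type",
            "weight_diff")
  out <- alloc[order(alloc$block, alloc$experimenter, alloc$test_slot), keep]
  rownames(out) <- NULL
  attr(out, "mice") <- mice
  class(out) <- c("design_table", "data.frame")
  out
}

#' Per-mouse view of a design table
#'
#' @param design a `design_table`.
#' @return data.frame with one row per enrolled mouse: design factors,
#'   `treatment` (`dexmedetomidine`/`saline`), weight and response type.
#' @export
design_mice <- function(design) {
  stopifnot(inherits(design, "design_table"))
  long <- rbind(
    data.frame(design[c("pair_id", "pool", "strain", "experimenter", "block",
                        "test_slot")],
               mouse_id = design$mouse_id_treated,
               treatment = "dexmedetomidine",
               body_weight_g = design$weight_treated,
               latent_type = design$type_treated,
               stringsAsFactors = FALSE),
    data.frame(design[c("pair_id", "pool", "strain", "experimenter", "block",
                        "test_slot")],
               mouse_id = design$mouse_id_control,
               treatment = "saline",
               body_weight_g = design$weight_control,
               latent_type = design$type_control,
               stringsAsFactors = FALSE))
  long[order(long$pair_id, long$treatment), ]
}

#' Build the default 48-pair phase-2 design from a characterized cohort
#'
#' Convenience wrapper: per strain, matches 8 balanced pairs first (mice
#' permitting feasible balanced cells), then 8 unbalanced pairs from the
#' remaining mice, and lays them out with [build_block_design()].
#'
#' @param mice per-mouse table with `mouse_id`, `strain`, `body_weight_g`,
#'   `latent_type` (ground truth or recovered cluster labels).
#' @param seed integer seed.
#' @param pairs_per_cell pairs per strain x pool (default 8 = 2
#'   experimenters x 4 blocks).
#' @return a `design_table`.
#' @export
build_default_design <- function(mice, seed = 1L, pairs_per_cell = 8L) {
  pairs <- NULL
  for (s in unique(as.character(mice$strain))) {
    bal <- match_pairs(mice, "balanced", s, pairs_per_cell, seed = seed)
    used <- unlist(bal[, c("mouse_id_1", "mouse_id_2")])
    unb <- match_pairs(mice, "unbalanced", s, pairs_per_cell, seed = seed,
                       exclude = used)
    pairs <- rbind(pairs, bal, unb)
  }
  build_block_design(pairs, mice, seed = seed)
}
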