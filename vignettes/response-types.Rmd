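---
title: "Characterizing individual behavioral response types and using them in experimental design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing individual behavioral response types and using them in experimental design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Mice of the same inbred strain, housed and tested under tightly
standardized conditions, still differ systematically in how their
anxiety-related and activity behavior changes over repeated exposures to a
mildly aversive arena (the modified Hole Board, mHB). These differences
are not noise: they form a small number of *individual response types* —
latent classes of the joint avoidance / exploration / locomotion time
course. A pharmacological experiment that ignores them inherits their
variance; one that matches treatment and control animals on response type
removes it from the treatment contrast. `behavtype` implements both the
characterization pipeline and the design machinery, driven end to end by a
synthetic-cohort generator so that every stage is testable against known
ground truth.

## Stage 1: integrated behavioral z-scores

Each raw ethogram variable $x_v$ (a count, a latency in seconds capped at
300, or a percentage) is normalized against the **pooled cohort** — all
strains together as the reference group — using the sample SD with the
$n-1$ denominator, and the member variables of a dimension are averaged
after sign alignment:

$$z_v = \frac{x_v - \bar x_v}{s_v}, \qquad
  Z_d = \frac{1}{|V_d|} \sum_{v \in V_d} \sigma_v \, z_v,$$

where $\sigma_v \in \{+1, -1\}$ is chosen so that a larger $Z_d$ always
means *more* of the named dimension. For avoidance this means board
entries and percentage time on board enter with $-1$ and latency to first
board entry with $+1$; for exploration and locomotion, counts enter with
$+1$ and latencies with $-1$. The sign map and the member lists are
user-overridable (`dimension_spec_default()`); the default follows the
standard mHB ethogram grouping. Mice that never display a latency event
carry the 300 s ceiling, which is why latencies are generated and stored
capped rather than censored. A variable with zero pooled SD is refused by
name rather than silently producing infinities.

## Stage 2: residualization

Per dimension, the integrated scores are transformed (log-shift for
avoidance, square-root-shift for exploration, rank for locomotion — the
shifts are $x - \min(x) + 1$ and $x - \min(x)$ because integrated z-scores
can be non-positive and a minimal order-preserving shift is the only
deterministic choice) and fitted with a linear mixed model:

* fixed: strain, experimenter;
* random intercepts: mouse, test group (weekly batch), test order —
  crossed, which is why the engine is `glmmTMB` rather than `nlme`
  (nested-only random structures);
* CAR(1) correlation across the five equally spaced trials within mouse,
  expressed as an `ar1()` term;
* a separate residual variance per strain (dispersion model).

**Trial is deliberately not a predictor**: the point of the fit is to
remove nuisance structure while leaving the across-trial habituation
signal in the residuals. The returned quantity is the conditional
standardized Pearson residual
$(y - X\hat\beta - Z\hat b) / \sqrt{\hat\sigma^2_{ar1} +
\hat\sigma^2_{strain}}$, where $\hat b$ contains only the random-intercept
predictions — the CAR(1) component is *kept inside* the residual because
it carries the trial-to-trial trajectory that the clustering consumes.
Whether to standardize marginally or conditionally is genuinely open; the
conditional choice is recorded in the object's metadata
(`standardization = "conditional"`).

Two numerical policies matter here:

* **Fallback chain.** If the full covariance cannot be estimated the model
  is refitted without the CAR(1) term ($\phi = 0$, weights retained), and
  as a last resort as the fixed-effects-only OLS fit; each step is logged
  in the model metadata and echoed into the pipeline manifest.
* **Variance-boundary acceptance.** Because the latent type structure is
  deliberately unmodelled and some nuisance variances can be truly zero,
  REML solutions often sit on the boundary of the parameter space, which
  makes the Hessian non-positive-definite even though the point estimates
  (coefficients, BLUPs, variance components, per-stratum SDs) are stable —
  we verified stability by refitting under a different optimizer and
  comparing residuals (correlation ≈ 1). Such fits are accepted with a
  logged note; only non-finite estimates trigger the fallback chain.
  Treating every boundary fit as a failure would make the OLS fallback the
  de-facto default, defeating the model.

## Stage 3: longitudinal clustering

The per-mouse residual trajectories are joined into one $5 \times 3$
matrix per mouse and compared with the Frobenius distance (plain Euclidean
distance over all 15 entries — the three dimensions are already on a
common standardized scale, so no rescaling is applied before distancing).
Lloyd k-means runs with:

* initialization by $k$ distinct trajectories sampled without replacement;
* one derived RNG stream per (k, restart) (`derive_seed()`), so changing
  the restart count never perturbs earlier streams;
* an iteration cap of 100 (assignments almost always stabilize in < 30);
* empty clusters repaired by reseeding from the point farthest from its
  assigned center;
* an internal assertion that the within-cluster SS never increases across
  iterations;
* best-of-restarts selection by total within-cluster SS. The study-scale
  schedule is 1000 restarts for each $k \in \{2, \dots, 6\}$, i.e. 5000
  candidate solutions.

Before any partitioning, the **gap statistic** asks whether the data are
best left as a single cluster: $B$ reference data sets are drawn uniformly
over each feature's observed range, and
$\mathrm{gap}(k) = \mathbb E_B[\log W^*_k] - \log W_k$ with the
one-standard-error rule (one cluster iff
$\mathrm{gap}(1) \ge \mathrm{gap}(2) - \mathrm{SE}(2)$).

The number of clusters is then chosen by a **majority vote of three
cluster validity indices**: Calinski–Harabasz (maximize), Davies–Bouldin
(minimize) and Ray–Turi (minimize), with ties broken toward the smallest
$k$. The CVI-voting literature this follows leaves the exact adjusted
voting rule underspecified; the plain majority vote used here is a
documented stand-in (the pipeline manifest says so explicitly) and the
index set is config-overridable.

Cluster characterization refits the integrated scores (locomotion
rank-transformed) with cluster, trial and their interaction as fixed
effects and a per-mouse random intercept and trial slope, and reports
estimated-marginal-mean contrasts between clusters within trial and
between trials 1 and 5 within cluster, each with Cohen's
$d = \hat\Delta / \hat\sigma_{resid}$ and the neurobehavioral bands
(small < 0.5 ≤ medium < 1.0 ≤ large < 1.5 ≤ very large).

## Stage 4: bootstrap stability

$B = 200$ samples of $n$ mice are drawn with replacement; each is
re-clustered at the base $k$ (50 restarts per sample — a deliberate
tractability reduction from 1000, config-overridable), labels are aligned
to the base solution by maximizing total overlap on the $k \times k$
contingency table (exhaustive over permutations; $k$ is small), and each
present mouse records whether it landed in its base cluster.

The per-mouse Jaccard index divides by the **number of bootstrap samples
containing the mouse** (multiplicity ignored), not by the raw $B$: since
$\approx 36.8\%$ of samples omit any given mouse, the raw-$B$ convention
bounds the index near $1 - 1/e \approx 0.63$ even for perfectly stable
clusters. Both conventions are computed and reported
(`jaccard`, `jaccard_raw_b`); the inclusion-based one is primary. The
report also carries, per mouse, both the inclusion count (the denominator)
and the with-multiplicity draw count (which sums to $B \times n$).

## Stage 5: the phase-2 design

96 of the characterized mice enter a pharmacological experiment as 48
weight-matched pairs, 16 per strain:

* **balanced pool** (8 pairs/strain): within strain × response type, mice
  are sorted by body weight and paired adjacently — both members share the
  type by construction;
* **unbalanced pool** (8 pairs/strain): drawn at random from the remaining
  mice of the strain, weight-sorted, paired adjacently ignoring type.

Adjacent pairing on the weight-sorted list is deterministic and attains
the minimum total within-pair weight difference (verified against
exhaustive matching enumeration in the tests). Which mice enter is
unavoidably a choice: the builder fills feasible balanced cells first
(keeping the tightest-weight pairs), then unbalanced cells at random.

Pairs are laid out as a complete randomized block design: exactly one pair
per (block × experimenter × strain × pool) cell, 4 blocks (test days) × 2
experimenters × 3 strains × 2 pools = 48 cells. Treatment (dexmedetomidine
vs saline) is a fair coin within each pair, and test order within each
block alternates balanced and unbalanced pairs. One allocation refinement
is our own: a strain's balanced pairs are dealt across experimenters *by
response type*, so each experimenter's balanced type composition is as
even as the pool permits. This is ordinary systematic-heterogenization
logic — having matched pairs on type, one can also control the type
distribution over the other design factors — and it is what lets the
balanced design recover confounder effects (e.g. experimenter) that random
type imbalance obscures in the unbalanced pool.

## Stage 6: factorial analysis

Phase-2 integrated z-scores (exploration log-shifted, locomotion
rank-transformed) are fitted with all fixed factors and all interactions
(treatment × strain × pool × experimenter on the combined data; treatment
× strain × experimenter per pool) plus a random block intercept, using
`nlme::lme`; F-tests use the between-within denominator-df convention.
Each term gets a partial eta squared
$\eta_p^2 = SS_{eff} / (SS_{eff} + SS_{err})$ with a 95% CI by
noncentral-F inversion (the CI method is not dictated by the banding
convention; noncentral-F inversion is the standard choice) and the bands
small ≤ 0.03 < medium < 0.10 ≤ large < 0.20 ≤ very large. Post hoc
contrasts are estimated marginal means with the Dunn–Šidák per-test level
$\alpha' = 1 - (1-\alpha)^{1/m}$ (0.025321, 0.016952, 0.01274 for
$m = 2, 3, 4$ at $\alpha = 0.05$) and Cohen's d standardized by the model
residual SD. The test statistic is labelled by whatever reference
distribution the denominator-df convention implies (t with finite df)
rather than guessing a z. `compare_pools()` classifies every term as
significant in both pools, neither, unbalanced-only (*augmented* — type
variation inflating an apparent effect) or balanced-only (*unmasked* —
type variation hiding a real one).

## The synthetic generator

The generator is the package's definition of the study conditions, not a
tuning dial:

* three strains with $n = 59/60/60$ and per-strain probabilities of latent
  type B of 0.881 / 0.300 / 0.100 (the strain-by-cluster composition of
  the characterized cohort);
* per-type mean trajectories as monotone linear ramps in z units (type A:
  avoidance $-0.5 \to +0.5$, exploration flat at $-0.3$, locomotion
  $+0.3 \to -0.3$; type B: avoidance $+0.5 \to -0.5$, exploration
  $-0.5 \to +0.5$, locomotion $-0.5 \to +0.5$). The magnitudes are free
  parameters chosen once as qualitatively realistic ramp heights — the
  source tables give no numeric cluster means — and are not calibrated
  further;
* additive strain and experimenter offsets (defaults of 0.2–0.5 z, the
  scale at which such nuisance effects are typically reported);
* a between-mouse random intercept (SD 0.3 z), CAR(1) noise with
  stationary SD 0.3 z and $\phi = 0.4$, generated recursively with the
  innovation SD normalized so the stationary variance is exactly
  `sd_noise`²;
* body weights from per-strain normal distributions (means 20.4 / 21.0 /
  24.1 g, the published arrival weights);
* test groups as randomized weekly batches of 30 (10/strain), test order
  randomized within batch, experimenters balanced within strain × batch;
* raw ethogram variables emitted as affine-plus-noise images of the latent
  dimension scores (counts rounded and non-negative, latencies capped at
  300 s, percentages clamped to [0, 100]), so the scoring stage has
  realistic multi-variable input whose integration approximately recovers
  the latent scores;
* phase 2 as one trial per mouse: strain + experimenter + type offset +
  treatment effect (default: activity-suppressing, exploration $-0.6$,
  locomotion $-0.8$, avoidance $+0.3$ z) + noise.

What it does **not** emulate: floor/ceiling effects beyond simple
clamping, non-Gaussian tails, corticosterone physiology, estrous or sex
effects, temporal drift between characterization and test, or
observer-scoring error structure. Passing tests therefore demonstrate that
the pipeline recovers planted structure of realistic shape and size — not
that real mHB data contain exactly two types.

The constructed confounding scenarios (`scenario_config_augmented()`,
`scenario_config_masked()`, `confound_treatment_with_type()`) use an equal
0.5/0.5 type mixture and parameters fixed a priori by power analysis: a
type offset of 2 z with noise 0.4 z makes a fully confounded unbalanced
pool detect a spurious "treatment" effect with high probability while the
balanced pool cannot be confounded at all; an experimenter offset of 1.2 z
against a 2.4 z type offset puts the balanced analysis near 90% power for
the experimenter effect while random type imbalance between experimenters
degrades the unbalanced analysis.

## Problem sizes used by the test suite

The suite runs the full study geometry where it is cheap (179 mice, 5000
restart schedule, 48-pair design) and scales simulation counts to what a
desk machine runs comfortably: 50 seeds for label recovery, 2000
simulations (pooled over the three independent null dimensions) for type-I
calibration against the binomial tolerance defined at 1000 simulations,
and 500 simulations per confounding scenario. Bootstrap re-clustering uses
50 restarts per sample, and module tests use 10–25 where the assertion
does not depend on restart depth.

## Known limitations

* The plain-majority CVI vote is a documented stand-in for the adjusted
  voting rule of the framework it follows.
* The mixed-model F-tests with a 4-level random block are mildly
  anticonservative (measured null rate ≈ 0.052–0.056 at nominal 0.05);
  this is a known small-sample property of REML F-tests with
  boundary-prone variance components, shared with the fixed-block
  equivalent within 0.2% of decisions.
* Residual standardization assumes the dispersion model (per-strain
  variance) captures stratum heteroscedasticity; per-stratum residual SDs
  are ≈ 1 when the generator and model agree, but drift by up to ~0.15
  when the unmodelled type mixture differs strongly between strata.
* `glmmTMB`'s ar1 parameterization absorbs the mouse random intercept when
  both are present (they are near-equivalent covariance representations at
  5 trials); the reported $\phi$ is then the lag-1 correlation of the
  *combined* persistent-plus-autoregressive process, which is larger than
  the innovation-level $\phi$ of the generator.
* Pair matching is greedy-adjacent (optimal for total within-pair
  difference, verified by enumeration), not optimal for any weighted
  multi-criterion objective.
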