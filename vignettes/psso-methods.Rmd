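---
title: "PSSO wrapper feature selection: models, design decisions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PSSO wrapper feature selection: models, design decisions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(snakeswarm)
```

This vignette is the package's own account of its science: the optimizer
model and its assumptions, the wrapper objective, the preprocessing and
rebalancing chain, the parameters that matter, the places where the design
was genuinely open and what was decided there, and what the synthetic
benchmarks do and do not demonstrate.

## 1. The optimizers

All three algorithms minimize a black-box objective `f(x)` over a box
`[lower, upper]^d`, with a fixed iteration budget `T`, a population of `N`
candidates, and full determinism given one root seed.  No gradients, no
constraints beyond the box, no early stopping: the convergence trace always
has length `T` and records the elitist best, so it is non-increasing by
construction.

### Snake Optimizer (SO)

The population is split into `floor(N/2)` males and the rest females.  Two
scheduled environment variables gate behaviour at iteration `C`:

* food quantity `Q = K1 * exp((C - T)/T)`, rising from `K1/e` to `K1`;
* temperature `Temp = exp(-C/T)`, falling from 1 to `1/e`.

With the defaults `K1 = 0.5` and gate thresholds 0.25 (food) and 0.6
(temperature): early iterations (low `Q`) are *exploration* — each snake
jumps relative to a random same-gender reference, scaled by its foraging
ability `AB = exp(-f_ref/f_self)` and the constant `K2 = 0.05`; once food is
plentiful and the environment is hot (`Temp > 0.6`) all snakes pursue the
best-ever position (`L_food`) with step `K3 * Temp * r * (L_food - x)`,
`K3 = 2`; when cold, one uniform draw per iteration selects *fighting*
(movement toward the best of the opposite gender, coefficient
`FA = exp(-f_opp_best/f_self)`) or *mating* (movement toward the paired
partner scaled by `Q`, coefficient `MA = exp(-f_partner/f_self)`), and after
mating an *egg hatching* event (probability `hatch_prob = 0.5`) replaces the
worst snake of each gender with a fresh uniform position.

Two textual ambiguities in the source description had to be resolved:

* **Temperature semantics.** The food-following rule is described with
  `Temp > 0.6` as "hot" while the fight rule calls the same condition
  "chilly".  We follow the internally consistent original: hot means
  food-following, cold means fight-or-mate.
* **Fight-vs-mate selection and the `±` operator.**  Neither is given a
  rule.  We use one uniform draw per iteration against `mode_split = 0.6`
  for the mode, and an independent Bernoulli(0.5) sign per candidate per
  update for the "diversity factor" `±`.  Treating the mode as
  per-iteration (not per-candidate) mirrors the original algorithm's
  single-mode iterations; it is an interpretation, flagged here.

The `exp(-a/b)` coefficients assume strictly positive fitness.  Objectives
may be negative, so coefficients are computed on values shifted by the
running minimum: `f' = f - f_min_seen + eps_fitness` (`eps = 1e-9`).  The
shift preserves ordering and keeps every coefficient in `(0, 1]`.

### PSO

The standard inertia-weight form, per dimension `j`:

```
v'_j = w v_j + c1 r1_j (pbest_j - x_j) + c2 r2_j (gbest_j - x_j)
x'_j = x_j + v'_j
```

Defaults `w = 0.5`, `c1 = 0.8`, `c2 = 0.9` follow the study configuration;
the study's sensitivity scan preferred `w = 0.8`, `c1 = c2 = 2`, and both
settings are reachable through `optimizer_config()`.  Velocities are
clamped to `±0.1 * (upper - lower)` per dimension — the same 0.1 factor used
to initialize velocities — and positions are clipped to the box.

### PSSO, and the two hybrid design decisions

The hybrid adds a snake-derived displacement to the PSO velocity:

```
v' = w v + c1 r1 (pbest - x) + c2 r2 (gbest - x) + dSO
```

`dSO` is never given a formula in the source description, only "a phrase for
environmental adaption inspired by snakes".  We reuse the snake movement
forms so the hybrid degrades gracefully to SO behaviour:

* food plentiful (`Q > 0.25`): `dSO = K3 * Temp * r3 * (L_food - x)` — the
  food-pursuit step as a velocity term;
* otherwise: `dSO = K3 * FA * r3 * (S_opposite_best - x)` — the gendered
  fight step.

Second decision: **egg hatching in the hybrid.** Both `dSO` forms are
attraction terms that vanish as `x` approaches the attractor; with a
converging inertia setting the swarm can fully collapse (pbest = gbest = x,
v ≈ 0), after which nothing moves.  On smooth objectives this is harmless —
collapse happens at the optimum — but on the discrete-in-effect landscapes
of feature masks we observed runs stalling one bit flip away from the
optimum of an 8-bit enumeration problem.  The snake repertoire contains the
remedy: the egg-hatching replacement.  PSSO therefore re-seeds the worst
male and worst female with probability `hatch_prob` after each iteration
(elitist bookkeeping keeps the best-ever solution either way).  Hatched
candidates restart with fresh velocities and are pulled back toward the
elitist best, re-sampling mask variants on the way.  With hatching, the
8-bit enumeration benchmark is solved to its exhaustive optimum in 20/20
seeds at `N = 20`, `T = 50`, and the 10-dimensional sphere still converges
below 1e-6.  Hatching (like `dSO`) is disabled by `delta_so = FALSE`, which
makes a PSSO iteration consume exactly the PSO RNG stream and produce
bit-identical states — a tested reduction identity.

### RNG discipline

One root seed derives independent named substreams (initialization,
movement, signs, mode draws, snake displacement).  Adding or removing draws
in one stream cannot shift another stream's sequence, which is what makes
the PSO/PSSO reduction exact and keeps experiments reproducible across code
paths.

## 2. The wrapper objective

A position vector concatenates one *mask* dimension per feature (raw box
`(0, 1)`, bit = raw ≥ 0.5, an empty mask is repaired to the arg-max raw) and
the model's hyperparameter dimensions (raw box `(1, 100)` affinely or
log-mapped to native ranges: random forest trees/depth in `[1, 100]`;
decision-tree depth `[1, 30]` (the rpart engine's hard cap) and minimum
split `[2, 100]`; SVM cost `[1e-2, 1e3]` and RBF width `[1e-4, 1e1]` on log
scales; kNN `k` in `[1, 100]` plus a uniform/distance-weight bit).  Mask and
hyperparameters are optimized jointly in one vector — the simplest reading
of a method described as doing both at once.

The fitness of a decoded solution is
`alpha * (1 - mean CV accuracy) + (1 - alpha) * n_selected / n_total`, with
seeded stratified `cv_folds = 5` folds computed on the (balanced) training
partition only; the held-out test partition is never touched during
optimization.  Fitness evaluations are memoized on the decoded encoding —
exact, because CV error is deterministic given the fold seed.  Every
reported fitness is re-derivable from `(error, n_selected, n_total, alpha)`
to 1e-12, and the test suite asserts it.

`alpha` defaults to 0.99 (accuracy dominates, the conventional wrapper
setting).  Note the gradient this implies: at `alpha = 0.99` and 31
features, dropping one feature is worth only `0.01/31 ≈ 3e-4` fitness —
smaller than typical CV-error noise between neighbouring masks — so
parsimony pressure is nearly informative-free and subset *identity* should
not be over-interpreted at that setting (see §5).

## 3. Preprocessing and SMOTE-ENN

The preprocessing chain mirrors standard clinical-tabular practice: rows
with more than half their cells missing are dropped ("several missing"
operationalized); remaining numeric gaps take the column mean,
categorical/binary gaps the mode; duplicates are removed.  Splitting is
stratified 80/20 (stratification is our addition — with a 5%-prior minority
class an unstratified 20% slice is frequently degenerate).  Numeric columns
are standardized with *population* mean/sd fitted on the training partition
only (a two-point column `[0, 2]` maps to `[-1, 1]`); categorical columns
are one-hot encoded against the train-observed category set, unseen test
categories map to an all-zero block; a zero-variance column is scaled by 1
and flagged.

SMOTE-ENN runs on the encoded training matrix: each minority class is
oversampled to the majority count with `x + gap * (nn - x)`, `gap ~ U(0,1)`,
`nn` one of `k_smote = 5` same-class Euclidean neighbours; then every sample
whose label disagrees with the majority of its `k_enn = 3` neighbours is
removed (both sides — the cleaned set is near parity rather than exactly
balanced).  Neighbour counts are the conventional defaults; the source
description names none.  Balancing is applied **after** the split by
default.  The alternative (balance first, then split) is supported via
`balance = "pre_split"` because the study's block diagram can be read that
way, but it leaks interpolated copies of training points into the test set
and inflates accuracy; the package default avoids it.

## 4. Metrics, ANOVA, robustness

Metrics are computed from one-vs-rest confusion tallies per class:
precision, recall, per-class accuracy, F1, specificity, and
`error_rate = 1 - accuracy`.  Multiclass aggregation is support-weighted
averaging, except overall accuracy which is plain correct/total; the two
coincide with the direct two-class formulas on binary problems (tested).
Zero-denominator metrics are reported as 0 with a flag rather than NaN so
weighted averages stay defined on sparse classes.  One-vs-rest AUC uses the
rank (Mann-Whitney) statistic with half-credit for ties and matches an
exhaustive pair-counting oracle exactly (tested on random instances).  The
with/without-optimizer comparison is a one-way ANOVA over two groups of
repeated accuracies via `stats::aov`.

The robustness protocol perturbs the **raw** data, then runs the full
pipeline, so injected missingness exercises the pipeline's own imputation:
missing mode deletes exactly `round(fraction * cells)` feature cells
(labels never touched); noise mode adds Gaussian noise of sd `sigma` per
column *on the standardized scale* (i.e. scaled by the column sd — the
source does not say which scale its `sigma = 0.01` refers to; the
standardized scale is the one on which the number is scale-free);
imbalance mode keeps `1 - magnitude` of every non-majority class, so the
study's "50% imbalance" halves them while keeping all classes present.

## 5. The synthetic generator, and what passing tests show

`generate_thyroid_like()` emulates the schema of the motivating data: 31
mixed columns (log-normal "lab analyte" numerics — right-skewed like TSH —
and Bernoulli "history flag" binaries), 5 classes with priors
`(0.50, 0.20, 0.15, 0.10, 0.05)` to reproduce the strong imbalance the
rebalancing step presupposes, a known 6-feature informative set, effect
size `delta = 3` applied as class-conditional shifts on the log/logit
scale with a per-feature random class ordering, and injectable uniform
missingness.  What it does **not** emulate: feature-feature correlation
structure, label noise, informative-feature redundancy, or the real data's
joint distribution — so passing recovery tests demonstrate that the search
machinery works, not that the pipeline's clinical accuracy claims transfer.

The packaged feature-recovery benchmark runs `select_and_tune()` on
generated data (n = 2000, d = 31, 6 informative, `delta = 3`) with the kNN
wrapper, `alpha = 0.9`, `N = 32`, `T = 60`, 5-fold CV, 10 seeds, and scores
the median Jaccard index between selected and true informative sets.  The
choices are deliberate: kNN is the classic wrapper base learner because
irrelevant dimensions corrupt its distance metric, giving the search a true
error signal for pruning (tree learners ignore irrelevant features almost
completely, which leaves only the parsimony term to prune with); and
`alpha = 0.9` makes one feature worth `0.1/31 ≈ 3e-3` fitness, above
CV-error noise, so subset identity is actually determined by the objective.
At `alpha = 0.99` the same benchmark measures mostly CV noise.

## 6. Numerical choices and degenerate inputs

* Box feasibility by clipping after every step; velocity clamp
  `±0.1 * width`.
* Integer hyperparameters round half-up after the affine map and clip to
  native bounds.
* Behaviour-coefficient denominators guarded by `eps_fitness = 1e-9` on
  shifted fitness.
* Non-finite objective values raise immediately with the offending
  position.
* A training CV fold losing a class raises `degenerate fold`; stratified
  folds make this unreachable for class counts ≥ folds.
* ENN neighbourhood ties are broken by the single nearest neighbour.
* `compare_with_anova` with zero within-group variance returns a flagged
  `p = 0` (unequal means) or `p = 1` (equal means) instead of NaN.
* The kNN backend is a compiled brute-force kernel with deterministic
  tie-breaking (nearer neighbour, then lower training index, then lower
  class code); off-the-shelf kNN implementations break ties randomly, which
  would break the seeded-reproducibility contract of the wrapper fitness.
* Problem sizes in the test-suite and acceptance script (population 16-32,
  30-100 iterations, n = 300-2000 synthetic rows) are chosen so the full
  study protocol remains reproducible on a single CPU in minutes; they are
  the package's benchmark conditions, stated here for reproducibility.

## 7. Known limitations

* The optimizers handle box constraints only; no discrete/combinatorial
  encodings beyond the threshold-decoded mask.
* Joint mask + hyperparameter search is the implemented reading; a
  two-pass (select then tune) protocol may behave differently and is not
  provided.
* SMOTE interpolates one-hot columns as if continuous; synthetic points can
  carry fractional category indicators.  ENN cleaning removes most such
  borderline artifacts, but the balanced matrix is not guaranteed to be
  valid one-hot.
* The with/without-optimizer ANOVA treats fold accuracies as independent
  observations, as in the source protocol; fold overlap makes the test
  anti-conservative.
* Wall-clock/memory profiling, deep-learning baselines, and external
  validation datasets are out of scope.
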