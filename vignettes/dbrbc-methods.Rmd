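---
title: "Dual-layer belief rule base classification: models, learning and attribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-layer belief rule base classification: models, learning and attribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbrbc)
```

## The model

`dbrbc` implements multilevel risk classification on tabular physiological
and behavioral data with a *belief rule base* (BRB): a set of conjunctive
IF-THEN rules whose consequents are belief distributions over the output
classes rather than single labels. A rule over attributes
$x_1, \dots, x_T$ has the form

$$
\text{IF } (x_1 \text{ is } A_1^k) \wedge \dots \wedge (x_T \text{ is } A_T^k)
\text{ THEN } \{(D_1, \beta_{1k}), \dots, (D_N, \beta_{Nk})\},
\qquad \textstyle\sum_n \beta_{nk} \le 1,
$$

where the $A_i^k$ are *reference values* discretizing each attribute's
range, $\theta_k \in [0,1]$ is the rule weight, $\delta_i \in (0,1]$ the
attribute weight, and strict inequality in the belief sum encodes
ignorance. With $R_i$ reference values per attribute the rule base
enumerates the full Cartesian product, $L = \prod_i R_i$ rules.

Forward inference is the classical rule-based evidential reasoning (ER)
pipeline:

1. **Input transformation.** A value is clamped to the reference span and
   distributed over its two adjacent reference values by linear
   interpolation, giving matching degrees that are non-negative and sum
   to 1 (`transform_input()`).
2. **Rule activation.** Rule $k$ receives weight
   $w_k \propto \theta_k \prod_i \alpha_{i,k}^{\bar\delta_i}$ with
   $\bar\delta_i = \delta_i / \max_j \delta_j$, normalized over rules
   (`activation_weights()`).
3. **ER combination.** Activated rules contribute basic probability
   masses $m_{nk} = w_k \beta_{nk}$; the unassigned remainder splits into a
   weighting part $\bar m_{Dk} = 1 - w_k$ and an incompleteness part
   $\tilde m_{Dk} = w_k (1 - \sum_n \beta_{nk})$. The analytic closed form
   of the recursive combination produces the aggregated class masses and a
   residual (`er_combine()`); the test suite checks it against an
   independent recursive two-at-a-time implementation to $10^{-10}$.
4. **Decision.** Argmax of the masses, ties to the lowest class index;
   residual mass is reported, never redistributed (`decide()`).

Two properties of ER are worth keeping in mind when reading outputs.
First, combining several rules that *agree* does not reproduce their
common belief vector — ER reinforces the dominant class, which is the
intended behavior of evidence accumulation. Second, if every activated
rule carries complete beliefs, the output residual is exactly zero.

## The coarse-to-fine hierarchy

A flat rule base over $M$ features needs $R^M$ rules (with the package's
default $R = 3$ and six survey features: $3^6 = 729$). The dual-layer
architecture replaces this with a *coarse* rule base that assigns each
record to one of three BMI groups (Lean / Overweight / Obese) and routes
it to one of three *fine* submodules, each over its own small feature
subset. With the default subsets — coarse: height, weight; Lean: height,
weight, meal count (NCP); Overweight: age, height, weight; Obese: gender,
height, weight, vegetable frequency (FCVC) — the total is
$3^2 + 3^3 + 3^3 + 3^4 = 144$ rules.

Routing is *hard*: the fine prediction is constrained to the routed
group's labels, so a coarse error cannot be repaired downstream. This is
a documented property, not a defect; the coarse task (a BMI threshold on
height and weight) is far easier than the fine one, and measured coarse
accuracy dominates fine accuracy on every synthetic benchmark in the test
suite.

Two design points were genuinely open:

* **Teacher routing at training time.** Submodules are trained on records
  whose *ground-truth* coarse label matches them, so coarse mistakes never
  contaminate submodule training; inference uses predicted routes.
* **Group-scoped reference frames.** Each submodule's reference values
  span the attribute range of *its own group's* training records, not the
  global range. A Lean-group weight span (say 38–77 kg) would otherwise
  collapse into the first cell of a global 39–145 kg frame and the
  submodule would lose nearly all resolution; scoping the frame to the
  group was the single largest accuracy improvement during development.

The fine labels follow the WHO-style BMI bands (insufficient < 18.5,
normal 18.5–25, overweight 25–30, obesity I 30–35, II 35–40, III ≥ 40,
lower bounds inclusive). The bands define seven classes but only six
published breakpoints; the overweight I/II internal boundary is not a
WHO quantity and is exposed as a parameter (`obesity_scheme()`, default
27.5, the interval midpoint). Tests never depend on its exact value.

## Parameter learning: cascaded DE–PSO

All free parameters of a rule base — $\theta$ ($L$ values), $\delta$
($T$ values) and $\beta$ ($L \times N$ values) — are encoded as one flat
vector in the unit box and learned by a two-stage cascade
(`train_rulebase()`): differential evolution (DE/rand/1/bin) explores
globally, then particle swarm optimization (PSO), seeded with the final
DE population, refines locally. Defaults follow the standard
configuration: population NP = 50, DE scaling F = 0.6, crossover
CR = 0.9, PSO inertia w = 0.7, learning factors c1 = c2 = 1.5, and a
*total* budget of G = 200 generations. The budget split is not dictated
by the configuration itself; the package reads G as shared and gives half
to each stage (`de_fraction = 0.5`), which solves a 20-dimensional sphere
benchmark to < 1e-3 where either stage alone at the same half-budget does
not.

Remaining numerical choices:

* **Fitness.** The blended objective is
  $\alpha \cdot \text{accuracy} + (1-\alpha) (1 - \text{nMAE})$ with
  $\alpha = 0.7$, where nMAE is the mean absolute deviation between the
  output masses and the one-hot truth, scaled by $N/2$ into $[0,1]$. The
  error term gives the search a gradient through plateaus of constant
  accuracy; a perfect one-hot classifier scores 1 for any $\alpha$.
* **Repair.** Candidates are clipped to the unit box; rule and attribute
  weights are floored at $10^{-6}$ (a vector that zeroes every rule a
  record activates would otherwise leave the inference undefined); any
  rule's beliefs summing above 1 are rescaled proportionally. Repair runs
  inside the objective, before evaluation, never after selection.
* **Initialization.** One DE member is data-seeded: unit weights and
  beliefs set to the activation-weighted class frequencies of the
  training records; the rest start uniform. This gives the search an
  informed anchor without constraining it.
* **Model selection.** Among the best-so-far incumbents of both stages,
  the vector with the highest *validation* fitness is decoded into the
  returned rule base (training fitness when no validation set is given).
* **Velocity clamp.** PSO velocities are clamped at 0.2 per dimension, a
  standard stabilizer for unit-box searches.

## Reverse contribution analysis and the contribution matrix

After forward inference the package supports backward reasoning.
`reconstruct_attributes()` searches the attribute ranges for inputs whose
forward-inferred masses are closest (mean absolute deviation) to a target
distribution, using seeded multi-start cyclic coordinate descent with
golden-section line searches — deterministic given the seed.

A dimension count shows why *joint* inversion cannot be accurate in
general: the output carries at most $N$ free coordinates (masses plus
residual, summing to 1), so with more unknown attributes than that the
preimage of a target is a manifold, and every point on it is an equally
valid inverse. For the three-attribute submodules the joint round-trip
error is therefore large (~0.3 normalized) *for any method*. The
per-attribute reconstruction error the model family reports is
well-posed only as a **conditional** inversion: each attribute is
reconstructed with the remaining attributes held at their observed
values, a one-dimensional problem whenever the output varies with that
attribute. `rca_roundtrip()` and `mae_mean_20()` therefore default to
`mode = "conditional"` (the joint mode remains available), and under it
the round-trip normalized MAE on trained submodules is in the 0.00–0.05
range — the scale practitioners should expect. `mae_mean_20()` averages
the normalized MAE over 20 repetitions with distinct derived seeds; since
the inversion is deterministic per seed, the repetitions only differ
through restart randomization.

The **contribution belief matrix** (`contribution_matrix()`) quantifies,
for each fine class, how much each attribute of the responsible submodule
drives that class's output mass: the raw contribution of attribute $i$ is
the mean drop in the class's mass over that class's records when the
attribute is *neutralized* — its matching vector replaced by the uniform
distribution over its reference values. Negative drops are floored at
zero and rows are normalized to sum to 1; attributes outside a class's
module are structurally missing and render as an en dash. Neutralization
was chosen over leave-one-out retraining because it is deterministic,
cheap, and produces non-negative row-normalizable scores. One caveat:
because ER sharpens agreeing evidence, neutralizing an attribute whose
beliefs are constant still perturbs the output slightly (it changes how
activation spreads over agreeing rules), so an inert attribute's
contribution collapses toward zero without reaching it exactly.

## Feature selection

`select_features()` runs the two-stage selector: gradient-boosted-tree
gain importances (xgboost, single-threaded, seeded), normalized to sum
to 1, are thresholded at 0.06 (strict inequality; an empty result falls
back to the top two with a warning), then sequential forward selection
greedily adds survivors while validation accuracy strictly improves. The
threshold is applied on the *normalized* scale — with 14–17 candidate
features a raw-gain threshold of 0.06 would be meaningless. Ties break
by gain rank then name, making the trajectory deterministic. The inner
model is a small flat BRB trained with a reduced budget (G = 40,
NP = 20); the wrapper criterion only needs relative comparisons, not a
fully converged model. Greedy forward search can miss jointly informative
pairs; that limitation is inherent to SFS and documented rather than
patched.

## The synthetic cohort generator

`generate_cohort()` emulates the structure of the obesity survey data the
model family targets, so everything is testable without downloads:
height ~ Normal(1.70 m, 0.09 m) truncated to ±3 sd; BMI uniform within
each class's band, with the unbounded top class capped at 50 kg/m²;
weight = BMI · height²; age uniform on 14–61 years; gender ~
Bernoulli(0.5); and class-conditional distributions for vegetable
frequency (FCVC, 1–3) and daily meal count (NCP, 1–4) whose effect
directions mirror the model family's reported findings — FCVC shifts
down with obesity severity, NCP separates insufficient (few meals) from
normal weight (regular three meals) — so attribution tests have known
ground truth. A `label_noise` rate resamples that fraction of labels
uniformly from other classes.

What the generator does *not* emulate: the real surveys' correlation
structure between lifestyle variables, their SMOTE-style augmentation,
class imbalance, and measurement error in self-reported data. Passing
tests on this cohort demonstrate that the machinery behaves as specified
under known structure, not that real-data accuracies transfer.

Because BMI is uniform *within* bands, adjacent classes touch at their
boundaries and a three-reference rule base cannot carve the curved BMI
boundary exactly; fine-grained accuracy on this cohort saturates around
0.7 regardless of training budget, while coarse accuracy exceeds 0.9.
The ablation benchmark therefore asserts orderings (hierarchical +
cascaded optimization ≥ flat + DE), never absolute accuracy levels.

`generate_from_rulebase()` supports simulate-then-refit studies: inputs
uniform over the frame ranges, labels *sampled* from the forward masses
(residual spread uniformly). Sampling bounds attainable accuracy by the
Bayes rate $E[\max_n p_n]$, so the packaged recovery benchmark
(`recovery_rulebase()`) uses a crisp geometry — reference values at
(0, 0.93, 1), one-hot beliefs, positive class on rules touching a top
reference — whose mixing band is narrow: Bayes accuracy ≈ 0.97–0.99,
majority baseline ≈ 0.92, and the refit model reaches ≥ 0.95 held-out
accuracy across seeds (`recovery_experiment()`).

## Problem sizes and benchmarks

The shipped benchmarks are desk-scale by design; sizes are stated here as
the package's own standard settings. The recovery experiment uses 600
training and 200 held-out records with the full default optimizer
configuration. The hierarchy benchmark uses 30 records per class (210
total, split 6:2:2) and G = 60 generations per module; the ablation
benchmark 20 records per class and G = 40, which preserves every ordering
of interest while keeping a full four-variant run around a minute. RCA
round-trips use 100 records per submodule. `scripts/acceptance.R`
recomputes all of these from scratch under a caller-supplied seed.

## Known limitations

* Hard routing caps fine accuracy by coarse accuracy; no soft mixture of
  submodules is offered.
* Three reference values per attribute limit boundary resolution
  (deliberately, to keep $R^M$ small); accuracy-critical deployments can
  raise `n_refs` per attribute at the usual exponential rule-count cost.
* Joint attribute reconstruction is underdetermined for multi-attribute
  modules (see above); per-attribute claims should always use the
  conditional mode.
* The DE/PSO cascade is a stochastic optimizer: different seeds give
  different parameter vectors of similar fitness; all entry points thread
  explicit seeds for reproducibility.
* Categorical attributes (gender, survey levels) are treated as numeric
  codes on the reference grid, matching the rule-count accounting of the
  model family; no dedicated categorical matching is implemented.
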