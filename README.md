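# dbrbc — dual-layer belief rule base classification with contribution analysis

`dbrbc` is an R package for multilevel risk classification on tabular
physiological and behavioral data — the motivating application is obesity
severity grading from anthropometric and dietary-habit survey variables —
built for settings where predictions must stay *traceable*: every decision
decomposes into human-readable IF-THEN rules, and every rule's influence can
be quantified. Its intended users are biostatisticians and health-informatics
researchers who need interpretable multiclass models with attribution, not
black-box accuracy alone.

## What it implements

**Belief rule base (BRB) inference.** A rule over attributes
x₁…x_T reads

    IF (x₁ is A₁ᵏ) ∧ … ∧ (x_T is A_Tᵏ)
    THEN {(D₁, β₁ₖ), …, (D_N, β_Nₖ)},   Σₙ βₙₖ ≤ 1

with rule weights θₖ, attribute weights δᵢ and reference values Aᵢᵏ
discretizing each attribute (R values per attribute ⇒ R^M conjunctive
rules). Inputs map to matching degrees by linear interpolation, rules
activate in proportion to θₖ·Πᵢ αᵢₖ^δ̄ᵢ, and the activated belief
distributions combine through the analytic evidential-reasoning (ER)
algorithm into class masses plus a residual (unassigned) mass.

**Coarse-to-fine hierarchy.** A 3-class coarse rule base (Lean /
Overweight / Obese, from BMI = weight/height²) routes each record to one of
three fine submodules with their own feature subsets, cutting the rule count
from 3⁶ = 729 (flat, six features) to 3² + 3³ + 3³ + 3⁴ = 144.

**Cascaded DE–PSO learning.** All rule parameters (θ, δ, β) are trained by
differential evolution (global stage) handing its population to particle
swarm optimization (refinement stage), maximizing a blended fitness
α·accuracy + (1−α)·(1 − normalized MAE), α = 0.7, NP = 50, F = 0.6,
CR = 0.9, w = 0.7, c1 = c2 = 1.5, G = 200 total generations.

**Reverse contribution analysis (RCA).** Backward reasoning reconstructs
input attribute values from an output belief distribution
(`reconstruct_attributes()`), and a contribution belief matrix
(`contribution_matrix()`) quantifies each attribute's row-normalized
contribution to each class by attribute neutralization.

**Supporting modules.** Two-stage feature selection (xgboost gain threshold
0.06 + sequential forward selection), stratified 6:2:2 splitting, CSV
ingestion for survey-style schemas, a synthetic cohort generator with known
effect structure, metrics and a four-variant ablation harness, plus a CLI
(`inst/cli/dbrbc.R`) with `simulate | split | select-features | train |
predict | evaluate | explain | ablate` subcommands.

## Worked example

```r
library(dbrbc)

ds <- generate_cohort(n_per_class = 30, seed = 42)      # 210 records, 7 classes
sp <- stratified_split(ds$fine_labels, seed = 7)        # 6:2:2 per class
tr <- ds$records[sp$train, ]

model <- build_hierarchy(tr, ds$scheme, fine_labels = ds$fine_labels[sp$train])
model <- train_hierarchy(model, tr, ds$fine_labels[sp$train],
                         ds$records[sp$validation, ], ds$fine_labels[sp$validation],
                         optimizer_config(G = 60, seed = 3))

pred <- predict(model, ds$records[sp$test, ])
compute_metrics(ds$fine_labels[sp$test], pred$fine, ds$scheme$fine_labels)
#> <metrics_report> accuracy 0.7143 | macro P 0.7240 R 0.7143 F1 0.7072
#>                 class support precision recall     f1
#> 1 Insufficient weight       6    1.0000 1.0000 1.0000
#> 2       Normal weight       6    0.8333 0.8333 0.8333
#> 3  Overweight level I       6    0.8000 0.6667 0.7273
#> ...
```

Fine-grained accuracy on this generator saturates around 0.7 because BMI is
uniform within each class band and three reference values per attribute
cannot carve the curved band boundaries exactly; coarse-group accuracy is
0.93 on the same split. The contribution belief matrix shows which
attributes drive each class (rows sum to 1; `–` marks attributes outside a
class's submodule):

```r
contribution_matrix(model, ds$records[sp$test, ], ds$fine_labels[sp$test])
#>               Class  height  weight     ncp     age  gender    fcvc
#> Insufficient weight  0.1060  0.3588  0.5352       –       –       –
#>       Normal weight  0.5764  0.2372  0.1864       –       –       –
#>  Overweight level I  0.5171  0.4829       –  0.0000       –       –
#> Overweight level II  0.4237  0.3966       –  0.1797       –       –
#>      Obesity type I  0.0000  1.0000       –       –  0.0000  0.0000
#>     Obesity type II  0.0000  1.0000       –       –  0.0000  0.0000
#>    Obesity type III  0.1391  0.3402       –       –  0.0526  0.4681
```

Meal count (`ncp`) dominates the insufficient-weight row and vegetable
frequency (`fcvc`) contributes to the top obesity class — exactly the
effect directions the synthetic generator encodes. Single records trace all
the way through:

```r
dbrb_predict(model, as.list(ds$records[sp$test[1], ]))$fine_dist
#> <belief_dist>
#> Insufficient weight       Normal weight
#>              0.9922              0.0029
#> residual: 0.0048
```

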