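---
title: "Forests of perfect trees: model, criteria and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forests of perfect trees: model, criteria and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfpt)
```

## The model

`rfpt` turns the usual random-forest logic on its head. Instead of
assembling deliberately varied, individually imperfect trees, it builds
*perfect* trees — classifiers with 100% sensitivity and specificity on the
training observations — in massive numbers, and asks of every feature: how
often, and in what way, does this feature participate in a perfect
classification?

Each tree node is a neuron: a sample with feature values
$x_1, \dots, x_n$ receives the projection score $s = \sum_j c_j x_j$ with
coefficients $c_j \in \{-1, 0, +1\}$, and is classified positive when $s$
strictly exceeds a threshold. The ternary restriction is deliberate: it
makes each coefficient directly readable (risk / silent / protection), it
bounds the per-neuron search at $3^n$ candidate vectors so the search can
be exhaustive, and it regularizes the node.

Trees use a *half Christmas tree* architecture. Neurons are arranged in a
chain of at most six (three cycles of two steps). Odd steps finalize the
predicted-negative samples — admissible only when every one of them is
truly class 0 — and reinject the rest into the trunk; even steps do the
same for the positive side. Before every step the grower first checks
whether some neuron classifies the whole active set without error; if so
both sides are finalized at once and the tree terminates. A tree is
perfect exactly when the active set empties within the budget, which by
the admissibility rule implies zero classification errors. Every tree is
grown on **all** observations — no bootstrapping, no weights — so
perfection always refers to the full sample.

A forest draws random feature subsets (uniform, without replacement within
a tree, with replacement across trees) until each feature has entered at
least `min_instances_per_feature` trees (default 100), and tallies what
happened in the perfect trees each feature joined.

## The ten criteria and the score

All criteria are proportions in $[0,1]$, computed per feature from the
tally. NIC1 divides by the selection count; all others divide by the
perfect-tree count:

| criterion | numerator event | reading |
|---|---|---|
| NIC1 | tree is perfect | predictive quality |
| NIC2 | all the feature's coefficients zero | no independent information |
| NIC3 / NIC4 | all coefficients positive / negative | consistent risk / protection |
| NIC5 | — (defined as NIC3 × NIC4) | between-tree paradoxical effect |
| NIC6 | coefficients of both signs in one tree | within-tree interaction |
| NIC7 / NIC8 | perfect within two neurons / one neuron | proximity to the outcome |
| NIC9 | enumerable (finite) solution set | non-degenerate relationship |
| NIC10 | unique solution | single pathway |

The composite score is

$$\mathrm{NICscore} = \mathrm{NIC1} - \mathrm{NIC2} - \mathrm{NIC6}
  + \mathrm{NIC8} + \mathrm{NIC9} + \mathrm{NIC10} \in [-2, 4],$$

with 4 attained only by features that are always perfect, single-neuron
and unique-solution. NIC5 is excluded because its rescaling to a 0–100%
range is undefined, and NIC7 because it nests NIC8; both are still
computed and reported. The hierarchical ranking
$(1-\mathrm{NIC2}, \mathrm{NIC1}, \mathrm{NIC10}, \mathrm{NIC8})$ — a
stable descending lexicographic sort — is the nested alternative; feature
selection cuts the score-sorted list at the first consecutive drop of at
least `min_gap` (default 1.0).

Features that never joined a perfect tree are flagged `no_pt`, zeroed and
ranked **last, not removed**: such features (like all-zero-coefficient
ones) can be essential intermediates in the cascade leading to the
outcome, so eliminating them outright would be unsafe for an explanatory
model.

## Numerical conventions

Several conventions are fixed here because no canonical choice exists;
each is load-bearing for reproducibility:

* **Prediction rule.** Positive iff score $>$ threshold; ties go negative.
* **Thresholds.** Candidates are midpoints between consecutive distinct
  sorted scores plus one value below the minimum and one above the
  maximum. This finite set realizes every achievable dichotomy of a finite
  sample, so the per-neuron search is complete.
* **Tie-breaks.** Among equally optimal coefficient vectors, the first in
  lexicographic order ($-1 < 0 < +1$); among thresholds, the smallest.
* **Step order.** Negative finalization leads (step 1); a cycle is one
  negative plus one positive step. Either polarity could lead; the choice
  is fixed for determinism and is configurable in spirit through the tree
  configuration.
* **Solution counting.** Only coefficient vectors are counted (thresholds
  form continuous intervals). Per-neuron counts multiply; a product of 1
  is `unique`, a finite product `finite`, and if any neuron's optimum is
  attained by *every* enumerated vector the tree is `unconstrained` — the
  no-convergence analogue of infinitely many solutions. Zero-finalization
  neurons still consume a step (fixed depth, no pruning).
* **Per-feature sign profile.** A feature's profile within a tree
  classifies its own coefficient across the used neurons; one sign plus
  zeros (`mixed_with_zero`) increments none of the four tallied
  categories. This matches published tallies in which a feature can be
  perfect in 170 trees yet all-positive in only 168.
* **Missing data.** Rejected at ingestion. The calculus is combinatorial;
  imputation toward a central value has no meaning in it.

## Search modes

The default `exhaustive_greedy` mode is exhaustive per neuron (all $3^n$
vectors × all thresholds) and greedy across neurons (each step takes the
maximal admissible finalization). `full_enumeration` explores entire
neuron sequences with memoization on the residual active set; it is exact
for perfect-tree existence and serves as the independent oracle in the
test suite, where the two modes agree on hundreds of randomized small
instances.

For neurons with many features ($n \gtrsim 8$), $3^n$ is out of reach;
`max_vectors` switches to a uniformly sampled, explicitly non-exhaustive
coefficient search. Trees grown this way are flagged, and their solution
counts refer to the sampled set only. How the original large-$n$ analyses
searched $3^{15}$ combinations per neuron is not documented anywhere we
could follow, so this heuristic mode makes no claim to reproduce published
large-$n$ rates.

## Randomness and reproducibility

One master seed determines everything. Feature-subset draws use
independent RNG substreams seeded by a deterministic mix of the master
seed and a chunk index (a chunk is a fixed block of trees, by default
8192, shrunk to about the feature count for narrow datasets so the quota
is not badly overshot). Chunked substreams — rather than one stream per
tree — keep the plan bitwise identical however chunks are distributed
over workers, while allowing the draws inside a chunk to vectorize; at the
scale the method targets (millions of trees) per-tree reseeding would
dominate the runtime. Heuristic neuron sampling, fold assignment in the
benchmark harness and the synthetic generator each use their own tagged
substreams, so the components cannot perturb one another's streams.

The quota rule stops at the first chunk boundary where every feature has
reached its minimum selections ("at least" semantics); an exact `n_trees`
can be requested instead, which is how published forests that overshoot
the quota (e.g. a mean of 153 selections against a quota of 100) are
reproduced.

## What the synthetic generator emulates — and what it does not

`synth_spec()` produces continuous class-conditional Gaussian features
(optionally t(3) for heavy tails) with planted archetypes: `separable`
(shift $\Delta$ with $\Delta/\sigma = 10$ by default — non-overlapping
class ranges at desk sample sizes, hence perfect single-feature trees with
a unique solution), `monotone_weak` ($\Delta/\sigma = 0.5$),
`paradoxical` (shift sign flips with a latent per-sample context, the
NIC5/NIC6 structure), `intermediate_null` (a deterministic average of two
planted parents — information without independent contribution), and
label-independent `noise`. Default dimensions (40 samples, 50 features,
prevalence 0.5) mirror a small two-arm expression study.

The generator does **not** simulate array normalization, batch effects,
probe-level replicates or correlated noise. Recovery results on synthetic
data therefore show that the machinery identifies the structures it
defines — separability, paradox, redundancy — not that it will rank
probes correctly in any particular real study.

## Benchmark harness

`confusion_metrics()` reports MCC (zero by convention when a denominator
factor vanishes) and accuracy. `compare_selectors()` evaluates named
feature sets with logistic regression, a quadratic-kernel SVM and a random
forest on identical stratified 3-fold × 20-repeat splits (single-class
training folds are regenerated from the next substream and logged).
`stepwise_aic_curve()` fits logistic models along a ranking, with
$\mathrm{AIC} = 2(k+1) - 2\log L$ (intercept counted; $k = 0$ is the null
model, $2 - 2m\log\tfrac12$ for a balanced sample of size $m$) and flags
complete separation, reporting the AIC at the fitter's convergence cap.
Gini-importance and SVM-RFE rankings are composed from the standard
`randomForest` and `e1071` machinery as comparison baselines; they are not
part of the core method.

## Problem sizes used in the checks

The shipped checks run at desk scale by design: oracle-equivalence on 200
random instances of up to 8 samples; recovery of one planted separable
feature among 50 (40 samples, quota 100, three seeds); forest property
tests at 10–50 features. The full-scale plan arithmetic (8,363,591
single-probe trees over 54,675 probes, mean 153 selections per probe) is
recomputed by actually drawing the plan, which takes about a second;
growing that forest's trees against real arrays is an hours-scale
computation on downloaded data and is deliberately out of the default
checks, as is the published 15-features-per-neuron benchmark (its
per-neuron search is not reproducible from the record, see above).

## Known limitations

* Perfection is defined on the training sample; with few samples and many
  features, perfect trees are abundant and the criteria measure structure,
  not generalization. The benchmark harness exists precisely to check
  selections out of sample.
* The greedy grower is not guaranteed optimal for $n > 1$ feature per
  neuron (the oracle equivalence is established for single-feature trees);
  a greedy-missed perfect tree would bias NIC1 downward slightly.
* Tied feature values shared across classes make perfection impossible for
  a single-feature tree; heavily discretized data will depress NIC1 for
  all features.
* `no_pt` features carry no criterion information and are ranked last;
  distinguishing "uninformative" from "intermediate" among them requires
  the multi-feature confirmation designs (`adjusted`, `stratified`).
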