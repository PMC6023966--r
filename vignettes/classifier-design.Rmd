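---
title: "Designing miRNA cell-classifier circuits: models, constraints and scores"
author: "mirdesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing miRNA cell-classifier circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirdesign)
```

## The design problem

A cell-classifier circuit is a synthetic gene circuit that senses endogenous
miRNA levels and triggers a response (typically an apoptosis signal) when the
cell looks diseased.  After binarizing each miRNA level into High (1) or Low
(0), the design problem becomes Boolean: find a function
$f\colon\{0,1\}^n \to \{0,1\}$ that reproduces the annotation (1 = positive /
diseased, 0 = negative / healthy) of every sample in a labeled expression
table.

`mirdesign` works with classifiers in conjunctive normal form.  A *gate* is a
clause — a disjunction of possibly negated inputs — and the classifier is the
conjunction of its gates.  The laboratory repertoire restricts what a gate may
look like, and those restrictions are what makes the search hard and
interesting: unconstrained rule learning is easy, but the result could not be
assembled from the available molecular parts.

## Feasibility constraints

A `constraint_profile()` captures assemblability:

* `max_gates`, `max_inputs` — global upper bounds on circuit size.  The
  defaults in `core_profile()` are 6 gates and 8 total inputs.
* gate types — each described by five bounds: lower/upper bounds on
  non-negated and negated inputs, plus a cap on how often the type may occur.
  The default repertoire has two types: an OR gate of non-negated inputs
  (Type 1) and a single-negated-input NOT gate (Type 2).  Occurrence caps
  default to `max_gates`, the least restrictive choice, and can be tightened
  in a config file (`save_constraints()` / `load_constraints()`).
* `unique_input` — optionally forbids one miRNA from feeding several gates,
  which can make a design more robust to level noise.
* `fn_bound`, `fp_bound` — upper bounds on false negatives (positives
  classified 0) and false positives (negatives classified 1).  Both default
  to 0: a perfect classifier.

`validate_classifier()` checks a classifier against a profile and returns
violations as data.  Gates that fit several types are routed by an exact
search over type assignments, because a greedy assignment can falsely reject
a feasible classifier.

## Global optimization

`find_optimal()` supports five modes: plain feasibility, and the four
hierarchies *minimize inputs* (`opt1`), *minimize gates* (`opt2`), *inputs
then gates* (`opt3`) and *gates then inputs* (`opt4`).  Optimality is
*global*: if the reported optimum uses $I$ inputs, no feasible classifier
with $I-1$ inputs exists.  With `enumerate_all = TRUE` the solver returns
every optimum, reduced to one representative per isomorphism class (solutions
that differ only in which integer identifier is attached to which
interchangeable gate), in deterministic lexicographic order.

The engine is a complete branch-and-bound:

1. Under a false-negative budget $f$, every gate of a solution must be true
   on all positives outside some misclassified set $F$, $|F| \le f$.  For
   each maximal $F$ the engine enumerates the *clause pool* — all
   sign-feasible clauses true on the remaining positives.  Truth of a
   disjunction is upward closed under adding literals, so a literal-ordered
   DFS with a reachability prune enumerates the pool completely.
2. Each clause *covers* (falsifies) a set of negatives.  A classifier is a
   set of distinct clauses whose union of covers leaves at most `fp_bound`
   negatives uncovered, within the gate/input budgets and occurrence caps.
   An index-ascending DFS over the sorted pool enumerates these sets exactly
   once; the only prunes are monotone budget and coverage bounds, so the
   search is exact.
3. Optimization is iterative deepening on the objective: budget level $k$ is
   only attempted after level $k-1$ has been exhausted, which turns the first
   success into a global optimality certificate.  Bi-level modes fix the
   upper-level optimum and then deepen the lower level.

For plain feasibility on large instances (the benchmark setting), a lazy
variant skips pool construction: it branches on the first uncovered negative
and enumerates, on demand, the inclusion-minimal clauses that falsify it
while staying true on all positives.  Replacing any clause of a solution by a
minimal sub-clause preserves the solution, so this search is complete for
feasibility whenever every gate type has sign lower bounds of at most one —
true for the core repertoire.  For profiles with larger lower bounds the
solver falls back to the pooled search automatically.

Duplicate gates are excluded from the search space: under conjunction they
are redundant and only inflate symmetry.  The engine contains no random
choices; identical inputs give identical solution sets.

`brute_force_oracle()` is a deliberately naive second implementation —
enumerate every structurally valid classifier, evaluate it, read off the
optima — used to verify the engine.  It refuses instances beyond 8 markers or
a total-input bound of 4.  The test suite checks engine/oracle agreement on
200 seeded instances for all five strategies, plus optimality certificates
(re-solving with a tightened bound is infeasible).

### Error-bound relaxation

Real tables are often inconsistent — the same binarized profile occurs with
both labels — so no perfect classifier exists.  `relax_and_solve()` walks a
schedule of `(fn, fp)` bound pairs, re-solving at each step, and returns the
first feasible step, keeping accuracy above simplicity in the optimization
hierarchy.  The default schedule orders pairs by total allowed errors
ascending and raises the FN bound first within equal totals:
`(0,0), (1,0), (0,1), (2,0), (1,1), (0,2), ...`.  Orderings of the pairs with
equal totals beyond total 1 are a genuine design choice (several are
defensible); this package fixes the rule above and exposes one-axis schedules
via `relaxation_policy(forbid_fp =)` / `forbid_fn`, for applications where
one error type is unacceptable — e.g. forbidding false positives so that no
healthy cell is killed, at the price of more missed diseased cells.

## Scores

In the Boolean setting, `boolean_rates()` reports FN/FP rates normalized by
class sizes.  Reports round to 2 decimals, half-up (`round_half_up()`); full
precision is kept internally.

In the continuous setting the classifier is viewed through a circuit output
model.  The built-in `default_output_model()` is a saturating surrogate: a
non-negated input contributes a Hill activation $x^k/(x^k + K^k)$, a negated
input the repression $K^k/(x^k + K^k)$; a gate's activation is the maximum
over its literals and the circuit output is `ymax` times the product of gate
activations.  Defaults: $k = 4$ (a steep but not step-like response), $K$ =
the dataset's binarization threshold (the natural scale separating Low from
High), `ymax` = 1.  The model is pluggable — `scoring_config(output_model =)`
accepts any function of (classifier, profile, config) — so a published
mechanistic ODE response can be substituted; the surrogate's absolute scores
should not be compared against scores computed under a different output
model.

On top of the outputs:

* `s_auc()` — AUC of the output as a ranking score for the positive class,
  mid-rank tie convention (constant outputs give 0.5).
* `margins()` — average margin `ma` (ratio of class mean outputs) and worst
  margin `mw` (worst positive/negative output pair, i.e. min over positives /
  max over negatives).  The ratio transform is the default; a log-ratio
  transform is available since published margin magnitudes suggest one.  The
  weight in `s_m()` is applied after the selected transform.
* `s_m()` — the convex combination $\lambda\,Ma + (1-\lambda)\,Mw$, default
  $\lambda = 0.5$ (both margins equally relevant).

`rank_solutions()` orders a set of optima by AUC, then `s_m`, then canonical
text — the rule used to pick a final design among Boolean-equivalent optima.

## Synthetic benchmarks and cross-validation

`generate_matrix()` draws i.i.d. fair-Bernoulli 0/1 matrices.  Two annotator
setups plant the ground truth:

* **Setup 1** draws a classifier satisfying the core constraints by uniform
  choices (gate count, admissible type per gate, input count within the type
  bounds and remaining budget, markers).  Labeling rows with such a
  classifier guarantees a feasible zero-error solution, so Setup 1 instances
  are never infeasible.  The published description fixes only "equal
  probabilities" over existing gates and inputs; this per-gate/per-input
  uniform construction is the package's reading and is the generator's fixed
  default.
* **Setup 2** uses a coin-toss template — up to $\lfloor n/10\rfloor$ gates
  (at least one gate is enforced, since annotation requires a function), up
  to 5 inputs per gate, each gate and input slot present with probability
  1/2, uniform marker assignment.  Literal signs are likewise fair coins (the
  template leaves them open; a fixed sign would make annotators
  systematically monotone).  Feasibility under the core constraints is
  deliberately not guaranteed.

`run_benchmark()` measures the solver over a dimension grid (the reference
grid is 10–500 × 10–500 in steps of 10, i.e. 2,500 instances) with
per-instance time limits, recording statuses instead of raising, and is
checkpoint-resumable.  `cross_validate()` implements conservative k-fold
cross-validation: seeded shuffle, contiguous folds whose sizes differ by at
most one, no class stratification by default (matching the study design,
which explicitly ignored class balance; a stratified mode exists but is off),
full relaxation per fold, and — the conservative part — a fold whose solve
exhausts its time budget counts its entire held-out set as mispredicted, so
the generalization error is an upper bound.

### What the synthetic data do and do not show

The generators emulate the *shape* of binarized miRNA tables (0/1 matrices,
planted or free annotations, class imbalance under skewed annotators).  They
do not emulate correlation structure between miRNAs — real expression levels
are strongly correlated, whereas benchmark columns are independent — nor
discretization noise near the binarization threshold.  Passing benchmark and
cross-validation tests therefore demonstrates the solver's correctness,
completeness and conservative error accounting, not expected error rates on
real tumor data.

## Numerical and degenerate-input choices

* Empty classifiers and empty gates are rejected; a marker appearing both
  negated and non-negated in one gate (a tautological clause) is rejected.
* Canonical order: literals sorted by marker token, non-negated before
  negated; gates sorted lexicographically by their literal sequences.  Any
  fixed total order satisfies the canonicalization contract; this one is
  deterministic and human-readable.
* One-class datasets are handled: with no negatives any clause true on all
  positives is a solution; with no positives a never-true gate is sought.
* Missing values are rejected, not imputed; discretization method choice is
  deliberately the user's (only the fixed-threshold helper `binarize()` is
  provided).
* Circuit outputs are clamped to the smallest positive double so margin
  ratios stay defined in saturating limits.
* Timeouts are statuses, not errors: `TIMEOUT` when nothing is proven,
  `FEASIBLE` when an incumbent exists but completeness of enumeration is
  unproven.

## Problem sizes used by the shipped tests

The suite verifies solver exactness on 6-marker / 8-sample instances (where
the exhaustive oracle is tractable), planted-recovery on 100 instances of
50 × 50 at a 5 s per-instance budget, the cross-validation learning curve on
an 8-marker ladder of 10/30/100 samples with 7 seeds and 5 folds, and tiny
benchmark grids; the full 2,500-cell grid and larger sweeps are available
through `benchmark_config()` for dedicated runs.

## Known limitations

* Worst-case search cost is exponential — global optimality over CNF
  structures is inherently combinatorial.  Large, hard instances end in
  `TIMEOUT` rather than a heuristic answer, by design.
* The weighted-input objective (penalizing specific miRNAs) is supported via
  exhaustive enumeration and limited to small marker counts.
* Continuous scores depend on the output model's parameters; they are
  comparable between classifiers scored under the same configuration, not
  across configurations.
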