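---
title: "Inferring cancer progression with bounded mutation losses"
author: "dollosa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring cancer progression with bounded mutation losses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dollosa)
```

## The problem

Single-cell sequencing of a tumor yields, after variant calling, an
`n x m` ternary matrix `I`: for each of `n` cells and `m` somatic
mutations, the mutation was called present (1), absent (0), or could not be
called (`?`, low coverage).  The biology we want back is the order in
which the mutations accumulated — a rooted *mutation tree* whose nodes are
mutation acquisitions and whose structure encodes which clones descend from
which.

Two obstacles stand between the matrix and the tree.  First, the data are
noisy: allelic dropout makes a truly present mutation read as absent with a
probability `alpha[j]` that can be large (tens of percent) and, in
single-cell RNA data, very different from mutation to mutation, because it
tracks gene expression; false positives occur at a small global rate
`beta`; and entries are missing outright.  Second, real tumors violate the
classical infinite-sites assumption (ISA): copy-number deletions can remove
a mutated allele, so a mutation gained once can later disappear from a
lineage.  A method that insists on a perfect phylogeny has to explain every
deletion away as error.

## The model

`dollosa` fits a *Dollo-k* phylogeny with a global loss budget: every
mutation is gained exactly once, may be lost at most `k` times, and the
tree carries at most `d` loss events in total.  `k = 0` recovers the
perfect phylogeny, `k = 1` the persistent phylogeny.  Loss events are
explicit nodes: a loss of mutation `p` must be a strict descendant of the
node where `p` was gained.  The bounds reflect the biology — reported
losses per tumor are few — and keep the search space manageable; beyond
them the reconstruction problem is NP-hard anyway, which is why the
optimizer is stochastic.

The *genotype profile* `D(T, v)` of a tree node `v` is the 0/1 vector of
mutations gained but not lost on the root-to-`v` path.  A cell attached at
`v` is modeled as carrying exactly that genotype, observed through the
error channel

```
P(1 | 1) = 1 - alpha[j]   P(0 | 1) = alpha[j]
P(0 | 0) = 1 - beta       P(1 | 0) = beta
P(? | .) = 1
```

Given a tree, each cell is attached to the node maximizing its row
log-likelihood (`best_attachment()`; every node is a legal attachment
point, including the germline root and loss nodes).  The fitted tree and
attachment imply a corrected binary matrix `E` whose rows are the attached
profiles.

The objective maximized over trees is the total attachment log-likelihood
plus a loss-prior term controlled by per-mutation prior loss probabilities
`gamma[j]`.  Two forms are available (`loss_prior_mode`):

* `"penalty"` (default): each loss of mutation `j` adds `log(gamma[j])`.
  This is the standard per-event log-prior; it penalizes losses, and
  `gamma[j] = 0` makes mutation `j` unlosable (objective `-Inf` if a loss
  is used).
* `"as-printed"`: each loss adds `-log(1 - gamma[j])`, a non-negative
  term.  This is the formulation in the source literature for this model
  family, kept for literal fidelity; note it *rewards* every loss, so with
  it the `d` cap is the only thing preventing gratuitous deletions.  The
  same literature observes that losses should be rarer than gains, which is
  why the penalty form is the default.

## The search

The tree space is explored by simulated annealing over four neighbourhood
operations, each of which returns a valid Dollo-k tree:

* **SPR** — prune the subtree at `u`, reattach it as a new child of `v`.
  `v` may be any node outside the pruned subtree other than `u`'s current
  parent.  We deliberately allow `v` to be an ancestor of `u`: if SPR is
  restricted to incomparable pairs, a chain-shaped tree admits *no* SPR at
  all and becomes an absorbing state of the search (we measured absorption
  within ~50–100 SPR steps on 20-mutation walks), after which no move can
  change the topology and branched histories are unrecoverable.
  Reattachment anywhere outside the subtree is the standard SPR semantics
  and keeps the neighbourhood ergodic and reversible.
* **Add a deletion** — splice a loss node for mutation `v` above an
  existing node `u` below `v`'s gain, refused when it would exceed `k` or
  `d` or duplicate a loss of `v` on that path or below.
* **Remove a deletion** — delete a loss node, reparenting its children.
* **Swap labels** — exchange the mutations of two gain nodes; losses
  stranded above their relocated gain are removed, as are losses stranded
  by SPR.

A proposal is drawn uniformly over all valid operation *instances* pooled
across the four kinds (`propose_move(sampling = "instances")`).  The
alternative — a kind first, then an instance — is available
(`sampling = "kinds"`); we measured it to converge measurably worse at
equal budget, because SPR, the only operation that repairs topology, is
throttled to a quarter of proposals regardless of how much topology there
is to fix.

Acceptance is the Metropolis rule `min{exp(delta/T), 1}`; cooling is
geometric, `T_i = T0 (1 - cr)^i`, stopping below `Tmin`.  The defaults
`T0 = 1e4`, `cr = 1e-2`, `Tmin = 1e-3` give chains of exactly 1604
proposals per restart.  The search runs `restarts` independent chains from
random gain-only trees (losses enter only through moves, so any `k`, `d`
start valid) and returns the best tree *ever visited*, which dominates
returning the final state.  Cells are re-attached optimally after every
move; each proposal is scored by full recomputation, a deliberate
correctness-first choice at desk scale (~1 ms per proposal at 100 cells x
20 mutations).

### Choosing the schedule

`T0` should be commensurate with the objective changes a move causes.  The
default `1e4` matches cohort-scale inputs (hundreds of cells, ~100
mutations, objective magnitudes in the thousands).  On small instances
(tens of cells, a handful of mutations) move deltas are of order 1–10; at
`T0 = 1e4` the chain then spends over half its fixed-length schedule in an
accept-everything random walk and tends to freeze in the high-entropy
region of tree space.  On a noise-free 25-cell x 5-mutation instance we
measured every default-schedule restart converging to the same suboptimal
local optimum while plain hill climbing from random starts found the global
optimum; `T0 = 20` recovers the matrix exactly.  Rule of thumb: set `T0`
to roughly 10x a typical move delta, and add restarts rather than
stretching single chains — the package's own tests use `T0 = 100` with 50
restarts on 8x4 toys and the defaults on 100x20 experiments.

The default of 10 restarts (16040 proposals) is sized for 20–30 mutations.
The chains here are short compared to the millions of iterations this
family of tools is usually given; restarts are the lever that buys search
quality, and on 4-mutation instances the annealer then matches exhaustive
enumeration over all valid Dollo trees in 9 of 10 seeded runs.  The single
failure mode we observed is instructive: occasionally the global optimum
requires a loss node with *no* children (a terminal clone defined only by
its deletion), which no single move can create — add-deletion always
splices a loss above an existing node — so reaching it needs two moves
through a strictly worse intermediate.  That is a structural property of
the neighbourhood, not of this implementation.

## What the simulator emulates — and what it does not

`simulate_scs_data()` generates the ground truth the recovery experiments
are scored against:

* a random gain tree (uniform attachment of each gain to a previously
  placed node), with losses planted per mutation with probability
  `gamma[j]` (or an exact count `n_losses`), each at a uniform valid site
  under the `k`/`d` bounds;
* cells attached uniformly at random over all nodes; true rows are the
  attached profiles;
* mutation-specific dropout rates drawn from `Beta(0.3, 0.3)` — both
  shapes below 1 gives the strongly bimodal rate profile seen in real
  single-cell RNA cohorts (spikes near 0.1 and 0.9), which is the regime
  where a mutation-specific error model earns its keep;
* loss priors drawn from `Triangular(0, 0.05, 0.1)`, the conventional
  distribution when only bounds and a mode are defensible;
* per-entry noise applied missing-first (probability `missing_rate`), then
  dropout flips `1 -> 0` at `alpha[j]` and false positives `0 -> 1` at
  `fp_rate`.  The order is fixed and regression-tested: flipping before
  masking would change the marginal flip rates among observed entries, and
  the flip log (used by the parsimony metric) only records flips that
  remain observable.

Defaults (100 cells, 20 mutations, `k = 1`, `d = 3`, false-positive rate
`1e-5`, 1% missing) describe a modest targeted single-cell experiment.
Deliberately *not* emulated: doublet captures (assumed removed upstream),
read-count/coverage information, per-cell error rates, and recurrent
gains.  Passing recovery tests on these simulations therefore shows the
estimator works when its error model is correct; it does not certify
robustness to doublets or to misspecified rates.

## Evaluation metrics

Tree accuracy is scored on gain nodes only — loss placement can be
non-identifiable (two losses on sibling branches can be exchanged without
changing the fit), so including losses would punish equivalent solutions:

* **Ancestor–descendant accuracy** — fraction of ordered gain pairs
  ancestral in the true tree that stay ancestral in the inferred tree;
* **Different-lineage accuracy** — fraction of unordered gain pairs on
  parallel branches that stay parallel;
* pairs attached to the same node do not arise (gains are unique), and
  vacuously empty pair sets score 1;
* **flip parsimony** — |flips used by the fit − flips planted by the
  simulator|;
* **dropout-rate recovery** — absolute error of the mean rate, and the
  per-mutation MSE.  The estimator `estimate_fn_rates()` is the natural
  ratio #(observed 0, corrected 1) / #(corrected 1, observed), defined as
  0 for mutations with no observed carrier; it is our choice, made once —
  the measure is standard but no closed-form estimator is prescribed for
  this model family.
* **three-gamete conflicts** (`count_conflicts()`) — unordered mutation
  pairs exhibiting the (1,0), (0,1) and (1,1) gametes, i.e. certificates
  of ISA violation; missing entries are compatible with anything
  (conservative, standard incomplete-phylogeny practice).

## Numerical and degenerate-input choices

* Attachment ties break to the smallest node id — exact reproducibility.
* `entry_log_likelihood()` returns true `-Inf` for zero-probability
  observations; the vectorized kernel substitutes `-1e12` so that matrix
  products stay NaN-free, and a cell whose best attachment is below
  `-1e11` raises an error naming the cell (only reachable with zero error
  rates and contradictory data).
* `gamma[j] = 0` plus a loss of `j` gives objective `-Inf` in penalty
  mode: such trees are proposed but never accepted.
* Display post-processing (`collapse_simple_paths()`,
  `collapse_low_support()`) never touches the fitted tree: it merges
  *display* nodes only.  Node support is
  `sum(cells in subtree(i)) / (sum(cells in subtree(parent)) - cells(parent))`;
  an empty denominator defines support 1 so uninformative structure is
  never deleted; low-support merges proceed deepest-first with supports
  recomputed after every merge, which makes the operation deterministic
  and idempotent at the threshold.
* The root is an unlabeled germline node above all gains, so a fully
  wild-type cell has a legal attachment point.

## Known limitations

* The annealing chains are short by construction; very large inputs need
  many restarts or a custom schedule via `anneal_control()`.
* Optima requiring childless loss nodes are reachable only through
  two-move paths (see above) and may be missed.
* The likelihood treats all cells as singlets; doublets must be filtered
  upstream.
* Loss placement within the correct branch is frequently non-identifiable;
  downstream interpretation should lean on the gain structure and on the
  support-collapsed display.

## A worked run

```{r, eval = FALSE}
sim <- simulate_scs_data(n = 100, m = 20, k = 1, d = 3, alpha = 0.1,
                         fp_rate = 1e-5, missing_rate = 0.01,
                         n_losses = 1, seed = 1)
fit <- dollo_fit(sim$observed, beta = 1e-5, alpha = 0.1, gamma = 0.05,
                 k = 1, d = 3, seed = 1)
summary(fit)
ancestor_descendant_accuracy(sim$tree, fit$tree)
different_lineage_accuracy(sim$tree, fit$tree)
plot(fit, collapse_simple = TRUE)
```

The package's acceptance tests run exactly this experiment over ten seeds
(mean accuracies above 0.9 on both measures), the exhaustive-enumeration
comparison on 4-mutation instances, and the estimator consistency checks
described above; problem sizes (8x4 toys, 25x5 noise-free, 100x20
recovery, 500-cell rate estimation) were chosen as the smallest instances
that still exercise each claim.
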