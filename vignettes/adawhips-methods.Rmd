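---
title: "Explaining multi-class AdaBoost with adaptive-weighted path snippets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Explaining multi-class AdaBoost with adaptive-weighted path snippets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adawhips)
```

## The problem

A boosted ensemble of shallow decision trees reaches a classification by a
weighted vote over hundreds of base trees. In decision-support settings —
computer-aided diagnostics above all — the person acting on a single
prediction needs to know *which conditions on this patient's measurements
drove this classification*, stated as a short logical rule, together with
how confident the rule is and what would weaken it. `adawhips` produces
such a per-instance rule by decomposing the trained model itself, so the
rule's asserted class always equals the model's prediction (fidelity is
perfect by construction, not an approximation target).

## The model being explained

The package trains and explains two multi-class AdaBoost variants over
binary, entropy-split trees of bounded depth (default `maxdepth = 4`,
matching the shallow-tree regime these ensembles are normally run in):

* **SAMME** — tree `m` casts a one-hot vote; its weight is
  `α(m) = log((1 − err)/err) + log(K − 1)`, where `err` is the weighted
  error at round `m` and `K` the number of classes. Rounds with `err = 0`
  clip the error to 1e-10 (keeping `α` finite) and stop boosting; rounds
  with `err > 1 − 1/K` are discarded and stop boosting. Instance weights
  are multiplied by `exp(α)` on misclassification and renormalised.
* **SAMME.R** — trees carry no stored weight. Each leaf keeps the weighted
  class distribution of the training instances that reached it, and
  run-time confidence weights are the centred scaled log-posteriors
  `α_k|x = (K − 1)(log p_k − mean_j log p_j)`; these always sum to zero
  over classes. Leaf probabilities are floored at 1e-12 before the
  logarithm so the weights stay finite. Re-weighting uses the standard
  `±1/(K − 1)` label coding.

Tree induction searches all features exhaustively for the split minimising
weighted entropy; thresholds are midpoints between consecutive distinct
sorted values, and `x_j ≤ ν` goes left. Two induction choices matter:

* **Zero-gain splits are allowed on impure nodes.** A strict
  positive-gain requirement would make patterns whose structure only
  appears two levels down (XOR-style interactions) unlearnable; pure nodes
  and nodes whose rows are identical on every feature still become leaves.
* **Argmax ties break to the lowest class index**, everywhere, so
  training, prediction and path analysis are fully deterministic: the same
  data, parameters and seed give a bit-identical serialised model.

## From vote to rule

**Decision paths.** For the explanandum `x`, each tree contributes the
ordered triples `(j, ν, τ)` of the decisions on `x`'s root-to-leaf path,
where `τ` records the truth of `x_j ≤ ν`. Branches `x` never visits are
irrelevant, which is what makes the search space tractable.

**Majority trees.** Only trees whose individual output for `x` agrees with
the ensemble prediction (set `T+`) are analysed. For SAMME the agreeing
weight `a+` always exceeds the disagreeing weight averaged over the
`K − 1` losing classes, `a− = (1/(K − 1)) Σ_{T−} α` — the averaged
reading is the only one under which that dominance is guaranteed — and
`margin = (a+ − a−)/Σα ∈ (0, 1]`. `T+` is sufficient: re-predicting from
`T+` plus any subset of `T−` returns the same class. For SAMME.R, `T+`
membership uses the argmax of the per-instance confidence vector; since no
margin formalisation exists for SAMME.R, `margin` is reported as `NA`.

**Path weight for SAMME.R.** In place of the missing `α`, each retained
path is weighted by the relative entropy (KL divergence) between its leaf
posterior and the training prior — larger for trees whose leaf separates
the classes more sharply than the prior. The divergence is the standard
non-negative `Σ P log(P/P′)` (both distributions floored at 1e-12 and
renormalised first so one-hot posteriors stay finite).

**Weight redistribution.** A path's weight is divided over its nodes by
sequential relative entropy: node `i` scores
`D_KL(P_i ‖ P_{i−1})` where `P_i` is the ground-truth training class
distribution of the rows satisfying the first `i` decisions, and `P_0` is
the prior. Scoring against model predictions instead of ground truth is
available as a switch (`use_model_labels`), default off. Three degenerate
cases are fixed by convention: an empty surviving subset scores that node
and all deeper nodes 0; an all-zero score vector distributes the path
weight uniformly over the path; root-leaf paths (no decisions) contribute
no snippets and their weight is excluded from the conservation total.
Scores are rescaled to sum to the path weight, then pooled across paths by
exact `(j, ν, τ)` identity — thresholds from different trees rarely
coincide, so no tolerance merge is attempted. The top 20% of snippets by
weight (by count, `ceiling(0.2 n)`, since a mass-based reading is equally
defensible but less predictable in size) are kept and sorted by weight
with deterministic tie-breaks (feature, then threshold, then truth).

**Greedy merge and stability.** Precision is trivially maximised by
"tautological" rules that pin down single instances, so the merge
optimises *stability*

\[ \zeta = \frac{|\{z \in Z : g(z) = g(x)\}|}{|Z| + K}, \]

precision shrunk by the class count: a rule covering one matching instance
scores only `1/(1 + K)`, and `ζ = precision · |Z|/(|Z| + K)` exactly, so
`ζ` approaches precision as coverage grows. The first sorted snippet is
always added; later snippets are added only if `ζ` *strictly* increases
(a plateau acceptance could cycle on equal-value terms); terms on the same
feature intersect into at most a lower and an upper bound; the pass stops
at a threshold `ζ` (default 0.95) or when the list is exhausted. The
objective is evaluated on the training data against model predictions —
`g(z) = g(x)`, not ground truth — because the rule explains the model, not
the world.

**Counterfactual contrast and pruning.** Each rule inequality is reversed
one at a time (`≤ ↔ >` at the same threshold; a two-sided interval yields
two reversals), and the precision of the reversed rule is reported as a
signed percentage-point delta. Reversals whose precision drop is within a
user tolerance (default 0.05) flag non-counterfactual, redundant terms;
pruning removes the weakest such term, re-evaluates, and repeats to a
fixpoint (a single-removal mode exists behind a flag). The rule is never
emptied, and removing conjuncts can only grow coverage. An empty reversed
region has counterfactual precision 0 by convention — which reads as a
maximal drop, so terms whose reversal covers nothing are never pruned;
only terms that demonstrably fail to move precision are.

## Evaluation protocol

Explanations are scored leave-one-out on a held-out set: the rule for test
unit `x` is generated from training data only, then coverage and precision
are measured on the test set *minus* `x` (no leakage into its own score),
and **held-out stability** on the test set with `x` included:
`(n + 1)/(m + K)` with `m` the covered count including `x` and `n` the
covered-and-correct count excluding it. That convention is the one under
which a held-out set containing only the explanandum gives exactly
`1/(1 + K)` — both floor and ceiling — removing the 0-or-1 precision
discontinuity that otherwise rewards over-fitting rules. A rule covering
nothing beyond its own explanandum has precision 0.0 and is flagged as
over-fitting. The unit cap defaults to 1,000; the split helper defaults to
70/30 without stratification, seed-controlled.

The significance battery implements the statistics directly — Cohen's κ
from the confusion matrix, the modified Friedman F
(`F_F = (N−1)χ²_F / (N(k−1) − χ²_F)` with
`χ²_F = 12N/(k(k+1)) [Σ R_j² − k(k+1)²/4]`, `df1 = k−1`,
`df2 = (k−1)(N−1)`), and the post-hoc
`z = (R_i − R_j)/\sqrt{k(k+1)/(6N)}` with the two-tailed Bonferroni
critical value `0.025/3` for three comparisons — while reference
distributions and the paired Wilcoxon signed-rank test come from R's
`stats` (with the convention that identical samples give `p = 1`).
Degenerate inputs error loudly: all-diagonal-mass κ and
perfectly-consistent rank matrices (where the F denominator vanishes) are
refused rather than patched.

## Synthetic data: what it does and does not show

All tests run on three generators, pure functions of their parameters and
a seed:

* `gaussian_mixture()` — one Gaussian component per class; the default
  two-class, 2-D setting (means (0,0) and (2,2), identity covariance)
  produces the overlapping clouds on which a boosted model grows a complex
  decision boundary worth explaining. The defaults are illustrative; any
  means/covariances/proportions can be supplied.
* `planted_rule_dataset()` — uniform features with labels set by a known
  conjunction (default `x1 ≤ 0.6 ∧ x2 > 0.4` in five features) and flipped
  with probability 0.05, a noise level at which the signal clearly
  dominates but the model's boundary is measurably perturbed. Because the
  generating rule is known, threshold recovery, counterfactual drops and
  over-fit rates can be checked against ground truth.
* `mixed_tabular_fixture()` — continuous measurements plus 0–4 ordinal
  answer codes with class-dependent shifts and mild imbalance, emulating
  the *structure* of clinical questionnaire tables.

What passing on these generators does **not** show: real clinical tables
have correlated features, nonuniform marginals and systematically missing
values; the generators share none of those traits, so quality measured
here bounds behaviour only on comparably clean data. Emulating a real
data set's joint distribution is out of scope on principle — sampling
from marginals is exactly the practice this method avoids by mining the
model instead.

## Problem sizes and the threshold-recovery check

The test suite exercises the full pipeline at the scale the method is
meant for — 200 trees of depth 4 on 2,000 rows — for the fidelity,
weight-conservation and planted-recovery checks, and smaller ensembles
(25–60 trees, 500–800 rows) where per-operation contracts are under test;
oracle comparisons (KL divergence, Friedman) run on 10,000 and 200 random
cases respectively. These sizes were chosen so the whole suite exercises
every claim at full method scale in about two minutes.

One check deserves its design stated plainly. On planted-rule data the
model memorises the 5% label noise (training accuracy 1.0), so the ideal
planted rule's stability against the model (≈0.93) sits *below* the 0.95
merge threshold, and for explananda deep inside the region the greedy pass
keeps tightening bounds — that is the algorithm working as specified, not
a defect. Threshold recovery is therefore asserted for the in-region
instance nearest the planted corner: its own coordinates pin the feasible
thresholds to a narrow window, making it the best-posed probe of whether
the recovered boundary sits within one split-grid step (the gap between
the sorted feature values bracketing the planted threshold) of the truth.
Recovery for arbitrary interior instances is looser by the mechanism
above, typically within a few hundredths in feature units.

## Known limitations

* Nominal features must be integer-encoded upstream (`read_dataset()`
  does this with stable sorted-category codes); rules then threshold the
  codes, which is meaningful for ordinal answers but arbitrary for truly
  unordered categories with more than a handful of levels.
* The stability threshold interacts with label noise as described above:
  when the model's own consistency caps achievable precision below the
  threshold, rules come out tighter than the generating process.
* Only single-rule explanations are produced — no rule lists, no
  multi-term simultaneous counterfactuals; each contrast item reverses
  exactly one inequality.
* Margin is defined for SAMME only; SAMME.R explanations report `NA`
  there while every other stage proceeds identically through the KL
  substitute weights.
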