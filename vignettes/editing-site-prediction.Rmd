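---
title: "Predicting A-to-I editing sites: mRMR ranking, incremental feature selection and random forests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting A-to-I editing sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editRF)
```

## The problem

A-to-I RNA editing — deamination of adenosine to inosine by ADAR enzymes
acting on double-stranded RNA — is read as an A-to-G change by sequencing.
Candidate editing sites called from RNA-seq are heavily contaminated by
DNA polymorphisms, alignment artifacts and sequencing error. When each
candidate site is summarized by a vector of alignment-derived features
(read depths, per-base composition ratios in plain and reduced-alphabet
"3AG"/"3TC" alignments, repeat-region membership, wild-type versus
ADAR-null contrasts), separating true sites from artifacts becomes binary
classification on a samples-by-features table: class 1 for validated
editing sites, class 0 for non-editing sites.

Most of those features are redundant with one another, and a compact
subset classifies as well as — or better than — the full table. The
package therefore combines three stages:

1. **mRMR ranking** orders all features by a trade-off between relevance
   to the label and redundancy with features already chosen;
2. **incremental feature selection (IFS)** cross-validates the classifier
   on every nested top-k set and picks the k with the best Matthews
   correlation coefficient (MCC);
3. a **random forest** trained on the full data restricted to the optimal
   set is the final predictor.

## Information-theoretic primitives

Relevance and redundancy are plug-in mutual information (MI), in bits,
between discretized variables. Continuous features are reduced to three
states around their mean:

$$s_i = \begin{cases} +1 & x_i > \bar{x} + t\,\sigma \\
                      -1 & x_i < \bar{x} - t\,\sigma \\
                      \phantom{+}0 & \text{otherwise,} \end{cases}$$

with $\sigma$ the *population* (1/n) standard deviation and $t = 1$ by
default. Three-state mean-plus/minus-sigma coding is the convention of the
classical mRMR tooling; the population form of $\sigma$ is fixed and
documented so that rankings are exactly reproducible (the two conventions
shift the cut points by a factor $\sqrt{n/(n-1)}$, which rarely changes a
state). A constant feature maps to all zeros and carries zero MI with
everything. Columns that are already discrete — at most 3 distinct values,
such as a 0/1 repeat-region flag — bypass thresholding and keep their own
alphabet (`passthrough_levels` controls the cutoff).

MI is estimated by the plug-in formula on the empirical joint
distribution, base 2, with $0 \log 0 = 0$. The estimate is non-negative,
symmetric, bounded by either marginal entropy, and equals the entropy on
identical arguments; the test suite checks all of these against an
independent contingency-table enumeration at $10^{-12}$.

## The mRMR ranking rule

Let $I(f; y)$ be a feature's MI with the labels and $S$ the set already
selected. Step 1 picks $\arg\max_f I(f;y)$. Step $k>1$ scores each
remaining feature by

* **MID** (difference, the default):
  $I(f;y) - \frac{1}{|S|}\sum_{s \in S} I(f;s)$
* **MIQ** (quotient):
  $I(f;y) \,/\, \max\!\big(\frac{1}{|S|}\sum_{s \in S} I(f;s),\;
  \varepsilon\big)$, $\varepsilon = 10^{-12}$

and ties break toward the lower original column index, so the full
ordering is deterministic. MID is the default because it is the baseline
"difference" criterion of the mRMR family; the criterion actually used in
the original study is not recorded, so the scheme is always reported
alongside results and MIQ is one flag away. Because the published
discretization and scheme are unknown, reproducing the published feature
ordering exactly is not guaranteed — agreement is expected at the level of
CV metrics, not of individual ranks.

## Cross-validation and metrics

Performance is summarized by sensitivity, specificity, accuracy and MCC
computed from a pooled confusion matrix. Stratified 10-fold CV shuffles
each class separately under the given seed and deals members round-robin
across folds, carrying the dealing offset from one class to the next; at
127 + 127 samples this yields fold sizes of 25–26 with per-fold class
counts within one of balance. All folds' held-out predictions are pooled
into one confusion matrix before the metrics are computed (micro-averaged
CV): with ~25-sample folds a per-fold MCC is too unstable to average
meaningfully, and pooling yields the single metric row per feature set
that an IFS sweep needs. Fold-averaged mode (`pooled = FALSE`) and
non-stratified folds are available for comparison.

Conventions for degenerate counts: a zero factor in the MCC denominator
gives MCC = 0; sensitivity (specificity) is `NaN` when no positives
(negatives) were evaluated, and such values are excluded from
aggregation.

## The classifier

The forest defaults mirror the classical Weka 3.6.4 RandomForest
configuration long used for this kind of table: 10 unpruned trees,
bootstrap row sampling, and $\lfloor \log_2 M \rfloor + 1$ candidate
features per split for an $M$-feature set. The ensemble behind the
contract is CRAN's `randomForest`; the package pins the seed around each
fit (restoring the caller's RNG state), stores the training feature list
for name-based alignment at prediction time, and resolves exact vote ties
to the negative class so that even-sized ensembles remain deterministic.
Ten trees are kept as the default for fidelity to that historical
configuration; `rf_config(n_trees = 100)` gives visibly smoother IFS
curves and is recommended when fidelity is not the point. Exact
tree-induction details differ across ecosystems, so metric-level — not
prediction-level — agreement with the original software is the realistic
target.

## The IFS sweep

`ifs_curve()` evaluates every top-k set, k = 1..N, under the *same* fold
assignment (same CV seed) so consecutive curve points differ only in the
feature set; this paired design removes fold-assignment noise from the
curve shape (per-k independent folds are available via
`paired_folds = FALSE`). The optimal k is the smallest k attaining the
maximum MCC — parsimony is the tie-break. The final model is then trained
once on the full dataset restricted to the top-k features; evaluating it
on an independent table gives the held-out row of the performance report.

A practical caveat observed with the synthetic generator: when the
planted signal is strong, the CV-MCC curve reaches its ceiling within the
first few features and stays flat as noise features are added (forests
are robust to irrelevant predictors). On such a plateau the argmax is
decided by sampling noise and the "optimal" k is not sharply identified —
only ties at the exact maximum collapse to the smallest k. Real feature
tables with weaker, partially redundant signals produce more peaked
curves.

## The synthetic generator

`generate_dataset()` plants known structure so every stage is testable
without external data: informative features are Normal(0, 1) in class 0
and Normal($\delta$, 1) in class 1; redundant features are copies of
informative ones plus Normal(0, `redundant_noise_sd`) perturbation; noise
features are Normal(0, 1) in both classes. Defaults (127 per class, 3
informative + 2 redundant + 72 noise, $\delta = 2$,
`redundant_noise_sd` = 0.1) mimic the 254-sample, 77-feature scale of a
balanced editing-site training table, with an effect size large enough
that the planted signal is unambiguous and a copy-noise small enough that
redundant features are near-duplicates. The generator emulates marginal
class shifts and pairwise redundancy only: real editing-site features are
bounded ratios and counts with skewed, correlated distributions, so
passing tests demonstrate that the machinery ranks, selects and validates
correctly — not that any particular biological table will yield a
particular accuracy.

Two statistical facts about this design are worth noting when reading
test output. A redundant near-copy is statistically exchangeable with its
source, so it can legitimately win rank 1 (pure relevance decides the
first pick); the redundancy penalty only guarantees that the *second*
member of the duplicate pair is demoted below some independent signal.
And under the null ($\delta = 0$) the pooled-CV MCC at n = 254 has a
standard deviation of about $1/\sqrt{254} \approx 0.06$ per seed, so
calibration is asserted on the across-seed mean, not on every individual
draw.

## Worked example

```{r example, eval = FALSE}
library(editRF)

train <- generate_dataset(synthetic_spec(seed = 1))
test  <- generate_dataset(synthetic_spec(seed = 1001))

res <- run_pipeline(train, test,
                    rf = rf_config(seed = 1), cv = cv_config(seed = 1),
                    out_dir = "editRF_out")
res$optimal_k
print(res$training_metrics)
print(res$testing_metrics)
```

With these seeds the sweep covers all 77 features in a few seconds on one
CPU; `editRF_out/` then contains the ranking TSV, the 77-row IFS curve
TSV, the selected-feature list, a two-row performance report (metrics at
3 decimals) and the serialized model. Identical configuration and seeds
reproduce all TSV outputs byte for byte.

## Problem sizes and numerical choices

The shipped tests run the full pipeline at up to 254 samples x 77
features and sweep stochastic properties over 20 generator seeds;
property checks against brute-force oracles use 10–16-sample tables where
exhaustive enumeration is exact. Small-table brute-force comparisons
accept a pick whose step score is within $10^{-9}$ of the maximum:
mathematically tied candidates can differ in the last float ulp between
two summation orders, and which of an exactly tied pair is chosen is a
tie-break convention, not a correctness question.

## Limitations

* The upstream feature extraction (alignments, reduced-alphabet
  recoding, wild-type/ADAR-null contrasts) is out of scope; the package
  starts from the feature table.
* Plug-in MI on three states is biased upward for small n; that bias is
  shared across features and mostly cancels in the ranking, but the
  relevance values themselves should not be read as unbiased dependence
  estimates.
* Greedy mRMR does not globally optimize the relevance/redundancy
  objective, and no variants beyond MID/MIQ are provided.
* No probability calibration, AUROC, or feature-importance analysis:
  importance claims rest on the mRMR/IFS selection, not on forest
  impurity measures.
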