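---
title: "Dual-screening QSAR: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-screening QSAR: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsarstack)
```

# The problem

Candidate compounds for estrogen-receptor-alpha (ERα) targeted breast-cancer
therapy come annotated with hundreds of precomputed molecular descriptors —
numeric summaries of structure and physicochemistry — together with a
measured bioactivity (pIC50, the negative log10 of the half-maximal
inhibitory concentration) and binary ADMET endpoints (absorption,
distribution, metabolism, excretion, toxicity; e.g. CYP3A4 metabolism, hERG
cardiotoxicity, micronucleus genotoxicity). Descriptor tables of this kind
are wide (hundreds of columns), dirty (large blocks of exact zeros where a
descriptor is undefined for most compounds, and sporadic extreme values),
and heterogeneous in units. `qsarstack` implements a complete workflow over
such tables:

1. **Cleaning** — eliminate near-null columns, winsorize at box-plot
   fences, iterate, min-max scale.
2. **Dual screening** — rank descriptors by a weighted combination of grey
   relational degree and Spearman rank correlation against pIC50 and keep
   the top 20.
3. **Regression** — a stacked ensemble (random forest + gradient-boosted
   trees, ordinary-least-squares meta learner on out-of-fold predictions)
   predicting pIC50 from the screened descriptors.
4. **Classification** — per ADMET endpoint, two feature-selection routes
   (tree-model importance; univariate FDR/FPR filtering) feeding a
   three-member hard-majority voting classifier.

Because the dataset the workflow was developed around is not publicly
deposited, the package ships a synthetic generator that reproduces its
statistical structure, and every claim the test suite makes is a property
of the method, not a reproduction of any published table.

# Cleaning

A *null* cell is a missing value or an exact zero. Columns whose null
fraction reaches 95% (the comparison is `>=`) are eliminated: a descriptor
that is zero for nearly every compound carries almost no information, and
its sample quantiles degenerate. The Kolmogorov–Smirnov scan then tests
each retained column against a normal law with column-estimated mean and
standard deviation. The scan is advisory only: on real descriptor tables
essentially every column rejects normality, which is precisely why outliers
are handled by distribution-free box-plot fences rather than a z-score
rule. (Because the null parameters are estimated from the same data, the
nominal p-values are approximate in the Lilliefors sense; since no data
decision rests on the exact p-value, this is accepted.)

Winsorization clips each column to
`[Q1 - k*IQR, Q3 + k*IQR]` with quartiles computed by the
linear-interpolation convention (R's default, `type = 7`) — the fence
values depend on this convention, so it is fixed and stated. The fence
multiplier `k` defaults to 1.5, Tukey's standard fences, and is exposed as
an argument (`fence_multiplier`) rather than hard-coded, because practice
varies between 1.0 and 1.5 and the choice is a policy, not a theorem.

Cleaning **iterates**: clipping a column whose quartiles sit at zero
collapses it to all zeros, and the next null scan removes it (reason
`post_winsor_null`). The loop runs drop → winsorize until a pass removes
nothing; it is idempotent, and the pIC50 target and endpoint labels are
exempt from every step. Any missing cells that survive are imputed to the
column median after the loop. Min–max scaling to [0, 1] finishes the
stage; the per-column (min, max) parameters are returned so that new data
can be mapped through the training-time transform, constant columns map to
0 and are flagged, and the inverse map recovers the clipped table to
numerical precision.

# The dual screen

For a reference sequence $x_0$ (pIC50) and comparison sequences $x_i$
(descriptor columns), the grey relational coefficient at each observation
$k$ is

$$\beta_{0i}(k) = \frac{\Delta_{\min} + \rho\,\Delta_{\max}}
                       {\Delta_{0i}(k) + \rho\,\Delta_{\max}},$$

where $\Delta_{0i}(k) = |x_0(k) - x_i(k)|$ and $\Delta_{\min}$,
$\Delta_{\max}$ are the global (two-level) minimum and maximum of
$\Delta$ over all columns and observations. The relational degree of
column $i$ is the mean $c_i = \frac1N \sum_k \beta_{0i}(k)$. The
resolution coefficient $\rho \in (0, 1]$ damps the influence of
$\Delta_{\max}$; the conventional 0.5 is the default and it is exposed as
an argument.

Two design points deserve emphasis:

* **Pre-scaling.** Grey relational analysis on raw heterogeneous-unit
  columns is dominated by whichever column has the largest magnitudes, so
  the reference and every column are min-max scaled to [0, 1] before
  differencing (standard grey-relational practice). `prescale = "none"`
  disables this for callers who have already scaled.
* **GRA measures similarity, not association strength.** A descriptor
  *negatively* associated with the target has uniformly large deltas and
  therefore a *low* degree — taking absolute values afterwards cannot
  recover it, because degrees are always positive. The screen is
  consequently oriented toward positively associated descriptors, which
  matches the descriptor sets such screens report in practice; the
  Spearman half (0.4 weight) is the component that sees negative monotone
  association.

Spearman correlation uses the closed form
$1 - 6\sum d_i^2 / (n(n^2-1))$ on tie-free data and the Pearson
correlation of average ranks when ties are present; the two branches agree
on tie-free data and the tie branch is the general definition. A constant
sequence has no rank ordering; its correlation is reported as 0 with a
degenerate flag rather than as an error, so that constant-after-cleaning
columns simply sort to the bottom.

The combined score takes absolute values of both statistics, min–max
normalizes each across descriptors, and combines them as
$Z = 0.6\,\bar{X} + 0.4\,\bar{Y}$. The weights reflect that the grey
degree tracks the sought association more stably on this kind of data;
they are exposed but sum-to-one constrained. The top-20 cut includes all
descriptors tied with the 20th score (identical columns produce exactly
equal scores, and splitting such a tie arbitrarily would make the
selection depend on column order).

# Stacked regression

The regressor stacks a random forest and gradient-boosted trees under an
ordinary-least-squares meta learner. Each base learner's hyperparameters
are chosen by K-fold (K = 5) cross-validated MSE over a deliberately small
grid (trees ∈ {100, 300}; boosting depth 3 with learning rate ∈ {0.05,
0.1} and rounds ∈ {100, 300}): the grids are a knob, and small defaults
keep the stage fast and honest — grid search here tunes, it does not
rescue a mis-specified model. The meta design matrix contains only
out-of-fold base predictions, so the meta fit never sees a prediction made
by a model trained on the same row; the no-leakage property is verified by
a permutation test (held-out R² collapses to ≈ 0 when labels are
shuffled). Bagging and extremely randomized trees are available as
alternative base learners. The meta learner is plain least squares over
the two base prediction columns: with two highly correlated, approximately
unbiased base predictors, anything richer adds variance without benefit.

# ADMET voting classifiers

Each endpoint gets three members — extremely randomized trees, a random
forest, and logistic regression — each bound to its own feature subset:
the tree members use model-importance selections (default sizes 80 and 40,
ranked by impurity/gain importance from an extra-trees and a
gradient-boosted classifier respectively), and the logistic member uses
the univariate error-rate selection. The univariate score is a two-sample
ANOVA F-test (features are continuous, labels binary; a chi-square score
would require nonnegative features). `fpr` mode keeps raw p < α; `fdr`
mode keeps Benjamini–Hochberg-adjusted p < α, so the FDR set is always a
subset of the FPR set at equal α, and on pure noise FPR selects ≈ 5% of
features while FDR selects none (both properties are tested). The final
prediction is a hard majority vote — the member count is odd by
construction so no tie-break rule is needed — and the ROC score is the
mean of member positive-class probabilities. Class imbalance is handled
only through the shared train/test split; no resampling is applied.

When the FDR route selects nothing for an endpoint (possible at small n or
weak signal), the pipeline falls back to the FPR route for that endpoint
and logs it, rather than fitting a member on an empty design.

# The synthetic generator

`generate_dataset()` emulates the structure the pipeline assumes, at the
default scale of 1974 compounds × 729 descriptors:

* **Planted signal.** 20 informative descriptors drive pIC50; half enter
  linearly, half through a monotone signed-square, so rank-based screening
  must work where Pearson-style linearity is broken. Effect magnitudes are
  uniform in [0.8, 1.5] on the standardized scale and oriented
  positively — see the GRA similarity note above. With 20 such effects the
  signal standard deviation is ≈ 4.5 against Gaussian noise with sd 0.5
  (the `noise_sd` default), i.e. a strong-signal regime.
* **Heterogeneous ranges.** Columns are shifted and scaled to arbitrary
  ranges (shift ∈ [−10, 50], scale ∈ [0.5, 20]), so the pipeline's own
  normalization is exercised rather than assumed.
* **Correlated nuisance.** Non-informative columns come in blocks of 5
  with within-block correlation ≈ 0.3, so selection cannot succeed by
  treating descriptors as independent.
* **Near-null columns.** A planted 10% of columns carry ≥ 95% exact zeros
  (a thin exponential tail fills the rest), reproducing the
  undefined-descriptor pathology the cleaning stage exists for.
* **Outliers.** Each live cell is replaced with probability 0.005 by
  `median ± 10 × IQR`, *after* pIC50 is computed — corruption of the
  measurements, not of the generative signal, which is exactly what
  winsorization is meant to repair.
* **Endpoints.** Each binary endpoint is Bernoulli(logistic(linear score))
  over 5 features with coefficients of magnitude 1.5–2.5 and random sign;
  prevalence varies with a random intercept in [−1, 1].

What the generator does **not** emulate: real descriptor marginals
(PaDEL/RDKit descriptors are often integer-valued, bounded, or
zero-inflated in structured ways), inter-descriptor correlation born of
shared substructure counts, assay noise heteroscedasticity, and any
chemical meaning. Passing tests therefore demonstrate that the pipeline's
statistical machinery behaves as designed under its stated assumptions —
not that any particular accuracy will be attained on a particular real
dataset.

# Numerical choices and degenerate inputs

* Quantiles: linear interpolation (`type = 7`) everywhere.
* Constant columns: pass winsorization unchanged; scale to 0 with a flag;
  Spearman degenerate-0; F-test p = 1 (never selected).
* Normalization of screening scores with zero spread maps all descriptors
  to 1 (they are indistinguishable, and the other score decides).
* Undefined precision (no predicted positives): flagged, F1 reported 0.
* ROC with tied scores: ties grouped at one threshold; AUC by trapezoid,
  which then equals the pairwise-comparison (Mann–Whitney) statistic
  exactly.
* Cohen's kappa with both marginals degenerate (chance agreement 1):
  defined 1 on perfect agreement, else 0 with a flag.
* Determinism: every stochastic step (generator, folds, forests, boosting)
  derives from an explicit integer seed; `ranger` and `xgboost` run
  single-threaded so results do not depend on scheduling.

# Problem sizes in the test suite

Unit tests run at small n (tens to hundreds of rows) with expected values
frozen from independent oracles — direct loop evaluation for the grey
degree, rank-Pearson for Spearman, pairwise comparison for AUC, hand
arithmetic for the metric formulas. The end-to-end property checks run the
full default scale (1974 × 729) for screening recovery over 10 simulated
datasets, and a 500–2000-row scale for the regression and classification
properties; these sizes give stable medians while keeping a full suite run
around a minute.

# Known limitations

* The grey half of the screen cannot detect negatively associated
  descriptors (inherent to GRA; discussed above). If such descriptors
  matter, raise the Spearman weight.
* Grid defaults are small; for serious use pass richer grids through
  `stacking_spec()`.
* The voting ensemble's advantage over its best member is only guaranteed
  when members are comparably strong; with one dominant member a hard
  majority can sit slightly below it.
* Five metrics and AUC are computed per endpoint, but endpoints are
  modeled independently — no multi-label structure is used.
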