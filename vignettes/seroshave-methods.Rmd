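---
title: "Methods: resampling-based autoantibody panel selection"
author: "seroshave authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resampling-based autoantibody panel selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Serum IgG autoantibodies against self proteins can discriminate disease
cases from controls. Protein microarrays (ProtoArray-style, ~9,480 human
proteins printed in duplicate spots) measure thousands of such
reactivities per serum sample at once. With cohorts of only 20 cases
(ALS) versus 20 non-diseased controls (NDC) and ~9,480 candidate
features, naive feature selection overfits catastrophically. `seroshave`
implements a resampling protocol designed to control that overfitting:
features are selected repeatedly inside random train/test splits, and
only features selected *stably across splits* enter the final panel.

# The pipeline

1. **Input** — GenePix GAL (layout) and per-sample GPR (quantification)
   files in the tab-separated ATF 1.0 dialect, plus a two-column sample
   sheet carrying the phenotype (GPRs carry none). The reader is
   non-destructive: bad-spot flags are recorded, not acted on.
2. **Joint preprocessing** — background subtraction
   (`max(F635 - B635, 1)`; spots with negative flags replaced by their
   unflagged duplicate, or 1 if none), arithmetic mean over duplicate
   spots, `log2`, then quantile normalization over *all* arrays jointly
   (cases and controls together, so group differences cannot be created
   by per-group normalization). After normalization every sample's
   sorted vector equals the mean of per-sample sorted log2 vectors; tied
   values share the mean of the reference values their ranks span, which
   preserves within-sample rank order and makes the operation
   idempotent.
3. **M-score screening** — for each feature, the minimum over intensity
   cutoffs of the exact hypergeometric upper-tail probability of the
   2x2 table (cases/controls above/below the cutoff), one-sided for
   case-elevated reactivity. Candidate cutoffs are midpoints between
   consecutive distinct pooled values plus one cutoff above the maximum
   (which yields the empty table, p = 1). Ties in p go to the largest
   cutoff. Because it minimizes over cutoffs, the M score is
   anti-conservative as a p-value; it is used for screening and ranking,
   with Benjamini-Hochberg FDR applied downstream on the full cohort.
4. **Subruns** — 100 times: draw a stratified 6+6 test set (14+14
   train); keep the 300 features with the best training M scores; run
   gene shaving (below) on the training samples; train a fresh random
   forest on the shaved selection and record its accuracy on the 12
   held-out samples. Preselection and shaving never see test columns —
   a property the test suite asserts by poisoning test columns and
   checking the selection is unchanged.
5. **Gene shaving** — iteratively fit a random forest (500 trees for the
   first fit, 200 after), record the out-of-bag (OOB) error, and drop
   the `ceiling(0.2 m)` features with the lowest permutation importance
   until 2 remain. The selection is the smallest set whose OOB error is
   within one standard error (`sqrt(err(1-err)/n_train)`, evaluated at
   the minimum) of the minimum OOB error.
6. **Panel** — count how often each feature appears in the 100 subrun
   selections; features selected in at least 10% of subruns form the
   panel, ordered by descending frequency (ties by whole-cohort M score,
   then id), truncated to 20.
7. **Verification** — 100 fresh stratified splits; a random forest
   trained on the fixed panel classifies each test set. ALS is the
   positive class: sensitivity counts detected patients, specificity
   correctly classified controls.
8. **NSC re-ranking** — nearest shrunken centroids over all features:
   `d_jk = (xbar_jk - xbar_j) / (m_k (s_j + s0))` with
   `m_k = sqrt(1/n_k - 1/n)`, `s_j` the pooled within-class SD and `s0`
   the median of the `s_j`. Features are ranked by descending
   `max_k |d_jk|`; the shrinkage threshold is chosen by stratified
   cross-validation (among error minima, the largest threshold, i.e. the
   smallest surviving set), and the number of surviving features at that
   threshold is the model's selection level.
9. **Report** — one row per panel feature: raw-scale group medians,
   selection frequency (%), NSC rank position, M-score and Welch-t
   p-values with genome-wide BH FDR and M-score rank position, all
   computed independently on the full 20 vs 20 cohort.

```r
library(seroshave)
gen <- generate_cohort(cohort_spec())
pp  <- preprocess_cohort(gen$cohort)
sel <- run_selection(pp$log, n_subruns = 100, master_seed = 42)
ms  <- m_score_matrix(pp$log)
panel <- final_panel(sel$freq, tiebreak_p = setNames(ms$p_value, ms$feature_id))
ver <- verify_panel(pp$log, panel, seed = 1)
nsc <- nsc_rank(pp$log, seed = 2)
report <- build_panel_report(pp$raw, pp$log, panel, sel$freq, nsc)
```

# Design choices where the design was open

* **"Joint preprocessing" is underdetermined.** The study data shipped
  preprocessed without stating the method. We chose background
  subtraction with floor 1, duplicate means, log2, and joint quantile
  normalization — the standard path of the array-analysis toolchains the
  field uses, with "joint" read as normalizing both groups together.
  Raw-scale medians in the report are taken *before* the log/quantile
  step, matching the ~10^3-scale medians such reports print.
* **The M statistic is used, not defined, in the source literature we
  mirror.** We fixed it as: one-sided (case-high), strict `>` counts,
  exact hypergeometric tail, minimum over midpoint cutoffs plus the
  above-maximum cutoff, ties to the largest cutoff. Monotone invariance
  (the score depends only on value orderings) is asserted by property
  tests, and the implementation is checked exactly against an
  enumeration oracle over all small case/control multisets.
* **No random-forest or NSC library is assumed.** The bagged-CART forest
  (Gini splits, sqrt-mtry, OOB error, permutation importance restricted
  to each tree's used features, which is exact because unused features
  cannot change a tree's predictions) is implemented in compiled code,
  and the NSC model directly from its defining formulas. All randomness
  flows through R's RNG, so `set.seed()` reproduces any fit bit for bit.
* **Seeds.** One master seed governs everything. Per-subrun and
  per-stage seeds are derived with a counter-based Lehmer-style mix
  (`(master * 48271 + index * 1013904223) mod (2^31 - 1)`), so any
  subrun can be reproduced in isolation and results do not depend on
  execution order. A plain XOR of small integers was rejected because it
  yields heavily correlated R RNG streams for consecutive indices.
* **Tree-count defaults** (500 initial / 200 per shaving iteration) are
  desk-scale: they keep a full 100-subrun run on the 9,480-feature
  cohort under a minute on one CPU while leaving OOB error estimates
  stable to ~±3% at n = 28.
* **Panel rule.** "The 20 most frequent features" and "at least 10% of
  subruns" both appear in the protocol we mirror; we apply the 10%
  threshold first and truncate to 20, because the threshold is described
  as the defining cut for the final candidates.
* **Degenerate inputs.** Zero-variance features get p = 1 (equal means)
  in the vectorized Welch test so genome-wide FDR stays defined; the
  scalar `welch_t` refuses them. Constant features have M score 1 by
  construction (only the empty cutoff exists). NSC errors out only if
  *every* feature has zero within-class variance.

# The synthetic cohort: what it emulates and what it does not

`cohort_spec()` defaults state the emulated world: 20 ALS vs 20 NDC,
9,480 features in duplicate spots, 20 planted case-elevated antibodies.
The log2 spot model is
`mu_j + delta_j 1[case] + b_ij + t_ijr` with `mu_j ~ N(10, 1)` (raw
baseline ~10^3 fluorescence units, matching printed report medians),
planted shift `delta = 1.0` (raw median ratio ~2, bracketing the
1.4-1.9 ratios reported for real case-elevated panels), subject-level
SD 0.25 shared by a feature's duplicates, and technical spot SD 0.15.
With those noise levels, simulated technical replicate pairs reproduce
the printed replicate-QC regime (Pearson r > 0.95 on log data, average
per-spot CV ~8-11% on raw data, inter-lot pairs worse than intra-lot),
which is the calibration anchor for `sigma_tech`.

The generator is Gaussian on the log2 scale — the simplest model
consistent with the printed CV and correlation levels. It does *not*
simulate heavy-tailed raw intensity distributions, spatial array
artifacts, control-spot chemistry, cross-reactivity between antibodies,
or batch structure beyond an optional per-feature lot offset. A green
planted-marker test therefore establishes that the selection machinery
recovers known case-elevated features at realistic noise, not that it
would behave identically on real serum profiles.

# What the stated world can and cannot reproduce

The headline numbers of the mirrored study (subrun accuracies 54.8-100%,
mean 85.6%; 207 features selected at least once; panel frequencies
10-36%) were computed on the original 40-array dataset, which is no
longer available; they are data-dependent and not reproducible targets.
Our acceptance surrogates instead fix the panel to the 20 planted
markers and verify it by 100 redrawn splits, which reaches the printed
verification levels (mean accuracy >= 99.9%, specificity 100% in every
run).

One surrogate criterion is *not* met by the stated world, and we report
it red rather than tuning toward it: with a planted log2 shift of 1.0
over a total per-feature SD of ~0.27, the gene-shaving OOB error reaches
0 early, the smallest-set rule then returns 2-3-feature subrun
selections, and ~200-250 total selections spread over 20
interchangeable strong markers cannot put 18 of them above the 10%
frequency threshold (the expectation is ~11-13 qualifying features, all
planted). The same concentration makes a *fixed* label permutation
over-select its best chance features (the maximum null selection
frequency exceeds 30% even though null accuracies stay at chance).
Both effects are properties of the smallest-set rule on strongly
separable or fixed-permutation data, not implementation defects; the
corresponding assertions are kept at their stated thresholds.

# Known limitations

* Binary classification only (ALS vs NDC); no multi-class centroids.
* The forest grows trees to purity with no class weighting; on strongly
  imbalanced training sets its votes favor the majority class.
* OOB error of fully grown bagged trees is pessimistic on
  uninformative data (a known property of bagging with small n); the
  selection rule compares OOB errors *relative to each other*, so this
  does not bias the chosen set size direction.
* Quantile normalization assumes globally comparable intensity
  distributions across arrays; lot-level batch correction is out of
  scope.
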