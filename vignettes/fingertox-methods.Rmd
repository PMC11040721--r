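---
title: "Predicting bioassay activity from probabilistic fingerprints: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting bioassay activity from probabilistic fingerprints: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fingertox)
```

## The problem

Nontarget high-resolution mass spectrometry detects thousands of chemicals in
environmental mixtures, most of which are never unambiguously identified.
Tools such as SIRIUS+CSI:FingerID nevertheless recover structural
information from MS² spectra in the form of *probabilistic molecular
fingerprints*: for each structural pattern (typically expressed as a SMARTS
query), a posterior probability that the pattern is present in the unknown
molecule. Classifiers that predict bioassay activity — here, activity in
nuclear-receptor and stress-response panels of the kind used to flag
potential endocrine disruptors — are trained on *binary* fingerprints
computed from known structures. The gap between the two representations is
the core methodological question this package addresses: how should a
binary-trained classifier consume a probability vector?

fingertox implements the full analysis pipeline around that question:
synthetic data generation with planted ground truth, deduplication and
feature filtering, anticlustering-based partitioning, imbalance-aware
single-output classifiers and a masked-loss multi-output network, Monte
Carlo inference over probabilistic fingerprints, and evaluation by the
false-positive rate at fixed recall.

## Monte Carlo consumption of probabilistic fingerprints

Given per-feature posteriors $p_j$ and a trained scorer $s(\cdot)$, the
*naive* approach binarizes at a fixed threshold ($p_j \ge 0.5 \Rightarrow 1$,
the boundary counted as present) and calls the model once. The Monte Carlo
strategy instead treats the fingerprint as a product of independent
Bernoullis and estimates the expected score

$$\hat y \;=\; \frac{1}{N}\sum_{n=1}^{N} s\!\left(x^{(n)}\right),
\qquad x^{(n)}_j \sim \mathrm{Bernoulli}(p_j),$$

with $N = 10{,}000$ by default. The estimand is the exact posterior
expectation $\mathbb{E}_{x\sim p}[s(x)]$, which
`brute_force_expectation()` computes by enumeration whenever at most 20
features have $0 < p_j < 1$; the test suite verifies unbiasedness and the
$N^{-1/2}$ error decay against that oracle. The final activity call is
`mean_score >= 0.5` (threshold configurable).

Two design choices matter for reproducibility:

* **Blocked sampling with prefix reuse.** Samples are generated in fixed
  512-row blocks with per-block child seeds, so the first $N'$ samples of a
  run are identical to a fresh run of size $N'$. Convergence curves
  (`convergence_analysis()`) therefore use common random numbers across the
  $N$-grid, and a chemical is flagged when its thresholded class at a
  smaller $N$ differs from the class at the largest $N$ — isolating genuine
  borderline chemicals (expected score near the threshold) rather than
  seed-to-seed noise. A fresh-stream comparison is available by changing the
  seed.
* **Only consumed features are sampled.** Sampling is restricted to the
  features the model actually uses; extra columns in the input are ignored
  by name. Multi-output models are scored on the same $N$ samples for all
  assays.

## Synthetic data: what it emulates, and what it does not

Because the real screening data (a ~10K chemical library with 12
active/inactive/inconclusive assay panels, and public MS² spectra for a
subset) requires downloads and a fingerprint-prediction run, the package
ships a generator that reproduces the *statistical structure* the pipeline
must cope with:

* **Correlated binary features.** `generate_fingerprints()` uses a
  latent-Gaussian copula: features in a block share latent correlation
  $\rho$, and feature $j$ is 1 when its latent variable falls below the
  $\mathrm{prev}_j$ quantile. At prevalence 1/2 the implied bit (phi)
  correlation is $\tfrac{2}{\pi}\arcsin\rho$, which the tests check. This
  was chosen over resampling real fingerprints because it gives exact,
  tunable block structure with a one-line generative story.
* **Planted toxicophores.** `plant_toxicophores()` gives each assay a
  sparse logistic ground truth: `sparsity` causal features with weight
  `effect_size` (default all positive — a structural alert *raises*
  activity), an intercept calibrated by bisection so the mean activation
  probability hits the target prevalence within ±0.002. Screening panels
  are heavily imbalanced; defaults use active fractions in the 2–12% range.
  A `share_fraction` of causal features is drawn from a pool common to all
  assays, inducing the inter-assay label correlation that motivates
  multi-output modelling; `assay_correlation()` recovers it.
* **Missing labels.** Entries are set missing completely at random per
  assay (16–60% in real panels). MCAR is an assumption — real
  inconclusiveness plausibly correlates with chemistry — and is documented
  as such: tests that pass under MCAR say nothing about informative
  missingness.
* **Conflicting duplicates.** A fraction of chemicals is emitted 2–3 times
  with labels flipped symmetrically at `flip_prob` on the extra copies; the
  first copy keeps the truth, so `deduplicate()` can be verified exactly at
  `flip_prob = 0`. Real conflict direction is uncharacterized; symmetric
  flips are the neutral choice.
* **Posterior-probability fingerprints.** `emulate_probabilistic_fingerprints()`
  emits, per entry, a Beta draw concentrated near the true bit
  (Beta(8, 2) rescaled per bit) or near its complement. The Beta(8, 2)
  shape reproduces the strongly bimodal profile of real fingerprint
  posteriors while keeping 0.5-thresholding meaningful. Because
  $P(\mathrm{Beta}(8,2) < 0.5) \approx 0.0195$ of concordant mass crosses
  the threshold, the discordant mixture weight is calibrated internally,
  $w_j = (e_j - \ell)/(1 - 2\ell)$ with $\ell$ the leak, so the realized
  0.5-threshold error equals the configured per-feature error $e_j$
  exactly in expectation. Errors below the leak floor are clamped with a
  warning; the degenerate `shape = c(Inf, Inf)` mode emits the bits
  themselves. Defaults place most features at 2–4% error with a 5% tail of
  "hard" features at 12%, mirroring the observed reliability profile of
  spectrum-derived fingerprints (most patterns mispredicted for <4% of
  chemicals, problem groups above 12%). The true joint distribution of
  real posteriors is unknown; the Beta mixture is a stand-in with all
  parameters exposed.

A single integer seed fans out to per-stage child seeds through
`child_seed(seed, stage)` (a fixed affine hash in the Lehmer modulus), so
any stage can be regenerated independently and every operation is
deterministic in `(inputs, seed)`.

## Data preparation

`deduplicate()` collapses repeated records with the any-active rule: active
if any record is active. The complement is not stated by the rule itself;
we resolve mixed inactive/missing records to *inactive* (an inconclusive
run carries no evidence against an observed inactive), with
`conflict = "strict"` available to resolve them to missing instead.

Feature filtering runs variance-first, then correlation (the order is a
fixed convention; the reverse is defensible but changes nothing
qualitative). The near-zero-variance rule removes constant features and
those with most-frequent/second-most-frequent ratio above 19 (95/5) and
under 10% distinct values — for binary features, minority prevalence below
5%. The correlation filter is the exhaustive-recompute greedy: repeatedly
find the pair with the largest |Pearson r|, remove the member with the
larger mean absolute correlation to the remaining features (ties to the
lower column index), until no pair exceeds the cutoff. This variant is
deterministic and order-independent, and the surviving set provably
contains no pair above the cutoff; surviving-feature counts are
non-decreasing across cutoffs 0.7/0.8/0.9. Pearson on binary columns is
the phi coefficient.

`compute_fingerprints()` (optional, requires the ChemmineOB/OpenBabel
backend) sets bit $(i,j)$ when chemical $i$ matches SMARTS pattern $j$ at
least once; unparseable SMILES are reported and dropped rather than
zero-filled, and unparseable SMARTS abort with the offending patterns
listed.

## Partitioning by anticlustering

Representative splits of an imbalanced, sparsely labelled panel are not
guaranteed by simple random sampling. Anticlustering partitions chemicals
into $K$ groups that are maximally *heterogeneous within* and therefore
similar *between*: it maximizes the diversity objective, the sum over
groups of within-group pairwise squared Euclidean distances, via balanced
random initialization and pairwise exchange local search (accepting only
objective-increasing swaps, up to `max_sweeps` sweeps, optional restarts).
The squared-Euclidean objective admits the centroid identity
$\sum_{i<j \in g}\lVert x_i - x_j\rVert^2 = n_g \sum_{i \in g}\lVert x_i -
\bar x_g\rVert^2$, making each candidate swap O(d); exchange search
reaches the exhaustive optimum on small instances (verified at $n = 8$,
$K = 2$ against all 35 balanced bipartitions).

Labels are encoded active = 1, inactive = 0, missing = 0.5 for the
distance computation — the missing state sits between the two observed
states rather than collapsing onto either. The metric/encoding is a
convention (the reference algorithm family does not fix one); a
features-augmented mode is available when fingerprints should also be
balanced. `split_train_test()` (default $K = 5$, i.e. 80/20) picks one
group uniformly at random as the test set; `make_cv_folds()` keeps all
$K = 10$ groups as folds. `stratified_subset()` covers the remaining
partitioning need: repeated random draws until per-assay
active/inactive/missing counts match the full-collection proportions
within a per-cell tolerance (round-half-away-from-zero on both the subset
size and the cell targets), returning the best attempt with a warning if
the tolerance is never met.

## Models

**Single-output.** `train_single_output()` grid-searches logistic
regression (linear baseline), random forests (ranger; the score is the
fraction of trees voting active — no probability calibration), and
gradient boosting (xgboost) by mean out-of-fold ROC-AUC over anticlustered
folds, refitting at the best grid point (ties to the first). The learner
set is deliberately a representative subset: ensemble methods are the
family that survives model selection on this kind of panel, and the
logistic baseline marks the linear floor. Rows with a missing label for
the assay are dropped. Imbalance resampling (`down`, `up`, `smote`) is
applied inside each fold, never to held-out rows. SMOTE synthesizes
minority points $x_i + u (x_{nn} - x_i)$, $u \sim U(0,1)$, among
`k_neighbors` minority neighbours, and its outputs are left continuous in
$[0,1]$ — trees and networks consume them directly, and re-binarizing
would discard the interpolation that is SMOTE's point.

**Multi-output.** `train_multi_output()` fits a fully connected network
(ReLU hidden layers, one sigmoid output per assay) by minimizing the
masked loss

$$L = -\frac{1}{M}\sum_{(i,a)\ \mathrm{observed}}
\left[y_{ia}\log \hat y_{ia} + (1-y_{ia})\log(1-\hat y_{ia})\right],$$

where $M$ counts observed cells; missing cells contribute zero loss and
exactly zero gradient (checked by finite differences). Training uses Adam,
optional dropout, L2 and batch normalization, and early stopping on the
masked loss of a validation slice carved from the training data by the
same anticlustering routine — keeping the partitioning philosophy
consistent end to end. An assay with no observed validation cell simply
drops out of the monitor through the mask. Default widths (32–256 range,
`c(32, 32)` in the shipped config) are desk-scale; the full-scale regime
(512–8192 units, up to 4 layers) is reachable through the same arguments.
Non-finite loss aborts with diagnostics rather than returning a broken
model. With a fixed seed and single-threaded BLAS the fit is bit-for-bit
reproducible.

## Evaluation

The selection metric is the false-positive rate at 90% recall
($\mathrm{FPR}_{\mathrm{TPR}=0.9}$): on the empirical step-function ROC
over distinct score thresholds (ties collapsed into one operating point,
no interpolation — interpolating would credit operating points the
classifier cannot realize), the minimum FPR among points with TPR at or
above the target, with the largest qualifying threshold reported. It is
the metric of a triage tool: catch 90% of the actives while minimizing the
postprocessing workload of false alarms. ROC-AUC uses the Mann–Whitney
formulation with ties counted half; balanced accuracy is
(sensitivity + specificity)/2 at 0.5. All metrics exclude missing labels
and report the evaluated count. `disagreement_rate()` quantifies how often
the Monte Carlo and naive routes give different activity calls, and
`permutation_importance()` (metric drop after within-column shuffling,
averaged over repeats) provides model-agnostic feature attribution —
chosen over exact SHAP because the scientific claim it supports here is
"the planted toxicophores rank highly", which column permutation tests
directly for any scorer.

## Numerical choices and degenerate inputs

* Intercept calibration brackets on $[-50, 50]$ and errors, naming the
  assay, if the target prevalence is unreachable at the planted effects.
* Exchange swaps are accepted only above a $10^{-9}$ objective gain;
  group sizes differ by at most one, the remainder going to the
  lowest-indexed groups.
* Constant columns correlate 0 by convention in the correlation filter
  (they are removed by the variance filter first anyway).
* `masked_bce` clips predictions to $[\varepsilon, 1-\varepsilon]$,
  $\varepsilon = 10^{-12}$, and defines the all-missing case as 0 with a
  warning.
* An all-constant probability vector (every $p_j \in \{0,1\}$) makes the
  MC prediction exact and its standard error 0; `predict_naive` and
  `predict_monte_carlo` agree identically there.
* SMOTE reduces `k_neighbors` with a warning when the minority class is
  too small; single-class inputs error.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run entirely on generated data at
sizes chosen to make the statistical assertions sharp while keeping a full
run comfortable on one CPU: calibration checks at $n \ge 5000$ draws
(binomial tolerances), label-correlation monotonicity at $n = 50{,}000$,
parameter recovery at $n = 5000$ chemicals × 100 features with 5 causal
features of effect 2.0, MC-estimator checks on 25 random toy models with
4–12 free features at $N = 10{,}000$, and an end-to-end pipeline run at
$n = 600$ × 50 features × 3 assays. The split-size arithmetic (a 6735-row
panel splitting 5388/1347 at $K = 5$; a 10% subset of 7483 chemicals
giving 748, with per-state targets 75/550/123 under proportions
10.08/73.54/16.38%) is exercised at full row counts, since it costs only
seconds.

## Known limitations

* The generator's independence assumptions (Bernoulli labels given
  features, MCAR missingness, per-feature independent posterior noise) are
  exactly the assumptions under which the Monte Carlo estimator is
  unbiased. Passing tests demonstrate correctness of the machinery, not
  robustness to correlated posterior errors or informative missingness in
  real spectra.
* The Monte Carlo strategy treats features as independent given the
  posteriors; real fingerprint posteriors are correlated through the
  fragmentation tree, and no variance-reduction or dependence modelling is
  attempted.
* Tree-ensemble scores are uncalibrated vote fractions; thresholding them
  at 0.5 is a convention, and the FPR-at-recall metric (which only uses
  ranks) is the more trustworthy summary.
* `compute_fingerprints()` matches SMARTS as-is: no salt stripping,
  neutralization or SMILES standardization is performed, and inputs are
  assumed pre-standardized.
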