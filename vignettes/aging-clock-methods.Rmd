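---
title: "Methods: proteomic aging clocks and aging-protein discovery in ahclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteomic aging clocks and aging-protein discovery in ahclock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ahclock)
```

## The analysis in one paragraph

`ahclock` analyses a log2 protein-abundance matrix (proteins × samples, as
exported from a DIA quantification run) together with per-sample metadata
(age in years, sex coded 0/1, BMI, an older/young group label, optionally an
ordinal lens-opacity grade). The stages are: impute missing quantifications;
standardize each protein and smooth it over age with LOESS; cluster the
fitted trajectories and test clusters for aging-protein enrichment; call
aging proteins (APs) by a dual criterion (group difference *and*
covariate-adjusted age association, with concordant direction); fit a
proteomic age clock — repeated cross-validated LASSO to stability-select a
signature, then ridge regression of age on the signature plus sex — and
bias-correct its predictions; stratify samples into accelerated,
decelerated and chronological agers by delta-age; and regress each AP on
delta-age (and on the ager groups) to nominate aging modulators. A
synthetic-cohort generator with planted ground truth supports all of the
package's recovery tests.

## Imputation

DIA missingness is predominantly left-censored: low-abundance signals fall
below the detection limit. The default `min_prob` method therefore draws
each missing cell from a Gaussian centered on the protein's 0.01 quantile of
observed values, with spread 0.3 × the protein's observed SD (the draw is
seeded and reproducible). `half_min`, `median` and `knn` (k = 5 nearest
samples by Euclidean distance over co-observed proteins) are provided for
sensitivity analyses. Proteins missing in more than half the samples carry
too little information to impute and are dropped (the cap is
configurable); a protein with no observed value at all is an error.
Observed cells are never altered, which the test suite checks cell by cell.

## Trajectories and clustering

Each protein is z-scored (mean 0, sample SD 1, denominator *n* − 1;
zero-variance proteins are dropped with a warning) and smoothed with LOESS
(`expression ~ age`), span 0.75, local degree 2, tricube weights, no
robustness iterations — the defaults of the R `loess` routine. Fits are
evaluated on a 50-point grid spanning the observed age range only; LOESS is
a local method and is not extrapolated. Fitted trajectory vectors (not the
raw z-score profiles, which mix noise into the distances) are clustered
agglomeratively on Euclidean distance, complete linkage by default
(`average` and `ward` are available), and the tree is cut at *k* clusters.
No principled default for *k* exists beyond convention; the package
defaults to 7 and `silhouette_report()` emits an average-silhouette-vs-k
table to aid the choice. Cluster enrichment for APs uses the upper-tail
hypergeometric probability (at least the observed AP count, given cluster
size, AP count and universe size), BH-adjusted across clusters; the
universe is the set of quantified proteins after filtering — the sampling
frame of the experiment — not the genome.

## The dual aging-protein criterion

A protein is an AP when (i) the Wilcoxon rank-sum test between the older
and young groups and (ii) the t-test on the age coefficient of
`expression ~ age + sex + bmi` are both significant after BH adjustment
(default FDR 0.05), and the group fold change agrees in sign with the age
slope. The concordance requirement is what makes "up-" and "downregulated
AP" well defined when the two tests could disagree; a flag disables it.
The Wilcoxon p is exact (full enumeration convention) when both groups have
at most 12 samples and there are no ties, and uses the normal approximation
with continuity and tie correction otherwise. Missing BMI values are
mean-imputed with a warning rather than dropping subjects, keeping the
clock cohort intact. The per-protein linear models are solved in one
vectorized QR decomposition, which keeps the 2,000-protein null
calibrations in the test suite fast.

Opacity correlations use Spearman's rank correlation (the LOCS III-style
grade is ordinal), per AP and for two composite scores (mean z-score over
up-APs and over down-APs), with |r| bins weak < 0.4 ≤ moderate < 0.6 ≤
strong.

## The age clock

Thirty-three samples (configurable) are drawn uniformly at random as the
training set. On the training set, with features standardized to training
mean 0 and SD 1, the LASSO is fitted `n_reps` times (default 1,000); each
repetition redraws a random 10-fold CV partition, picks the penalty
minimizing CV mean-squared error on a 100-point log-spaced grid descending
four orders of magnitude from the smallest all-zero penalty, and records
which features have nonzero coefficients. Features retained in strictly
more than half the repetitions form the signature. The only randomness the
procedure requires is the CV partition; an optional bootstrap-resampling
mode additionally resamples training rows, which restores frequency spread
on fixed designs where fold redraws alone leave inclusion at the CV-minimal
penalty nearly deterministic (the CV-minimum is known to overselect — on
toy designs a spuriously correlated noise feature can be retained in nearly
every repetition, which is why the package judges signature quality on
cohort-scale recovery runs rather than toy examples).

The clock itself is ridge regression (closed form, intercept unpenalized)
of age on the standardized signature proteins plus sex, penalty chosen by
10-fold CV on the training set over the grid `10^seq(4, -4)`. The closed
form keeps the estimator transparent (the single-feature solution
Σxy/(Σx² + λ) is asserted against the solver in the tests) and reduces
exactly to OLS at λ = 0.

Raw clock predictions compress toward the training mean (regression
dilution), so the calibration line `predicted ~ chronological` is fitted by
OLS — on the training samples by default, avoiding test-set leakage; a
`calibrate_on = "all"` flag reproduces the alternative reading — and all
predictions are mapped through its inverse:
`unbiased = (predicted − intercept) / slope`. Delta-age is unbiased minus
chronological age; by construction its mean over the calibration samples is
exactly zero (a property the acceptance script recomputes), and MAE is the
mean absolute delta-age. Ager classes use the thresholds: decelerated
(delta-age ≤ −5 y), accelerated (≥ +5 y), chronological (|delta-age| < 2 y),
with the 2–5-year gaps left unclassified.

For ager stratification and modulator models the delta-age is computed from
a ridge model on *all* identified APs (not the reduced signature), matching
the configuration in which the stratification was designed; this is
configurable. Per-protein AUC is the Mann–Whitney probability (ties ½) that
an older-group value exceeds a young-group value, with the older-vs-young
orientation fixed so that values below 0.5 indicate downregulation.
`random_signature_null()` refits the clock on uniformly drawn protein sets
of matched size to show the selected signature outperforms chance.

## Modulators

Each AP is regressed as `expression ~ age + sex + bmi + delta_age`; the
delta-age t-test at raw p < 0.05 nominates a modulator (BH-adjusted values
are always reported so stricter filtering is possible). Because delta-age
estimates the latent offset between biological and chronological age, the
age covariate absorbs ordinary trends and the delta-age coefficient
isolates association with age *acceleration*. Ager-group contrasts refit
with the class factor (CA reference, unclassified samples excluded) and
t-test the AA−CA and DA−CA contrasts; the package reports signed
coefficients and labels (decelerating/accelerating/both) without imposing a
biological reading of the sign, which is interpretive.

## The synthetic cohort generator

`simulate_cohort()` emulates the cohort structure the analysis assumes: 19
young (ages uniform on 19–35) and 33 older (50–91) subjects; 634 proteins
with baselines ~ N(20, 2²) log2 units; Gaussian measurement noise (default
SD 0.5 log2 units); sex ~ Bernoulli(0.5) and BMI ~ N(24, 3²) truncated to
[15, 40] with small effects on every protein (0.2 and 0.02 log2 units per
unit, defaults); a latent per-subject offset δ ~ N(0, 6²) years defining
biological age b = age + δ. Trend proteins follow one of seven archetype
curves of chronological age — linear up/down, early-plateau up/down
(logistic, midpoint at 25 % of the span), late rise/fall (midpoint 75 %),
and a nonmonotone mid-life bump — scaled to 1.5 log2 units across the span
(the scale of top aging-protein fold changes); logistic transitions use
scale 0.15 of the span, i.e. roughly a decade, matching the smooth
trajectories the shapes emulate. Clock proteins are linear in biological
age with alternating signs, which is what makes delta-age identifiable and
modulator recovery a meaningful test. Left-censoring below each protein's
0.05 quantile is applied before 2 % MCAR dropout so the two mechanisms stay
separable. Planted slopes, loadings, archetype labels, δ and true ager
classes are returned as ground truth.

What the generator does *not* emulate: peptide-level structure, shared
covariance beyond the single latent δ (real proteomes have correlated
modules), heavy-tailed or intensity-dependent noise, and batch effects.
Passing recovery tests therefore demonstrate correctness of the estimators
under the stated model, not robustness to everything real cohorts do.

## Recovery experiments and problem sizes

The test suite's cohort-scale experiments (also the package's acceptance
checks) use: AP recovery on 52 × 634 cohorts with 40 planted *linear*
trend proteins (effect 1.5, noise 0.5) over five seeds — linear shapes are
planted because only they deliver the full 1.5-log2 effect between the two
groups, and the dual AP criterion is directional by construction (the
sigmoid and bump shapes are exercised by the trajectory experiment
instead); clock recovery with 15 planted clock proteins (noise
0.3, δ SD 6) at 200 LASSO repetitions, judged on signature content,
test-set correlation and a 50-draw random-signature null; modulator
recovery over ten replicate 52 × 200 cohorts with planted loadings of 3
log2 units per span — "strong signal" calibrated by power analysis to the
scale of the largest observed AP fold changes — plus a 2,000-protein null
calibration at δ ≡ 0; and trajectory recovery on 70 trend proteins (10 per
archetype, noise 0.2) scored by adjusted Rand index at k = 7. These sizes
were chosen as the smallest cohort-realistic configurations that exercise
every code path.

## Known limitations

Exact Wilcoxon enumeration is only used for small groups (≤ 12 per arm);
the tie-corrected normal approximation governs cohort-scale calls.
Hierarchical clustering breaks distance ties by input order, so cluster
*labels* (not memberships) can depend on protein order. The CV-minimal
LASSO penalty overselects on designs with few strong predictors; the
majority-vote threshold mitigates but does not eliminate this, and users
wanting sparser signatures should raise `freq_threshold` or use the
bootstrap mode. Delta-age used in modulator models is estimated from the
same matrix, so modulator p-values are anti-conservative for proteins that
dominate the clock; the package reports BH-adjusted values alongside for
that reason.
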