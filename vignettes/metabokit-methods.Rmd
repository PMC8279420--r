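---
title: "Statistical methods in metabokit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods in metabokit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

metabokit implements the statistical workflow a quantified metabolomics or
proteomics experiment goes through between instrument output and a results
table: input validation, missing-value handling, normalization, outlier
screening, and the exploratory, inferential, multivariate, network and
predictive analyses that follow. This vignette explains the models and
procedures, the defaults and their rationale, the numerical choices, and
the limits of what the synthetic-data tests demonstrate.

```{r setup}
library(metabokit)
```

## The data model

The central container, `omics_data`, joins a samples-by-features intensity
matrix to the sample metadata: column 1 of the target CSV is the sample
id, column 2 the group label, columns 3+ optional covariates. The features
CSV is a pure numeric block in the same row order. Group levels are ordered
by first appearance, and *every* two-group contrast in the package — fold
changes, t statistics, model coefficients, odds ratios, the "positive"
class of a classifier — is the second level versus the first. An
append-only log records each processing step so a report can state the
effective sample size after subsetting or outlier removal.

Zeros and missing values are distinct. A reported zero for an endogenous
compound usually means "below the detection limit", so `recode_zeros()`
turns exact zeros into missing values by default; compounds whose absence
is biologically real (drugs, exposures) can be exempted by id and keep
their zeros.

## Missing values

Filtering precedes imputation. `filter_missing()` removes a feature only
when its within-group missing fraction exceeds the cutoff (default 20%) in
*every* group: a feature still well measured in one group can carry a
genuine group difference, and the group-wise reading preserves it. The
opposite behaviour (`rule = "any"`) is available. Entirely missing
features are removed at any cutoff, since nothing can be imputed from
nothing.

Six imputation methods are provided: zero, half-minimum (a conventional
proxy for signals below the limit of quantification), median, mean,
minimum, and k-nearest neighbours (default k = 5). The kNN distance is
Euclidean over mutually observed features, excluding the feature being
imputed, on per-feature standardized values so that high-intensity
features do not dominate the metric; the imputed value is the mean of the
k nearest donors' raw values.

## Normalization

All six methods operate per feature with sample mean $m$ and sample
standard deviation $s$ (n − 1 denominator):

| method | transform | use case |
|---|---|---|
| autoscale | $(x-m)/s$ | unit variance; every feature equally weighted |
| level | $(x-m)/m$ | changes relative to mean response |
| log | $\ln(x+1)$ | variance stabilization only |
| log_scale | autoscaling of $\ln(x+1)$ | log then unit variance |
| vast | $\frac{x-m}{s}\cdot\frac{m}{s}$ | up-weights stable (low-CV) features |
| log_pareto | $(\ln(x+1)-m')/\sqrt{s'}$ | compromise between log and autoscaling |

The log family uses $\ln(x+1)$ so zero intensities stay finite; this is
stated here prominently because it changes values relative to a plain
logarithm at low intensities. Constant features carry no information under
any scaling and are dropped with a logged warning rather than producing
division-by-zero artefacts.

## Outlier detection

`detect_outliers()` is a group-aware multivariate screen: compute the
sample–sample distance matrix (Euclidean by default; maximum, Manhattan,
Canberra and Minkowski available), embed the samples in a two-dimensional
principal coordinate space (classical MDS), and within each group measure
each sample's Euclidean distance to its own group centroid. A sample is
flagged when that distance exceeds the Tukey fence $Q_3 + x \cdot IQR$ of
its group's distances. Quartiles use linear interpolation between order
statistics (R's default type 7); fences are per group because a tight
group must not inherit a loose group's spread. The multiplier defaults to
the classical $x = 1.5$; raising it makes the screen less sensitive.

Two properties of this detector are worth understanding before trusting
it blindly. First, sensitivity is excellent: a sample shifted by several
within-group standard deviations across many features dominates the first
principal coordinate and is flagged essentially always (the package's
acceptance checks observe 100% detection of a 6-sd planted outlier over
100 simulated studies). Second, specificity is bounded by the Tukey rule
itself: the fence is scale-free, so on clean Gaussian-like data each
sample still has roughly a 1–2% chance of falling beyond $Q_3 + 1.5\,IQR$
of its group's distances. With ~40 samples the probability that *no*
clean sample is flagged alongside a true outlier is therefore only about
0.4–0.7, at any embedding dimension. Treat the flag list as a screen to
review, not a verdict; raising `x` to 3 trades a little sensitivity for
substantially fewer incidental flags.

## Univariate and moderated tests

Per-feature two-group comparisons use Welch's t by default (the
equal-variance Student test and the paired test are switches), the
Mann-Whitney U (exact when both groups have at most 8 samples and no ties,
tie-corrected normal approximation otherwise), one-way ANOVA and
Kruskal-Wallis for multi-group designs, and ANCOVA — the group term tested
by the nested-model F against the covariate-only model. All tests are
two-sided; every table is Benjamini-Hochberg adjusted internally (via
`stats::p.adjust`), per table rather than across tables.

The moderated layer fits one OLS design
`[intercept, covariates, group]` to all features at once and shrinks the
per-feature residual variances by empirical Bayes. Assuming
$s_g^2 \sim s_0^2 F(d_g, d_0)$, the prior $(d_0, s_0^2)$ is estimated by
method of moments on $\log s_g^2$, matching its mean and variance to the
scaled-F theory through the digamma and trigamma functions; the trigamma
equation is solved by a safeguarded Newton iteration. The moderated
variance is $\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$, the
moderated t is $\beta_g / (\sqrt{u_g}\,\tilde s_g)$ on $d_0 + d_g$
degrees of freedom. When the observed spread of log-variances does not
exceed what sampling alone implies, $d_0 = \infty$ and every variance
collapses to $s_0^2$. The test suite verifies this machinery feature-wise
against the independent Bioconductor implementation of the same
methodology. `limma_pipeline()` always produces the with- and
without-covariate tables side by side; with orthogonal (balanced)
covariates the group coefficients agree exactly, which is also tested.

## Multivariate models

PCA is the column-centred SVD. PLS-DA is PLS2 fitted by NIPALS against the
centred one-hot group matrix; no scaling happens inside the model because
normalization is an explicit upstream step (only centring is applied).
Variable importance is
$VIP_j = \sqrt{p \sum_a SSY_a w_{ja}^2 / \sum_a SSY_a}$ with normalized
weight vectors, so the mean squared VIP is identically 1 — a property the
tests assert on arbitrary data. Cross-validation (leave-one-out or
stratified k-fold) classifies by the nearest training-group centroid in
latent-score space; the overall error rate is reported per component
count. Sparse PLS-DA soft-thresholds the X-weight vector each iteration,
keeping the `keepX` largest magnitudes (ties broken by feature order);
with `keepX = p` it reproduces PLS-DA to numerical precision.

k-means uses Lloyd's algorithm with 20 random restarts per k plus a warm
start derived from the k−1 solution (its widest cluster split at the
farthest member), which guarantees the reported within-cluster sum of
squares curve is non-increasing in k. The automatic choice of k takes the
maximal second difference of **log** WSS — relative curvature — rather
than of raw WSS: on clearly separated three-cluster data the absolute
drop from k = 1 to 2 is so large that raw curvature regularly elects
k = 2, while the sharpest *relative* bend is robustly at the true k. This
is the one place the package's concrete "elbow" rule was revised after
the raw-difference variant demonstrably mis-ranked unambiguous cluster
structure.

## Correlation and network analysis

Pairwise correlations (Pearson, Spearman, Kendall) come with two-sided
p-values: the t approximation on n − 2 degrees of freedom for Pearson and
Spearman, the tie-corrected normal approximation for Kendall. The
correlation network keeps pairs with $|r|$ at or above the threshold; the
redundancy screen defaults to 0.97.

The Gaussian graphical model estimates a sparse inverse correlation
matrix by the graphical lasso, implemented in-package as standard
blockwise coordinate descent (the inner per-column problem is a lasso).
Features are standardized first so the penalty is scale-free; at
$\rho = 0$ the exact unpenalized solution (direct inversion, requiring
n > p) is returned, and the tests verify the coordinate-descent path
against it. Partial correlations follow the usual sign convention
$\pi_{ij} = -\Omega_{ij}/\sqrt{\Omega_{ii}\Omega_{jj}}$; edges are entries
above a 1e-8 numerical zero. One structural caveat the tests make
explicit: a chain $x \to y \to z$ is only *identifiable* at moderate
penalty when the indirect marginal correlation ($b^2$ for chain
coefficient $b$) lies below the penalty while the direct correlations lie
above it. At $b = 0.7$ the indirect correlation is 0.49 and no graphical
lasso will zero it at a moderate $\rho$; the recovery simulations
therefore use $b = 0.5$, n = 400, $\rho = 0.3$, a regime where the
reference solution recovers the chain essentially always.

## Predictive models and odds ratios

Train/test splitting is stratified by group (`floor(test_prop * n_g)` per
group) and seeded; a proportion that would leave a group without test
samples yields an empty test set with a warning, and `test_prop = 0`
explicitly disables external validation. Penalized logistic regression
(glmnet) selects lambda by stratified k-fold cross-validated deviance over
a 100-point grid spanning four decades below $\lambda_{max}$; the minimum
rule is the default and the one-standard-error rule a flag. Features are
standardized inside the fit and coefficients reported on that scale, so
the penalty treats features symmetrically. The random forest is fitted on
the training split only and all its metrics come from the held-out test
set; the evaluation record stores both id lists so disjointness is
checkable after the fact. Accuracy intervals are exact Clopper-Pearson;
sensitivity and specificity take the second group level as positive.
Odds ratios come from one joint logistic model over the selected features
(plus covariates), $OR = e^{\beta}$ with Wald intervals; (quasi-)perfect
separation is detected and those ORs reported missing rather than as
astronomical numbers.

## Rank products

For K pairwise comparisons the per-feature log2 fold changes are ranked
within each comparison (average ranks on ties), and the rank product is
the geometric mean of a feature's ranks, once for each direction.
Significance uses within-comparison rank permutations:
$p = (1 + \#\{\text{permuted } RP \le \text{observed}\})/(1 + n_{perm})$,
smoothed so p is never zero, and the expected proportion of false
positives at a feature's position is $PFP = p \cdot p_{features} /
\text{rank position}$. For tiny instances an exact mode enumerates all
$(p!)^K$ equally likely rank configurations, which the tests compare
against an independent enumeration.

Two design points matter. Unpaired comparisons are a seeded *disjoint*
random matching of group-1 to group-2 samples (each sample used at most
once, capped at `max_comparisons`): the permutation null assumes the K
comparisons are independent, and building them from all cross pairs —
which reuse every sample many times — demonstrably overdisperses the
observed rank products and destroys the calibration of p. Second, fold
changes need positive intensities, so rank products run on the raw or
merely log-transformed matrix, never after centring/scaling; the pipeline
keeps the imputed pre-normalization matrix for exactly this purpose.

## The synthetic-data generator

`fixture_spec()`/`generate_fixture()` emulate the package's input
contract with known ground truth: log-normal intensities (meanlog 10,
sdlog 0.5 — a realistic intensity scale and spread for quantified omics
data), a multiplicative group effect $e^{\text{effect} \cdot
\text{sdlog}}$ on the informative features (so "effect 2" means two
within-group log-scale standard deviations), correlated blocks through a
shared latent factor on the log scale, MCAR missingness, injected zeros,
an optional sample shifted by a chosen number of sds in a chosen fraction
of features, and covariates. One seed drives everything; the same spec
reproduces byte-identical CSVs. The standard presets used throughout the
tests are `two_group_basic` (20 + 20 × 100, 5 informative at effect 2),
`three_group` (3 × 15 × 80), `outlier_one` (the two-group base with one
6-sd/60% outlier and no group effect), and `null_global` (20 + 20 × 150,
no effects).

What passing these tests shows — and what it does not. The generator
produces independent log-normal features with clean MCAR missingness and
exchangeable samples. Real studies add batch structure, drift,
intensity-dependent missingness (censoring), and heavy feature
correlation; none of these is simulated, so calibration and recovery
results here are statements about the methods' correctness under their
own assumptions, not about robustness to violated ones. Batch/drift
correction is explicitly out of scope.

## Numerical choices and degenerate inputs

Quartiles: type 7 everywhere. Distances: Minkowski exponent defaults to
2; Canberra's 0/0 terms follow `stats::dist`. NIPALS convergence: relative
score change below 1e-9, 500 iterations cap. Graphical lasso: outer loop
tolerance 1e-6 on the mean absolute change of the working covariance, 200
outer iterations, explicit non-convergence error with diagnostics.
Constant features: dropped with warnings under scaling, reported as
missing correlations, rejected from the GGM. Singleton groups: never
flagged as outliers (no spread to define a fence), warned about. A t-test
on constant data reports a missing p with a warning rather than failing
the whole table. All randomized stages (splits, folds, restarts,
permutations, fixtures) refuse nothing but derive every stream from a
single user seed, which makes every pipeline run, and its manifest
replay, byte-identical.

Problem sizes in the test-suite simulations (50–100 seeded replicates at
the preset sizes above, 199 permutations for the null-calibration check,
25–50 seeds for recovery rates) were chosen to make the Monte Carlo error
small relative to each property's margin while keeping the default suite
quick to run.

## Known limitations

- The exploratory report renders to markdown; PDF typesetting is out of
  scope.
- No OPLS-DA, SVM, batch correction, QC-drift correction, or
  repeated-measures designs.
- The moderated layer handles the two-group contrast (with covariates);
  multi-level designs route to ANOVA/ANCOVA instead.
- GGM edges carry no inferential p-values — the lasso's selection is the
  inference, and post-selection p-values would be misleading.
- The outlier screen's specificity caveat above applies to any Tukey-type
  rule; decisions about removing samples should involve the embedded plot
  (`autoplot()` on the result), not only the flag column.
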