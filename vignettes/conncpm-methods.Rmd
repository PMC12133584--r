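---
title: "Connectome-based predictive modeling and its failure modes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome-based predictive modeling and its failure modes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Connectome-based predictive modeling (CPM) predicts a behavioral outcome
from a subject's functional connectome — the symmetric matrix of
connectivity values ("edges") between brain parcels. For $P$ parcels there
are $E = P(P-1)/2$ edges; `conncpm` vectorizes the upper triangle in
row-major pair order, so all analysis operates on an $N \times E$ subject-by-edge
matrix.

On a training sample, each edge $c_e$ is correlated with the outcome $y$
(Pearson, two-sided p from the $t$ transform on $n-2$ df). Edges with
$p < \theta$ (default $\theta = 0.01$; 0.05 as the lenient alternative)
form the **positive set** ($r_e > 0$) and **negative set** ($r_e < 0$).
The subject-level summary score is

$$ s_i \;=\; \sum_{e \in \mathrm{pos}} c_{ie} \;-\; \sum_{e \in \mathrm{neg}} c_{ie}, $$

and a one-parameter ordinary least squares fit $y_i = a + b\,s_i$ maps
scores to predicted outcomes (positive-only and negative-only score modes
use one sum alone). Accuracy is the Pearson correlation between predicted
and observed outcomes in held-out subjects, averaged over 100 random
70/30 train/test splits. Significance comes from a permutation null: the
outcome is reassigned at random over subjects, the *entire*
cross-validated pipeline (selection included) is rerun, and the p-value
is the proportion of permuted mean accuracies strictly greater than the
observed mean — reported as a bound `< 1/n` when no permutation exceeds it.
Bonferroni correction (`min(1, m p)`) covers the family of outcomes.

Assumptions worth keeping in mind: edge-outcome relationships are modeled
as linear and summarized additively; selection treats edges
independently; Pearson accuracy is scale-free, so calibration of the
predictions is not assessed.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `p_threshold` | 0.01 | edge-selection threshold (two-sided); 0.05 = lenient variant |
| `n_splits` / `train_fraction` | 100 / 0.70 | split scheme for cross-validation |
| `n_permutations` | 1000 | permutation-null size (`perm_splits` trims splits per permutation for desk-scale runs, logged) |
| `score_mode` | combined | combined / positive_only / negative_only summary score |
| MI `n_iterations` | 100 | classification repetitions per left-out subject |
| MI `subsample_fraction` | 0.8 | training subsample per iteration (of the N−1 remaining) |
| MI `p_threshold` | 0.05 | binary-stage selection threshold (see below) |
| `mi_cut` | 0.5 | MI above this = frequently misclassified |
| inverse `train_cut` / `test_cut` | 0.4 / 0.5 | MI cuts defining the correctly classified training and misclassified test subgroups |

## Design choices where the design was open

**Selection p-values.** Edge selection uses the parametric $t$ transform
of Pearson $r$; in the cross-validation hot path the equivalent critical
value $|r| > r_{crit}(\theta, n)$ is compared instead of transforming
every edge, which is algebraically identical and much faster.

**Splits.** Subject-level simple random splits without stratification;
uniqueness is enforced by rejecting duplicate index sets. One master seed
drives everything: per-split, per-permutation, per-flip and per-MI-iteration
seeds are derived deterministically from (seed, stream, index), so any
single unit of work is reproducible in isolation and whole runs are
bit-identical under a fixed configuration.

**Empty feature sets.** A split whose required feature set is empty (or
whose test-set accuracy is undefined) records a missing accuracy with a
warning and is excluded from the mean; a run aborts only when more than
half the splits fail, with guidance to relax the threshold. The same
policy applies inside permutations (permutations with no valid split drop
out of the null denominator).

**Permutations reuse the observed splits**, isolating the reassignment of
the outcome as the only varying factor. The strict exceedance proportion
is the default estimator; the conventional $(k+1)/(n+1)$ estimator is
available (`estimator = "plus_one"`).

**Lesioning.** A virtual lesion removes every edge incident to one
network (incidence rule: either endpoint in the network — severing a
network must cut its between-network couplings too; `within_only`
restricts to internal edges). The lesioned pipeline is rerun from feature
selection under the same splits, and the per-split paired difference in
accuracy is summarized by its mean and standard error. Because selection
here is edge-wise, removing columns before selection and pruning lesioned
edges from full-set masks give identical results; both interfaces exist.
Significance of the mean paired difference uses a matched-split sign-flip
permutation (10,000 flips, two-sided, $(k+1)/(n+1)$ — a sign-flip test
cannot report zero), Bonferroni-corrected over the 12 networks; a paired
t-test is available. A caveat this package's own simulations exposed:
with lenient thresholds, lesioning even a *signal-free* network slightly
*improves* accuracy (order $+0.003$ at $E \approx 1800$), because the lesion
prunes false-positive feature candidates. Specificity claims about null
networks are therefore evaluated under conditions where the lesion cannot
alter selection (strong planted coupling, strict threshold); at lenient
thresholds a small positive offset is expected and is not a bug.

**Misclassification index.** The binary analysis median-splits the
outcome (at-median subjects go to the low class, a deterministic tie
rule) and, for each left-out subject, repeatedly (default 100×) draws a
random 80% subsample of the remaining subjects, selects edges against the
class labels (point-biserial correlation), computes the positive and
negative summary scores, and trains a linear-kernel support-vector
classifier (`e1071::svm`, cost 1) on that two-dimensional score
representation. MI is the fraction of iterations misclassifying the
subject. The 2-D score representation preserves the CPM feature pipeline;
a raw-edge-input SVM variant sits behind `input = "edges"`. The binary
stage defaults to $\theta = 0.05$: point-biserial correlations with a
median-split class are attenuated (by roughly the ratio of the biserial
to the continuous correlation, and further by any discordant admixture),
and at $\theta = 0.01$ a subsample of ~70 subjects selects too few
features to classify with. Degenerate iterations (single-class subsample,
or no feature separating the classes) fall back to a training-majority
vote. Covariate dissection correlates MI with each covariate within low
and high scorers, and each covariate with the outcome within correctly
(MI < 0.5) and frequently misclassified (MI > 0.5) subjects; two-level
categorical covariates are encoded 0/1, more levels as an indicator of
the modal category; strata under 4 subjects are flagged not-computed.
Covariate-controlled accuracy is the test-set partial Pearson correlation
between predicted and observed outcomes given the covariate (regressing
the covariate out of the outcome beforehand is the usual alternative; the
partial-correlation route leaves the fitted model untouched).

**Inverse models.** The inverse experiment fits a full-sample CPM on
correctly classified subjects (MI < 0.4) and applies it, frozen, to
frequently misclassified subjects (MI > 0.5), once directly and once with
every summary score negated before the fitted coefficients. Negating the
scalar input of a fixed linear map negates the prediction-observation
Pearson correlation exactly, so `r_inverted = -r_direct` to machine
precision; the package computes both sides rather than asserting the
identity. Refitting on negated scores instead (`refit_inverted = TRUE`)
flips the slope back and reproduces the direct predictions — a useful
reminder that only the *frozen*-model inversion is informative.

## The synthetic generator

Restricted clinical data cannot ship with a package, so `conncpm`
includes a generator producing exactly the statistical structure the
pipeline assumes. A latent standard-normal trait $c_i$ drives everything:

* planted positive edges: $\mathrm{baseline}_e + \beta\,c_i + \varepsilon$,
  planted negative edges with $-\beta$; all other edges are baseline plus
  noise. Edge baselines are drawn once per edge from $N(0.25, 0.1)$ so
  matrices look heterogeneous; values are not squashed into $[-1, 1]$ by
  default because CPM is scale-free in the edges (`squash = TRUE` applies
  tanh for cosmetic realism).
* observed outcomes: rescaled $\lambda c_i + \varepsilon$ on a
  NIH-Toolbox-like scale (mean 100, sd 15). Defaults $\lambda = 0.8$,
  noise sd 0.6 give trait-outcome reliability 0.8, a realistic value for
  composite cognition scores.
* covariates: $\rho\,c_i + \varepsilon$, coupled only in *concordant*
  subjects when stereotype-breaking is on. Defaults $\rho_{SES} = +0.75$
  and $\rho_{antipsychotic} = -0.5$ were chosen so the population
  covariate-outcome correlations among concordant subjects are about
  $+0.48$ and $-0.37$ — the magnitudes reported for correctly classified
  early-psychosis patients.
* a **discordant** fraction of subjects has the edge-trait coupling sign
  flipped, modeling individuals whose brain-behavior relationship opposes
  the majority pattern; their covariates are uncoupled under stereotype
  breaking.

Default coupling strength is $\beta = 0.5$ against unit edge noise
(per-edge edge-outcome correlation $\approx 0.36$). What the generator does
*not* emulate: spatial autocorrelation between edges, site effects,
head-motion artifacts, non-Gaussian FC distributions, or any genuine
fMRI time-series structure. Passing tests therefore demonstrate that the
*algorithms* behave as specified under the assumed generative structure —
not that real early-psychosis connectomes carry signal of any particular
strength.

### Preset study conditions

`synthetic_preset()` freezes the conditions used throughout the test
suite and the acceptance script (all at the study's n = 92 unless noted):
`tiny` (24 × 20 parcels, smoke tests), `full-scale` (333-parcel
Gordon-sized atlas, 1% planted edges), `null` (45 parcels, E = 990,
$\beta = 0$), `signal` (100 parcels, E = 4950, 1% planted split DMN-VIS
positive / SM-RSP negative), `lesion` (61 parcels, all 10 planted edges
strictly within DMN at $\beta = 2$), and `discordant` (25 parcels,
E = 300, 25 + 25 planted edges — "widespread" signal — with a 30%
discordant subgroup). The problem sizes were picked so the full
validation battery (200 null replicates for the type-I check, 20
replicates each for lesioning and misclassification) runs on a single
CPU in well under half an hour; the 12-network structure and planted
placements mirror the qualitative geography of the real findings
(default-mode/visual positive features, somatomotor/retrosplenial
negative features).

## Numerical notes and limitations

* Constant edges get $r = 0$, $p = 1$ and are never selected; a constant
  outcome is an error. Degenerate test-set variance or undefined partial
  correlations record missing splits.
* OLS on a scalar score is computed in closed form; `fit_cpm` requires at
  least three distinct training scores.
* The per-split engine caches centered training matrices when
  `n_splits × n_train × E` fits in a few hundred MB, making the
  1000-permutation default tractable; beyond that it recomputes per split.
* Serialized models (plain text, 17 significant digits) round-trip
  exactly, as do all fixture files.
* MI is a biased estimate of a subject's true misclassification
  probability near 0 or 1 with 100 iterations (binomial resolution 0.01),
  and MI-based subgroup cuts (0.4 / 0.5) are conventions, not estimates.
* The package does not implement regularized-regression CPM variants,
  parcel- or edge-level importance, Haufe-transformed weights, site
  harmonization, or any imaging I/O — inputs are precomputed connectivity
  matrices.
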