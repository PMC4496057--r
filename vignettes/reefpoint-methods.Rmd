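---
title: "Methods: point annotation of benthic imagery with partial automation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: point annotation of benthic imagery with partial automation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefpoint)
```

## The estimation problem

Percent cover of benthic substrata (corals, algal functional groups, sand,
and so on) is routinely estimated from downward-facing survey photographs
by *random point annotation*: a fixed number of random pixel locations is
superimposed on each image and an expert assigns a substratum label to
each point. The cover of label $m$ in image $i$ for annotator $a$ is the
fraction of points carrying that label,

$$c_i^a(m) = \frac{\#\{k : y_{i,k}^a = m\}}{\#\{k\}},$$

and ecological conclusions rest on means of $c_i^a(m)$ across images.
Manual annotation is the bottleneck: a classifier can label patches
automatically, but with lower accuracy than an expert. `reefpoint`
implements the full tool chain around this trade-off: the data model and
pre-/post-processing rules, a patch classifier with per-label scores,
three deployment modes for the classifier, an agreement/error evaluation
suite, and synthetic generators so every stage can be exercised and
tested without field imagery.

## Data model and processing rules

A `labelset` is an ordered label vocabulary with named functional groups
$\Psi$ (e.g. `coral`, `macroalgae`, `CCA`, `turf`) and dataset-scoped
remap presets. `consensus_labelset()` ships the 20-label consensus
vocabulary used for multi-location reef work, including two presets:
collapsing coral genera to a generic hard-coral label (for archives that
never resolved genus) and mapping `Bare space` to crustose coralline
algae (for a location where bare rock is effectively CCA-covered).
An `annotation_set` is one annotator's table of
`(image_id, point_index, row, col, label)`; coordinates are 0-based with
row 0 at the image top (a convention we fix once, since file formats in
the wild disagree).

Two rules reflect how multi-annotator campaigns are cleaned in practice:

* **Transect hardware.** Annotators disagree on whether points falling on
  sampling apparatus should be labelled as hardware or as the substratum
  beneath it. `harmonize_transect_hardware()` applies a majority rule:
  when at least 2 annotators call a point hardware, all annotators'
  labels at that point become hardware. The rule is idempotent.
* **Reference rebalancing.** Training pools inherit the class proportions
  of the survey they came from. To avoid evaluating a classifier under
  the silent assumption that training and test proportions match,
  `rebalance_reference()` discards a uniform random subset of
  out-of-group (e.g. non-coral) annotations so the group's proportion
  rises by a stated relative fraction (default 10%). The discard count
  is chosen by scanning the integer counts for the achieved proportion
  closest to the target, ties toward fewer discards; for the documented
  worked example (19,566 coral / 74,634 non-coral) this keeps 66,070
  non-coral points, within a couple of counts of the published figure for
  that design, whose rounding rule is not stated — tests therefore accept
  a ±5 band.

## The automated annotator

The classifier scores a square patch centered on each point. The default
encoder summarizes **color** (per-channel mean, variance and an 8-bin
intensity histogram) and **texture** (histograms of gradient energy over
6 orientation bins at 2 dyadic smoothing scales), giving a 42-dimensional
vector; patch side length defaults to 224 px and should be reduced for
small imagery. This is a deliberately simple, documented stand-in for
heavier patch encodings (e.g. Fisher vectors over dense local
descriptors); the encoder is an object carrying `encoder_id`, `dim` and
an `encode()` closure, so alternatives plug in without touching the rest
of the pipeline. Constant patches encode to exactly zero texture energy,
and the encoding is a pure function of the patch, hence
translation-invariant; edge patches are completed by mirror reflection.

`train_classifier()` fits a one-versus-rest **linear SVM** per label
(via `e1071`/libsvm) on standardized features and collapses each binary
machine to an affine rule $s_m(x) = w_m^\top x + b_m$, so scoring is a
single matrix product and exactly reproducible. Labels in the vocabulary
that never occur in training get a $-\infty$ offset sentinel: they can
never win the argmax, matching what training on a finite reference pool
implies. The cost parameter defaults to a small grid (0.1, 1, 10) chosen
by accuracy on a held-out fifth of the training data; tie-breaking in
the argmax is by label order, which makes automated annotation fully
deterministic.

## Operational modes

**Deferral (semi-automated).** Each point receives a score vector
$[s_{i,k}]$; low, flat score vectors signal likely errors. The deferral
rule keeps the automated label only when the classifier is confident:

$$y_{i,k} = \begin{cases} y_{i,k}^{\text{auto}} & \max[s_{i,k}] > \epsilon \\ y_{i,k}^{\text{human}} & \text{otherwise,} \end{cases}$$

with a *strict* inequality, kept exactly as specified. The fraction of
automated decisions $\lambda(\epsilon)$ — the level of alleviation — is a
step function of $\epsilon$ that only changes at observed maximum
scores, so `epsilon_for_level()` scans the achievable levels and returns
the threshold nearest the target, resolving exact ties toward the
*lower* level (less automation). The endpoints are exact by
construction: the largest maximum score yields the human-only set and
anything below the smallest yields the automated-only set, which is what
`alleviation_curve()` relies on for its boundary identities. A target
level of 50% is the conventional operating point.

**Cover correction (fully automated).** The expected automated cover is
the true cover mixed through the classifier's row-stochastic confusion
matrix $Q'$: $\mathbb{E}[c^{\text{auto}}] = Q'^\top c$. Inverting the
map per image,

$$c_i^{\text{corrected}}(m) = (Q')^{-\top} c_i^{\text{auto}}(m),$$

de-biases the estimate at the price of extra variance. $Q'$ is estimated
by k-fold cross-validation (default 20 folds) on the reference pool with
folds stratified **by image**, never splitting one image's points across
the boundary, to avoid leakage between co-located patches. Numerical
choices: zero-count confusion rows are replaced by identity rows before
inversion; a $10^{-8}$ ridge on the diagonal guards the solve without
visibly perturbing well-conditioned cases; matrices with reciprocal
condition below $10^{-10}$ fall back to the Moore–Penrose pseudo-inverse
with a warning. Because confusion rows sum to one the corrected vector
still sums to one, but entries may be negative; they are returned as-is
by default since truncation would re-introduce bias in aggregate
(`clip = TRUE` clips and renormalizes for display). The equation is
applied per image, as written; an aggregate-cover path is exposed via
`abundance_mode(per_image = FALSE)` for users who prefer to correct the
pooled cover once.

**Suggestion.** `refine_suggestions()` ranks all labels by score per
point and returns the top k (default 5), ties by label order — the
interface mode in which the human picks among machine suggestions.

## Evaluation suite

Agreement is measured by **Cohen's kappa**
$\kappa = (p_o - p_e)/(1 - p_e)$ over the keys shared by two annotation
sets (points missing from either are dropped pairwise), and by the
binary **group kappa** $\kappa_\Psi$ after collapsing labels to
in-group/out-group. When both annotators are constant and identical,
$p_e = 1$ and $\kappa$ is defined as 1; constant-but-unequal inputs
raise a degenerate-case error rather than returning a misleading number.
`expected_kappa()` provides the closed-form expectation for an annotator
drawn from a known confusion matrix and prevalence, used as the analytic
oracle in the tests. Pairwise cover error uses
$d_i^a(m) = c_i^a(m) - c_i^{\text{ref}}(m)$, its per-label mean
$e^a(m)$ (the bias over images), and the mean absolute error, the mean
of $|e|$ over a chosen grouping of annotators and labels.

Inference on the $d$'s avoids normality assumptions:

* `permutation_mean_test()` is a one-sample **sign-flip permutation
  t-test** of zero mean — the natural null device for paired
  differences. For $n \le 12$ all $2^n$ sign patterns are enumerated
  exactly; otherwise random patterns are drawn with the observed pattern
  included in numerator and denominator. Two-sided p-values count
  $|t^*| \ge |t|$; with all-equal-sign data the statistic is $\pm\infty$
  and the exact p-value is the mass of the two extreme patterns. The
  companion Bonferroni threshold defaults to eight comparisons,
  $0.05/8 = 0.00625$.
* `bootstrap_percentile_t_ci()` is the **percentile-t (studentized)
  bootstrap**: the interval is
  $(\bar d - t^*_{1-\alpha/2}\,\widehat{se},\;
    \bar d - t^*_{\alpha/2}\,\widehat{se})$ with $t^*$ quantiles from
  resampled studentized means. The original sample is included as one
  replicate (its $t^* = 0$), which also guarantees the interval contains
  the sample mean; constant input yields a degenerate zero-width
  interval.

Mann-Whitney U, Kruskal-Wallis, one-sample Kolmogorov-Smirnov and
Pearson correlation are thin delegations to the stock `stats` routines
through `standard_tests()`.

## Synthetic generators: what they emulate, and what not

The synthetic module makes the whole pipeline testable without field
data by emulating three things:

* **Imagery.** `generate_mosaic()` partitions a canvas into contiguous
  regions by a nearest-seed (Voronoi) rule — chosen over blob-growth
  precisely because it admits an exact per-pixel brute-force oracle —
  and renders each region with its class's base color, an oriented
  sinusoidal texture, and additive Gaussian noise (sd 0.02). The default
  palette has four classes separated in both color and texture frequency
  so the default encoder's task is feasible but not trivial.
* **Annotators.** `simulate_annotator()` draws each point's assigned
  label from the confusion row of its true label. Simulated experts use
  diagonally dominant matrices (host-like annotators default to 0.9–0.95
  diagonal in the workflows), giving kappas in the range reported for
  trained human annotators.
* **Classifier scores.** `simulate_scores()` draws the argmax label
  through a confusion matrix and the maximum score from
  $\mathcal N(\mu_{\text{correct}}, \sigma)$ or
  $\mathcal N(\mu_{\text{error}}, \sigma)$ depending on whether the
  argmax is correct (defaults $\mu_{\text{correct}} = 1$,
  $\mu_{\text{error}} = -1$, $\sigma = 0.5$; the deferral analyses use
  $\pm 3$ for a cleanly separated regime). This encodes the premise that
  low maxima flag likely errors, which is exactly what makes deferral
  useful; setting the two means equal produces the degenerate,
  uninformative regime used to test that the selection effect vanishes.

Simulation studies follow the canonical survey design: 200 images per
location with 10 random points per image, six annotators, a 50% deferral
operating point, and a 10% relative rebalance of the focal group. What
passing these tests shows is that the estimators and modes behave as
their theory predicts on data that satisfies the generating assumptions
(independent points, class-conditional scores, row-stochastic annotator
confusion). What they cannot show is robustness to the properties of
real photoquadrats that the generators do not model: optical blur,
turbidity and lighting gradients, spatial autocorrelation of labels
beyond region boundaries, annotator drift over sessions, and patch
encoders confronted with natural texture.

## Problem sizes and numerical defaults

The bundled workflows (`run_end_to_end()`, `run_training_size_sweep()`)
default to 96-px mosaics, 6 training and 3 evaluation images with 60
points each, a 16-px encoder patch and image-stratified cross-validation
with as many folds as training images. These sizes are chosen so a full
pipeline run is a matter of seconds while every stage still has enough
data to be statistically meaningful (the holdout kappa at the default
palette separation is ~0.9); all sizes are plain `run_config()` fields.
All randomness flows from explicit seeds — there is no hidden global
generator state, and the private-stream helper restores the caller's
RNG state — so identical configs produce byte-identical reports, which
the workflow tests assert via the config hash.

## Known limitations

* The default encoder is a compact color/texture summary, not a learned
  or Fisher-vector encoding; on real imagery a stronger encoder (plugged
  in through the encoder interface) will be needed to approach expert
  agreement.
* Cover correction assumes the deployment data are drawn from the same
  distribution the confusion matrix was estimated on; under distribution
  shift $Q'$ must be re-estimated from a labelled subsample.
* Corrected covers may be negative per image; only aggregates should be
  interpreted.
* The CLI reads PNG imagery (8-bit RGB); JPEG inputs should be converted
  beforehand.
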