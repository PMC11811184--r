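---
title: "Detecting region-based feature coding in single neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting region-based feature coding in single neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regiontune)
```

## The model

Neurons in the human medial temporal lobe (MTL) respond to complex visual
objects. Two coding schemes are commonly contrasted: *category selectivity*
(a neuron fires for dogs, or for a handful of categories) and *axis coding*
(the rate varies linearly along a direction in a high-dimensional visual
feature space). `regiontune` implements a third, intermediate description:
**region-based feature coding**. Stimuli are laid out in a 2D feature
embedding (t-SNE/UMAP/PCA of deep-network features, or any precomputed 2D
layout), and a *feature neuron* is one whose firing is elevated for stimuli
falling in a contiguous region of that space — a receptive field in feature
space rather than in retinotopic space. The package detects such regions,
relates them to classical category selectivity and axis models, decodes
object category from pseudo-populations, and links regions to recognition
memory and image memorability.

Because the underlying human single-unit recordings are not generally
redistributable, the package ships a synthetic-data generator with planted
ground truth. Every analysis stage is exercised, and its operating
characteristics measured, on data whose correct answer is known.

## Tuning-region detection

For a neuron with response $r_i$ (mean firing rate 250–1250 ms after onset;
0–300 ms after fixation onset in fixation-based analyses) to stimulus $i$ at
embedding coordinate $x_i \in [0,1]^2$, the smoothed density map on a
$100 \times 100$ pixel grid is the unnormalized Gaussian kernel sum

$$m(p) = \sum_i r_i \, e^{-\lVert p - x_i \rVert^2 / 2\sigma^2}.$$

The kernel SD is $\sigma = sq$ (in units of the space side), a single
empirical scaling knob with per-dataset presets in `sq_presets` (0.021 for
the 500-object ImageNet-style layout used throughout the tests). A local
*average* estimator (dividing by the summed kernel weights) would give
identical permutation p-values, since the denominator is
permutation-invariant; the weighted sum is kept because it is the direct
smoothing of the discrete rate map.

Significance is assessed per pixel by permutation: responses are shuffled
across stimulus coordinates (`n_permutations`, default 1000), and
$p = (1 + \#\{\text{null} \ge \text{obs}\}) / (1 + N)$. The add-one
estimator never returns 0 and resolves ties conservatively — a constant
response vector yields $p = 1$ everywhere and no region. Pixels with
$p < 0.01$ within the mask are clustered (4-connectivity by default;
8 available) and clusters no larger than 2.5% of the masked pixels are
discarded. A neuron with a surviving cluster is a feature neuron.

Edge and corner pixels far from every stimulus see only kernel tails and are
false-positive prone, so a mask keeps pixels within
`mask_radius_factor` $\times\ \sigma$ (default 2, which keeps the
smoothing support inside the mask) of at least one stimulus. An optional
cluster-mass correction (`cluster_correction`) additionally requires a
cluster's summed observed density to beat the 95th percentile of the largest
null-cluster mass; it is off by default, matching the primary selection
rule.

Pixels are half-open: pixel $(i,j)$ covers $[(i-1)/R, i/R)$ per axis, so
stimulus-to-pixel assignment is unambiguous; coordinates exactly at 1 fall
in the last pixel.

## Category selectivity and its relation to regions

`classify_selectivity()` follows the classical two-step screen: a one-way
ANOVA across categories ($P < 0.05$) plus the requirement that a selected
category's mean response exceed the baseline mean by 1.5 baseline SDs.
Baseline mean and SD are computed across per-trial baseline-window
(−500–0 ms) rates: when each image appears once, trial-level SD is the only
well-defined reading of "SD during baseline", and it is what the package
uses.

Neurons with one selected category are SC; with several, MC. MC neurons are
subtyped by geometry: if all selected-category centroids fall inside one
connected cluster of the neuron's significant-pixel map — computed *without*
the minimum-cluster-size threshold, so narrow peaks are retained — the
neuron is a feature-MC neuron (categories contiguous in feature space),
otherwise non-feature-MC. The centroid-in-one-component rule is an
operationalization choice; the published description ("clustered within the
same region") does not fully pin it down.

Supporting indices: the category selectivity index
$d' = (\mu_{best} - \mu_{least}) / \sqrt{(\sigma^2_{best} +
\sigma^2_{least})/2}$ with population (divide-by-$n$) variances, the depth
of selectivity $DOS = (n - \sum_j r_j / r_{max}) / (n-1)$, and the ordered
response-ratio curve. $d'$ and DOS are scale-invariant; both are `NA` on
degenerate all-zero input rather than an error.

## Axis models

`fit_axis_model()` regresses responses on high-dimensional features with
partial least squares (SIMPLS, 10 components by default), evaluated by the
Pearson correlation between held-out predictions and observed responses for
a random 50/50 split. The null distribution re-runs the full
shuffle/split/fit/predict cycle 1000 times; the model is significant when
the observed correlation exceeds the null's 95th percentile. The observed
statistic uses a single split by default: averaging it over several splits
(available via `n_splits`) shrinks its variance relative to the single-split
null draws and drives the null selection rate from the nominal 5% toward 0,
so the calibrated single-split form is the default.

## Population decoding

`sliding_decoding()` implements the maximum-correlation-coefficient
classifier: z-score each neuron, estimate a mean template per category from
the training trials, and assign each test trial to the
highest-correlating template. Bins of 500 ms advance in 50 ms steps from
−500 ms (31 bins by default); 8-fold cross-validation is repeated 50 times.
Two choices where the protocol is silent: folds are *stratified* (random
partitioning can leave a fold without a class at small trial counts), and
z-scoring parameters come from the training folds only, to avoid leakage.
Per-bin significance against chance is the fraction of repeats at or below
chance ($1/n_{classes}$; 2% for 50 categories), FDR-corrected across bins
(Benjamini–Hochberg, $Q < 0.05$). Note this repeat-counting rule is liberal
at small repeat counts; the package also reports the full repeat-by-bin
accuracy matrix so users can apply stricter criteria.

## Memory and memorability

`score_recognition()` excludes reaction-time outliers (RT > 5 s or beyond
the session mean + 3 SD), then scores hits (old trials with response ≥ 4 on
the 1–6 scale), accuracy (hits + correct rejections) and confidence. The
confidence metric averages responses over old trials *judged old* (range
4–6) by default, since the published axis runs 4–6; averaging over all old
trials is available via `confidence_scope`.

`in_out_memory_comparison()` pairs, per feature neuron or per session
(with session-level regions formed by aggregating the session's feature
neurons' regions), the hit rate and confidence for stimuli inside versus
outside tuning regions, excluding sessions with hit rate ≤ 60%.
`matched_memorability_comparison()` repeats the comparison after restricting
out-region stimuli to memorability scores within ±2 SD of the in-region
mean, separating region effects from intrinsic memorability.
Memorability-encoding neurons are selected by a two-sided Pearson
correlation between firing rate and memorability ($P < 0.05$), with the
sign recorded — both directions carry information.
`cross_phase_analysis()` asks whether learning-phase regions predict
recognition-phase responses (for all, old-only and new-only stimuli) and
quantifies region overlap across phases as intersection over the smaller
region, calling overlap > 0.5 invariant. Whether the published overlap
denominator is the smaller region, the union, or the learning-phase region
is not stated; the smaller-region convention is the most permissive reading
of "more than 50% region overlap" and is used here.

Saccades are detected with the standard video-oculography thresholds
(velocity > 30°/s *or* acceleration > 8000°/s², sustained ≥ 4 ms, deflection
> 0.1°); fixations are the complement. The OR combination follows the
Eyelink parser the thresholds come from — an AND rule would split a
ballistic saccade where its acceleration crosses zero mid-flight.

## Statistical conventions

Two conventions were reverse-engineered from published values and frozen:

* **Binomial selection test.** With $k$ of $n$ neurons selected at chance
  $p_0 = 0.05$, the package's default p-value is the *strict* upper tail
  $P(X > k)$. The printed formula reads $P(X \ge k)$, but the strict tail
  reproduces every published value (e.g. 89/874 → 1.60 × 10⁻¹⁰, 61/453 →
  1.19 × 10⁻¹²) where the weak tail does not; the weak tail is available via
  `strict = FALSE`.
* **Proportion comparisons.** `chi2_proportions()` is the Pearson χ² with
  df = 1 and no continuity correction on the 2×2 table, with the
  subpopulation-vs-whole-population (overlapping groups) layout — this
  reproduces the published 1.79 × 10⁻⁸ for 25/89 vs 77/874. One published
  bound ($P < 10^{-20}$ for 31/116 vs 104/1162) is not reproducible under
  either layout and is treated as unreliable.

## The synthetic generator: what it does and does not emulate

`generate_stimulus_set()` places category centroids on a jittered grid
(emulating an embedding whose perplexity was tuned so objects spread
approximately homogeneously) with isotropic Gaussian clusters
(`cluster_spread` 0.03 at the default 50 × 10 layout). High-dimensional
features carry the 2D layout in their first two dimensions plus
category-structured low-variance directions, so their 2D projection matches
the coordinates. Memorability scores are Beta(4, 4) — unimodal on [0, 1],
matching the qualitative shape of real memorability distributions (no
numeric claim).

Neurons are homogeneous Poisson (baseline 5 Hz) — a minimal noise model that
makes rate recovery analytic; real MTL neurons show burstiness, adaptation
and latency structure that this does not emulate, so passing tests certify
the *procedure*, not real-data effect sizes. Planted tuning adds a Gaussian
rate bump (gain 20 Hz, width 0.08, the planted region being the 2-width
disc), a clipped linear axis drive, or a per-category gain. Recovery studies
plant each neuron's center on a randomly chosen category cluster whose
2-width disc lies wholly inside the space: a field in an empty part of the
space generates no data at one trial per stimulus, and a field clipped by the
embedding boundary loses most of its support to the mask — both are
unobservable by construction, whereas real tuning regions by definition cover
stimuli. Planting on interior clusters makes the measured detection rate a
property of the detector rather than of layout geometry. One presentation
per stimulus is the default, as in the emulated tasks; `n_trials_per_stimulus`
raises it. Memory sessions follow the phased task (100 learning images,
50 old + 50 new recognition trials, 1–6 confidence responses): hits follow
the logistic model
$P(\text{resp} \ge 4) = \text{logit}^{-1}(\beta_0 + \beta_{mem}\,m +
\beta_{region}\,\mathbb{1}_{in})$, with $\beta_0 = 0.85$ (~70% baseline hit
rate, clearing the 60% session filter) and null effects
($\beta_{mem} = \beta_{region} = 0$) by default; reaction times are
shifted-lognormal, right-skewed with median ≈ 1 s, so the RT-outlier filter
has something to act on. False alarms use the same linear predictor minus
`new_bias` (1.7, ≈ 30% false-alarm rate). Confidence grades come from a
latent strength; the hit probability itself is exactly the logistic model,
which is what makes coefficient recovery by `glm()` a meaningful test.

## Operating characteristics measured in the test suite

The suite (and `scripts/acceptance.R`, which recomputes everything from a
seed) measures, at the 500-stimulus/50-category scale: the analytic
reproduction of the published binomial and χ² values; a false-positive rate
of 0–2% for region detection on 200 null neurons (nominal bound 8% at the
5%-chance convention; 200 permutations, whose add-one p floor of 1/201
still resolves the 0.01 pixel threshold, stand in for the published 1000 —
p-value resolution, not the threshold, is what scales down); detection of
≥ 90% of planted interior-cluster regions with median Jaccard ≈ 0.4 against
the planted disc;
≥ 90% recovery of planted SC/feature-MC/non-feature-MC labels; a 5 ± 3%
null selection rate for axis models (200 simulations, 200 permutations);
shuffled-label decoding at the 2% chance level and perfect decoding of a
separable noise-free population; and recovery of a planted
$\beta_{region} = 1$ memory benefit at $P < 0.01$ across 50 sessions with a
calibrated null. Problem sizes (200 null neurons, 50 planted neurons,
10 decoding repeats, 200 session replicates) were chosen as the smallest
that leave the Monte-Carlo error well below each decision margin.

## Known limitations

* The kernel-size rule is under-determined in its published form
  ("proportional to the number of clusters, the dimension, and an empirical
  factor"); only the per-dataset `sq` values are published, so `sq` is the
  single exposed knob.
* Detection power depends on stimulus density: sparse sets (≪ 300 stimuli)
  fragment the mask and shrink clusters below the 2.5% threshold; the
  published protocol's 500-stimulus scale is the intended operating point.
* The feature-MC/non-feature-MC boundary inherits the centroid-in-one-
  component interpretation; neurons whose selected categories straddle a
  cluster boundary can flip subtype under small kernel changes.
* t-SNE/UMAP are delegated to optional packages; the pipeline itself is
  reducer-agnostic and all shipped tests run on `"none"`/`"pca"` paths.
* Synthetic memorability, features and behavior are stand-ins; nothing here
  validates a specific memorability model or feature extractor.
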