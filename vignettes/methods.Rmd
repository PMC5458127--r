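---
title: "Methods: sparse feature decoding and zero-shot category identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sparse feature decoding and zero-shot category identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gendecode)
```

## The decoding model

The package decodes *visual feature vectors* — the unit activations of an
image-computable feature model such as GIST or one layer of a convolutional
network — from multi-voxel fMRI activity patterns, and then identifies the
*object category* a person saw or imagined by comparing the decoded vector
with category-average feature prototypes. Because the comparison happens in
feature space, identification is zero-shot: it extends to categories never
used for decoder training.

Each feature unit $t_\ell$ gets its own linear decoder over $d$ voxels,

$$ t_\ell = \mathbf{w}^\top [\mathbf{x}; 1] + \epsilon,
   \qquad \epsilon \sim \mathcal{N}(0, \beta^{-1}), $$

with the bias absorbed as a constant regressor. Sparsity comes from an
automatic-relevance-determination (ARD) prior: each weight $w_i$ has an
individual Gaussian prior precision $\alpha_i$ with a non-informative
hyperprior, and the intractable joint posterior over
$(\mathbf{w}, \boldsymbol\alpha, \beta)$ is approximated by deterministic
iterative inference. `vb_ard()` iterates the evidence fixed point

$$ \Sigma = (\beta X^\top X + \mathrm{diag}\,\boldsymbol\alpha)^{-1},\quad
   \boldsymbol\mu = \beta\, \Sigma X^\top \mathbf{t}, \quad
   \gamma_i = 1 - \alpha_i \Sigma_{ii}, \quad
   \alpha_i \leftarrow \gamma_i / \mu_i^2, \quad
   \beta \leftarrow \frac{N - \sum_i \gamma_i}{\lVert \mathbf{t} - X\boldsymbol\mu \rVert^2}. $$

$\gamma_i \in [0,1]$ is the effective number of well-determined parameters
contributed by weight $i$. We use this update (rather than the slower
posterior-mean update $\alpha_i \leftarrow 1/(\mu_i^2+\Sigma_{ii})$, which
shares the same fixed points $\alpha_i(\mu_i^2+\Sigma_{ii})=1$ but raises
the precision of an irrelevant weight only linearly per iteration) because
it drives irrelevant precisions to infinity geometrically: pruning at
$\alpha_i > 10^8$ then completes within the default 500 iterations. Pruned
weights are exactly zero and their columns leave the active set. The
type-II log likelihood (evidence) is recorded per iteration; on all tested
problems it is non-decreasing between pruning events, and the property
suite asserts this.

Two behaviours of evidence-based ARD are worth knowing:

* **It is not an oracle.** A pure-noise regressor whose in-sample
  correlation satisfies roughly $N r^2 > 1$ passes the evidence bar and is
  retained. On noise-only training data some voxels therefore survive; the
  model is still useless for prediction (held-out correlation at chance),
  which is what the tests assert.
* **Preselection interacts with this.** Following the reference design,
  `select_voxels()` keeps the `max_voxels` voxels with the largest
  absolute Pearson correlation to the target unit (absolute rather than
  signed ranking, since a strongly anticorrelated voxel is equally
  informative for a linear readout; ties broken by ascending index, and
  zero-variance voxels score 0). Preselection feeds ARD the most
  spuriously correlated voxels under a null, which is fine — the
  identification chance level is unaffected — but it means retained-voxel
  counts are not a significance test.

Inputs and targets are z-scored with training statistics before fitting
(purely for conditioning; statistics are stored in the decoder and inverted
at prediction). The fit is deterministic given the data. The bias column
carries its own ARD precision like any other weight; with a z-scored target
its weight is ~0 and pruning it is harmless because the stored target mean
restores the offset.

## Preprocessing

Volume-wise voxel time courses are processed per run: a least-squares line
over the volume index (with intercept) is subtracted per voxel and the
residual is divided by the voxel's run mean and scaled by 100 — percent
signal change about zero. We divide rather than subtract the mean so the
output is dimensionless and scale-invariant; this is standard practice and
the chosen reading of "normalized relative to the mean amplitude". Note the
operation is not re-applicable: its output has zero run mean, and
normalising by a near-zero mean is undefined (the error path). The
*detrending* component is idempotent and tested as such.

Samples are then formed by averaging the volumes of each block window,
shifted by one volume (3 s at TR 3 s) to compensate for the hemodynamic
delay — an integer volume shift, never interpolation. Defaults: 3 volumes
per 9-s stimulus block, 5 per 15-s imagery period. Repetitions of the same
test category (35 stimulus, 10 imagery) are averaged across trials to
raise SNR before decoding.

## Identification

`build_category_bank()` averages the feature vectors of all images of a
category into one prototype row. `identify_rank()` scores candidates by
the Pearson correlation between the decoded vector and each prototype and
picks the argmax; ties break by category label order and zero-variance
prototypes rank last with a flag. Two-way (pairwise) accuracy scores every
(test item, foil) pair, counting exact ties 0.5 so a degenerate null sits
exactly at the 50% chance level; multi-way accuracy samples candidate sets
of a given size (chance $100/\text{size}$%). The exclusion list of
`sample_candidate_set()` supports removing semantic neighbours of the
target from the foil pool, supplied by the caller as explicit labels.

Pearson scores are invariant under one global affine transform applied to
both sides; they are *not* invariant under per-unit affine maps (those
reweight units), which is easy to verify and is the behaviour the tests
pin down.

## Discriminability statistics, taxonomy, GIST

Per-unit category discriminability is the one-way ANOVA F ratio of
between- to within-category mean squares; zero within-variance with
nonzero between-variance flags $+\infty$, and all-identical values give 0.
Its relation to decodability is summarised by the correlation between
per-unit accuracy and $\log_{10} F$ (F spans orders of magnitude; the
raw-F correlation is also available). Correlations are Fisher
z-transformed (clipped at $\pm(1-10^{-12})$, since synthetic data produce
exact $\pm 1$) before one-sided one-sample t-tests against chance; the
Shapiro-Wilk normality p-value is attached as a diagnostic, never as a
gate.

Semantic distance between categories is the edge count of the unique path
in a rooted taxonomy, computed from node depths via the lowest common
ancestor and cross-checked against an independent breadth-first-search
oracle in the tests. Taxonomies are strict trees (single parent); the
occasional multiple inheritance of real lexical ontologies is out of
scope, and synthetic taxonomies are random binary trees.

The GIST descriptor converts an image to luminance
($0.299R + 0.587G + 0.114B$), caps the width at 256 pixels
(aspect-preserving bilinear resize), filters with a Gabor bank — 16
orientations $\times$ 4 scales, centre frequencies $0.25/2^{s-1}$
cycles/pixel with one-octave bandwidth, applied in the frequency domain
with the DC gain forced to zero — pools response magnitudes over a
$4\times4$ grid (remainder pixels go to the last row/column of blocks),
and concatenates scale-major, then orientation, then block: $16 \times 4
\times 16 = 1{,}024$ values. Zero-mean filters make the descriptor exactly
invariant to adding a constant to the image. The precise Gabor
parameterisation (bandwidth, frequency ladder) is not dictated by the
reference description; the defaults above are conventional and documented
here once.

## The synthetic experiment generator

`synth_config()` fixes the study conditions; `simulate_experiment()`
generates a complete experiment with known ground truth. The defaults
reproduce the reference design counts exactly: 150 training categories
$\times$ 8 exemplars (1,200 single presentations, 24 runs of 50 blocks),
50 disjoint test categories shown 35 times (35 runs) and imagined 10 times
(20 runs of 25 blocks), TR 3 s, 9-s stimulus blocks, 15-s imagery periods.

The generative model: category mean features
$\mu_c \sim \mathcal{N}(0, \sigma_b^2)$ per unit, exemplar features
$\mu_c + \mathcal{N}(0, \sigma_w^2)$; a sparse encoding matrix $W$ (each
voxel loads on a fixed fraction of the units of its coupled feature
layer); stimulus volumes $x = W f_{\text{exemplar}} + \mathcal{N}(0,
\sigma_n^2)$ and imagery volumes $x = g\, W \mu_c + \mathcal{N}(0,
\sigma_n^2)$ — the imagery signal is category-level only and attenuated by
$g \in [0,1]$, emulating the weaker, prototype-like imagery response. A
per-ROI imagery onset lag supports time-resolved analyses. Signals start
one volume after block onset (a stylised hemodynamic lag matching the
one-volume analysis shift); volumes ride on a baseline of 100 so percent
signal change approximately equals the injected signal.

Desk-scale choices, made once: 2 feature layers $\times$ 16 units coupled
one-to-one to 2 ROIs $\times$ 64 voxels; $\sigma_b = 1$, $\sigma_w = 0.5$,
$\sigma_n = 2$ (per volume, in percent-signal-change units — after
35-trial averaging this is a strong but not saturating SNR); encoding
sparsity 0.2; imagery gain 0.6; 200 extra candidate categories so the
pairwise analysis has $50 \times 200 = 10{,}000$ item-by-foil
combinations per simulated experiment. Every category, including test
categories, gets 8 exemplars in the feature table while only exemplar 1
of a test category is presented in the scanner — so the category-average
prototype is genuinely distinct from the presented image, as when
prototypes come from a large annotated database. Three RNG streams are
derived from the master seed (features/taxonomy, weights, session
order/noise), so changing $\sigma_n$ never changes $W$ or the features.

What the generator does *not* emulate: hemodynamic response convolution,
spatial voxel correlations, scanner drift beyond the linear trend, and
between-subject variability. Passing tests therefore demonstrate the
correctness and internal consistency of the pipeline under the stated
generative model, not performance on real recordings.

## Statistical design of the null (chance-level) check

With all encoding weights set to zero, two-way identification must sit at
50%. The per-combination outcomes are *not* independent Bernoulli draws:
all foils for one test item are compared against the same decoded vector,
so each item contributes one rank statistic, not 200 coin flips. Under the
null the accuracy fraction is a two-sample Mann-Whitney statistic with
$n$ items and $m$ foils, with exact variance $(n + m + 1) / (12 n m)$ per
replicate experiment. The acceptance check therefore pools $R$ independent
replicate simulations and compares the pooled accuracy against 50% within
$3 \times 100\sqrt{(n+m+1)/(12 n m R)}$ percentage points — a closed-form
SE fixed by the design, about three times wider than the (inapplicable)
per-combination binomial SE.

## Numerical choices and degenerate inputs

* Convergence: maximum relative change of $\boldsymbol\mu$ below $10^{-6}$
  or 500 iterations; non-convergence is recorded in the trace and the last
  iterate returned.
* Pruning threshold $\alpha > 10^8$; pruned weights are exact zeros so
  serialised decoders are sparse and reproducible.
* Correlations over fewer than 3 observations, or with a zero-variance
  side, are undefined: they are excluded from averages and counted, never
  zero-filled.
* Voxel-selection ties break by ascending voxel index; identification ties
  by category label order; time-course peak ties by earliest offset.
* Problem sizes in the test-suite: end-to-end properties run on a reduced
  design (40 training categories $\times$ 4 exemplars, 10 test categories,
  6/4 repetitions, 8 units per layer, 32 voxels per ROI) whose generative
  structure is identical to the full design; the null chance-level check
  runs at the full reference counts.

## Known limitations

* The VB approximation is a point-precision (evidence) treatment of the
  ARD hyperparameters; posterior uncertainty over $\alpha$ is not
  propagated.
* Identification assumes prototypes live in the same feature space as the
  decoders' training targets; no cross-feature-space calibration is
  attempted.
* The time-resolved analysis decodes single volumes without temporal
  smoothing; display-style multi-volume averaging is out of scope.
* Real lexical taxonomies with multiple inheritance are not supported.
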