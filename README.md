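# gendecode

Generic object decoding from multi-voxel fMRI patterns: predict
visual-feature vectors from brain activity with sparse Bayesian linear
regression, then identify *arbitrary* object categories — including ones
never used for training — by matching the decoded vector against
category-average feature prototypes.

The package is aimed at researchers analysing (or simulating) visual
decoding experiments in which a subject views or imagines object images
while volume-wise voxel activity is recorded. It covers the whole
workflow: run-wise preprocessing, decoder training, feature decoding,
accuracy metrics, zero-shot identification, discriminability statistics,
taxonomy-based semantic-distance analyses, GIST image descriptors, and a
synthetic-experiment generator with known ground truth.

## The model

Each feature unit `t` (one scalar output of an image-computable feature
model, e.g. a GIST dimension) gets its own linear decoder over `d` voxels:

    t = wᵀ [x; 1] + ε,   ε ~ N(0, 1/β)

with an automatic-relevance-determination (ARD) prior — one Gaussian prior
precision `α_i` per weight — estimated by iterative variational/evidence
updates:

    Σ = (β XᵀX + diag(α))⁻¹,   μ = β Σ Xᵀ t,
    γ_i = 1 − α_i Σ_ii,   α_i ← γ_i / μ_i²,   β ← (N − Σ γ_i) / ‖t − Xμ‖²

Irrelevant weights have their precision driven to infinity and are pruned
to exactly zero, so each unit decoder ends up reading a sparse set of
voxels. Voxels are preselected per unit by absolute Pearson correlation
with the target (a configurable cap, 500 per visual subarea and 1,000 for
pooled regions in the reference design).

Identification then ranks candidate categories by the Pearson correlation
between the decoded feature vector and each category's average feature
vector; the argmax is the predicted category. Chance for a two-way
(true-vs-foil) comparison is 50%.

## Worked example

Simulate a small experiment with known ground truth, run the full
pipeline, and evaluate:

```r
library(gendecode)

cfg <- synth_config(n_train_categories = 40, exemplars_per_category = 4,
                    n_test_categories = 10, test_repetitions = 6,
                    imagery_repetitions = 4, n_candidate_categories = 40,
                    units_per_layer = 8, voxels_per_roi = 32,
                    stimulus_blocks_per_run = 20, imagery_blocks_per_run = 10,
                    seed = 1)
sim <- simulate_experiment(cfg)
res <- run_decoding_pipeline(sim, max_voxels = 24,
                             conditions = c("stimulus", "imagery"))

unitwise_accuracy(res$pred_stimulus, res$true_test_features)$mean_r
category_profile_accuracy(res$pred_imagery, sim$truth$bank)$mean_r
pairwise_accuracy(res$pred_stimulus, res$bank,
                  foil_labels = sim$truth$roles$candidate)$accuracy
head(identify_rank(res$pred_stimulus$values[1, ], res$bank), 3)
```

Output:

```
mean unit-wise decoding accuracy (stimulus): r = 0.850
category-profile accuracy (imagery):         r = 0.732
pairwise identification: 99.0% over 400 combinations
       category     score rank zero_variance
tst002   tst002 0.7615953    1         FALSE
cnd028   cnd028 0.7122893    2         FALSE
tst005   tst005 0.3884036    3         FALSE
```

Reading: the decoders recover the presented images' feature values with a
mean per-unit correlation of 0.85; imagery-driven activity (weaker,
category-level signal) still tracks the category prototypes at r = 0.73;
and decoded vectors identify the seen category against random database
foils 99% of the time — here the true category `tst002` is ranked first
out of 50 candidates. All decoded categories were absent from decoder
training: identification is zero-shot.

A command-line interface wrapping the same functions ships at
`inst/cli/gendecode` (subcommands `simulate`, `preprocess`, `train`,
`decode`, `evaluate`, `identify`, `timecourse`, `gist`, `report`), so the
stages can be chained through TSV files.

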