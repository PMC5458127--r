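test_that("default generator reproduces the reference design counts", {
  cfg <- synth_config(seed = 5)
  set.seed(5)
  truth <- generate_features(cfg)
  train_items <- truth$features$items$category_label %in% truth$roles$train
  expect_identical(sum(train_items), 150L * 8L)           # 1,200 exemplars
  expect_length(truth$roles$test, 50L)
  expect_length(intersect(truth$roles$train, truth$roles$test), 0L)
  # sessions: 35 x 50 stimulus test blocks, 10 x 50 imagery blocks
  set.seed(6)
  w <- generate_weights(cfg)
  sess <- generate_sessions(cfg, truth, w, include = c("test", "imagery"))
  test_blocks <- unique(paste(sess$test$meta$run_id,
                              sess$test$meta$block_id)[
                                sess$test$meta$condition == "stimulus"])
  expect_length(test_blocks, 50L * 35L)
  im_blocks <- unique(paste(sess$imagery$meta$run_id,
                            sess$imagery$meta$block_id)[
                              sess$imagery$meta$condition == "imagery"])
  expect_length(im_blocks, 50L * 10L)
  expect_identical(length(unique(sess$test$meta$run_id)), 35L)
  expect_identical(length(unique(sess$imagery$meta$run_id)), 20L)
  # trial averaging of the preprocessed test session gives 35 per category
  blocks <- extract_block_samples(sess$test, 1, 3)
  avg <- average_trials(blocks)
  expect_true(all(attr(avg, "n_trials") == 35L))
})

test_that("feature generator respects the variance structure", {
  # sd_w = 0: every exemplar equals its category mean
  cfg0 <- synth_config(within_category_sd = 0, n_train_categories = 10L,
                       n_test_categories = 5L, n_candidate_categories = 5L,
                       units_per_layer = 4L)
  set.seed(1)
  tr0 <- generate_features(cfg0)
  mu_rows <- tr0$category_means[tr0$features$items$category_label, ]
  expect_equal(unname(tr0$features$values), unname(mu_rows))
  expect_equal(unname(tr0$bank$values), unname(tr0$category_means))
  # sd_b = 0: no category signal, unit F statistics near 1
  cfg1 <- synth_config(between_category_sd = 0, n_train_categories = 100L,
                       n_test_categories = 10L, n_candidate_categories = 0L,
                       units_per_layer = 8L)
  set.seed(2)
  tr1 <- generate_features(cfg1)
  f <- unit_f_statistic(tr1$features)
  # mean of F(k-1, n-k) is (n-k)/(n-k-2), ~1; check each unit's F is not
  # extreme under the null (99.9% band)
  k <- length(unique(tr1$features$items$category_label))
  n <- nrow(tr1$features$values)
  expect_true(all(f < qf(0.999, k - 1, n - k)))
  expect_gt(mean(f), 0.8); expect_lt(mean(f), 1.3)
})

test_that("weights respect coupling and sparsity; null world has zero
          voxel-feature correlation", {
  cfg <- small_synth_config()
  set.seed(3)
  w <- generate_weights(cfg)
  roi <- rep(unname(cfg$layer_roi_coupling), each = cfg$voxels_per_roi)
  layer <- rep(names(cfg$layer_roi_coupling), each = cfg$units_per_layer)
  # voxels only load on their coupled layer
  expect_true(all(w[roi == "ROI1", layer == "layer2"] == 0))
  expect_true(all(w[roi == "ROI2", layer == "layer1"] == 0))
  # per-voxel active count matches the sparsity target exactly
  nact <- rowSums(w[roi == "ROI1", layer == "layer1"] != 0)
  expect_true(all(nact == round(cfg$encoding_sparsity * cfg$units_per_layer)))

  # null world: voxel activity uncorrelated with features
  cfg0 <- small_synth_config(encoding_scale = 0, seed = 21)
  sim <- simulate_experiment(cfg0, include = "train")
  expect_true(all(sim$truth$w == 0))
  blocks <- extract_block_samples(preprocess_runs(sim$sessions$train), 1, 3)
  f <- sim$truth$features
  fv <- f$values[match(blocks$meta$sample_id, f$items$item_id), 1]
  rs <- suppressWarnings(as.vector(cor(blocks$values, fv)))
  n <- nrow(blocks$values)
  expect_lt(max(abs(rs), na.rm = TRUE), 4 / sqrt(n))
})

test_that("noiseless sessions reproduce W f exactly after block averaging", {
  cfg <- small_synth_config(noise_sd = 0, imagery_gain = 1, seed = 9)
  sim <- simulate_experiment(cfg, include = c("test", "imagery"))
  blocks <- extract_block_samples(sim$sessions$test, 1,
                                  cfg$stimulus_block_volumes)
  f <- sim$truth$features
  fv <- f$values[match(blocks$meta$sample_id, f$items$item_id), , drop = FALSE]
  expected <- fv %*% t(sim$truth$w) + cfg$baseline
  expect_equal(unname(blocks$values), unname(expected), tolerance = 1e-10)
  # imagery carries the category-mean signal
  im <- extract_block_samples(sim$sessions$imagery, 1,
                              cfg$imagery_block_volumes)
  mu <- sim$truth$category_means[im$meta$category_label, , drop = FALSE]
  expect_equal(unname(im$values),
               unname(mu %*% t(sim$truth$w) + cfg$baseline),
               tolerance = 1e-10)
})

test_that("simulation streams are independent: noise level does not change
          the weights or features", {
  cfg_a <- small_synth_config(noise_sd = 0.5, seed = 33)
  cfg_b <- small_synth_config(noise_sd = 5, seed = 33)
  sim_a <- simulate_experiment(cfg_a, include = "train")
  sim_b <- simulate_experiment(cfg_b, include = "train")
  expect_identical(sim_a$truth$w, sim_b$truth$w)
  expect_identical(sim_a$truth$features$values, sim_b$truth$features$values)
  expect_identical(sim_a$truth$taxonomy$edges, sim_b$truth$taxonomy$edges)
  # same seed, same config: identical sessions
  sim_c <- simulate_experiment(cfg_a, include = "train")
  expect_identical(sim_a$sessions$train$values, sim_c$sessions$train$values)
})
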