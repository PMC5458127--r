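test_that("decoder training preserves unit order and finds encoding voxels", {
  set.seed(1)
  x <- matrix(rnorm(60 * 8), 60, 8, dimnames = list(NULL, paste0("v", 1:8)))
  feats <- make_feature_table(cbind(uA = x[, 5],                  # exact copy
                                    uB = 0.5 * x[, 2] + rnorm(60, 0, 0.1)),
                              rep(c("A", "B"), 30))
  samp <- make_block_samples(x, rep(c("A", "B"), 30))
  ds <- train_decoders(samp, feats, max_voxels = 3)
  expect_identical(ds$unit_ids, c("uA", "uB"))
  expect_identical(ds$models[[1]]$voxel_ids[1], "v5")
  expect_identical(ds$models[[2]]$voxel_ids[1], "v2")

  # item mismatch is reported with the offending ids
  feats_bad <- make_feature_table(feats$values, feats$items$category_label,
                                  item_id = paste0("x", 1:60))
  expect_error(train_decoders(samp, feats_bad, max_voxels = 3), "mismatch")
})

test_that("decoded feature tables carry sample labels through", {
  set.seed(2)
  x <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("v", 1:6)))
  feats <- make_feature_table(cbind(u1 = x[, 1], u2 = x[, 2], u3 = x[, 3]),
                              rep(c("A", "B"), 20))
  samp <- make_block_samples(x, rep(c("A", "B"), 20))
  ds <- train_decoders(samp, feats, max_voxels = 2)
  one <- make_block_samples(x[1, , drop = FALSE], "A", sample_id = "s1")
  pred <- decode_features(ds, one)
  expect_identical(dim(pred$values), c(1L, 3L))
  expect_identical(pred$items$category_label, "A")
  pred_all <- predict(ds, samp)
  expect_identical(pred_all$items$category_label,
                   samp$meta$category_label)
})

test_that("unit-wise accuracy matches hand-computed correlations", {
  truth <- make_feature_table(cbind(u1 = c(1, 2, 3, 4)), rep("A", 4))
  pred <- make_feature_table(cbind(u1 = c(2, 1, 4, 3)), rep("A", 4))
  expect_equal(unname(unitwise_accuracy(pred, truth)$per_unit), 0.6)
  # perfect and anti-perfect
  p2 <- make_feature_table(cbind(u1 = c(1, 2, 3, 4)), rep("A", 4))
  expect_equal(unname(unitwise_accuracy(p2, truth)$per_unit), 1)
  p3 <- make_feature_table(cbind(u1 = -c(1, 2, 3, 4)), rep("A", 4))
  expect_equal(unname(unitwise_accuracy(p3, truth)$per_unit), -1)
})

test_that("unit-wise accuracy is symmetric, affine-invariant, and excludes
          degenerate units with a count", {
  set.seed(3)
  tv <- matrix(rnorm(30), 10, 3)
  pv <- matrix(rnorm(30), 10, 3)
  pv[, 3] <- 5                                     # zero-variance unit
  truth <- make_feature_table(tv, rep("A", 10))
  pred <- make_feature_table(pv, rep("A", 10))
  a <- unitwise_accuracy(pred, truth)
  b <- unitwise_accuracy(truth, pred)
  expect_equal(a$per_unit, b$per_unit)
  expect_identical(a$n_undefined, 1L)
  expect_true(is.na(a$per_unit[3]))
  # positive per-unit affine rescaling leaves r unchanged
  pred2 <- make_feature_table(sweep(pv, 2, c(2, 3, 1), "*") + 7,
                              rep("A", 10))
  expect_equal(unitwise_accuracy(pred2, truth)$per_unit[1:2],
               a$per_unit[1:2], tolerance = 1e-12)
})

test_that("category-profile accuracy is exact on bank rows and flags
          constant bank columns", {
  set.seed(4)
  bankv <- matrix(rnorm(12), 3, 4)
  bank <- category_bank(bankv, c("A", "B", "C"), c(2L, 2L, 2L),
                        unit_ids = paste0("u", 1:4))
  labels <- c("B", "A", "C", "B", "A")
  pred <- feature_table(bankv[match(labels, c("A", "B", "C")), ],
                        paste0("t", 1:5), labels, unit_ids = paste0("u", 1:4))
  out <- category_profile_accuracy(pred, bank)
  expect_equal(unname(out$per_unit), rep(1, 4))
  bank0 <- category_bank(cbind(bankv[, 1:3], 2), c("A", "B", "C"),
                         c(2L, 2L, 2L), unit_ids = paste0("u", 1:4))
  out0 <- category_profile_accuracy(pred, bank0)
  expect_identical(out0$n_undefined, 1L)
})

test_that("time-resolved decoding peaks at the offset carrying the signal", {
  set.seed(5)
  nvox <- 6; nunit <- 3
  w <- matrix(rnorm(nvox * nunit), nvox, nunit)
  cats <- c("A", "B", "C")
  mu <- matrix(rnorm(nunit * 3), 3, nunit, dimnames = list(cats, NULL))
  # 3 runs, 3 blocks each; signal injected only 2 volumes after onset
  runs <- lapply(1:3, function(r) {
    series <- matrix(rnorm(nvox * 30, 0, 0.01), nvox, 30,
                     dimnames = list(paste0("v", 1:nvox), NULL))
    blocks <- data.frame(block_id = cats, category = cats,
                         onset = c(2L, 10L, 18L), n_volumes = 3L,
                         condition = "stimulus")
    for (i in 1:3)
      series[, blocks$onset[i] + 2 + 1] <-
        series[, blocks$onset[i] + 2 + 1] + as.vector(w %*% mu[i, ])
    make_run_samples(series, blocks, run_id = paste0("r", r))
  })
  vs <- voxel_samples(do.call(rbind, lapply(runs, `[[`, "values")),
                      do.call(rbind, lapply(runs, `[[`, "meta")),
                      voxel_ids = paste0("v", 1:nvox))
  feats <- feature_table(mu[rep(cats, 2), ], paste0(rep(cats, 2), "_i"),
                         rep(cats, 2), unit_ids = paste0("u", 1:nunit))
  bank <- build_category_bank(feats)
  # decoders trained directly on signal-bearing single volumes
  train <- gendecode:::.extract_blocks(vs, 2L, 1L)
  tf <- feature_table(mu[train$meta$category_label, ],
                      train$meta$sample_id, train$meta$category_label,
                      unit_ids = paste0("u", 1:nunit))
  ds <- train_decoders(train, tf, max_voxels = nvox)
  tc <- timecourse_profile(ds, vs, bank, window = 0:4)
  expect_identical(unname(tc$peak), 2L)

  # offsets that run off the end are skipped with a warning and counted
  expect_warning(tc2 <- timecourse_profile(ds, vs, bank, window = c(2L, 12L)),
                 "skipped")
  expect_gt(tc2$n_skipped[["12"]], 0)
  expect_identical(unname(tc2$peak), 2L)
})
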