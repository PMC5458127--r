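# Small in-code fixtures shared across test files.

# A volume-wise sample set with one run: `series` is a voxels x volumes
# matrix; blocks described by (block_id, category, onset, condition).
make_run_samples <- function(series, blocks, run_id = "run1",
                             tr_seconds = 3) {
  nvol <- ncol(series)
  cond <- rep("rest", nvol)
  blk <- rep(NA_character_, nvol)
  cat_l <- rep("none", nvol)
  onset <- seq_len(nvol) - 1L
  for (i in seq_len(nrow(blocks))) {
    rows <- blocks$onset[i] + seq_len(blocks$n_volumes[i]) - 1L
    cond[rows + 1L] <- blocks$condition[i]
    blk[rows + 1L] <- blocks$block_id[i]
    cat_l[rows + 1L] <- blocks$category[i]
    onset[rows + 1L] <- blocks$onset[i]
  }
  meta <- data.frame(sample_id = sprintf("%s_v%03d", run_id, seq_len(nvol) - 1L),
                     run_id = run_id, block_id = blk, category_label = cat_l,
                     condition = cond, onset_volume = onset,
                     stringsAsFactors = FALSE)
  voxel_samples(t(series), meta,
                voxel_ids = rownames(series), tr_seconds = tr_seconds)
}

# A tiny block-wise sample set with explicit values and categories.
make_block_samples <- function(values, categories,
                               sample_id = paste0("s", seq_len(nrow(values)))) {
  meta <- data.frame(sample_id = sample_id, run_id = "run1",
                     block_id = sample_id, category_label = categories,
                     condition = "stimulus",
                     onset_volume = seq_len(nrow(values)) - 1L,
                     stringsAsFactors = FALSE)
  voxel_samples(as.matrix(values), meta)
}

make_feature_table <- function(values, categories,
                               item_id = paste0("s", seq_len(nrow(values)))) {
  feature_table(as.matrix(values), item_id, categories)
}

# Scaled-down synthetic configuration for end-to-end tests: same generative
# structure as the defaults, smaller counts so a full pipeline runs in
# seconds.
small_synth_config <- function(...) {
  synth_config(n_train_categories = 40L, exemplars_per_category = 4L,
               n_test_categories = 10L, test_repetitions = 6L,
               imagery_repetitions = 4L, n_candidate_categories = 40L,
               units_per_layer = 8L, voxels_per_roi = 32L,
               stimulus_blocks_per_run = 20L, imagery_blocks_per_run = 10L,
               ...)
}
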