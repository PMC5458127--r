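#' Configuration of a synthetic decoding experiment
#'
#' Defaults reproduce the reference experimental design at desk scale: 150
#' training categories x 8 exemplars (1,200 training images, each shown
#' once), 50 disjoint test categories with 35 stimulus repetitions and 10
#' imagery repetitions, TR 3 s, 9-s stimulus blocks (3 volumes), 15-s
#' imagery periods (5 volumes), runs of 50 stimulus / 25 imagery blocks
#' (hence 24 training, 35 test and 20 imagery runs). The feature space and
#' voxel counts are desk-scale choices: 2 synthetic feature layers x 16
#' units coupled one-to-one to 2 ROIs x 64 voxels.
#'
#' @param ... Named overrides of the fields below.
#'
#' @section Fields:
#' \describe{
#'   \item{n_train_categories, exemplars_per_category}{150 x 8 training
#'     design.}
#'   \item{n_test_categories, test_repetitions, imagery_repetitions}{50
#'     held-out categories; 35 / 10 repetitions. Train and test category
#'     sets are disjoint by construction.}
#'   \item{n_candidate_categories}{Extra categories (200) populating the
#'     identification bank, standing in for a large image database.}
#'   \item{units_per_layer, layer_roi_coupling, voxels_per_roi}{Feature
#'     layers, their coupled ROIs, and voxels per ROI. Voxels of an ROI
#'     encode only units of its coupled layer.}
#'   \item{between_category_sd, within_category_sd}{SDs of category-mean and
#'     exemplar-level feature variation (1 and 0.5).}
#'   \item{noise_sd}{Volume-wise voxel noise SD in percent-signal-change
#'     units (2).}
#'   \item{encoding_sparsity, encoding_scale}{Fraction of nonzero encoding
#'     weights per voxel within its coupled layer (0.2) and the SD of the
#'     resulting clean voxel signal (1; 0 gives a null world with W = 0).}
#'   \item{imagery_gain}{Attenuation g in [0, 1] of the category-level
#'     imagery signal (0.6).}
#'   \item{imagery_onset_lag}{Per-ROI onset lag of the imagery signal, in
#'     volumes (all 0 by default).}
#'   \item{hemodynamic_lag_volumes}{Lag between block onset and signal (1
#'     volume = 3 s), matching the one-volume analysis shift.}
#'   \item{tr_seconds, stimulus_block_volumes, imagery_block_volumes}{3 s,
#'     3, 5.}
#'   \item{stimulus_blocks_per_run, imagery_blocks_per_run}{50, 25.}
#'   \item{pre_rest_volumes, post_rest_volumes, imagery_cue_volumes,
#'     imagery_post_volumes}{Rest padding and imagery trial structure, in
#'     volumes (2, 2, 1, 2).}
#'   \item{baseline}{Raw-signal baseline amplitude (100), so percent signal
#'     change approximately equals the injected signal.}
#'   \item{seed}{Master seed; independent streams are derived for features,
#'     weights and session noise, so changing `noise_sd` does not change W.}
#' }
#' @return A list of class `"synth_config"`.
#' @export
synth_config <- function(...) {
  cfg <- list(
    n_train_categories = 150L,
    exemplars_per_category = 8L,
    n_test_categories = 50L,
    test_repetitions = 35L,
    imagery_repetitions = 10L,
    n_candidate_categories = 200L,
    units_per_layer = 16L,
    voxels_per_roi = 64L,
    layer_roi_coupling = c(layer1 = "ROI1", layer2 = "ROI2"),
    between_category_sd = 1,
    within_category_sd = 0.5,
    noise_sd = 2,
    encoding_sparsity = 0.2,
    encoding_scale = 1,
    imagery_gain = 0.6,
    imagery_onset_lag = NULL,            # named per-ROI lags; NULL = all 0
    hemodynamic_lag_volumes = 1L,
    tr_seconds = 3,
    stimulus_block_volumes = 3L,
    imagery_block_volumes = 5L,
    stimulus_blocks_per_run = 50L,
    imagery_blocks_per_run = 25L,
    pre_rest_volumes = 2L,
    post_rest_volumes = 2L,
    imagery_cue_volumes = 1L,
    imagery_post_volumes = 2L,
    baseline = 100,
    seed = 1L)
  over <- list(...)
  cfg <- .merge_config(cfg, over, "synth_config")
  rois <- unname(cfg$layer_roi_coupling)
  if (is.null(cfg$imagery_onset_lag))
    cfg$imagery_onset_lag <- stats::setNames(rep(0L, length(rois)), rois)
  with(cfg, {
    stopifnot(between_category_sd >= 0, within_category_sd >= 0,
              noise_sd >= 0, encoding_sparsity >= 0, encoding_sparsity <= 1,
              imagery_gain >= 0, imagery_gain <= 1, baseline > 0)
  })
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic experiment config:\n")
  cat("  training:", x$n_train_categories, "categories x",
      x$exemplars_per_category, "exemplars\n")
  cat("  test:", x$n_test_categories, "categories,", x$test_repetitions,
      "stimulus /", x$imagery_repetitions, "imagery repetitions\n")
  cat("  layers:", paste(names(x$layer_roi_coupling), collapse = ", "),
      "->", paste(x$layer_roi_coupling, collapse = ", "),
      "(", x$units_per_layer, "units,", x$voxels_per_roi, "voxels each )\n")
  cat("  sd_b =", x$between_category_sd, " sd_w =", x$within_category_sd,
      " sd_n =", x$noise_sd, " gain =", x$imagery_gain, "\n")
  invisible(x)
}

.layer_of_units <- function(cfg) {
  rep(names(cfg$layer_roi_coupling), each = cfg$units_per_layer)
}

.unit_ids <- function(cfg) {
  paste0(.layer_of_units(cfg), "_u",
         sprintf("%02d", rep(seq_len(cfg$units_per_layer),
                             length(cfg$layer_roi_coupling))))
}

.roi_of_voxels <- function(cfg) {
  rep(unname(cfg$layer_roi_coupling), each = cfg$voxels_per_roi)
}

.voxel_ids <- function(cfg) {
  paste0(.roi_of_voxels(cfg), "_v",
         sprintf("%03d", rep(seq_len(cfg$voxels_per_roi),
                             length(cfg$layer_roi_coupling))))
}

# Random strict binary taxonomy over the category labels.
.random_binary_tree <- function(labels) {
  groups <- as.list(labels)
  edges <- list()
  next_id <- 1L
  while (length(groups) > 1) {
    pick <- sample(length(groups), 2)
    node <- sprintf("node%04d", next_id); next_id <- next_id + 1L
    edges[[length(edges) + 1L]] <-
      data.frame(parent = node,
                 child = c(groups[[pick[1]]][1], groups[[pick[2]]][1]),
                 stringsAsFactors = FALSE)
    merged <- node
    groups[[pick[1]]] <- merged
    groups[[pick[2]]] <- NULL
  }
  taxonomy(do.call(rbind, edges))
}

#' Generate category-structured feature vectors, bank and taxonomy
#'
#' Category mean features are drawn Normal(0, sd_b^2) per unit; exemplar
#' features are the category mean plus Normal(0, sd_w^2) noise. Training
#' categories get `exemplars_per_category` exemplars, test categories one
#' (the single test image of each category), candidate categories
#' `exemplars_per_category`. The category-average bank is recomputed from
#' the exemplars, and a random binary taxonomy is grown over all category
#' labels. Reproducible given the RNG state.
#'
#' @param cfg A [synth_config()].
#' @return List with `features` (all exemplars), `bank`, `taxonomy`,
#'   `category_means` (matrix), and `roles` (labels by train/test/candidate
#'   role).
#' @export
generate_features <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  units <- .unit_ids(cfg)
  nu <- length(units)
  roles <- list(
    train = sprintf("trn%03d", seq_len(cfg$n_train_categories)),
    test = sprintf("tst%03d", seq_len(cfg$n_test_categories)),
    candidate = if (cfg$n_candidate_categories > 0)
      sprintf("cnd%03d", seq_len(cfg$n_candidate_categories))
    else character(0))
  cats <- unlist(roles, use.names = FALSE)
  mu <- matrix(stats::rnorm(length(cats) * nu, 0, cfg$between_category_sd),
               length(cats), nu, dimnames = list(cats, units))
  # every category gets the same number of exemplars; only exemplar 1 of a
  # test category is ever presented, so its category-average bank row is a
  # genuine prototype distinct from the presented image
  nex <- stats::setNames(rep(cfg$exemplars_per_category, length(cats)), cats)
  item_cat <- rep(cats, nex)
  item_id <- paste0(item_cat, "_ex",
                    unlist(lapply(nex, seq_len), use.names = FALSE))
  ex <- mu[item_cat, , drop = FALSE] +
    matrix(stats::rnorm(length(item_cat) * nu, 0, cfg$within_category_sd),
           length(item_cat), nu)
  features <- feature_table(ex, item_id, item_cat, unit_ids = units)
  list(features = features,
       bank = build_category_bank(features),
       taxonomy = .random_binary_tree(cats),
       category_means = mu,
       roles = roles)
}

#' Generate sparse encoding weights
#'
#' Voxels of each ROI linearly encode a sparse random subset (fraction
#' `encoding_sparsity`) of the units of the coupled feature layer, with
#' Gaussian weights scaled so the clean signal `W f` has SD approximately
#' `encoding_scale` under the feature distribution. `encoding_scale = 0`
#' yields the null world W = 0.
#'
#' @param cfg A [synth_config()].
#' @return Matrix W, voxels x units, with voxel/unit dimnames.
#' @export
generate_weights <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  units <- .unit_ids(cfg); voxels <- .voxel_ids(cfg)
  ulayer <- .layer_of_units(cfg)
  vroi <- .roi_of_voxels(cfg)
  w <- matrix(0, length(voxels), length(units),
              dimnames = list(voxels, units))
  fvar <- cfg$between_category_sd^2 + cfg$within_category_sd^2
  for (layer in names(cfg$layer_roi_coupling)) {
    roi <- cfg$layer_roi_coupling[[layer]]
    vi <- which(vroi == roi); ui <- which(ulayer == layer)
    nact <- max(1L, round(cfg$encoding_sparsity * length(ui)))
    sc <- cfg$encoding_scale / sqrt(nact * fvar)
    for (v in vi) {
      sel <- sample(ui, nact)
      w[v, sel] <- stats::rnorm(nact) * sc
    }
  }
  w
}

# Build one volume-wise session (train/test: stimulus; imagery).
.build_session <- function(cfg, w, feats_by_block, cats_by_block, condition,
                           blocks_per_run, block_volumes, cue_volumes,
                           post_block_volumes, roi_lags) {
  voxels <- rownames(w)
  vroi <- .roi_of_voxels(cfg)
  nblocks <- length(cats_by_block)
  nruns <- nblocks / blocks_per_run
  stopifnot(nruns == round(nruns))
  per_block <- cue_volumes + block_volumes + post_block_volumes
  nvol <- cfg$pre_rest_volumes + blocks_per_run * per_block +
    cfg$post_rest_volumes
  lag <- cfg$hemodynamic_lag_volumes
  vlist <- vector("list", nruns); mlist <- vector("list", nruns)
  for (r in seq_len(nruns)) {
    run_id <- sprintf("%s_run%02d", condition, r)
    bidx <- (r - 1) * blocks_per_run + seq_len(blocks_per_run)
    sig <- matrix(0, nvol, length(voxels))
    cond <- rep("rest", nvol)
    blk <- rep(NA_character_, nvol)
    cat_l <- rep("none", nvol)
    onset <- seq_len(nvol) - 1L
    for (j in seq_len(blocks_per_run)) {
      b <- bidx[j]
      start <- cfg$pre_rest_volumes + (j - 1) * per_block   # 0-based
      on <- start + cue_volumes
      rows <- on + seq_len(block_volumes) - 1L
      cond[rows + 1L] <- condition
      blk[rows + 1L] <- names(cats_by_block)[b]
      cat_l[rows + 1L] <- cats_by_block[b]
      onset[rows + 1L] <- on
      clean <- as.vector(w %*% feats_by_block[b, ])
      for (roi in unique(vroi)) {
        rl <- if (!is.null(roi_lags) && roi %in% names(roi_lags))
          roi_lags[[roi]] else 0L
        srows <- on + lag + rl + seq_len(block_volumes) - 1L
        srows <- srows[srows < nvol]
        vsel <- vroi == roi
        sig[srows + 1L, vsel] <- sig[srows + 1L, vsel] +
          rep(clean[vsel], each = length(srows))
      }
    }
    noise <- matrix(stats::rnorm(nvol * length(voxels)), nvol) * cfg$noise_sd
    vlist[[r]] <- cfg$baseline + sig + noise
    mlist[[r]] <- data.frame(
      sample_id = sprintf("%s_v%03d", run_id, seq_len(nvol) - 1L),
      run_id = run_id, block_id = blk, category_label = cat_l,
      condition = cond, onset_volume = onset, stringsAsFactors = FALSE)
  }
  voxel_samples(do.call(rbind, vlist), do.call(rbind, mlist),
                voxel_ids = voxels, tr_seconds = cfg$tr_seconds)
}

#' Generate volume-wise fMRI sessions from ground truth
#'
#' Builds the training, test and imagery sessions as volume-wise
#' [voxel_samples()]. Stimulus volumes carry `x = W f_exemplar + noise`
#' around the baseline, starting `hemodynamic_lag_volumes` after block
#' onset; imagery volumes carry the attenuated category-level signal
#' `g W mu_c + noise` with an additional per-ROI onset lag. Presentation
#' order is randomised per run (each test/imagery run cycles through all
#' test categories). Reproducible given the RNG state.
#'
#' @param cfg A [synth_config()].
#' @param truth Output of [generate_features()].
#' @param w Encoding weights from [generate_weights()].
#' @param include Which sessions to build (default all three).
#' @return Named list of volume-wise [voxel_samples()] objects.
#' @export
generate_sessions <- function(cfg, truth, w,
                              include = c("train", "test", "imagery")) {
  stopifnot(inherits(cfg, "synth_config"))
  out <- list()
  feats <- truth$features
  if ("train" %in% include) {
    ids <- feats$items$item_id[feats$items$category_label %in%
                                 truth$roles$train]
    ord <- sample(ids)
    fb <- feats$values[match(ord, feats$items$item_id), , drop = FALSE]
    cats <- stats::setNames(
      feats$items$category_label[match(ord, feats$items$item_id)], ord)
    out$train <- .build_session(cfg, w, fb, cats, "stimulus",
                                cfg$stimulus_blocks_per_run,
                                cfg$stimulus_block_volumes, 0L, 0L, NULL)
  }
  if ("test" %in% include) {
    test_items <- paste0(truth$roles$test, "_ex1")   # one image per category
    ord <- unlist(lapply(seq_len(cfg$test_repetitions),
                         function(i) sample(test_items)))
    fb <- feats$values[match(ord, feats$items$item_id), , drop = FALSE]
    cats <- stats::setNames(
      feats$items$category_label[match(ord, feats$items$item_id)], ord)
    out$test <- .build_session(cfg, w, fb, cats, "stimulus",
                               cfg$stimulus_blocks_per_run,
                               cfg$stimulus_block_volumes, 0L, 0L, NULL)
  }
  if ("imagery" %in% include) {
    ord <- unlist(lapply(seq_len(cfg$imagery_repetitions),
                         function(i) sample(truth$roles$test)))
    fb <- cfg$imagery_gain *
      truth$category_means[ord, , drop = FALSE]
    cats <- stats::setNames(ord, ord)
    out$imagery <- .build_session(cfg, w, fb, cats, "imagery",
                                  cfg$imagery_blocks_per_run,
                                  cfg$imagery_block_volumes,
                                  cfg$imagery_cue_volumes,
                                  cfg$imagery_post_volumes,
                                  cfg$imagery_onset_lag)
  }
  out
}

#' Simulate a complete synthetic decoding experiment
#'
#' Master wrapper: derives independent RNG streams from the master seed for
#' (1) features/taxonomy, (2) encoding weights and (3) session order/noise,
#' then generates everything. Changing `noise_sd` therefore leaves the
#' features and weights untouched.
#'
#' @param cfg A [synth_config()].
#' @param include Sessions to build (default all).
#' @return Object of class `"gd_simulation"`: `cfg`, `truth` (features,
#'   bank, taxonomy, category means, roles, weights `w`), and `sessions`.
#' @export
simulate_experiment <- function(cfg = synth_config(),
                                include = c("train", "test", "imagery")) {
  stopifnot(inherits(cfg, "synth_config"))
  seed <- as.integer(cfg$seed) %% 2100000000L
  set.seed(seed)
  truth <- generate_features(cfg)
  set.seed(seed + 1000003L)
  w <- generate_weights(cfg)
  set.seed(seed + 2000003L)
  sessions <- generate_sessions(cfg, truth, w, include = include)
  truth$w <- w
  structure(list(cfg = cfg, truth = truth, sessions = sessions),
            class = "gd_simulation")
}

#' @export
print.gd_simulation <- function(x, ...) {
  cat("Synthetic decoding experiment (seed", x$cfg$seed, ")\n")
  for (s in names(x$sessions))
    cat("  ", s, ": ", nrow(x$sessions[[s]]$values), " volumes x ",
        ncol(x$sessions[[s]]$values), " voxels\n", sep = "")
  invisible(x)
}

#' Run the full decoding pipeline on a simulated experiment
#'
#' Preprocesses each session (run-wise detrend/normalise, one-volume shift,
#' block averaging), trains one ARD decoder per unit on the training
#' session, decodes trial-averaged test (and optionally imagery) samples,
#' and assembles the identification bank over the test + candidate
#' categories.
#'
#' @param sim A `"gd_simulation"`.
#' @param max_voxels Voxel cap for preselection (default 50, desk scale).
#' @param max_iterations,tol,prune_alpha Passed to [vb_ard()].
#' @param conditions Which test conditions to decode
#'   (`"stimulus"`, `"imagery"`).
#' @return List: `decoders`, `pred_stimulus` (and `pred_imagery`),
#'   `true_test_features`, `bank` (test + candidate categories),
#'   `train_samples`.
#' @export
run_decoding_pipeline <- function(sim, max_voxels = 50L,
                                  max_iterations = 500L, tol = 1e-6,
                                  prune_alpha = 1e8,
                                  conditions = "stimulus") {
  stopifnot(inherits(sim, "gd_simulation"))
  cfg <- sim$cfg
  shift <- cfg$hemodynamic_lag_volumes
  feats <- sim$truth$features
  tr_blocks <- extract_block_samples(preprocess_runs(sim$sessions$train),
                                     shift, cfg$stimulus_block_volumes)
  tr_feats <- .subset_features(feats, tr_blocks$meta$sample_id)
  decoders <- train_decoders(tr_blocks, tr_feats, max_voxels = max_voxels,
                             max_iterations = max_iterations, tol = tol,
                             prune_alpha = prune_alpha)
  idbank <- .subset_bank(sim$truth$bank,
                         c(sim$truth$roles$test, sim$truth$roles$candidate))
  out <- list(decoders = decoders, bank = idbank, train_samples = tr_blocks)
  if ("stimulus" %in% conditions) {
    te_blocks <- extract_block_samples(preprocess_runs(sim$sessions$test),
                                       shift, cfg$stimulus_block_volumes)
    te_avg <- average_trials(te_blocks)
    out$pred_stimulus <- decode_features(decoders, te_avg)
    # true features of the single test exemplar per category, keyed by the
    # category label so they align with the trial-averaged predictions
    tf <- .subset_features(feats, unique(te_blocks$meta$sample_id))
    out$true_test_features <- feature_table(
      tf$values, tf$items$category_label, tf$items$category_label,
      unit_ids = tf$unit_ids)
  }
  if ("imagery" %in% conditions && !is.null(sim$sessions$imagery)) {
    im_blocks <- extract_block_samples(preprocess_runs(sim$sessions$imagery),
                                       shift, cfg$imagery_block_volumes)
    out$pred_imagery <- decode_features(decoders, average_trials(im_blocks))
  }
  out
}

.subset_features <- function(features, item_ids) {
  m <- match(item_ids, features$items$item_id)
  if (anyNA(m)) stop("unknown item(s): ",
                     paste(utils::head(item_ids[is.na(m)], 5), collapse = ", "))
  feature_table(features$values[m, , drop = FALSE],
                features$items$item_id[m],
                features$items$category_label[m],
                unit_ids = features$unit_ids)
}

.subset_bank <- function(bank, labels) {
  m <- match(labels, bank$category_labels)
  if (anyNA(m)) stop("unknown bank label(s)")
  category_bank(bank$values[m, , drop = FALSE], labels, bank$n_items[m],
                unit_ids = bank$unit_ids)
}
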