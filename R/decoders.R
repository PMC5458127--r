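#' Train one ARD decoder per feature unit
#'
#' For every unit of the training feature table: preselect the voxels most
#' correlated with that unit over the training samples ([select_voxels()]),
#' then fit a VB-ARD sparse linear model ([vb_ard()]). Samples and feature
#' items are aligned 1:1 by `sample_id` / `item_id`. The fit is
#' deterministic given the inputs.
#'
#' @param samples Block-wise training [voxel_samples()].
#' @param features Training [feature_table()] (one row per training item).
#' @param max_voxels Voxel cap for preselection (500 per subarea, 1000 for
#'   pooled regions in the reference design).
#' @param max_iterations,tol,prune_alpha Passed to [vb_ard()].
#' @return An object of class `"decoder_set"`: `unit_ids`, a list of
#'   `"vb_ard"` models, and training metadata (caps, configuration hash).
#' @export
train_decoders <- function(samples, features, max_voxels = 500L,
                           max_iterations = 500L, tol = 1e-6,
                           prune_alpha = 1e8) {
  stopifnot(inherits(samples, "voxel_samples"),
            inherits(features, "feature_table"))
  sid <- samples$meta$sample_id
  fid <- features$items$item_id
  unmatched <- c(setdiff(sid, fid), setdiff(fid, sid))
  if (length(unmatched) || length(sid) != length(fid))
    stop("sample/feature item mismatch: ",
         paste(utils::head(unique(unmatched), 10), collapse = ", "),
         if (length(unique(unmatched)) > 10) ", ..." else "")
  fvals <- features$values[match(sid, fid), , drop = FALSE]

  x <- samples$values
  models <- vector("list", ncol(fvals))
  for (k in seq_len(ncol(fvals))) {
    t_k <- fvals[, k]
    sel <- select_voxels(x, t_k, max_voxels = max_voxels)
    models[[k]] <- vb_ard(x[, sel, drop = FALSE], t_k,
                          max_iterations = max_iterations, tol = tol,
                          prune_alpha = prune_alpha,
                          voxel_ids = samples$voxel_ids[sel])
  }
  cfg <- list(max_voxels = as.integer(max_voxels),
              max_iterations = as.integer(max_iterations),
              tol = tol, prune_alpha = prune_alpha)
  structure(list(unit_ids = features$unit_ids,
                 models = models,
                 meta = c(cfg, list(n_train = nrow(x),
                                    config_hash = config_hash(cfg)))),
            class = "decoder_set")
}

#' @export
print.decoder_set <- function(x, ...) {
  nret <- vapply(x$models, function(m)
    sum(m$active[seq_along(m$voxel_ids)]), 0L)
  cat("Decoder set:", length(x$unit_ids), "unit decoders",
      "(median", stats::median(nret), "voxels retained)\n")
  invisible(x)
}

#' Decode feature vectors from voxel samples
#'
#' Applies every unit decoder to each sample, producing a predicted feature
#' table that carries the samples' item and category labels.
#'
#' @param decoders A `"decoder_set"` from [train_decoders()].
#' @param samples A [voxel_samples()] object (typically trial-averaged).
#' @return A [feature_table()] of predicted feature values.
#' @export
decode_features <- function(decoders, samples) {
  stopifnot(inherits(decoders, "decoder_set"),
            inherits(samples, "voxel_samples"))
  preds <- vapply(decoders$models, function(m) predict(m, samples$values),
                  numeric(nrow(samples$values)))
  if (nrow(samples$values) == 1L)
    preds <- matrix(preds, nrow = 1)
  colnames(preds) <- decoders$unit_ids
  feature_table(preds, samples$meta$sample_id, samples$meta$category_label,
                unit_ids = decoders$unit_ids)
}

#' @rdname decode_features
#' @param object,... Method arguments (`predict(decoders, samples)`).
#' @export
predict.decoder_set <- function(object, samples, ...) {
  decode_features(object, samples)
}

# Internal: column-wise Pearson r between two matrices, NA where either
# column has zero variance or there are fewer than 3 observations (r over
# two points is always +/-1 and carries no information).
.colwise_cor <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  if (nrow(a) < 3) return(rep(NA_real_, ncol(a)))
  suppressWarnings(vapply(seq_len(ncol(a)), function(j) {
    sa <- stats::sd(a[, j]); sb <- stats::sd(b[, j])
    if (is.na(sa) || is.na(sb) || sa == 0 || sb == 0) return(NA_real_)
    stats::cor(a[, j], b[, j])
  }, 0))
}

#' Unit-wise decoding accuracy
#'
#' Pearson correlation between true and predicted values of each feature
#' unit across items, plus the mean over units — the primary decoding
#' accuracy metric. Units with zero variance on either side are recorded as
#' undefined (`NA`) and excluded from the mean; their count is reported.
#'
#' @param pred,truth [feature_table()] objects with matching items (aligned
#'   by `item_id`) and units.
#' @return List with `per_unit` (named vector of r), `mean_r`, and
#'   `n_undefined`.
#' @export
unitwise_accuracy <- function(pred, truth) {
  stopifnot(inherits(pred, "feature_table"), inherits(truth, "feature_table"))
  if (!identical(sort(pred$unit_ids), sort(truth$unit_ids)))
    stop("unit sets differ between pred and truth")
  if (nrow(pred$values) < 3) stop("need at least 3 items")
  m <- match(pred$items$item_id, truth$items$item_id)
  if (anyNA(m)) stop("items differ between pred and truth")
  tv <- truth$values[m, pred$unit_ids, drop = FALSE]
  r <- .colwise_cor(pred$values, tv)
  names(r) <- pred$unit_ids
  list(per_unit = r, mean_r = mean(r, na.rm = TRUE),
       n_undefined = sum(is.na(r)))
}

#' Category-profile decoding accuracy
#'
#' For each unit, the Pearson correlation between the predicted series over
#' test trials and the category-average feature values of the corresponding
#' labelled categories — the accuracy metric for category-average feature
#' prediction (and the only one available for imagery, where no ground-truth
#' image exists).
#'
#' @param pred Predicted [feature_table()] (one row per test trial or
#'   trial-averaged category).
#' @param bank A [category_bank()] containing every labelled category.
#' @param labels Category labels per row of `pred` (default: its own item
#'   labels).
#' @return List with `per_unit` r, `mean_r`, `n_undefined`.
#' @export
category_profile_accuracy <- function(pred, bank,
                                      labels = pred$items$category_label) {
  stopifnot(inherits(pred, "feature_table"), inherits(bank, "category_bank"))
  m <- match(labels, bank$category_labels)
  if (anyNA(m))
    stop("label(s) not in bank: ",
         paste(utils::head(unique(labels[is.na(m)]), 5), collapse = ", "))
  bu <- match(pred$unit_ids, bank$unit_ids)
  if (anyNA(bu)) stop("unit sets differ between pred and bank")
  bv <- bank$values[m, bu, drop = FALSE]
  r <- .colwise_cor(pred$values, bv)
  names(r) <- pred$unit_ids
  list(per_unit = r, mean_r = mean(r, na.rm = TRUE),
       n_undefined = sum(is.na(r)))
}

#' Time-resolved category-profile accuracy
#'
#' Decodes from the single volume at each offset around the block onset
#' (volume-wise, non-averaged input; no temporal smoothing) and computes the
#' category-profile accuracy at every offset, per decoder group (e.g. one
#' decoder set per feature layer). Blocks whose probed volume falls outside
#' their run are skipped with a warning and counted.
#'
#' @param decoders A `"decoder_set"` or a named list of decoder sets.
#' @param volumewise Volume-wise, preprocessed [voxel_samples()].
#' @param bank A [category_bank()].
#' @param window Integer vector of volume offsets relative to block onset.
#' @param average_by_category Average same-category samples before decoding
#'   (default `TRUE`, matching the trial-averaged analysis).
#' @return Object of class `"gd_timecourse"`: matrix `r` (offsets x groups
#'   of mean per-unit r), `peak` (named vector of peak offsets, earliest on
#'   ties), and `n_skipped` per offset.
#' @export
timecourse_profile <- function(decoders, volumewise, bank,
                               window = -2:8, average_by_category = TRUE) {
  if (inherits(decoders, "decoder_set")) decoders <- list(all = decoders)
  stopifnot(all(vapply(decoders, inherits, TRUE, "decoder_set")))
  if (is.null(names(decoders)))
    names(decoders) <- paste0("group", seq_along(decoders))
  window <- as.integer(window)
  r <- matrix(NA_real_, length(window), length(decoders),
              dimnames = list(as.character(window), names(decoders)))
  skipped <- stats::setNames(integer(length(window)), as.character(window))
  for (i in seq_along(window)) {
    vols <- tryCatch(
      .extract_blocks(volumewise, shift_volumes = window[i],
                      volumes_per_block = 1L, on_oob = "skip"),
      error = function(e) NULL)
    if (is.null(vols)) { skipped[i] <- NA_integer_; next }
    skipped[i] <- attr(vols, "n_skipped")
    if (skipped[i] > 0)
      warning(skipped[i], " block(s) skipped at offset ", window[i],
              " (window outside run)", call. = FALSE)
    smp <- if (average_by_category) average_trials(vols) else vols
    for (g in seq_along(decoders)) {
      pred <- decode_features(decoders[[g]], smp)
      r[i, g] <- category_profile_accuracy(pred, bank)$mean_r
    }
  }
  peak <- vapply(seq_along(decoders), function(g) {
    ok <- which(!is.na(r[, g]))
    window[ok[which.max(r[ok, g])]]       # which.max takes the earliest tie
  }, 0L)
  names(peak) <- names(decoders)
  structure(list(r = r, peak = peak, n_skipped = skipped, window = window),
            class = "gd_timecourse")
}

#' @export
print.gd_timecourse <- function(x, ...) {
  cat("Time-resolved profile accuracy over offsets",
      min(x$window), "..", max(x$window), "volumes\n")
  cat("  peak offset per group:",
      paste(names(x$peak), x$peak, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.gd_timecourse <- function(x, ...) {
  graphics::matplot(x$window, x$r, type = "b", pch = 16, lty = 1,
                    xlab = "volumes from onset",
                    ylab = "mean profile correlation", ...)
  graphics::legend("topright", colnames(x$r), col = seq_len(ncol(x$r)),
                   lty = 1, pch = 16, bty = "n")
  invisible(x)
}
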