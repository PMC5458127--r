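#' Within-run linear detrending and percent-signal-change normalisation
#'
#' For each voxel, a least-squares line over the volume index (including its
#' intercept) is subtracted from the time course and the residual is divided
#' by the voxel's original run mean and multiplied by 100, yielding percent
#' signal change about zero. Each voxel's output therefore has (numerically)
#' zero mean within the run.
#'
#' @param run_values Numeric matrix, voxels x volumes, raw amplitudes of one
#'   run (arbitrary positive units).
#' @return Matrix of the same shape in percent-signal-change units.
#' @export
detrend_normalize_run <- function(run_values) {
  run_values <- as.matrix(run_values)
  nvol <- ncol(run_values)
  if (nvol < 3) stop("need at least 3 volumes per run, got ", nvol)
  mu <- rowMeans(run_values)
  if (any(mu <= 0))
    stop("normalisation undefined: voxel run mean <= 0 (voxel ",
         which(mu <= 0)[1], ")")
  x <- seq_len(nvol) - 1
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  slope <- (run_values %*% xc) / sxx
  resid <- run_values - mu - slope %*% rbind(xc)
  100 * resid / mu
}

# Internal: detrending only (subtract LS line incl. intercept), no
# normalisation. Idempotent; used by the property tests.
.detrend_run <- function(run_values) {
  run_values <- as.matrix(run_values)
  nvol <- ncol(run_values)
  x <- seq_len(nvol) - 1
  xc <- x - mean(x)
  slope <- (run_values %*% xc) / sum(xc^2)
  run_values - rowMeans(run_values) - slope %*% rbind(xc)
}

#' Apply run-wise detrending/normalisation to a volume-wise sample set
#'
#' Convenience wrapper that applies [detrend_normalize_run()] to each run of
#' a volume-wise [voxel_samples()] object.
#'
#' @param samples A volume-wise [voxel_samples()] object.
#' @return A [voxel_samples()] object with normalised values.
#' @export
preprocess_runs <- function(samples) {
  stopifnot(inherits(samples, "voxel_samples"))
  out <- samples$values
  for (r in unique(samples$meta$run_id)) {
    idx <- which(samples$meta$run_id == r)
    out[idx, ] <- t(detrend_normalize_run(t(samples$values[idx, , drop = FALSE])))
  }
  samples$values <- out
  samples
}

# Internal workhorse for block extraction; on_oob = "skip" drops blocks whose
# window leaves the run (used by the time-resolved analysis) and reports the
# count in attr(, "n_skipped").
.extract_blocks <- function(samples, shift_volumes, volumes_per_block,
                            on_oob = c("error", "skip")) {
  on_oob <- match.arg(on_oob)
  stopifnot(inherits(samples, "voxel_samples"))
  meta <- samples$meta
  keep <- meta$condition != "rest"
  rows <- list(); mrows <- list(); skipped <- 0L
  for (r in unique(meta$run_id[keep])) {
    ridx <- which(meta$run_id == r)           # consecutive volumes of the run
    bmeta <- meta[ridx, ]
    binrun <- which(bmeta$condition != "rest")
    for (g in split(binrun, paste(bmeta$block_id[binrun],
                                  bmeta$onset_volume[binrun]))) {
      onset <- bmeta$onset_volume[g[1]]
      win <- onset + shift_volumes + seq_len(volumes_per_block) - 1
      if (min(win) < 0 || max(win) >= length(ridx)) {
        if (on_oob == "skip") { skipped <- skipped + 1L; next }
        stop("block '", bmeta$block_id[g[1]], "' in run ", r,
             ": window [", min(win), ",", max(win),
             "] exceeds run boundary (", length(ridx), " volumes)")
      }
      vals <- samples$values[ridx[win + 1L], , drop = FALSE]
      rows[[length(rows) + 1L]] <- colMeans(vals)
      mrows[[length(mrows) + 1L]] <-
        data.frame(sample_id = bmeta$block_id[g[1]],
                   run_id = r,
                   block_id = bmeta$block_id[g[1]],
                   category_label = bmeta$category_label[g[1]],
                   condition = bmeta$condition[g[1]],
                   onset_volume = onset,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no blocks found (all windows out of bounds?)")
  meta_out <- do.call(rbind, mrows)
  values <- do.call(rbind, rows)
  # restore chronological order within run (split() sorts by name)
  ord <- order(match(meta_out$run_id, unique(meta$run_id)),
               meta_out$onset_volume)
  out <- voxel_samples(values[ord, , drop = FALSE], meta_out[ord, ],
                       voxel_ids = samples$voxel_ids,
                       tr_seconds = samples$tr_seconds)
  attr(out, "n_skipped") <- skipped
  out
}

#' Average volumes within each block
#'
#' Converts a volume-wise sample set into one sample per block by averaging
#' the volumes in the window `[onset + shift, onset + shift + n)` of each
#' block, after shifting by `shift_volumes` to compensate for the
#' hemodynamic delay (default one volume = 3 s at TR 3 s). Default window
#' lengths are 3 volumes for 9-s stimulus blocks and 5 for 15-s imagery
#' periods.
#'
#' @param samples Volume-wise [voxel_samples()] with block metadata.
#' @param shift_volumes Integer volume shift (default 1).
#' @param volumes_per_block Number of volumes averaged per block.
#' @return A block-wise [voxel_samples()] object, one row per block, in
#'   onset order; `sample_id` is the block identifier.
#' @export
extract_block_samples <- function(samples, shift_volumes = 1L,
                                  volumes_per_block = 3L) {
  .extract_blocks(samples, as.integer(shift_volumes),
                  as.integer(volumes_per_block), on_oob = "error")
}

#' Average samples across trials of the same category
#'
#' Averages all samples sharing a category label (e.g. the 35 test-session
#' repetitions or 10 imagery repetitions per category) to increase the
#' signal-to-noise ratio. Categories keep their order of first appearance.
#'
#' @param samples A block-wise [voxel_samples()] object.
#' @return A [voxel_samples()] with one row per category; per-category trial
#'   counts in `attr(, "n_trials")`.
#' @export
average_trials <- function(samples) {
  stopifnot(inherits(samples, "voxel_samples"))
  if (nrow(samples$values) == 0) stop("empty sample set")
  cats <- unique(samples$meta$category_label)
  idx <- lapply(cats, function(cc) which(samples$meta$category_label == cc))
  nvox <- ncol(samples$values)
  vals <- vapply(idx, function(i)
    colMeans(samples$values[i, , drop = FALSE]), numeric(nvox))
  values <- if (nvox == 1) matrix(vals, ncol = 1) else t(vals)
  counts <- stats::setNames(lengths(idx), cats)
  meta <- data.frame(sample_id = cats,
                     run_id = "pooled",
                     block_id = cats,
                     category_label = cats,
                     condition = samples$meta$condition[vapply(idx, `[`, 0L, 1)],
                     onset_volume = 0L,
                     stringsAsFactors = FALSE)
  out <- voxel_samples(values, meta, voxel_ids = samples$voxel_ids,
                       tr_seconds = samples$tr_seconds)
  attr(out, "n_trials") <- counts
  out
}
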