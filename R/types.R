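#' Volume- or trial-wise voxel activity samples
#'
#' The central container for fMRI data: a samples x voxels matrix of voxel
#' amplitudes together with per-sample metadata describing the run/block
#' structure of the experiment. Rows are fMRI volumes for raw data, or block
#' averages / trial averages after preprocessing.
#'
#' @param values Numeric matrix, samples x voxels.
#' @param meta Data frame with one row per sample and columns `sample_id`,
#'   `run_id`, `block_id`, `category_label`, `condition` (one of `"stimulus"`,
#'   `"imagery"`, `"rest"`) and `onset_volume` (0-based volume index of the
#'   block onset within its run; must be non-decreasing within a run).
#' @param voxel_ids Character vector of unique voxel identifiers, one per
#'   column of `values`.
#' @param tr_seconds Volume sampling interval (repetition time) in seconds.
#' @return An object of class `"voxel_samples"`.
#' @export
voxel_samples <- function(values, meta, voxel_ids = colnames(values),
                          tr_seconds = 3) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  required <- c("sample_id", "run_id", "block_id", "category_label",
                "condition", "onset_volume")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols))
    stop("sample metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  meta <- meta[required]
  if (nrow(values) != nrow(meta))
    stop("row count of values (", nrow(values),
         ") does not match sample metadata (", nrow(meta), ")")
  if (is.null(voxel_ids)) voxel_ids <- paste0("vox", seq_len(ncol(values)))
  voxel_ids <- as.character(voxel_ids)
  if (length(voxel_ids) != ncol(values))
    stop("voxel_ids length does not match number of voxel columns")
  if (anyDuplicated(voxel_ids))
    stop("duplicate voxel_id: ",
         paste(unique(voxel_ids[duplicated(voxel_ids)]), collapse = ", "))
  bad <- !meta$condition %in% c("stimulus", "imagery", "rest")
  if (any(bad))
    stop("unknown condition label: ",
         paste(unique(meta$condition[bad]), collapse = ", "))
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1 || tr_seconds <= 0)
    stop("tr_seconds must be a positive scalar")
  meta$onset_volume <- as.integer(meta$onset_volume)
  if (any(!is.na(meta$onset_volume) & meta$onset_volume < 0))
    stop("onset_volume must be >= 0")
  for (r in unique(meta$run_id)) {
    ons <- meta$onset_volume[meta$run_id == r]
    ons <- ons[!is.na(ons)]
    if (length(ons) > 1 && any(diff(ons) < 0))
      stop("onset_volume not non-decreasing within run ", r)
  }
  colnames(values) <- voxel_ids
  structure(list(values = values, meta = meta, voxel_ids = voxel_ids,
                 tr_seconds = as.numeric(tr_seconds)),
            class = "voxel_samples")
}

#' @export
print.voxel_samples <- function(x, ...) {
  cat("Voxel samples:", nrow(x$values), "samples x", ncol(x$values),
      "voxels (TR", x$tr_seconds, "s)\n")
  cat("  runs:", length(unique(x$meta$run_id)),
      " conditions:", paste(unique(x$meta$condition), collapse = "/"), "\n")
  invisible(x)
}

#' @export
dim.voxel_samples <- function(x) dim(x$values)

#' Image-by-unit visual feature table
#'
#' Holds the outputs of a visual feature model (e.g. GIST or one layer of a
#' convolutional network): one row per image (or trial), one column per
#' feature unit, with a category label per item.
#'
#' @param values Numeric matrix, items x units; no missing values allowed.
#' @param item_id Character vector of item identifiers.
#' @param category_label Character vector of category labels, one per item.
#' @param unit_ids Character vector of unique unit identifiers.
#' @return An object of class `"feature_table"`.
#' @export
feature_table <- function(values, item_id, category_label,
                          unit_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("feature values contain missing entries")
  if (is.null(unit_ids)) unit_ids <- paste0("unit", seq_len(ncol(values)))
  unit_ids <- as.character(unit_ids)
  if (length(unit_ids) != ncol(values))
    stop("unit_ids length does not match number of unit columns")
  if (anyDuplicated(unit_ids))
    stop("duplicate unit_id: ",
         paste(unique(unit_ids[duplicated(unit_ids)]), collapse = ", "))
  item_id <- as.character(item_id)
  category_label <- as.character(category_label)
  if (length(item_id) != nrow(values) || length(category_label) != nrow(values))
    stop("item_id / category_label length does not match number of rows")
  colnames(values) <- unit_ids
  structure(list(values = values,
                 items = data.frame(item_id = item_id,
                                    category_label = category_label,
                                    stringsAsFactors = FALSE),
                 unit_ids = unit_ids),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("Feature table:", nrow(x$values), "items x", ncol(x$values), "units;",
      length(unique(x$items$category_label)), "categories\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Category-average feature bank
#'
#' One row per category: the mean feature vector over all items of that
#' category. Used as the set of category prototypes in identification.
#' Normally built with [build_category_bank()].
#'
#' @param values Numeric matrix, categories x units.
#' @param category_labels Unique category labels, one per row.
#' @param n_items Positive integer count of items averaged per category.
#' @param unit_ids Unit identifiers (same order as the source feature table).
#' @return An object of class `"category_bank"`.
#' @export
category_bank <- function(values, category_labels, n_items,
                          unit_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  category_labels <- as.character(category_labels)
  if (anyDuplicated(category_labels))
    stop("duplicate category label in bank")
  if (length(category_labels) != nrow(values))
    stop("one row per category required")
  n_items <- as.integer(n_items)
  if (length(n_items) != nrow(values) || any(n_items < 1))
    stop("n_items must be a positive integer per category")
  if (is.null(unit_ids)) unit_ids <- paste0("unit", seq_len(ncol(values)))
  colnames(values) <- unit_ids
  rownames(values) <- category_labels
  structure(list(values = values, category_labels = category_labels,
                 n_items = n_items, unit_ids = as.character(unit_ids)),
            class = "category_bank")
}

#' @export
print.category_bank <- function(x, ...) {
  cat("Category feature bank:", nrow(x$values), "categories x",
      ncol(x$values), "units (", sum(x$n_items), "items )\n")
  invisible(x)
}

#' Rooted taxonomy tree over category identifiers
#'
#' A strict rooted tree (every node has a single parent) used for
#' shortest-path semantic distances between categories.
#'
#' @param edges Data frame (or 2-column matrix) of parent -> child pairs.
#' @return An object of class `"taxonomy"` with components `nodes`, `parent`
#'   (named vector, `NA` for the root), `root` and `depth`.
#' @export
taxonomy <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2) stop("taxonomy edges need two columns (parent, child)")
  parent <- as.character(edges[[1]])
  child <- as.character(edges[[2]])
  if (any(parent == child)) stop("not a tree: self-loop at ",
                                 parent[parent == child][1])
  if (anyDuplicated(child))
    stop("not a tree: node ", child[duplicated(child)][1],
         " has more than one parent")
  nodes <- union(parent, child)
  pmap <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  pmap[child] <- parent
  roots <- nodes[is.na(pmap)]
  if (length(roots) != 1)
    stop("not a tree: expected exactly one root, found ", length(roots))
  root <- roots
  # depth by walking to the root; detects cycles (walk longer than node count)
  depth <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  depth[root] <- 0L
  for (n in nodes) {
    path <- character(0)
    cur <- n
    while (is.na(depth[cur])) {
      path <- c(path, cur)
      cur <- pmap[[cur]]
      if (length(path) > length(nodes))
        stop("not a tree: cycle involving ", n)
    }
    if (length(path))
      depth[path] <- depth[[cur]] + rev(seq_along(path))
  }
  structure(list(nodes = nodes, parent = pmap, root = root, depth = depth,
                 edges = data.frame(parent = parent, child = child,
                                    stringsAsFactors = FALSE)),
            class = "taxonomy")
}

#' @export
print.taxonomy <- function(x, ...) {
  cat("Taxonomy:", length(x$nodes), "nodes, root '", x$root, "', max depth ",
      max(x$depth), "\n", sep = "")
  invisible(x)
}
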