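# TSV formats: UTF-8, first row is the header. Sample files carry the six
# reserved metadata columns before the voxel columns; feature files carry
# (item_id, category_label) before the unit columns. Numeric values are
# written with 17 significant digits so read(write(x)) round-trips exactly
# at double precision.

.meta_cols <- c("sample_id", "run_id", "block_id", "category_label",
                "condition", "onset_volume")

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  nfields <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(unique(nfields)) > 1) {
    bad <- which(nfields != nfields[1])[1]
    stop("parse error at line ", bad, " of ", path,
         ": ragged row (", nfields[bad], " fields, expected ", nfields[1], ")")
  }
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "", check.names = FALSE,
                    colClasses = "character")
}

.num <- function(x, what, path) {
  y <- suppressWarnings(as.numeric(x))
  if (anyNA(y) && !all(is.na(y) == (x %in% c("NA", ""))))
    stop("parse error in ", path, ": non-numeric value in ", what)
  y
}

.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Read / write voxel sample tables
#'
#' Tab-separated values with the reserved metadata columns
#' `sample_id, run_id, block_id, category_label, condition, onset_volume`
#' followed by one column per voxel.
#'
#' @param path File path.
#' @param x A [voxel_samples()] object.
#' @param tr_seconds Repetition time recorded in the file header comment is
#'   not used; supply it here when reading (default 3).
#' @return `read_samples` returns a [voxel_samples()] object;
#'   `write_samples` returns `path` invisibly.
#' @export
read_samples <- function(path, tr_seconds = 3) {
  tab <- .read_tsv(path)
  if (!all(.meta_cols %in% names(tab)))
    stop("parse error in ", path, ": malformed header, missing column(s) ",
         paste(setdiff(.meta_cols, names(tab)), collapse = ", "))
  voxcols <- setdiff(names(tab), .meta_cols)
  if (!length(voxcols)) stop("parse error in ", path, ": no voxel columns")
  bad <- which(!tab$condition %in% c("stimulus", "imagery", "rest"))
  if (length(bad))
    stop("parse error at line ", bad[1] + 1L, " of ", path,
         ": unknown condition label '", tab$condition[bad[1]], "'")
  values <- vapply(voxcols, function(cn) .num(tab[[cn]], cn, path),
                   numeric(nrow(tab)))
  if (nrow(tab) == 1L) values <- matrix(values, nrow = 1,
                                        dimnames = list(NULL, voxcols))
  meta <- tab[.meta_cols]
  meta$onset_volume <- as.integer(.num(meta$onset_volume, "onset_volume", path))
  voxel_samples(values, meta, voxel_ids = voxcols, tr_seconds = tr_seconds)
}

#' @rdname read_samples
#' @export
write_samples <- function(x, path) {
  stopifnot(inherits(x, "voxel_samples"))
  meta <- x$meta
  meta[] <- lapply(meta, as.character)
  vals <- apply(x$values, 2, .fmt_num)
  if (nrow(x$values) == 1L) vals <- matrix(vals, nrow = 1)
  out <- cbind(meta, as.data.frame(vals, stringsAsFactors = FALSE,
                                   optional = TRUE))
  names(out) <- c(.meta_cols, x$voxel_ids)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write feature tables
#'
#' Tab-separated values with columns `item_id, category_label` followed by
#' one column per feature unit.
#'
#' @param path File path.
#' @param x A [feature_table()] object.
#' @return `read_features` returns a [feature_table()]; `write_features`
#'   returns `path` invisibly.
#' @export
read_features <- function(path) {
  tab <- .read_tsv(path)
  if (!all(c("item_id", "category_label") %in% names(tab)))
    stop("parse error in ", path,
         ": malformed header, expected item_id and category_label")
  unitcols <- names(tab)[!names(tab) %in% c("item_id", "category_label")]
  if (!length(unitcols)) stop("parse error in ", path, ": no unit columns")
  if (anyDuplicated(unitcols))
    stop("parse error in ", path, ": duplicate unit_id ",
         unitcols[duplicated(unitcols)][1])
  values <- vapply(unitcols, function(cn) .num(tab[[cn]], cn, path),
                   numeric(nrow(tab)))
  if (nrow(tab) == 1L) values <- matrix(values, nrow = 1,
                                        dimnames = list(NULL, unitcols))
  feature_table(values, tab$item_id, tab$category_label, unit_ids = unitcols)
}

#' @rdname read_features
#' @export
write_features <- function(x, path) {
  stopifnot(inherits(x, "feature_table"))
  vals <- apply(x$values, 2, .fmt_num)
  if (nrow(x$values) == 1L) vals <- matrix(vals, nrow = 1)
  out <- cbind(x$items, as.data.frame(vals, stringsAsFactors = FALSE,
                                      optional = TRUE))
  names(out) <- c("item_id", "category_label", x$unit_ids)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a taxonomy edge list
#'
#' Two-column TSV (`parent`, `child`); the root is the unique node that never
#' appears as a child.
#'
#' @param path File path.
#' @return A [taxonomy()] object.
#' @export
read_taxonomy <- function(path) {
  tab <- .read_tsv(path)
  if (ncol(tab) < 2)
    stop("parse error in ", path, ": expected two columns (parent, child)")
  taxonomy(tab[, 1:2])
}

#' @rdname read_taxonomy
#' @param x A [taxonomy()] object.
#' @export
write_taxonomy <- function(x, path) {
  stopifnot(inherits(x, "taxonomy"))
  utils::write.table(x$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write / read a fitted decoder set as a directory of TSV files
#'
#' The directory holds `manifest.tsv` (key-value training metadata),
#' `units.tsv` (per-unit noise precision and convergence info) and one
#' `weights_<k>.tsv` per unit with columns voxel_id, mu, sigma, alpha,
#' center, scale (the `.bias.` row carries the bias weight and the target
#' normalisation statistics). No binary serialisation is used.
#'
#' @param x A `decoder_set` from [train_decoders()].
#' @param path Directory to create.
#' @return `write_decoder_set` returns `path` invisibly; `read_decoder_set`
#'   returns a `decoder_set`.
#' @export
write_decoder_set <- function(x, path) {
  stopifnot(inherits(x, "decoder_set"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  man <- data.frame(key = names(x$meta),
                    value = vapply(x$meta, function(v)
                      paste(as.character(v), collapse = ","), ""),
                    stringsAsFactors = FALSE)
  utils::write.table(man, file.path(path, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  units <- data.frame(unit_id = x$unit_ids,
                      file = sprintf("weights_%04d.tsv", seq_along(x$unit_ids)),
                      beta = .fmt_num(vapply(x$models, `[[`, 0, "beta")),
                      iterations = vapply(x$models, function(m)
                        m$trace$iterations, 0L),
                      converged = vapply(x$models, function(m)
                        m$trace$converged, TRUE),
                      stringsAsFactors = FALSE)
  utils::write.table(units, file.path(path, "units.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (k in seq_along(x$models)) {
    m <- x$models[[k]]
    tab <- data.frame(
      voxel_id = c(m$voxel_ids, ".bias."),
      mu = .fmt_num(m$mu),
      sigma = .fmt_num(m$sigma_diag),
      alpha = .fmt_num(m$alpha),
      center = .fmt_num(c(m$x_center, m$t_center)),
      scale = .fmt_num(c(m$x_scale, m$t_scale)),
      stringsAsFactors = FALSE)
    utils::write.table(tab, file.path(path, units$file[k]), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_decoder_set
#' @export
read_decoder_set <- function(path) {
  man <- .read_tsv(file.path(path, "manifest.tsv"))
  meta <- as.list(stats::setNames(man$value, man$key))
  for (k in c("max_voxels", "max_iterations"))
    if (!is.null(meta[[k]])) meta[[k]] <- as.integer(meta[[k]])
  for (k in c("tol", "prune_alpha"))
    if (!is.null(meta[[k]])) meta[[k]] <- as.numeric(meta[[k]])
  units <- .read_tsv(file.path(path, "units.tsv"))
  models <- lapply(seq_len(nrow(units)), function(k) {
    tab <- .read_tsv(file.path(path, units$file[k]))
    p <- nrow(tab)
    mu <- .num(tab$mu, "mu", units$file[k])
    alpha <- .num(tab$alpha, "alpha", units$file[k])
    structure(list(
      voxel_ids = tab$voxel_id[-p],
      mu = mu,
      sigma_diag = .num(tab$sigma, "sigma", units$file[k]),
      alpha = alpha,
      beta = .num(units$beta[k], "beta", "units.tsv"),
      x_center = .num(tab$center[-p], "center", units$file[k]),
      x_scale = .num(tab$scale[-p], "scale", units$file[k]),
      t_center = .num(tab$center[p], "center", units$file[k]),
      t_scale = .num(tab$scale[p], "scale", units$file[k]),
      active = mu != 0,
      trace = list(iterations = as.integer(units$iterations[k]),
                   converged = as.logical(units$converged[k]),
                   evidence = numeric(0), final_change = NA_real_,
                   pruned_at = integer(0))),
      class = "vb_ard")
  })
  structure(list(unit_ids = units$unit_id, models = models, meta = meta),
            class = "decoder_set")
}

#' Stage logging
#'
#' Timestamped log lines for pipeline stages; used by the command-line
#' interface and available to scripts. Controlled by
#' `options(gendecode.log_level = "info"|"quiet")`.
#'
#' @param stage Stage name.
#' @param ... Message parts pasted together.
#' @export
gd_log <- function(stage, ...) {
  if (identical(getOption("gendecode.log_level", "info"), "quiet"))
    return(invisible(NULL))
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", stage, "] ", ...)
  invisible(NULL)
}

#' Hash of a configuration list for logging
#'
#' @param config A list.
#' @return MD5 hex digest of the deparsed configuration.
#' @export
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config[order(names(config))]), f)
  unname(tools::md5sum(f))
}
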