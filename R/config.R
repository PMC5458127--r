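#' Pipeline configuration with documented defaults
#'
#' Every tunable of the pipeline in one structured list. Values mirror the
#' study design where one is stated (voxel caps, block lengths, shift) and
#' otherwise hold the package defaults. Unknown keys are rejected so typos
#' in configuration files fail loudly.
#'
#' Sections and defaults:
#' \describe{
#'   \item{preprocess}{`shift_volumes = 1` (one-volume hemodynamic shift at
#'     TR 3 s), `stimulus_block_volumes = 3` (9-s blocks),
#'     `imagery_block_volumes = 5` (15-s imagery periods).}
#'   \item{regression}{`max_voxels = 500` (per-subarea cap; 1000 for pooled
#'     regions), `max_iterations = 500`, `tol = 1e-6`, `prune_alpha = 1e8`.}
#'   \item{identification}{`set_size = 2`, `repetitions = 100`.}
#'   \item{seed}{master random seed, default 1.}
#'   \item{synthetic}{see [synth_config()].}
#' }
#'
#' @param ... Named overrides, e.g. `regression = list(max_voxels = 100)`.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    preprocess = list(shift_volumes = 1L,
                      stimulus_block_volumes = 3L,
                      imagery_block_volumes = 5L),
    regression = list(max_voxels = 500L,
                      max_iterations = 500L,
                      tol = 1e-6,
                      prune_alpha = 1e8),
    identification = list(set_size = 2L, repetitions = 100L),
    seed = 1L,
    synthetic = unclass(synth_config()))
  structure(.merge_config(cfg, list(...), "config"), class = "pipeline_config")
}

.merge_config <- function(base, override, where) {
  if (!length(override)) return(base)
  if (is.null(names(override)) || any(names(override) == ""))
    stop("configuration entries under '", where, "' must be named")
  unknown <- setdiff(names(override), names(base))
  if (length(unknown))
    stop("unknown configuration key(s) under '", where, "': ",
         paste(unknown, collapse = ", "))
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]) &&
        !is.null(names(base[[k]]))) {
      base[[k]] <- .merge_config(base[[k]], override[[k]],
                                 paste(where, k, sep = "/"))
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Read a YAML configuration file
#'
#' Reads a YAML file and merges it over [pipeline_config()] defaults;
#' unknown keys raise an error. The fully resolved configuration (with its
#' hash and seed) is echoed to the log.
#'
#' @param path Path to a YAML file; `NULL` returns the defaults.
#' @return A `"pipeline_config"` list.
#' @export
read_config <- function(path = NULL) {
  if (is.null(path)) {
    cfg <- pipeline_config()
  } else {
    if (!file.exists(path)) stop("config file not found: ", path)
    raw <- yaml::read_yaml(path)
    if (is.null(raw)) raw <- list()
    cfg <- do.call(pipeline_config, raw)
  }
  gd_log("config", "resolved config hash=", config_hash(unclass(cfg)),
         " seed=", cfg$seed)
  cfg
}
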