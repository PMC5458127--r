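#' Shortest path length between two categories in a taxonomy
#'
#' Edge count of the unique tree path, computed from node depths via the
#' lowest common ancestor: `d(a, b) = depth(a) + depth(b) - 2 depth(lca)`.
#' This is the semantic distance used in the rank-distance analysis.
#'
#' @param tree A [taxonomy()].
#' @param a,b Node identifiers.
#' @return Non-negative integer path length.
#' @export
shortest_path_length <- function(tree, a, b) {
  stopifnot(inherits(tree, "taxonomy"))
  for (n in c(a, b))
    if (!n %in% tree$nodes) stop("node not in taxonomy: ", n)
  if (a == b) return(0L)
  da <- tree$depth[[a]]; db <- tree$depth[[b]]
  pa <- a; pb <- b
  while (da > db) { pa <- tree$parent[[pa]]; da <- da - 1L }
  while (db > da) { pb <- tree$parent[[pb]]; db <- db - 1L }
  while (pa != pb) {
    pa <- tree$parent[[pa]]; pb <- tree$parent[[pb]]; da <- da - 1L
  }
  as.integer(tree$depth[[a]] + tree$depth[[b]] - 2L * da)
}

#' Distances from one node to many
#'
#' @param tree A [taxonomy()].
#' @param from Source node.
#' @param to Character vector of target nodes (default: all nodes).
#' @return Named integer vector of path lengths.
#' @export
taxonomy_distances <- function(tree, from, to = tree$nodes) {
  vapply(to, function(b) shortest_path_length(tree, from, b), 0L)
}

#' Correlation between identification rank and semantic distance
#'
#' Given a candidate ranking for a target category (from [identify_rank()]),
#' correlates the rank position of each candidate with its tree path length
#' to the target. Positive r means higher-ranked (more similar to the
#' decoded vector) candidates are semantically closer to the target.
#'
#' @param ranked Data frame from [identify_rank()] (columns `category`,
#'   `rank`).
#' @param tree A [taxonomy()].
#' @param target Target category identifier.
#' @return Pearson correlation between rank and distance.
#' @export
rank_distance_correlation <- function(ranked, tree, target) {
  d <- taxonomy_distances(tree, target, ranked$category)
  if (stats::sd(d) == 0 || stats::sd(ranked$rank) == 0)
    return(NA_real_)
  stats::cor(ranked$rank, d)
}

#' Rank-distance analysis over repeated candidate draws
#'
#' For each target category, repeatedly samples a candidate set of foils
#' plus the target, ranks the candidates against the decoded vector, and
#' correlates rank with semantic distance; correlations are computed per
#' repetition and then averaged ("correlation-first", matching the reported
#' aggregation), with the "average-distances-first" variant also returned.
#'
#' @param preds Predicted [feature_table()], one row per target category.
#' @param bank Candidate [category_bank()].
#' @param tree A [taxonomy()] covering all candidate categories.
#' @param n_foils Foils per candidate set.
#' @param n_repetitions Candidate-set draws per target.
#' @param exclusions Labels excluded from the foil pool.
#' @return List with `mean_r` (mean correlation over repetitions and
#'   targets), `per_target` mean r, `r_distance_first` (correlation of rank
#'   with the repetition-averaged distances), and `n_undefined`.
#' @export
rank_distance_analysis <- function(preds, bank, tree, n_foils = 99L,
                                   n_repetitions = 20L,
                                   exclusions = character(0)) {
  stopifnot(inherits(preds, "feature_table"), inherits(bank, "category_bank"))
  labs <- preds$items$category_label
  per_target <- numeric(nrow(preds$values))
  n_undef <- 0L
  dist_by_rank <- matrix(0, n_foils + 1L, length(labs))
  for (i in seq_along(labs)) {
    rs <- numeric(n_repetitions)
    for (rep in seq_len(n_repetitions)) {
      cand <- sample_candidate_set(bank, labs[i], n_foils, exclusions)
      rk <- identify_rank(preds$values[i, ], cand)
      d <- taxonomy_distances(tree, labs[i], rk$category)
      dist_by_rank[, i] <- dist_by_rank[, i] + d / n_repetitions
      rs[rep] <- if (stats::sd(d) == 0) NA_real_ else stats::cor(rk$rank, d)
    }
    n_undef <- n_undef + sum(is.na(rs))
    per_target[i] <- mean(rs, na.rm = TRUE)
  }
  ranks <- seq_len(n_foils + 1L)
  rdf <- mean(vapply(seq_along(labs), function(i)
    if (stats::sd(dist_by_rank[, i]) == 0) NA_real_
    else stats::cor(ranks, dist_by_rank[, i]), 0), na.rm = TRUE)
  list(mean_r = mean(per_target, na.rm = TRUE),
       per_target = stats::setNames(per_target, labs),
       r_distance_first = rdf,
       n_undefined = n_undef)
}
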