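#' Build a category-average feature bank
#'
#' Averages the feature vectors of all items of each category, producing one
#' prototype vector per category — the candidate set used for zero-shot
#' identification.
#'
#' @param features A [feature_table()].
#' @return A [category_bank()]; categories in order of first appearance,
#'   with per-category item counts.
#' @export
build_category_bank <- function(features) {
  stopifnot(inherits(features, "feature_table"))
  cats <- unique(features$items$category_label)
  idx <- lapply(cats, function(cc)
    which(features$items$category_label == cc))
  values <- t(vapply(idx, function(i)
    colMeans(features$values[i, , drop = FALSE]),
    numeric(ncol(features$values))))
  category_bank(values, cats, lengths(idx), unit_ids = features$unit_ids)
}

#' Rank candidate categories by correlation with a decoded vector
#'
#' Computes the Pearson correlation between the predicted feature vector and
#' every category-average vector in the bank and ranks categories by
#' descending r. The top-ranked category is the identified one. Ties are
#' broken by category label order; zero-variance bank rows are scored
#' `-Inf` (ranked last) and flagged.
#'
#' @param pred_vector Numeric vector of decoded unit values (>= 3 units).
#' @param bank A [category_bank()] with matching units.
#' @return Data frame with columns `category`, `score`, `rank` (descending
#'   score) and a `zero_variance` flag.
#' @export
identify_rank <- function(pred_vector, bank) {
  stopifnot(inherits(bank, "category_bank"))
  pred_vector <- as.numeric(pred_vector)
  if (length(pred_vector) < 3) stop("need at least 3 units")
  if (length(pred_vector) != ncol(bank$values))
    stop("pred_vector length does not match bank units")
  if (nrow(bank$values) == 0) stop("empty bank")
  score <- .rowwise_cor_vec(bank$values, pred_vector)
  zv <- is.na(score)
  score[zv] <- -Inf
  ord <- order(-score, bank$category_labels)
  data.frame(category = bank$category_labels[ord],
             score = score[ord],
             rank = seq_along(ord),
             zero_variance = zv[ord],
             stringsAsFactors = FALSE)
}

# Pearson r between each row of m and vector v; NA where either side has
# zero variance.
.rowwise_cor_vec <- function(m, v) {
  vc <- v - mean(v)
  sv <- sqrt(sum(vc^2))
  mc <- m - rowMeans(m)
  sm <- sqrt(rowSums(mc^2))
  out <- as.vector(mc %*% vc) / (sm * sv)
  out[sm == 0 | sv == 0] <- NA_real_
  out
}

#' Sample a candidate set of categories
#'
#' The true category plus `n_foils` categories drawn without replacement
#' from the bank, excluding the true category and any explicit exclusion
#' list (e.g. semantic neighbours of the target). Uses R's RNG, so results
#' are reproducible under `set.seed()`.
#'
#' @param bank A [category_bank()].
#' @param true_category Label of the true category (must be in the bank).
#' @param n_foils Number of foil categories.
#' @param exclusions Character vector of labels never sampled as foils.
#' @return A [category_bank()] restricted to the candidate set (true
#'   category first).
#' @export
sample_candidate_set <- function(bank, true_category, n_foils,
                                 exclusions = character(0)) {
  stopifnot(inherits(bank, "category_bank"))
  if (!true_category %in% bank$category_labels)
    stop("true category '", true_category, "' not in bank")
  pool <- setdiff(bank$category_labels, c(true_category, exclusions))
  if (n_foils > length(pool))
    stop("insufficient foil pool: need ", n_foils, ", have ", length(pool))
  foils <- if (n_foils > 0) sample(pool, n_foils) else character(0)
  keep <- match(c(true_category, foils), bank$category_labels)
  category_bank(bank$values[keep, , drop = FALSE],
                bank$category_labels[keep], bank$n_items[keep],
                unit_ids = bank$unit_ids)
}

#' Pairwise (two-way) identification accuracy
#'
#' For every combination of a test item and a foil category (foil != the
#' item's true category), identification is correct when the decoded vector
#' correlates more strongly with the true category-average vector than with
#' the foil's. Exact ties count 0.5, keeping the null exactly at the 50%
#' chance level. Accuracy is reported in percent.
#'
#' @param preds Predicted [feature_table()], one row per test item.
#' @param bank A [category_bank()] containing the true categories and all
#'   foil candidates.
#' @param true_labels True category per row of `preds` (default: its item
#'   labels).
#' @param foil_labels Optional restriction of the foil pool (e.g. only the
#'   database candidate categories, as when the foils come from a large
#'   annotated image database); default: every bank category other than the
#'   item's true one.
#' @return List with `accuracy` (percent), `n_combinations`, and `per_item`
#'   (fraction of foils beaten per test item).
#' @export
pairwise_accuracy <- function(preds, bank,
                              true_labels = preds$items$category_label,
                              foil_labels = NULL) {
  stopifnot(inherits(preds, "feature_table"), inherits(bank, "category_bank"))
  ti <- match(true_labels, bank$category_labels)
  if (anyNA(ti))
    stop("true label(s) missing from bank: ",
         paste(utils::head(true_labels[is.na(ti)], 5), collapse = ", "))
  bu <- match(preds$unit_ids, bank$unit_ids)
  if (anyNA(bu)) stop("unit sets differ between preds and bank")
  if (!is.null(foil_labels)) {
    fi <- match(foil_labels, bank$category_labels)
    if (anyNA(fi)) stop("foil label(s) missing from bank")
  } else fi <- NULL
  bv <- bank$values[, bu, drop = FALSE]
  n_items <- nrow(preds$values)
  per_item <- numeric(n_items)
  correct <- 0
  combos <- 0L
  for (i in seq_len(n_items)) {
    r <- .rowwise_cor_vec(bv, preds$values[i, ])
    r[is.na(r)] <- -Inf
    rt <- r[ti[i]]
    foil <- if (is.null(fi)) r[-ti[i]] else r[setdiff(fi, ti[i])]
    sc <- sum(rt > foil) + 0.5 * sum(rt == foil)
    correct <- correct + sc
    combos <- combos + length(foil)
    per_item[i] <- sc / length(foil)
  }
  list(accuracy = 100 * correct / combos,
       n_combinations = combos,
       per_item = stats::setNames(per_item, preds$items$item_id))
}

#' Multi-way identification accuracy over sampled candidate sets
#'
#' Repeatedly samples a candidate set of a given size for each test item
#' (its true category plus random foils) and scores the repetition correct
#' when the true category attains the highest correlation with the decoded
#' vector. Chance level is `100 / set_size` percent. Reproducible under
#' `set.seed()`.
#'
#' @param preds Predicted [feature_table()].
#' @param bank Candidate [category_bank()].
#' @param set_size Candidate-set size (true category + `set_size - 1` foils).
#' @param n_repetitions Candidate-set draws per test item.
#' @param exclusions Labels excluded from the foil pool.
#' @return List with `accuracy` (percent), `per_item_rank` (mean rank of the
#'   true category per item), `n_repetitions`, `set_size`.
#' @export
multiway_accuracy <- function(preds, bank, set_size = 2L,
                              n_repetitions = 100L,
                              exclusions = character(0)) {
  stopifnot(inherits(preds, "feature_table"), inherits(bank, "category_bank"),
            set_size >= 2)
  labs <- preds$items$category_label
  correct <- 0L
  total <- 0L
  mean_rank <- numeric(nrow(preds$values))
  for (i in seq_len(nrow(preds$values))) {
    ranks <- numeric(n_repetitions)
    for (rep in seq_len(n_repetitions)) {
      cand <- sample_candidate_set(bank, labs[i], set_size - 1L, exclusions)
      rk <- identify_rank(preds$values[i, ], cand)
      ranks[rep] <- rk$rank[rk$category == labs[i]]
      correct <- correct + (ranks[rep] == 1L)
      total <- total + 1L
    }
    mean_rank[i] <- mean(ranks)
  }
  list(accuracy = 100 * correct / total,
       per_item_rank = stats::setNames(mean_rank, preds$items$item_id),
       n_repetitions = as.integer(n_repetitions),
       set_size = as.integer(set_size))
}
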