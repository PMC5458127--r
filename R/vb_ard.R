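#' Correlation-based voxel preselection
#'
#' Ranks voxels by the absolute Pearson correlation between each voxel's
#' values and the target feature unit over the training samples, and returns
#' the indices of the top `max_voxels` (all voxels when the cap exceeds the
#' voxel count). Zero-variance voxels receive r = 0; ties are broken by
#' ascending voxel index.
#'
#' @param x Numeric matrix, samples x voxels.
#' @param t Numeric target vector (one feature unit).
#' @param max_voxels Maximum number of voxels to keep (default 500, the
#'   per-subarea cap; pooled regions use 1000).
#' @return Integer vector of column indices, in descending |r| order.
#' @export
select_voxels <- function(x, t, max_voxels = 500L) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("need at least 3 samples to rank voxels")
  if (max_voxels < 1) stop("max_voxels must be >= 1")
  if (stats::sd(t) == 0)
    stop("target is constant: correlation-based selection undefined")
  r <- suppressWarnings(as.vector(stats::cor(x, t)))
  r[is.na(r)] <- 0                       # zero-variance voxels
  ord <- order(-abs(r), seq_along(r))
  ord[seq_len(min(as.integer(max_voxels), ncol(x)))]
}

#' Sparse linear regression by variational Bayes with ARD priors
#'
#' Fits the linear model t = w' [x; 1] + e, e ~ N(0, 1/beta), with an
#' automatic-relevance-determination prior: each weight w_i has its own
#' Gaussian prior precision alpha_i with a non-informative hyperprior, and
#' the intractable joint posterior is approximated variationally. The
#' fixed-point updates are
#' \deqn{\Sigma = (\beta X'X + diag(\alpha))^{-1}, \quad
#'       \mu = \beta \Sigma X' t,}
#' \deqn{\gamma_i = 1 - \alpha_i \Sigma_{ii}, \quad
#'       \alpha_i \leftarrow \gamma_i / \mu_i^2, \quad
#'       \beta \leftarrow (N - \sum_i \gamma_i) / \|t - X\mu\|^2,}
#' the standard evidence-procedure fixed point for ARD regression
#' (\eqn{\gamma_i} is the effective number of well-determined parameters).
#' It drives the precisions of irrelevant weights to infinity geometrically,
#' and the recorded evidence trace is in practice non-decreasing between
#' pruning events.
#' Weights whose precision exceeds `prune_alpha` are pruned to exactly zero
#' and their columns dropped from subsequent iterations; the bias is a
#' constant regressor with its own ARD precision like any other weight.
#'
#' Inputs and target are z-scored with training statistics before fitting
#' (for conditioning); the statistics are stored and inverted at prediction
#' time. The fit is deterministic given the data.
#'
#' @param x Numeric matrix, samples x voxels (the preselected voxels).
#' @param t Numeric target vector (one feature unit).
#' @param max_iterations Maximum fixed-point iterations (default 500).
#' @param tol Convergence threshold on the maximum relative change of the
#'   posterior mean (default 1e-6).
#' @param prune_alpha Precision above which a weight is pruned (default 1e8).
#' @param voxel_ids Optional voxel identifiers (default: column names).
#' @return An object of class `"vb_ard"` with posterior mean `mu` and
#'   marginal variances `sigma_diag` (selected voxels + bias, pruned entries
#'   exactly 0), precisions `alpha` (`Inf` for pruned weights), noise
#'   precision `beta`, normalisation statistics, and a convergence `trace`
#'   (iterations, evidence path, pruning events, final change).
#' @seealso [predict.vb_ard()], [select_voxels()], [train_decoders()]
#' @export
vb_ard <- function(x, t, max_iterations = 500L, tol = 1e-6,
                   prune_alpha = 1e8, voxel_ids = colnames(x)) {
  x <- as.matrix(x)
  t <- as.numeric(t)
  if (!all(is.finite(x)) || !all(is.finite(t)))
    stop("non-finite values in inputs")
  n <- nrow(x)
  if (n < 2 || length(t) != n)
    stop("need N >= 2 samples with matching target length")
  d <- ncol(x)
  if (is.null(voxel_ids)) voxel_ids <- paste0("vox", seq_len(d))

  x_center <- colMeans(x)
  x_scale <- apply(x, 2, stats::sd)
  x_scale[x_scale == 0] <- 1
  t_center <- mean(t)
  t_scale <- stats::sd(t)
  if (is.na(t_scale) || t_scale == 0) t_scale <- 1
  xs <- sweep(sweep(x, 2, x_center), 2, x_scale, "/")
  ts <- (t - t_center) / t_scale

  phi <- cbind(xs, 1)                    # bias absorbed as a constant column
  m <- d + 1L
  active <- rep(TRUE, m)
  alpha <- rep(1, m)
  beta <- 1 / max(stats::var(ts), .Machine$double.eps)

  gram <- crossprod(phi)
  phity <- crossprod(phi, ts)
  tt <- sum(ts^2)

  mu_full <- numeric(m)
  sig_full <- numeric(m)
  evidence <- numeric(0)
  pruned_at <- integer(0)
  it <- 0L
  change <- Inf
  converged <- FALSE

  while (it < max_iterations) {
    it <- it + 1L
    a <- which(active)
    ga <- gram[a, a, drop = FALSE]
    ca <- beta * ga + diag(alpha[a], length(a))
    ch <- tryCatch(chol(ca), error = function(e) NULL)
    if (is.null(ch)) { ch <- chol(ca + diag(1e-10, length(a))) }
    sig <- chol2inv(ch)
    mu <- beta * as.vector(sig %*% phity[a])

    rss <- tt - 2 * sum(mu * phity[a]) + sum(mu * (ga %*% mu))
    rss <- max(rss, 0)
    tr_xsx <- sum(ga * sig)
    # evidence (type-II log likelihood) at the current alpha/beta
    evidence <- c(evidence,
                  0.5 * (sum(log(alpha[a])) + n * log(beta) -
                         beta * rss - sum(alpha[a] * mu^2) -
                         2 * sum(log(diag(ch))) - n * log(2 * pi)))

    mu_new <- numeric(m)
    mu_new[a] <- mu
    change <- max(abs(mu_new - mu_full) / pmax(abs(mu_full), 1e-12))
    if (it > 1 && change < tol) {
      mu_full <- mu_new
      sig_full[] <- 0; sig_full[a] <- diag(sig)
      converged <- TRUE
      break
    }
    mu_full <- mu_new
    sig_full[] <- 0; sig_full[a] <- diag(sig)

    gamma <- 1 - alpha[a] * diag(sig)
    gamma <- pmin(pmax(gamma, 0), 1)
    alpha_new <- gamma / pmax(mu^2, .Machine$double.xmin)
    alpha_new[mu == 0] <- Inf
    alpha[a] <- alpha_new
    beta <- max(n - sum(gamma), .Machine$double.eps) /
      max(rss, .Machine$double.eps)

    drop_now <- a[alpha_new > prune_alpha]
    if (length(drop_now)) {
      active[drop_now] <- FALSE
      mu_full[drop_now] <- 0
      sig_full[drop_now] <- 0
      alpha[drop_now] <- Inf
      pruned_at <- c(pruned_at, it)
      if (!any(active)) break            # everything pruned: null model
    }
  }

  structure(list(
    voxel_ids = as.character(voxel_ids),
    mu = mu_full,
    sigma_diag = sig_full,
    alpha = alpha,
    beta = beta,
    active = active,
    x_center = x_center, x_scale = x_scale,
    t_center = t_center, t_scale = t_scale,
    trace = list(iterations = it, converged = converged,
                 final_change = change, evidence = evidence,
                 pruned_at = unique(pruned_at))),
    class = "vb_ard")
}

#' Predict feature values from a fitted ARD decoder
#'
#' Applies the stored input normalisation and the posterior-mean linear map
#' `mu' [x; 1]`, then inverts the target normalisation. Columns of `newdata`
#' are matched to the decoder's voxel identifiers by name; prediction is
#' therefore invariant to column permutation.
#'
#' @param object A `"vb_ard"` fit.
#' @param newdata Matrix (samples x voxels) with column names, or a
#'   [voxel_samples()] object.
#' @param ... Unused.
#' @return Numeric vector of predicted feature values.
#' @export
predict.vb_ard <- function(object, newdata, ...) {
  if (inherits(newdata, "voxel_samples")) newdata <- newdata$values
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata))) {
    if (ncol(newdata) != length(object$voxel_ids))
      stop("newdata has no column names and wrong number of columns")
  } else {
    miss <- setdiff(object$voxel_ids, colnames(newdata))
    if (length(miss))
      stop("missing voxel column(s): ", paste(miss, collapse = ", "))
    newdata <- newdata[, object$voxel_ids, drop = FALSE]
  }
  xs <- sweep(sweep(newdata, 2, object$x_center), 2, object$x_scale, "/")
  d <- length(object$voxel_ids)
  ys <- as.vector(xs %*% object$mu[seq_len(d)]) + object$mu[d + 1L]
  ys * object$t_scale + object$t_center
}

#' Coefficients of an ARD decoder
#'
#' @param object A `"vb_ard"` fit.
#' @param standardized If `TRUE`, return the posterior mean in the z-scored
#'   space used for fitting; otherwise (default) coefficients on the
#'   original data scale, with an `(Intercept)` term.
#' @param ... Unused.
#' @return Named numeric vector; pruned weights are exactly zero.
#' @export
coef.vb_ard <- function(object, standardized = FALSE, ...) {
  d <- length(object$voxel_ids)
  if (standardized)
    return(stats::setNames(object$mu, c(object$voxel_ids, "(Intercept)")))
  w <- object$mu[seq_len(d)] * object$t_scale / object$x_scale
  b <- object$t_center + object$t_scale * object$mu[d + 1L] -
    sum(w * object$x_center)
  stats::setNames(c(b, w), c("(Intercept)", object$voxel_ids))
}

#' @export
print.vb_ard <- function(x, ...) {
  d <- length(x$voxel_ids)
  cat("VB-ARD sparse linear decoder\n")
  cat("  voxels:", d, " retained:", sum(x$active[seq_len(d)]),
      " bias retained:", x$active[d + 1L], "\n")
  cat("  noise precision beta:", format(x$beta, digits = 4),
      " iterations:", x$trace$iterations,
      if (!x$trace$converged) " (not converged)" else "", "\n")
  invisible(x)
}

#' @export
summary.vb_ard <- function(object, ...) {
  d <- length(object$voxel_ids)
  act <- which(object$active[seq_len(d)])
  out <- list(
    n_voxels = d,
    n_retained = length(act),
    bias_retained = object$active[d + 1L],
    beta = object$beta,
    iterations = object$trace$iterations,
    converged = object$trace$converged,
    weights = data.frame(voxel_id = object$voxel_ids[act],
                         mu = object$mu[act],
                         sd = sqrt(object$sigma_diag[act]),
                         alpha = object$alpha[act],
                         stringsAsFactors = FALSE))
  class(out) <- "summary.vb_ard"
  out
}

#' @export
print.summary.vb_ard <- function(x, ...) {
  cat("VB-ARD decoder:", x$n_retained, "of", x$n_voxels,
      "voxels retained; beta =", format(x$beta, digits = 4), "\n")
  cat(" ", x$iterations, "iterations,",
      if (x$converged) "converged" else "NOT converged", "\n")
  if (nrow(x$weights)) {
    cat("  retained weights (standardized space):\n")
    print(utils::head(x$weights[order(-abs(x$weights$mu)), ], 10),
          row.names = FALSE)
  }
  invisible(x)
}

#' @export
fitted.vb_ard <- function(object, ...) {
  stop("vb_ard does not store its training data; use predict() with the ",
       "training matrix")
}

#' Residuals of an ARD decoder on given data
#'
#' @param object A `"vb_ard"` fit.
#' @param newdata Matrix of voxel values.
#' @param t Observed target values.
#' @param ... Unused.
#' @return Numeric vector `t - predict(object, newdata)`.
#' @export
residuals.vb_ard <- function(object, newdata, t, ...) {
  t - predict(object, newdata)
}
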