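test_that("voxel preselection ranks by |r| with deterministic tie-breaking", {
  set.seed(1)
  t <- rnorm(30)
  x <- cbind(a = t, b = rnorm(30), c = -t + rnorm(30, 0, 0.2),
             d = rep(1, 30))                       # d has zero variance
  sel <- select_voxels(x, t, max_voxels = 2)
  expect_identical(sel[1], 1L)                      # exact copy ranks first
  expect_identical(sel, c(1L, 3L))
  expect_identical(select_voxels(x, t, max_voxels = 10), c(1L, 3L, 2L, 4L))
  expect_error(select_voxels(x, rep(2, 30)), "constant")
  # exact ties broken by ascending index
  x2 <- cbind(t, t, t)
  expect_identical(select_voxels(x2, t, 3), c(1L, 2L, 3L))
})

test_that("voxel cap returns exactly the requested number from a large pool", {
  set.seed(2)
  x <- matrix(rnorm(60 * 2000), 60, 2000)
  sel <- select_voxels(x, rnorm(60), max_voxels = 500)
  expect_length(sel, 500)
  expect_false(anyDuplicated(sel) > 0)
})

test_that("ARD recovers a single informative voxel and matches the OLS oracle", {
  set.seed(10)
  x <- matrix(rnorm(50 * 10), 50, 10, dimnames = list(NULL, paste0("v", 1:10)))
  t <- 2 * x[, 1]
  fit <- vb_ard(x, t)
  cf <- coef(fit)
  ols <- unname(coef(lm(t ~ x[, 1]))[2])
  expect_lt(abs(cf[["v1"]] - ols) / abs(ols), 0.01)
  expect_equal(unname(cf[paste0("v", 2:10)]), rep(0, 9))  # pruned exactly
  # noiseless training data: training-set correlation essentially 1
  expect_gt(cor(predict(fit, x), t), 0.999)
})

test_that("a noise-trained decoder predicts no better than the mean", {
  set.seed(20)
  n <- 100
  x <- matrix(rnorm(n * 20), n, 20, dimnames = list(NULL, paste0("v", 1:20)))
  t <- rnorm(n)
  fit <- vb_ard(x, t)
  xnew <- matrix(rnorm(500 * 20), 500, 20,
                 dimnames = list(NULL, paste0("v", 1:20)))
  pred <- predict(fit, xnew)
  # mean prediction within 3 SE of mean(t); no predictive skill vs fresh noise
  expect_lt(abs(mean(pred) - mean(t)), 3 * sd(t) / sqrt(n))
  expect_lt(abs(cor(pred, rnorm(500))), 3 / sqrt(500))
  # most weights pruned to exactly zero
  expect_gt(sum(coef(fit)[-1] == 0), 10)
})

test_that("duplicated informative columns share the single-column solution", {
  set.seed(30)
  x <- matrix(rnorm(60 * 5), 60, 5)
  x <- cbind(x, x[, 1])
  colnames(x) <- paste0("v", 1:6)
  t <- 1.5 * x[, 1] + rnorm(60, 0, 0.1)
  fit <- vb_ard(x, t)
  single <- vb_ard(x[, c(1, 2:5)], t)
  cf <- coef(fit); cs <- coef(single)
  expect_lt(abs((cf[["v1"]] + cf[["v6"]]) - cs[["v1"]]) / abs(cs[["v1"]]),
            0.01)
  expect_equal(cor(predict(fit, x), t), cor(predict(single, x[, 1:5]), t),
               tolerance = 1e-4)
})

test_that("prediction respects voxel ids and errors on missing columns", {
  set.seed(40)
  x <- matrix(rnorm(40 * 4), 40, 4, dimnames = list(NULL, paste0("v", 1:4)))
  t <- x[, 2] - x[, 4] + rnorm(40, 0, 0.05)
  fit <- vb_ard(x, t)
  xnew <- matrix(rnorm(10 * 4), 10, 4, dimnames = list(NULL, paste0("v", 1:4)))
  p1 <- predict(fit, xnew)
  p2 <- predict(fit, xnew[, c(3, 1, 4, 2)])        # permuted columns
  expect_identical(p1, p2)
  expect_error(predict(fit, xnew[, 1:3]), "v4")
  # all-zero normalised input returns the (destandardised) bias
  x0 <- matrix(rep(fit$x_center, each = 2), 2,
               dimnames = list(NULL, paste0("v", 1:4)))
  expect_equal(predict(fit, x0),
               rep(fit$t_center + fit$t_scale * fit$mu[5], 2))
})

test_that("support recovery holds on model-generated data and scales with t", {
  for (seed in c(101, 202)) {
    set.seed(seed)
    n <- 60; d <- 30; support <- c(3, 11, 25)
    x <- matrix(rnorm(n * d), n, d, dimnames = list(NULL, paste0("v", 1:d)))
    w <- numeric(d); w[support] <- c(1.2, -0.8, 1.0)
    noise_sd <- sqrt(sum(w^2)) / sqrt(10)            # SNR 10 in variance
    t <- as.vector(x %*% w) + rnorm(n, 0, noise_sd)
    fit <- vb_ard(x, t)
    retained <- which(fit$active[1:d])
    expect_true(all(support %in% retained))
    xh <- matrix(rnorm(200 * d), 200, d, dimnames = list(NULL, paste0("v", 1:d)))
    th <- as.vector(xh %*% w) + rnorm(200, 0, noise_sd)
    expect_gt(cor(predict(fit, xh), th), 0.9)
    # scaling the target by c scales the weights by c
    fit2 <- vb_ard(x, 3 * t)
    expect_equal(coef(fit2)[-1], 3 * coef(fit)[-1], tolerance = 1e-6)
  }
})

test_that("the evidence trace is non-decreasing between pruning events", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 50; d <- 15
    x <- matrix(rnorm(n * d), n, d)
    w <- numeric(d); w[1:3] <- c(2, -1, 0.5)
    t <- as.vector(x %*% w) + rnorm(n, 0, 0.5)
    fit <- vb_ard(x, t)
    ev <- fit$trace$evidence
    steps <- setdiff(seq_len(length(ev) - 1), fit$trace$pruned_at)
    diffs <- (ev[steps + 1] - ev[steps]) / pmax(1, abs(ev[steps]))
    expect_gt(min(diffs), -1e-8)
  }
})

test_that("non-finite inputs are rejected", {
  x <- matrix(c(1, NA, 2, 3), 2, 2)
  expect_error(vb_ard(x, c(1, 2)), "non-finite")
})
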