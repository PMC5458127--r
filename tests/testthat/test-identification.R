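test_that("category bank averages items and conserves counts", {
  ft <- make_feature_table(rbind(c(0, 0), c(2, 4), c(5, 5)),
                           c("A", "A", "B"))
  bank <- build_category_bank(ft)
  expect_equal(unname(bank$values["A", ]), c(1, 2))
  expect_equal(unname(bank$values["B", ]), c(5, 5))
  expect_identical(sum(bank$n_items), 3L)
  # one item per category: bank equals the table
  ft1 <- make_feature_table(rbind(c(1, 2), c(3, 4)), c("A", "B"))
  expect_equal(unname(build_category_bank(ft1)$values), unname(ft1$values))
})

test_that("ranking prefers the correlated prototype and matches a
          brute-force oracle", {
  bank <- category_bank(rbind(c(1, 2, 3), c(3, 2, 1)), c("up", "down"),
                        c(1L, 1L), unit_ids = paste0("u", 1:3))
  rk <- identify_rank(c(1, 2, 3), bank)
  expect_identical(rk$category[1], "up")
  expect_equal(rk$score, c(1, -1))

  # brute-force oracle on a random 10-category, 20-unit problem
  set.seed(6)
  bv <- matrix(rnorm(200), 10, 20)
  bank10 <- category_bank(bv, sprintf("c%02d", 1:10), rep(1L, 10),
                          unit_ids = paste0("u", 1:20))
  pred <- rnorm(20)
  oracle <- sapply(1:10, function(i) cor(pred, bv[i, ]))
  expect_equal(identify_rank(pred, bank10)$category,
               sprintf("c%02d", order(-oracle)))
  # zero-variance prototype is ranked last and flagged
  bv[3, ] <- 7
  bank_zv <- category_bank(bv, sprintf("c%02d", 1:10), rep(1L, 10),
                           unit_ids = paste0("u", 1:20))
  rk_zv <- identify_rank(pred, bank_zv)
  expect_identical(rk_zv$category[10], "c03")
  expect_true(rk_zv$zero_variance[10])
  expect_identical(rk_zv$score[10], -Inf)
})

test_that("candidate sets respect pool, exclusions, and seeding", {
  set.seed(7)
  bank <- category_bank(matrix(rnorm(60), 12, 5), sprintf("c%02d", 1:12),
                        rep(1L, 12), unit_ids = paste0("u", 1:5))
  c0 <- sample_candidate_set(bank, "c05", 0)
  expect_identical(c0$category_labels, "c05")
  call <- sample_candidate_set(bank, "c05", 11)
  expect_setequal(call$category_labels, bank$category_labels)
  expect_error(sample_candidate_set(bank, "c05", 12), "insufficient")
  expect_error(sample_candidate_set(bank, "c05", 11, exclusions = "c01"),
               "insufficient")
  set.seed(99); a <- sample_candidate_set(bank, "c05", 5)
  set.seed(99); b <- sample_candidate_set(bank, "c05", 5)
  expect_identical(a$category_labels, b$category_labels)
})

test_that("pairwise accuracy is exact on a hand-enumerable problem", {
  # 3 categories, 4 units; preds equal to their bank rows -> 100%
  bv <- rbind(A = c(1, 0, 0, 1), B = c(0, 1, 1, 0), C = c(1, 1, 0, 0))
  bank <- category_bank(bv, rownames(bv), rep(1L, 3),
                        unit_ids = paste0("u", 1:4))
  preds <- feature_table(bv, rownames(bv), rownames(bv),
                         unit_ids = paste0("u", 1:4))
  out <- pairwise_accuracy(preds, bank)
  expect_equal(out$accuracy, 100)
  expect_identical(out$n_combinations, 6L)

  # hand-built predictions: enumerate every (item, foil) outcome by hand
  pv <- rbind(p1 = c(1, 0, 0, 0.8), p2 = c(1, 0.2, 0.4, 0.9))
  preds2 <- feature_table(pv, c("p1", "p2"), c("A", "B"),
                          unit_ids = paste0("u", 1:4))
  r <- function(a, b) cor(a, b)
  expected <- 100 * mean(c(r(pv[1, ], bv["A", ]) > r(pv[1, ], bv["B", ]),
                           r(pv[1, ], bv["A", ]) > r(pv[1, ], bv["C", ]),
                           r(pv[2, ], bv["B", ]) > r(pv[2, ], bv["A", ]),
                           r(pv[2, ], bv["B", ]) > r(pv[2, ], bv["C", ])))
  expect_equal(pairwise_accuracy(preds2, bank)$accuracy, expected)

  # anti-correlated prediction scores below chance
  anti <- feature_table(-bv["A", , drop = FALSE], "pA", "A",
                        unit_ids = paste0("u", 1:4))
  expect_lt(pairwise_accuracy(anti, bank)$accuracy, 50)
})

test_that("ranking is invariant under an affine map applied to both sides", {
  set.seed(8)
  bv <- matrix(rnorm(50), 5, 10)
  pred <- rnorm(10)
  bank1 <- category_bank(bv, paste0("c", 1:5), rep(1L, 5),
                         unit_ids = paste0("u", 1:10))
  bank2 <- category_bank(2.5 * bv - 4, paste0("c", 1:5), rep(1L, 5),
                         unit_ids = paste0("u", 1:10))
  expect_identical(identify_rank(pred, bank1)$category,
                   identify_rank(2.5 * pred - 4, bank2)$category)
  expect_equal(identify_rank(pred, bank1)$score,
               identify_rank(2.5 * pred - 4, bank2)$score, tolerance = 1e-12)
})

test_that("multi-way identification reduces to pairwise at set size 2 and is
          perfect for exact predictions", {
  set.seed(9)
  bv <- matrix(rnorm(80), 8, 10)
  bank <- category_bank(bv, paste0("c", 1:8), rep(1L, 8),
                        unit_ids = paste0("u", 1:10))
  preds <- feature_table(bv[1:3, ], paste0("c", 1:3), paste0("c", 1:3),
                         unit_ids = paste0("u", 1:10))
  out <- multiway_accuracy(preds, bank, set_size = 4, n_repetitions = 20)
  expect_equal(out$accuracy, 100)
  expect_equal(unname(out$per_item_rank), rep(1, 3))
  # agreement between set_size-2 multiway and pairwise on full enumeration
  set.seed(10)
  noisy <- feature_table(bv[1:3, ] + matrix(rnorm(30, 0, 2), 3),
                         paste0("c", 1:3), paste0("c", 1:3),
                         unit_ids = paste0("u", 1:10))
  mw <- multiway_accuracy(noisy, bank, set_size = 2, n_repetitions = 500)
  pw <- pairwise_accuracy(noisy, bank)
  expect_lt(abs(mw$accuracy - pw$accuracy), 10)   # Monte Carlo vs exhaustive
})

test_that("null multi-way identification sits at chance (set size 10)", {
  set.seed(11)
  nunits <- 12; n_items <- 40
  bv <- matrix(rnorm(120 * nunits), 120, nunits)
  bank <- category_bank(bv, sprintf("c%03d", 1:120), rep(1L, 120),
                        unit_ids = paste0("u", 1:nunits))
  # predictions unrelated to any prototype
  preds <- feature_table(matrix(rnorm(n_items * nunits), n_items),
                         sprintf("c%03d", 1:n_items),
                         sprintf("c%03d", 1:n_items),
                         unit_ids = paste0("u", 1:nunits))
  out <- multiway_accuracy(preds, bank, set_size = 10, n_repetitions = 250)
  # repetitions for one item share its decoded vector, so the null variance
  # is dominated by the per-item win probability p(q) = (1-q)^(k-1), q ~ U:
  # E p = 1/k, E p^2 = 1/(2k-1)
  sd_null <- 100 * sqrt((1 / 19 - 1 / 100) / n_items)
  expect_lt(abs(out$accuracy - 10), 3 * sd_null)
})
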