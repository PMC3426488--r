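test_that("symmetric uncertainty matches hand-computed entropies", {
  # identical two-class variables are fully informative
  x <- c("A", "B", "A", "B")
  expect_equal(symmetric_uncertainty(x, x), 1)
  # a constant variable carries no information
  y <- rep("Z", 4)
  expect_equal(symmetric_uncertainty(x, y), 0)
  # joint counts {(A,A):2, (A,B):1, (B,B):3}
  xx <- c("A", "A", "A", "B", "B", "B")
  yy <- c("A", "A", "B", "B", "B", "B")
  # H(x) = 1, H(y) = -(1/3 log 1/3 + 2/3 log 2/3), H(x,y) from 3 cells
  hx <- 1
  hy <- -(2 / 6 * log2(2 / 6) + 4 / 6 * log2(4 / 6))
  hxy <- -(2 / 6 * log2(2 / 6) + 1 / 6 * log2(1 / 6) + 3 / 6 * log2(3 / 6))
  expect_equal(symmetric_uncertainty(xx, yy), 2 * (hx + hy - hxy) / (hx + hy))
  expect_error(symmetric_uncertainty(x, c("A", "B")), "length mismatch")
})

test_that("symmetric uncertainty is symmetric and bijection-invariant", {
  set.seed(4)
  for (rep in 1:10) {
    x <- sample(letters[1:3], 40, replace = TRUE)
    y <- sample(LETTERS[1:4], 40, replace = TRUE)
    s <- symmetric_uncertainty(x, y)
    expect_equal(s, symmetric_uncertainty(y, x))
    relabel <- setNames(c("w", "u", "v"), letters[1:3])
    expect_equal(symmetric_uncertainty(unname(relabel[x]), y), s)
    expect_gte(s, 0)
    expect_lte(s, 1)
    expect_equal(s, oracle_su(x, y), tolerance = 1e-12)
  }
})

test_that("CFS merit reduces to r_cf for singletons and penalizes duplicates", {
  tab <- random_table(120, accs = c(0.8, 0.5), seed = 6)
  m1 <- cfs_merit(tab, 1)
  expect_equal(m1$merit,
               symmetric_uncertainty(tab$predictions[, 1], tab$true_labels))
  # a pair of identical predictors collapses to the singleton merit
  # (2 r / sqrt(2 + 2) = r): duplication never helps
  dup <- prediction_table(cbind(tab$predictions, copy = tab$predictions[, 1]),
                          true_labels = tab$true_labels)
  expect_equal(cfs_merit(dup, c(1, 3))$merit, m1$merit)
  # among equally informative predictors, adding an exact duplicate
  # strictly lowers the pair's merit
  eq <- random_table(120, accs = c(0.7, 0.7), seed = 16)
  eqd <- prediction_table(cbind(eq$predictions, copy = eq$predictions[, 1]),
                          true_labels = eq$true_labels)
  expect_lt(cfs_merit(eqd, c(1, 2, 3))$merit, cfs_merit(eqd, 1:2)$merit)
  expect_error(cfs_merit(tab, integer(0)), "nonempty")
})

test_that("merit matches the brute-force formula on every subset", {
  tab <- random_table(100, accs = c(0.35, 0.55, 0.7, 0.85), seed = 8)
  for (k in 1:4) {
    combos <- combn(4, k)
    for (ci in seq_len(ncol(combos))) {
      sub <- combos[, ci]
      expect_equal(cfs_merit(tab, sub)$merit,
                   oracle_merit(tab$predictions, tab$true_labels, sub),
                   tolerance = 1e-9)
    }
  }
})

test_that("greedy backward chain is nested and drops duplicates first", {
  # equally skilled predictors, so removals differ only through redundancy;
  # predictor 5 duplicates predictor 1 exactly
  tab <- random_table(150, accs = rep(0.7, 4), seed = 10)
  dup <- prediction_table(cbind(tab$predictions,
                                dup1 = tab$predictions[, 1]),
                          true_labels = tab$true_labels)
  chain <- greedy_backward_chain(dup)
  expect_length(chain$subsets, 5)
  for (k in 1:5) expect_length(chain$subsets[[k]], k)
  for (k in 1:4)
    expect_true(all(chain$subsets[[k]] %in% chain$subsets[[k + 1]]))
  # first removal eliminates one of the two identical copies
  removed <- setdiff(chain$subsets[[5]], chain$subsets[[4]])
  expect_true(removed %in% c(1, 5))
  # and the first removal maximizes merit over all single removals (oracle)
  cand <- sapply(1:5, function(d)
    oracle_merit(dup$predictions, dup$true_labels, setdiff(1:5, d)))
  expect_equal(chain$merits[4], max(cand), tolerance = 1e-9)
})

test_that("select_minimalist returns the chain subset of the requested size", {
  tab <- random_table(150, accs = c(0.75, 0.5, 0.6, 0.55), seed = 10)
  chain <- greedy_backward_chain(tab)
  expect_equal(unname(select_minimalist(tab, 4)), 1:4)
  expect_equal(unname(select_minimalist(tab, 1)), chain$subsets[[1]])
  expect_equal(unname(select_minimalist(tab, 2)), sort(chain$subsets[[2]]))
  expect_error(select_minimalist(tab, 0), "K must be")
  expect_error(select_minimalist(tab, 9), "K must be")
})

test_that("top-K selection agrees with a sorting oracle", {
  tab <- random_table(300, accs = c(0.5, 0.9, 0.3, 0.7, 0.6), seed = 12)
  expect_equal(unname(top_k_by_accuracy(tab, 5)), 1:5)
  acc <- predictor_accuracies(tab)
  expect_equal(unname(top_k_by_accuracy(tab, 1)), unname(which.max(acc)))
  for (k in 1:5) {
    oracle <- sort(order(-acc, seq_along(acc))[1:k])
    expect_equal(unname(top_k_by_accuracy(tab, k)), oracle)
  }
})

test_that("exhaustive search enumerates all combinations and dominates", {
  tab <- random_table(150, accs = c(0.4, 0.8, 0.5, 0.65), seed = 14)
  res <- exhaustive_search(tab, K = 2, scheme = "weighted_vote",
                           folds = 5, seed = 3)
  expect_equal(nrow(res$scores), choose(4, 2))
  expect_equal(res$best_accuracy, max(res$scores$accuracy))
  # K = N is the single full combination
  res4 <- exhaustive_search(tab, K = 4, scheme = "weighted_vote",
                            folds = 5, seed = 3)
  expect_equal(nrow(res4$scores), 1L)
  expect_equal(unname(res4$best_subset), 1:4)
  # the minimalist subset can never beat the exhaustive optimum
  mini <- select_minimalist(tab, 2)
  mini_acc <- cross_validate(tab, subset = mini, scheme = "weighted_vote",
                             folds = 5, seed = 3)$overall_accuracy
  expect_lte(mini_acc, res$best_accuracy)
})

test_that("an independent-errors predictor survives deep into the chain", {
  # three near-duplicate predictors plus one independent one of equal skill:
  # CFS must keep the independent predictor into the size-2 subset
  cfg <- sim_config(
    n_proteins = 600,
    class_priors = c(A = 0.4, B = 0.3, C = 0.3),
    predictors = list(
      predictor_spec("red1", "grp", 0.6),
      predictor_spec("red2", "grp", 0.6),
      predictor_spec("red3", "grp", 0.6),
      predictor_spec("solo", "own", 0.6)),
    group_coupling = 0.95, seed = 21)
  tab <- generate_predictions(cfg)$table
  expect_true("solo" %in% names(select_minimalist(tab, 2)))
})
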