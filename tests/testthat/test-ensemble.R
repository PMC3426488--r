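test_that("one-hot encoding has one active column per (row, predictor)", {
  tab <- prediction_table(cbind(a = c("X", "Y", "X"), b = c("P", "Q", "R")))
  enc <- encode_features(tab, 1)
  expect_equal(dim(enc$X), c(3L, 2L))
  expect_equal(unname(rowSums(enc$X)), rep(1, 3))
  # 2 predictors x (2 + 3) observed labels
  enc2 <- encode_features(tab, 1:2)
  expect_equal(ncol(enc2$X), 5L)
  expect_equal(unname(rowSums(enc2$X)), rep(2, 3))
  expect_equal(colnames(enc2$X), c("a=X", "a=Y", "b=P", "b=Q", "b=R"))
  expect_error(encode_features(tab, integer(0)), "nonempty")
})

test_that("a trained encoder maps novel labels to an all-zero block", {
  train <- prediction_table(cbind(a = c("X", "Y")))
  test <- prediction_table(cbind(a = c("X", "Z")))
  enc <- encode_features(train, 1)
  out <- encode_features(test, 1, encoder = enc$encoder)
  expect_equal(unname(out$X[1, ]), c(1, 0))
  expect_equal(unname(out$X[2, ]), c(0, 0))
})

test_that("weighted voting follows the weighted argmax with vocab tie-break", {
  vocab <- c("A", "B")
  expect_equal(weighted_vote(c("B", "B", "B"), c(0.1, 0.1, 0.1), vocab), "B")
  expect_equal(weighted_vote(c("A", "B"), c(0.9, 0.5), vocab), "A")
  # exact tie resolved by vocabulary order
  expect_equal(weighted_vote(c("A", "B"), c(0.5, 0.5), vocab), "A")
  expect_error(weighted_vote(c("A", "B"), c(-0.1, 0.5), vocab), "negative")
  expect_error(weighted_vote(c("A", "B"), 0.5, vocab), "aligned")
  # the worked example row under equal weights elects the 6-vote majority
  expect_equal(weighted_vote(worked_example_row(), rep(1, 9),
                             unified_locations()), "Nucleus")
})

test_that("equal-weight voting equals plurality voting", {
  tab <- random_table(60, accs = c(0.5, 0.6, 0.7), seed = 31)
  vocab <- sort(unique(tab$true_labels))
  for (j in 1:20) {
    row <- tab$predictions[j, ]
    plur_counts <- sapply(vocab, function(l) sum(row == l))
    plurality <- vocab[which.max(plur_counts)]
    expect_equal(weighted_vote(row, rep(1, 3), vocab), plurality)
  }
})

test_that("weighted_vote training stores per-predictor accuracies as weights", {
  truth <- rep(c("A", "B"), each = 5)
  p1 <- truth; p1[1:2] <- "B"              # accuracy 0.8
  p2 <- truth; p2[1:4] <- "B"              # accuracy 0.6
  tab <- prediction_table(cbind(p1 = p1, p2 = p2), true_labels = truth)
  model <- train_meta(tab, 1:2, scheme = "weighted_vote")
  expect_equal(unname(model$weights), c(0.8, 0.6))
})

test_that("every scheme learns a perfect feature to training accuracy 1", {
  set.seed(40)
  truth <- sample(c("A", "B", "C"), 60, replace = TRUE)
  noise <- sample(c("A", "B", "C"), 60, replace = TRUE)
  tab <- prediction_table(cbind(oracle = truth, rand = noise),
                          true_labels = truth)
  for (scheme in ensemble_schemes()) {
    model <- train_meta(tab, 1:2, scheme = scheme)
    pred <- predict_meta(model, tab)
    expect_equal(overall_accuracy(pred, truth), 1,
                 info = paste("scheme:", scheme))
  }
})

test_that("prediction requires the model's predictor columns", {
  tab <- random_table(50, accs = c(0.8, 0.6), seed = 33)
  model <- train_meta(tab, 1:2, scheme = "weighted_vote")
  expect_error(predict_meta(model, tab[, 1]), "pred2")
  expect_error(train_meta(prediction_table(cbind(a = c("X", "X"),
                                                 b = c("X", "Y")),
                                           true_labels = c("X", "X")),
                          1:2, scheme = "logistic_regression"),
               "single-class")
})

test_that("voting and naive Bayes predictions ignore predictor column order", {
  tab <- random_table(120, accs = c(0.5, 0.7, 0.6), seed = 35)
  perm <- c(3, 1, 2)
  tab_perm <- tab[, perm]
  for (scheme in c("weighted_vote", "naive_bayes")) {
    m1 <- train_meta(tab, 1:3, scheme = scheme)
    m2 <- train_meta(tab_perm, 1:3, scheme = scheme)
    expect_equal(predict_meta(m2, tab_perm), predict_meta(m1, tab),
                 info = paste("scheme:", scheme))
  }
})

test_that("training is deterministic: refitting reproduces predictions", {
  res <- generate_predictions(sim_preset("yeast_lowres", n_proteins = 200,
                                         seed = 17))
  for (scheme in ensemble_schemes()) {
    m1 <- train_meta(res$table, 1:9, scheme = scheme)
    m2 <- train_meta(res$table, 1:9, scheme = scheme)
    expect_identical(predict_meta(m1, res$table),
                     predict_meta(m2, res$table),
                     info = paste("scheme:", scheme))
  }
})

test_that("multinomial LR agrees with an independent reference fit", {
  skip_if_not_installed("nnet")
  res <- generate_predictions(sim_preset("yeast_lowres", n_proteins = 700,
                                         seed = 23))
  train <- res$table[1:500, ]
  test <- res$table[501:700, ]
  model <- train_meta(train, 1:9, scheme = "logistic_regression")
  mine <- predict_meta(model, test)

  # reference: nnet multinomial regression on identical encodings
  enc <- encode_features(train, 1:9)
  Xtr <- enc$X
  Xte <- encode_features(test, 1:9, encoder = enc$encoder)$X
  colnames(Xtr) <- colnames(Xte) <- paste0("V", seq_len(ncol(Xtr)))
  df_tr <- data.frame(y = factor(train$true_labels), Xtr)
  ref <- nnet::multinom(y ~ ., data = df_tr, trace = FALSE, maxit = 500,
                        decay = 1e-4)
  ref_pred <- as.character(predict(ref, newdata = data.frame(Xte)))
  expect_gte(mean(mine == ref_pred), 0.99)
})

test_that("the full ensemble beats its best component out of sample", {
  accs <- sapply(1:5, function(r) {
    res <- generate_predictions(sim_preset("yeast_lowres", n_proteins = 1600,
                                           seed = 50 + r))
    train <- res$table[1:800, ]
    test <- res$table[801:1600, ]
    model <- train_meta(train, 1:9, scheme = "logistic_regression")
    ens <- overall_accuracy(predict_meta(model, test), test$true_labels)
    best <- max(predictor_accuracies(test))
    c(ens = ens, best = best)
  })
  expect_gt(mean(accs["ens", ]), mean(accs["best", ]))
})
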