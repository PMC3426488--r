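#' One-hot encode predictor outputs
#'
#' Builds the design matrix used by the classifier-based ensemble schemes:
#' one binary column per (predictor, observed label) pair. When an existing
#' encoder is supplied (prediction time), labels unseen at training map to an
#' all-zero block for that predictor.
#'
#' @param table a \code{\link{prediction_table}}.
#' @param subset predictor indices or names (nonempty).
#' @param encoder optional encoder from a previous call; when \code{NULL} a
#'   new encoder is built from the observed labels.
#' @return list with \code{X} (numeric matrix, one row per protein) and
#'   \code{encoder} (per-predictor label sets defining the columns).
#' @export
encode_features <- function(table, subset, encoder = NULL) {
  stopifnot(inherits(table, "prediction_table"))
  idx <- resolve_predictors(table, subset)
  if (length(idx) == 0) stop("subset must be nonempty")
  nms <- table$predictor_names[idx]
  if (is.null(encoder)) {
    encoder <- lapply(idx, function(j) sort(unique(table$predictions[, j])))
    names(encoder) <- nms
  } else {
    missing <- setdiff(names(encoder), table$predictor_names)
    if (length(missing) > 0)
      stop("table lacks predictor column(s): ", paste(missing, collapse = ", "))
    nms <- names(encoder)
    idx <- match(nms, table$predictor_names)
  }
  blocks <- lapply(seq_along(nms), function(b) {
    labs <- encoder[[b]]
    col <- table$predictions[, idx[b]]
    m <- matrix(0, nrow = length(col), ncol = length(labs),
                dimnames = list(NULL, paste(nms[b], labs, sep = "=")))
    hit <- match(col, labs)
    ok <- !is.na(hit)
    m[cbind(which(ok), hit[ok])] <- 1
    m
  })
  X <- do.call(cbind, blocks)
  rownames(X) <- table$protein_ids
  list(X = X, encoder = encoder)
}

#' Accuracy-weighted vote on one protein
#'
#' Each predictor casts its weight for its predicted label; the label with
#' the largest weighted sum wins. Votes for labels outside the vocabulary are
#' ignored; ties are broken by vocabulary order.
#'
#' @param row per-predictor labels for one protein.
#' @param weights nonnegative per-predictor weights (typically training
#'   accuracies).
#' @param vocabulary ordered unified label vocabulary.
#' @return the winning label.
#' @export
weighted_vote <- function(row, weights, vocabulary) {
  if (length(row) != length(weights))
    stop("weights not aligned with predictors (", length(weights), " vs ",
         length(row), ")")
  if (any(weights < 0)) stop("negative weight")
  score <- vapply(vocabulary, function(l) sum(weights[row == l]), numeric(1))
  vocabulary[which.max(score)]
}

# LDA-weighted voting: a Fisher discriminant learns one scalar weight per
# predictor separating (protein, location) agreement patterns of true
# locations from false ones; prediction maximizes the weighted vote sum plus
# a log-prior offset per location. This is a voting scheme -- the weight a
# predictor carries does not depend on which label it votes for -- which is
# what distinguishes it from the unrestricted classifier schemes.
# A ridge term on the pooled covariance absorbs collinearity between
# predictors that vote (nearly) identically.
fit_lda_vote <- function(preds, truth, classes, ridge = 1e-6) {
  np <- ncol(preds)
  n <- nrow(preds)
  # one row per (protein, candidate location): z_i = [predictor i votes L]
  Z <- do.call(rbind, lapply(classes, function(L) (preds == L) * 1))
  ybin <- as.vector(vapply(classes, function(L) truth == L, logical(n)))
  mu1 <- colMeans(Z[ybin, , drop = FALSE])
  mu0 <- colMeans(Z[!ybin, , drop = FALSE])
  Sw <- (crossprod(sweep(Z[ybin, , drop = FALSE], 2, mu1)) +
         crossprod(sweep(Z[!ybin, , drop = FALSE], 2, mu0))) /
    max(1, nrow(Z) - 2) + diag(ridge, np)
  w <- solve(Sw, mu1 - mu0)
  # orient so that agreeing with the truth raises the score
  if (sum(w * (mu1 - mu0)) < 0) w <- -w
  # put the discriminant on its log-likelihood-ratio scale so the vote score
  # and the location log-prior combine on comparable footing
  s <- as.numeric(Z %*% w)
  m1 <- mean(s[ybin]); m0 <- mean(s[!ybin])
  v <- (sum((s[ybin] - m1)^2) + sum((s[!ybin] - m0)^2)) /
    max(1, length(s) - 2)
  a <- if (v > 0) (m1 - m0) / v else 1
  prior <- vapply(classes, function(L) mean(truth == L), numeric(1))
  list(w = as.numeric(w) * a, offset = log(pmax(prior, 1e-12)),
       classes = classes)
}

predict_lda_vote <- function(fit, preds) {
  scores <- vapply(seq_along(fit$classes), function(k) {
    as.numeric((preds == fit$classes[k]) %*% fit$w) + fit$offset[k]
  }, numeric(nrow(preds)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  colnames(scores) <- fit$classes
  scores
}

#' Ensemble schemes
#'
#' @return character vector of supported scheme ids.
#' @export
ensemble_schemes <- function() {
  c("weighted_vote", "lda", "naive_bayes", "decision_tree",
    "logistic_regression")
}

# predictor columns of the subset as a data.frame of factors with the
# encoder's label sets as levels (unseen labels become NA at predict time)
factor_frame <- function(table, encoder) {
  nms <- names(encoder)
  idx <- match(nms, table$predictor_names)
  if (anyNA(idx))
    stop("table lacks predictor column(s): ",
         paste(nms[is.na(idx)], collapse = ", "))
  df <- as.data.frame(lapply(seq_along(nms), function(b) {
    factor(table$predictions[, idx[b]], levels = encoder[[b]])
  }), col.names = make.names(nms), stringsAsFactors = TRUE)
  df
}

#' Train a meta-classifier ensemble
#'
#' Fits an ensemble over the categorical outputs of the selected predictors.
#' Voting uses each predictor's training accuracy as its weight. The
#' classifier schemes treat predictor outputs as nominal features (one-hot
#' encoded for LDA and logistic regression) with the true location as the
#' multinomial target:
#' \describe{
#'   \item{weighted_vote}{accuracy-weighted plurality voting;}
#'   \item{lda}{LDA-weighted voting: a Fisher discriminant (ridge
#'     \code{1e-6} on the pooled covariance) learns one weight per predictor
#'     from (protein, candidate-location) agreement patterns; prediction
#'     maximizes the weighted vote sum plus a location log-prior. Unlike the
#'     classifier schemes this remains a voting rule — a predictor carries
#'     the same weight whatever label it votes for;}
#'   \item{naive_bayes}{categorical naive Bayes with Laplace add-one
#'     smoothing;}
#'   \item{decision_tree}{CART tree, minimum leaf size 2, no complexity
#'     pruning;}
#'   \item{logistic_regression}{multinomial (softmax) regression with mild L2
#'     regularization (default \code{lambda = 1e-3}) so that separable
#'     one-hot data still converge.}
#' }
#' All schemes are deterministic given the training table. Prediction ties
#' are broken by vocabulary order.
#'
#' @param table a \code{\link{prediction_table}} with true labels.
#' @param subset predictor indices or names.
#' @param scheme one of \code{\link{ensemble_schemes}}.
#' @param vocabulary ordered label vocabulary; defaults to the sorted set of
#'   observed true labels.
#' @param lr_lambda L2 penalty for logistic regression.
#' @param lda_ridge ridge added to the pooled covariance for LDA.
#' @return an object of class \code{ensemble_model}.
#' @export
train_meta <- function(table, subset, scheme = "logistic_regression",
                       vocabulary = NULL, lr_lambda = 1e-3,
                       lda_ridge = 1e-6) {
  stopifnot(inherits(table, "prediction_table"))
  scheme <- match.arg(scheme, ensemble_schemes())
  if (is.null(table$true_labels)) stop("training requires true labels")
  idx <- resolve_predictors(table, subset)
  rows <- complete_rows(table)
  sub_tab <- table[rows, idx]
  truth <- table$true_labels[rows]
  if (is.null(vocabulary)) vocabulary <- sort(unique(truth))
  observed <- vocabulary[vocabulary %in% truth]
  if (length(observed) < 2 && scheme %in% c("lda", "logistic_regression"))
    stop("single-class training data; cannot fit ", scheme)
  y <- factor(truth, levels = observed)
  enc <- encode_features(sub_tab, seq_along(idx))

  fit <- weights <- NULL
  if (scheme == "weighted_vote") {
    weights <- predictor_accuracies(sub_tab)
  } else if (scheme == "logistic_regression") {
    X <- enc$X
    if (ncol(X) < 2) X <- cbind(X, `.pad` = 0)  # glmnet needs >= 2 columns
    # warm-start down a lambda path for reliable convergence at weak penalty
    fit <- glmnet::glmnet(X, y, family = "multinomial", alpha = 0,
                          lambda = lr_lambda * 10^seq(3, 0, by = -0.5),
                          standardize = FALSE)
  } else if (scheme == "lda") {
    fit <- fit_lda_vote(sub_tab$predictions, truth, observed,
                        ridge = lda_ridge)
  } else if (scheme == "naive_bayes") {
    df <- factor_frame(sub_tab, enc$encoder)
    fit <- e1071::naiveBayes(df, y, laplace = 1)
  } else if (scheme == "decision_tree") {
    df <- factor_frame(sub_tab, enc$encoder)
    df$.class <- y
    fit <- rpart::rpart(.class ~ ., data = df, method = "class",
                        control = rpart::rpart.control(
                          minsplit = 4, minbucket = 2, cp = 0,
                          maxdepth = 30, xval = 0))
  }
  structure(list(scheme = scheme,
                 selected_predictors = table$predictor_names[idx],
                 label_vocabulary = vocabulary,
                 observed_classes = observed,
                 encoder = enc$encoder,
                 weights = weights, fit = fit, lr_lambda = lr_lambda),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat("<ensemble_model> scheme:", x$scheme, "\n")
  cat("predictors:", paste(x$selected_predictors, collapse = ", "), "\n")
  cat("vocabulary:", paste(x$label_vocabulary, collapse = ", "), "\n")
  invisible(x)
}

# argmax over a posterior/score matrix with columns named by class,
# breaking ties by vocabulary order
argmax_by_vocab <- function(prob, vocabulary) {
  classes <- vocabulary[vocabulary %in% colnames(prob)]
  prob <- prob[, classes, drop = FALSE]
  classes[max.col(prob, ties.method = "first")]
}

#' Predict with a fitted ensemble model
#'
#' @param model an \code{\link{ensemble_model}} from \code{\link{train_meta}}.
#' @param table a \code{\link{prediction_table}} containing the model's
#'   selected predictor columns (extra columns are ignored).
#' @return character vector of unified labels, one per protein.
#' @export
predict_meta <- function(model, table) {
  stopifnot(inherits(model, "ensemble_model"),
            inherits(table, "prediction_table"))
  missing <- setdiff(model$selected_predictors, table$predictor_names)
  if (length(missing) > 0)
    stop("table lacks predictor column(s): ", paste(missing, collapse = ", "))
  idx <- match(model$selected_predictors, table$predictor_names)
  preds <- table$predictions[, idx, drop = FALSE]
  vocab <- model$label_vocabulary

  if (model$scheme == "weighted_vote") {
    out <- apply(preds, 1, weighted_vote, weights = model$weights,
                 vocabulary = vocab)
    return(unname(out))
  }
  sub_tab <- table[, idx]
  if (model$scheme == "logistic_regression") {
    X <- encode_features(sub_tab, seq_along(idx), encoder = model$encoder)$X
    if (ncol(X) < 2) X <- cbind(X, `.pad` = 0)
    prob <- drop(predict(model$fit, newx = X, type = "response",
                         s = model$lr_lambda))
    if (is.null(dim(prob))) prob <- matrix(prob, nrow = 1,
                                           dimnames = list(NULL, names(prob)))
    return(argmax_by_vocab(prob, vocab))
  }
  if (model$scheme == "lda") {
    scores <- predict_lda_vote(model$fit, preds)
    return(argmax_by_vocab(scores, vocab))
  }
  df <- factor_frame(sub_tab, model$encoder)
  if (model$scheme == "naive_bayes") {
    prob <- predict(model$fit, df, type = "raw")
    return(argmax_by_vocab(prob, vocab))
  }
  if (model$scheme == "decision_tree") {
    prob <- predict(model$fit, df, type = "prob")
    return(argmax_by_vocab(prob, vocab))
  }
  stop("unknown scheme: ", model$scheme)
}
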