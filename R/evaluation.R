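#' Overall accuracy
#'
#' Fraction of proteins whose predicted location equals the annotation — the
#' multiclass generalization of (TP+TN)/(TP+TN+FP+FN).
#'
#' @param pred,truth label vectors of equal length.
#' @return value in \[0, 1\].
#' @export
overall_accuracy <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("length mismatch: ", length(pred), " vs ", length(truth))
  if (length(pred) < 1) stop("need at least one prediction")
  mean(pred == truth)
}

#' Per-class Matthews correlation coefficient
#'
#' One-vs-rest binarization against \code{cls}:
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FN)(TP+FP)(TN+FP)(TN+FN)}}}
#' By convention the value is 0 whenever a denominator factor is 0.
#'
#' @param pred,truth label vectors of equal length.
#' @param cls the positive class.
#' @return value in \[-1, 1\].
#' @export
per_class_mcc <- function(pred, truth, cls) {
  if (length(pred) != length(truth))
    stop("length mismatch: ", length(pred), " vs ", length(truth))
  tp <- sum(pred == cls & truth == cls)
  tn <- sum(pred != cls & truth != cls)
  fp <- sum(pred == cls & truth != cls)
  fn <- sum(pred != cls & truth == cls)
  denom <- sqrt(as.numeric(tp + fn) * (tp + fp) * (tn + fp) * (tn + fn))
  if (denom == 0) return(0)
  (as.numeric(tp) * tn - as.numeric(fp) * fn) / denom
}

per_class_confusion <- function(pred, truth, classes) {
  t(vapply(classes, function(cls) {
    c(TP = sum(pred == cls & truth == cls),
      FP = sum(pred == cls & truth != cls),
      TN = sum(pred != cls & truth != cls),
      FN = sum(pred != cls & truth == cls))
  }, numeric(4)))
}

# run expr with a reproducible RNG state, restoring the caller's stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

#' Stratified fold assignment
#'
#' Assigns each protein to one of \code{folds} test folds, stratified by true
#' location so every fold sees (approximately) the dataset's class mix.
#' Classes with fewer members than folds fall back to plain random assignment
#' with a warning.
#'
#' @param truth vector of true labels.
#' @param folds number of folds (>= 2).
#' @param seed RNG seed.
#' @return integer vector of fold ids in 1..folds.
#' @export
make_folds <- function(truth, folds = 10, seed = 1) {
  if (folds < 2) stop("folds must be >= 2")
  if (length(truth) < folds) stop("fewer proteins than folds")
  n <- length(truth)
  assign <- integer(n)
  with_seed(seed, {
    for (cls in sort(unique(truth))) {
      members <- which(truth == cls)
      if (length(members) < folds) {
        warning("class '", cls, "' has fewer members (", length(members),
                ") than folds; assigning non-stratified")
        assign[members] <- sample.int(folds, length(members), replace = TRUE)
      } else {
        ids <- rep_len(seq_len(folds), length(members))
        assign[members] <- sample(ids)
      }
    }
  })
  assign
}

#' Cross-validated evaluation of an ensemble
#'
#' Runs seeded stratified k-fold cross-validation: within each fold the
#' ensemble (and, optionally, the predictor subset) is fit on the training
#' rows only and applied to the held-out rows; pooled held-out predictions
#' are scored by overall accuracy and per-class MCC.
#'
#' By default the supplied subset is held fixed across folds
#' (\code{selection = "fixed"}). With \code{selection = "cfs"} or
#' \code{"topk"} the subset of size \code{K} is re-selected inside every
#' training fold, so subset selection never sees test rows.
#'
#' @param table a \code{\link{prediction_table}} with true labels.
#' @param subset predictor indices or names (ignored unless
#'   \code{selection = "fixed"}); default all predictors.
#' @param scheme ensemble scheme id (see \code{\link{train_meta}}).
#' @param folds number of folds.
#' @param seed RNG seed controlling fold assignment.
#' @param selection \code{"fixed"}, \code{"cfs"} or \code{"topk"}.
#' @param K subset size for in-fold selection.
#' @param ... passed to \code{\link{train_meta}}.
#' @return an object of class \code{eval_report}: overall accuracy, per-class
#'   MCC, per-class confusion counts, pooled predictions, fold assignment and
#'   the per-fold selected subsets.
#' @export
cross_validate <- function(table, subset = NULL, scheme = "logistic_regression",
                           folds = 10, seed = 1,
                           selection = c("fixed", "cfs", "topk"), K = NULL,
                           ...) {
  stopifnot(inherits(table, "prediction_table"))
  selection <- match.arg(selection)
  if (is.null(table$true_labels)) stop("evaluation requires true labels")
  rows <- complete_rows(table)
  tab <- table[rows, ]
  truth <- tab$true_labels
  if (is.null(subset)) subset <- seq_len(n_predictors(tab))
  vocab <- sort(unique(truth))
  fold_id <- make_folds(truth, folds = folds, seed = seed)
  pred <- character(length(truth))
  fold_subsets <- vector("list", folds)
  for (f in seq_len(folds)) {
    test <- which(fold_id == f)
    train <- which(fold_id != f)
    train_tab <- tab[train, ]
    sub_f <- switch(selection,
      fixed = resolve_predictors(tab, subset),
      cfs = select_minimalist(train_tab, K),
      topk = top_k_by_accuracy(train_tab, K))
    fold_subsets[[f]] <- tab$predictor_names[sub_f]
    model <- train_meta(train_tab, sub_f, scheme = scheme,
                        vocabulary = vocab, ...)
    pred[test] <- predict_meta(model, tab[test, ])
  }
  mcc <- vapply(vocab, function(cls) per_class_mcc(pred, truth, cls),
                numeric(1))
  structure(list(overall_accuracy = overall_accuracy(pred, truth),
                 per_class_mcc = mcc,
                 confusion = per_class_confusion(pred, truth, vocab),
                 n = length(truth),
                 predictions = pred, truth = truth,
                 fold_id = fold_id, fold_subsets = fold_subsets,
                 scheme = scheme, folds = folds, seed = seed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d-fold CV, scheme %s, n=%d\n", x$folds,
              x$scheme, x$n))
  cat(sprintf("overall accuracy: %.4f\n", x$overall_accuracy))
  print(round(x$per_class_mcc, 4))
  invisible(x)
}

#' Cross-validated performance as a function of subset size K
#'
#' Drives the performance-versus-K experiment: in \code{"exhaustive"} mode
#' every size-K combination is evaluated (the dot cloud); in
#' \code{"minimalist"} mode only the greedy backward CFS chain subset per K;
#' in \code{"topk"} mode the K individually most accurate predictors. Fold
#' assignment is shared across subsets and schemes so scores are comparable.
#'
#' @param table a \code{\link{prediction_table}} with true labels.
#' @param schemes character vector of scheme ids.
#' @param mode \code{"exhaustive"}, \code{"minimalist"} or \code{"topk"}.
#' @param folds,seed CV parameters.
#' @param ks subset sizes to evaluate (default 2..N).
#' @return data.frame with columns \code{K}, \code{subset} (comma-joined
#'   predictor names), \code{scheme}, \code{accuracy} and \code{minimalist}
#'   (flag marking greedy-chain subsets).
#' @export
performance_vs_k <- function(table, schemes = "logistic_regression",
                             mode = c("exhaustive", "minimalist", "topk"),
                             folds = 10, seed = 1,
                             ks = 2:n_predictors(table)) {
  stopifnot(inherits(table, "prediction_table"))
  mode <- match.arg(mode)
  np <- n_predictors(table)
  if (any(ks < 1 | ks > np)) stop("ks out of range 1..", np)
  chain <- if (np >= 2) greedy_backward_chain(table) else NULL
  chain_key <- vapply(seq_len(np), function(k) {
    if (is.null(chain)) "" else paste(sort(chain$subsets[[k]]), collapse = ",")
  }, character(1))
  rows <- list()
  for (K in ks) {
    subs <- switch(mode,
      exhaustive = {
        cm <- utils::combn(np, K)
        lapply(seq_len(ncol(cm)), function(i) cm[, i])
      },
      minimalist = list(sort(unname(select_minimalist(table, K)))),
      topk = list(sort(unname(top_k_by_accuracy(table, K)))))
    for (sub in subs) {
      key <- paste(sort(sub), collapse = ",")
      for (sc in schemes) {
        rep <- cross_validate(table, subset = sub, scheme = sc,
                              folds = folds, seed = seed)
        rows[[length(rows) + 1]] <- data.frame(
          K = K,
          subset = paste(table$predictor_names[sub], collapse = ","),
          scheme = sc,
          accuracy = rep$overall_accuracy,
          minimalist = identical(key, chain_key[K]),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
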