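#' Symmetric uncertainty between two categorical variables
#'
#' Normalized mutual information \eqn{2 I(X;Y) / (H(X) + H(Y))} with entropies
#' in bits; the canonical correlation measure for nominal attributes in
#' correlation-based feature selection. Returns 0 when both variables are
#' constant (\eqn{H(X)+H(Y)=0}) and 1 when the variables determine each other.
#'
#' @param x,y categorical vectors of equal length.
#' @return a value in \[0, 1\].
#' @export
symmetric_uncertainty <- function(x, y) {
  if (length(x) != length(y))
    stop("length mismatch: ", length(x), " vs ", length(y))
  if (length(x) < 1) stop("need at least one observation")
  n <- length(x)
  joint <- table(x, y)
  px <- rowSums(joint) / n
  py <- colSums(joint) / n
  hx <- -sum(ifelse(px > 0, px * log2(px), 0))
  hy <- -sum(ifelse(py > 0, py * log2(py), 0))
  if (hx + hy == 0) return(0)
  pj <- joint / n
  hxy <- -sum(ifelse(pj > 0, pj * log2(pj), 0))
  mi <- hx + hy - hxy
  max(0, min(1, 2 * mi / (hx + hy)))
}

# pairwise SU among predictor columns and between each predictor and truth,
# on complete rows only; shared by cfs_merit and the greedy chain
su_matrices <- function(table) {
  rows <- complete_rows(table)
  if (length(rows) < 1) stop("no complete rows")
  preds <- table$predictions[rows, , drop = FALSE]
  truth <- table$true_labels[rows]
  np <- ncol(preds)
  r_cf <- vapply(seq_len(np), function(i) symmetric_uncertainty(preds[, i], truth),
                 numeric(1))
  r_ff <- diag(1, np)
  if (np > 1) {
    for (i in seq_len(np - 1)) for (j in seq(i + 1, np)) {
      r_ff[i, j] <- r_ff[j, i] <- symmetric_uncertainty(preds[, i], preds[, j])
    }
  }
  names(r_cf) <- table$predictor_names
  dimnames(r_ff) <- list(table$predictor_names, table$predictor_names)
  list(r_cf = r_cf, r_ff = r_ff)
}

merit_from_su <- function(su, subset) {
  k <- length(subset)
  rcf <- mean(su$r_cf[subset])
  if (k == 1) return(rcf)
  m <- su$r_ff[subset, subset]
  rff <- mean(m[upper.tri(m)])
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

#' CFS merit of a predictor subset
#'
#' Correlation-based feature selection scores a subset of k predictors by
#' \deqn{Merit = \frac{k \, \bar r_{cf}}{\sqrt{k + k(k-1) \bar r_{ff}}}}
#' where \eqn{\bar r_{cf}} is the mean symmetric uncertainty between subset
#' members and the true location and \eqn{\bar r_{ff}} the mean symmetric
#' uncertainty between member pairs. High merit means the members are jointly
#' informative about the class yet mutually non-redundant.
#'
#' @param table a \code{\link{prediction_table}} with true labels.
#' @param subset predictor indices or names (nonempty).
#' @return list with \code{subset} (names), \code{indices} and \code{merit}.
#' @export
cfs_merit <- function(table, subset) {
  stopifnot(inherits(table, "prediction_table"))
  if (is.null(table$true_labels)) stop("CFS merit requires true labels")
  idx <- resolve_predictors(table, subset)
  if (length(idx) == 0) stop("subset must be nonempty")
  su <- su_matrices(table)
  list(subset = table$predictor_names[idx], indices = idx,
       merit = merit_from_su(su, idx))
}

resolve_predictors <- function(table, subset) {
  if (is.character(subset)) {
    idx <- match(subset, table$predictor_names)
    if (anyNA(idx))
      stop("unknown predictor(s): ", paste(subset[is.na(idx)], collapse = ", "))
  } else {
    idx <- as.integer(subset)
    if (any(idx < 1 | idx > n_predictors(table)))
      stop("predictor index out of range")
  }
  if (anyDuplicated(idx)) stop("duplicated predictors in subset")
  idx
}

#' Greedy backward elimination chain of predictor subsets
#'
#' Starting from the full predictor set, repeatedly removes the single
#' predictor whose removal leaves the subset with the highest CFS merit,
#' recording every intermediate subset down to size 1. The recorded chain is
#' nested: each subset is its predecessor minus exactly one predictor. Ties in
#' merit (within 1e-12) are broken by removing the predictor with the lowest
#' standalone class correlation, then by column order.
#'
#' @param table a \code{\link{prediction_table}} with true labels and at
#'   least 2 predictors.
#' @return an object of class \code{subset_chain}: list with \code{subsets}
#'   (list indexed by size; \code{subsets[[k]]} is the size-k predictor index
#'   set) and \code{merits} (CFS merit of each recorded subset).
#' @export
greedy_backward_chain <- function(table) {
  stopifnot(inherits(table, "prediction_table"))
  if (is.null(table$true_labels)) stop("selection requires true labels")
  np <- n_predictors(table)
  if (np < 2) stop("need at least 2 predictors")
  su <- su_matrices(table)
  subsets <- vector("list", np)
  merits <- numeric(np)
  cur <- seq_len(np)
  subsets[[np]] <- cur
  merits[np] <- merit_from_su(su, cur)
  for (k in seq(np - 1, 1)) {
    cand_merit <- vapply(seq_along(cur),
                         function(d) merit_from_su(su, cur[-d]), numeric(1))
    best <- max(cand_merit)
    tied <- which(cand_merit >= best - 1e-12)
    if (length(tied) > 1) {
      # remove the least class-informative predictor among tied removals
      rcf <- su$r_cf[cur[tied]]
      tied <- tied[rcf <= min(rcf) + 1e-12]
    }
    drop <- tied[1]
    cur <- cur[-drop]
    subsets[[k]] <- cur
    merits[k] <- merit_from_su(su, cur)
  }
  structure(list(subsets = subsets, merits = merits,
                 predictor_names = table$predictor_names),
            class = "subset_chain")
}

#' @export
print.subset_chain <- function(x, ...) {
  for (k in rev(seq_along(x$subsets))) {
    cat(sprintf("K=%d  merit=%.4f  {%s}\n", k, x$merits[k],
                paste(x$predictor_names[x$subsets[[k]]], collapse = ", ")))
  }
  invisible(x)
}

#' Minimalist predictor subset of size K
#'
#' Returns the size-K subset recorded by the greedy backward CFS chain — the
#' package's approximation to the smallest predictor set whose joint
#' predictions correlate best with the true locations.
#'
#' @param table a \code{\link{prediction_table}} with true labels.
#' @param K subset size, 1..number of predictors.
#' @return integer vector of predictor indices (named by predictor).
#' @export
select_minimalist <- function(table, K) {
  np <- n_predictors(table)
  if (K < 1 || K > np) stop("K must be in 1..", np)
  if (np == 1) return(stats::setNames(1L, table$predictor_names))
  chain <- greedy_backward_chain(table)
  idx <- chain$subsets[[K]]
  stats::setNames(idx, table$predictor_names[idx])
}

#' Per-predictor overall accuracy
#'
#' @param table a \code{\link{prediction_table}} with true labels.
#' @return named numeric vector of training accuracies over complete rows.
#' @export
predictor_accuracies <- function(table) {
  stopifnot(inherits(table, "prediction_table"))
  if (is.null(table$true_labels)) stop("accuracies require true labels")
  rows <- complete_rows(table)
  acc <- colMeans(table$predictions[rows, , drop = FALSE] ==
                    table$true_labels[rows])
  stats::setNames(acc, table$predictor_names)
}

#' Top-K predictors by accuracy
#'
#' Baseline selection strategy: keep the K individually most accurate
#' predictors, ignoring redundancy. Ties are broken by column order.
#'
#' @inheritParams select_minimalist
#' @return integer vector of predictor indices (named by predictor).
#' @export
top_k_by_accuracy <- function(table, K) {
  np <- n_predictors(table)
  if (K < 1 || K > np) stop("K must be in 1..", np)
  acc <- predictor_accuracies(table)
  idx <- order(-acc, seq_len(np))[seq_len(K)]
  idx <- sort(idx)
  stats::setNames(idx, table$predictor_names[idx])
}

#' Exhaustive search over all size-K predictor combinations
#'
#' Evaluates every size-K subset by cross-validated ensemble accuracy and
#' returns the best one along with the full score list (the "dot cloud" of a
#' performance-versus-K plot). Only feasible when \code{choose(N, K)} is of
#' desk scale.
#'
#' @param table a \code{\link{prediction_table}} with true labels.
#' @param K subset size.
#' @param scheme ensemble scheme id (see \code{\link{train_meta}}).
#' @param folds number of CV folds.
#' @param seed RNG seed for the fold assignment (shared by all subsets, so
#'   scores are directly comparable).
#' @return list with \code{best_subset} (indices), \code{best_accuracy}, and
#'   \code{scores}: data.frame of subset (comma-joined names) and accuracy.
#' @export
exhaustive_search <- function(table, K, scheme = "logistic_regression",
                              folds = 10, seed = 1) {
  np <- n_predictors(table)
  if (K < 1 || K > np) stop("K must be in 1..", np)
  combos <- utils::combn(np, K)
  accs <- numeric(ncol(combos))
  labels <- character(ncol(combos))
  for (c_i in seq_len(ncol(combos))) {
    sub <- combos[, c_i]
    rep <- cross_validate(table, subset = sub, scheme = scheme,
                          folds = folds, seed = seed)
    accs[c_i] <- rep$overall_accuracy
    labels[c_i] <- paste(table$predictor_names[sub], collapse = ",")
  }
  best <- which.max(accs)
  list(best_subset = stats::setNames(combos[, best],
                                     table$predictor_names[combos[, best]]),
       best_accuracy = accs[best],
       scores = data.frame(subset = labels, accuracy = accs,
                           stringsAsFactors = FALSE))
}
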