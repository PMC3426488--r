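#' Vote profile of one protein
#'
#' Summarizes how the component predictors voted on a single protein. For a
#' protein with true location \code{real}, the profile records the majority
#' vote count (\code{vmax}), the second-majority count (\code{vsec}), the
#' number of correct votes (\code{vcorrect}), and, per predictor, the number
#' of predictors agreeing with it (\code{v_pi}, including itself). Each
#' predictor is classified by exactly one indicator:
#' \describe{
#'   \item{alpha}{correct and in a minority group (its label's count is below
#'     \code{vmax}) — the prediction is uniquely valuable;}
#'   \item{beta}{correct and in the majority group (count equals
#'     \code{vmax}); ties for the top count all belong to the majority
#'     group;}
#'   \item{theta}{incorrect.}
#' }
#'
#' @param row character vector of per-predictor labels for one protein.
#' @param true_label the protein's annotated location.
#' @return an object of class \code{vote_profile}: list with \code{vmax},
#'   \code{vsec}, \code{vcorrect}, \code{v_pi}, \code{alpha}, \code{beta},
#'   \code{theta} and the label count table.
#' @examples
#' vp <- vote_profile(c("Cytosol", "Nucleus", "Nucleus", "Mitochondrion",
#'                      "Nucleus", "Cytosol", "Nucleus", "Nucleus", "Nucleus"),
#'                    "Cytosol")
#' vp$vmax  # 6
#' @export
vote_profile <- function(row, true_label) {
  row <- trimws(as.character(row))
  true_label <- trimws(true_label)
  if (length(row) < 2) stop("need at least 2 predictors")
  if (all(row == "NA")) stop("all predictions missing for this protein")
  counts <- table(row)
  vmax <- max(counts)
  not_top <- counts[counts < vmax]
  vsec <- if (length(not_top) > 0) max(not_top) else 0L
  vcorrect <- sum(row == true_label)
  v_pi <- as.integer(counts[row])
  correct <- row == true_label
  alpha <- as.integer(correct & v_pi < vmax)
  beta <- as.integer(correct & v_pi == vmax)
  theta <- as.integer(!correct)
  structure(list(vmax = as.integer(vmax), vsec = as.integer(vsec),
                 vcorrect = as.integer(vcorrect), v_pi = v_pi,
                 alpha = alpha, beta = beta, theta = theta,
                 counts = counts),
            class = "vote_profile")
}

#' Per-protein contribution of one predictor
#'
#' The contribution score rewards predictors that are correct when most of
#' the ensemble is wrong, and penalizes incorrect votes more heavily the more
#' predictors share them. For predictor \code{i} on one protein the term is
#' \deqn{\alpha_i (2 v_{max} - v_{p_i}) + \beta_i v_{sec} +
#'       \theta_i (v_{correct} - v_{p_i} - v_{max})}
#' so a correct minority vote earns up to \eqn{2 v_{max} - 1}, a correct
#' majority vote earns the (small) second-majority count, and an incorrect
#' vote is penalized by its own support plus the majority size, offset by the
#' number of correct votes.
#'
#' @param profile a \code{\link{vote_profile}}.
#' @param i predictor index.
#' @return the (signed, integer-valued) contribution term.
#' @export
protein_contribution <- function(profile, i) {
  stopifnot(inherits(profile, "vote_profile"))
  if (i < 1 || i > length(profile$v_pi))
    stop("predictor index ", i, " out of range 1..", length(profile$v_pi))
  profile$alpha[i] * (2 * profile$vmax - profile$v_pi[i]) +
    profile$beta[i] * profile$vsec +
    profile$theta[i] * (profile$vcorrect - profile$v_pi[i] - profile$vmax)
}

#' Contribution scores of all predictors in a table
#'
#' Sums the per-protein contribution terms over all proteins with complete
#' predictions and truth, then normalizes across predictors to z-scores
#' \eqn{(CS - \mu)/\sigma} using the population standard deviation. A high
#' normalized score marks a predictor whose correct predictions are rarely
#' shared — exactly the predictors an ensemble cannot afford to drop — while
#' low scores mark predictors that are redundant or follow incorrect
#' majorities.
#'
#' @param table a \code{\link{prediction_table}} with true labels.
#' @return an object of class \code{contribution_result}: list with
#'   \code{raw_scores}, \code{normalized_scores} (both named per predictor),
#'   \code{mu}, \code{sigma} and \code{n_used} (number of proteins scored).
#' @export
contribution_scores <- function(table) {
  stopifnot(inherits(table, "prediction_table"))
  if (is.null(table$true_labels))
    stop("contribution scores require true labels")
  rows <- complete_rows(table)
  if (length(rows) < 1) stop("no complete rows to score")
  np <- n_predictors(table)
  raw <- numeric(np)
  for (j in rows) {
    vp <- vote_profile(table$predictions[j, ], table$true_labels[j])
    raw <- raw + vp$alpha * (2 * vp$vmax - vp$v_pi) +
      vp$beta * vp$vsec +
      vp$theta * (vp$vcorrect - vp$v_pi - vp$vmax)
  }
  names(raw) <- table$predictor_names
  mu <- mean(raw)
  sigma <- sqrt(mean((raw - mu)^2))  # population sd across predictors
  normalized <- if (sigma > 0) (raw - mu) / sigma else raw * 0
  structure(list(raw_scores = raw, normalized_scores = normalized,
                 mu = mu, sigma = sigma, n_used = length(rows)),
            class = "contribution_result")
}

#' @export
print.contribution_result <- function(x, ...) {
  cat("<contribution_result> over", x$n_used, "proteins\n")
  print(data.frame(predictor = names(x$raw_scores),
                   raw = unname(x$raw_scores),
                   normalized = round(unname(x$normalized_scores), 4)),
        row.names = FALSE)
  invisible(x)
}
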