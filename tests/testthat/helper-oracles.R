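# Independent brute-force oracles, written from the definitions and kept
# free of package internals: plain loops, no shared helpers.

# per-predictor contribution scores by direct enumeration of every
# (protein, predictor) case
oracle_contribution <- function(preds, truth) {
  n <- nrow(preds)
  np <- ncol(preds)
  scores <- numeric(np)
  for (j in seq_len(n)) {
    row <- preds[j, ]
    labs <- unique(row)
    cnt <- sapply(labs, function(l) sum(row == l))
    vmax <- max(cnt)
    below <- cnt[cnt != vmax]
    vsec <- if (length(below) > 0) max(below) else 0
    vcorrect <- sum(row == truth[j])
    for (i in seq_len(np)) {
      vpi <- cnt[[row[i]]]
      if (row[i] == truth[j]) {
        if (vpi < vmax) {
          scores[i] <- scores[i] + (2 * vmax - vpi)   # correct, minority
        } else {
          scores[i] <- scores[i] + vsec               # correct, majority
        }
      } else {
        scores[i] <- scores[i] + (vcorrect - vpi - vmax)  # incorrect
      }
    }
  }
  scores
}

# symmetric uncertainty from first principles (entropies in bits)
oracle_su <- function(x, y) {
  n <- length(x)
  ent <- function(v) {
    p <- sapply(unique(v), function(l) sum(v == l)) / n
    -sum(p * log2(p))
  }
  hx <- ent(x)
  hy <- ent(y)
  if (hx + hy == 0) return(0)
  joint <- paste(x, y, sep = "\r")
  hxy <- ent(joint)
  2 * (hx + hy - hxy) / (hx + hy)
}

# CFS merit from the formula, using oracle_su throughout
oracle_merit <- function(preds, truth, subset) {
  k <- length(subset)
  rcf <- mean(sapply(subset, function(i) oracle_su(preds[, i], truth)))
  if (k == 1) return(rcf)
  pairs <- utils::combn(subset, 2)
  rff <- mean(apply(pairs, 2, function(p) oracle_su(preds[, p[1]], preds[, p[2]])))
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

# small random prediction table with some class signal: each predictor is
# correct with its own probability, otherwise votes a random wrong class
random_table <- function(n, accs, classes = c("Cytosol", "Mitochondrion",
                                              "Nucleus", "Secretory"),
                         seed = 1) {
  set.seed(seed)
  truth <- sample(classes, n, replace = TRUE)
  m <- sapply(seq_along(accs), function(i) {
    ok <- runif(n) < accs[i]
    wrong <- sapply(truth, function(tc) sample(setdiff(classes, tc), 1))
    ifelse(ok, truth, wrong)
  })
  colnames(m) <- paste0("pred", seq_along(accs))
  prediction_table(m, true_labels = truth)
}

# compact six-predictor configuration: one coupled sequence-feature group,
# one homology tool and one independent-errors (PPI-like) tool
six_predictor_config <- function(n, seed) {
  sim_config(
    n_proteins = n,
    class_priors = c(Cytosol = 0.4075, Mitochondrion = 0.1432,
                     Nucleus = 0.1915, Secretory = 0.2578),
    predictors = list(
      predictor_spec("seq1", "sequence", 0.55),
      predictor_spec("seq2", "sequence", 0.50),
      predictor_spec("seq3", "sequence", 0.46),
      predictor_spec("seq4", "sequence", 0.42),
      predictor_spec("homol", "homology", 0.51),
      predictor_spec("ppi", "ppi", 0.56)),
    group_coupling = 0.85, seed = seed)
}

# the published worked example row
worked_example_row <- function() {
  c("Cytosol", "Nucleus", "Nucleus", "Mitochondrion", "Nucleus",
    "Cytosol", "Nucleus", "Nucleus", "Nucleus")
}
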