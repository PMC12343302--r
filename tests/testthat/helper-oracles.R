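# Independent oracle implementations used across the suite. These are kept
# deliberately naive (loops, exhaustive enumeration) and share no code with
# the package internals they check.

# Brute-force confusion tabulation: precision/coverage by explicit counting.
oracle_confidence <- function(decisions, truth) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(decisions)) {
    if (decisions[i] == "normal") {
      if (truth[i] == "normal") tp <- tp + 1L else fp <- fp + 1L
    } else if (decisions[i] == "aphasic") {
      if (truth[i] == "aphasic") tn <- tn + 1L else fn <- fn + 1L
    }
  }
  list(ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
       n_pos = tp + fp, n_neg = tn + fn,
       coverage_pos = (tp + fp) / sum(truth == "normal"),
       coverage_neg = (tn + fn) / sum(truth == "aphasic"))
}

# Exhaustive threshold search for one class: try every distinct observed
# argmax-class score (plus 0.5) as a strict cut-off, apply the
# min_classified floor, maximise precision, break ties toward the smaller
# threshold. Loop-based and independent of tune_thresholds().
oracle_tune_one <- function(score, is_argmax, truth, class, min_classified) {
  cands <- sort(unique(c(0.5, score[is_argmax & score >= 0.5])))
  best_theta <- NA_real_
  best_prec <- -Inf
  for (th in cands) {
    n_iss <- 0L
    n_ok <- 0L
    for (i in seq_along(score)) {
      if (is_argmax[i] && score[i] > th) {
        n_iss <- n_iss + 1L
        if (truth[i] == class) n_ok <- n_ok + 1L
      }
    }
    if (n_iss < min_classified) next
    prec <- n_ok / n_iss
    if (prec > best_prec + 1e-12) {
      best_prec <- prec
      best_theta <- th
    }
  }
  list(theta = best_theta, precision = best_prec)
}

# Weighted Gini-optimal decision stump over all midpoint thresholds of a
# single feature, with the 'tie goes to aphasic (0)' leaf rule. Used as the
# hand-rolled AdaBoost step oracle.
oracle_stump <- function(x, y01, w) {
  xs <- sort(unique(x))
  cuts <- (head(xs, -1) + xs[-1]) / 2
  gini <- function(w1, w) if (w <= 0) 0 else 2 * (w1 / w) * (1 - w1 / w)
  W <- sum(w); W1 <- sum(w[y01 == 1])
  best <- list(cost = W * gini(W1, W), cut = NA_real_)
  for (ct in cuts) {
    l <- x <= ct
    lw <- sum(w[l]); lw1 <- sum(w[l & y01 == 1])
    rw <- W - lw; rw1 <- W1 - lw1
    cost <- lw * gini(lw1, lw) + rw * gini(rw1, rw)
    if (cost < best$cost - 1e-12) best <- list(cost = cost, cut = ct)
  }
  if (is.na(best$cut)) stop("oracle_stump: no impurity-reducing cut")
  l <- x <= best$cut
  leaf <- function(sel) {
    w1 <- sum(w[sel & y01 == 1]); w0 <- sum(w[sel]) - w1
    if (w1 > w0) 1L else 0L
  }
  pl <- leaf(l); pr <- leaf(!l)
  list(cut = best$cut, pred = ifelse(l, pl, pr))
}

# One full AdaBoost iteration starting from weights D (already normalised):
# fit oracle stump, weighted error on the full set, alpha with learn-rate
# shrinkage, multiplicative weight update + renormalisation.
oracle_adaboost_step <- function(x, y01, D, learn_rate) {
  st <- oracle_stump(x, y01, D)
  miss <- st$pred != y01
  eps <- sum(D[miss])
  alpha <- learn_rate * 0.5 * log((1 - eps) / eps)
  D2 <- D * exp(ifelse(miss, alpha, -alpha))
  D2 <- D2 / sum(D2)
  list(eps = eps, alpha = alpha, weights = D2)
}

# Hand-build a rusboost object holding only single-leaf trees with fixed
# votes, for testing the score-aggregation contract in isolation.
toy_vote_ensemble <- function(votes, alpha) {
  leaf <- function(pred) {
    nodes <- matrix(c(0L, 0L, 0L, 0L, pred), 1, 5,
                    dimnames = list(NULL, c("var", "bin", "left", "right", "pred")))
    # a pure leaf: class probability equals the hard vote
    list(nodes = nodes, p1 = as.numeric(pred), gains = numeric(0),
         gain_var = integer(0))
  }
  structure(list(
    trees = lapply(as.integer(votes == "normal"), leaf),
    alpha = alpha, epsilon = rep(0.1, length(alpha)),
    edges = list(numeric(0)), config = ensemble_config(n_cycles = length(alpha)),
    classes = c("aphasic", "normal"), feature_names = "x", n_features = 1L,
    final_weights = NULL, subsample_sizes = NULL, weight_trace = NULL
  ), class = "rusboost")
}

# Random scored-case tables for calibration tests.
random_scores <- function(n) {
  s_pos <- runif(n)
  data.frame(score_negative = 1 - s_pos, score_positive = s_pos,
             argmax_class = ifelse(s_pos > 0.5, "normal", "aphasic"),
             stringsAsFactors = FALSE)
}

# Small labelled cohort pieces reused by the pipeline tests.
cohort_label_frame <- function(cohort) {
  data.frame(patient_id = cohort$features$patient_id, cohort$labels,
             check.names = FALSE, stringsAsFactors = FALSE)
}
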