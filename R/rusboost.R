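#' Random under-sampling boosted tree ensembles
#'
#' A from-scratch binary RUSBoost classifier: AdaBoost over depth-limited
#' decision trees in which each boosting iteration trains its tree on a
#' random under-sample of the majority class (all minority cases plus a
#' random subset of majority cases), while the weighted error and the
#' multiplicative case-weight updates are computed on the *full* training
#' set. Class scores are normalized weighted-vote fractions, so the two
#' per-class scores always sum to one and the calibration thresholds live
#' on a fixed \[0, 1\] scale across tasks.
#'
#' @name rusboost
NULL

#' Ensemble configuration
#'
#' Defaults follow the conventional boosted-tree settings for this
#' procedure: 100 learning cycles, learning rate 0.1, at most 10 splits per
#' tree, minimum leaf size 1, and 10 quantile bins per continuous predictor
#' for the split search.
#'
#' @param n_cycles boosting iterations (>= 1).
#' @param learn_rate shrinkage applied to each learner weight, in (0, 1\].
#' @param max_splits maximum internal nodes per tree (best-first growth).
#' @param min_leaf minimum cases per leaf.
#' @param n_bins quantile bins per predictor for the split search (>= 2).
#' @param undersample_ratio majority:minority case ratio after sampling
#'   (1 = balanced).
#' @param undersample set `FALSE` to disable under-sampling (plain boosting;
#'   used to measure the imbalance benefit).
#' @param seed RNG seed for the per-iteration majority sub-samples.
#' @return an `ensemble_config` list.
#' @export
ensemble_config <- function(n_cycles = 100L, learn_rate = 0.1,
                            max_splits = 10L, min_leaf = 1L, n_bins = 10L,
                            undersample_ratio = 1, undersample = TRUE,
                            seed = 1L) {
  cfg <- list(n_cycles = as.integer(n_cycles), learn_rate = learn_rate,
              max_splits = as.integer(max_splits),
              min_leaf = as.integer(min_leaf), n_bins = as.integer(n_bins),
              undersample_ratio = undersample_ratio,
              undersample = isTRUE(undersample), seed = as.integer(seed))
  if (cfg$n_cycles < 1L) stop("ensemble_config: n_cycles must be >= 1", call. = FALSE)
  if (cfg$learn_rate <= 0 || cfg$learn_rate > 1)
    stop("ensemble_config: learn_rate must lie in (0, 1]", call. = FALSE)
  if (cfg$max_splits < 1L) stop("ensemble_config: max_splits must be >= 1", call. = FALSE)
  if (cfg$n_bins < 2L) stop("ensemble_config: n_bins must be >= 2", call. = FALSE)
  class(cfg) <- "ensemble_config"
  cfg
}

# Quantile bin edges per predictor; ties collapse duplicate edges.
bin_edges <- function(X, n_bins) {
  lapply(seq_len(ncol(X)), function(j) {
    e <- unique(unname(quantile(X[, j], probs = seq_len(n_bins - 1) / n_bins,
                                type = 7)))
    e[is.finite(e)]
  })
}

# Map a feature matrix to integer bins: x <= edge_b  <=>  bin <= b.
bin_features <- function(X, edges) {
  B <- matrix(1L, nrow(X), ncol(X))
  for (j in seq_len(ncol(X))) {
    if (length(edges[[j]]))
      B[, j] <- findInterval(X[, j], edges[[j]], left.open = TRUE) + 1L
  }
  B
}

# Best-first growth of a weighted, depth-limited tree on pre-binned data.
# Node table columns: var, bin, left, right, pred (0/1), with var = 0 at
# leaves. Split gains are kept for impurity-based importance.
grow_tree <- function(B, y, w, rows, max_splits, min_leaf, n_bins) {
  nodes <- list(list(rows = rows, var = 0L, bin = 0L, left = 0L, right = 0L))
  cand <- list(best_split_cpp(B, y, w, rows, n_bins, min_leaf))
  open <- 1L   # node ids whose candidate split is still on offer
  gains <- numeric(0)
  gain_var <- integer(0)
  n_internal <- 0L
  root_w <- sum(w[rows])
  while (n_internal < max_splits && length(open)) {
    g <- vapply(open, function(i) cand[[i]]$gain, 0)
    if (max(g) <= 0) break
    pick <- open[which.max(g)]        # earliest id wins ties
    sp <- cand[[pick]]
    rows_p <- nodes[[pick]]$rows
    go_left <- B[rows_p, sp$var] <= sp$bin
    l_id <- length(nodes) + 1L
    r_id <- length(nodes) + 2L
    nodes[[pick]]$var <- sp$var
    nodes[[pick]]$bin <- sp$bin
    nodes[[pick]]$left <- l_id
    nodes[[pick]]$right <- r_id
    nodes[[l_id]] <- list(rows = rows_p[go_left], var = 0L, bin = 0L,
                          left = 0L, right = 0L)
    nodes[[r_id]] <- list(rows = rows_p[!go_left], var = 0L, bin = 0L,
                          left = 0L, right = 0L)
    cand[[l_id]] <- best_split_cpp(B, y, w, nodes[[l_id]]$rows, n_bins, min_leaf)
    cand[[r_id]] <- best_split_cpp(B, y, w, nodes[[r_id]]$rows, n_bins, min_leaf)
    open <- c(setdiff(open, pick), l_id, r_id)
    gains <- c(gains, sp$gain / root_w)   # node-probability scale
    gain_var <- c(gain_var, sp$var)
    n_internal <- n_internal + 1L
  }
  tab <- matrix(0L, length(nodes), 5L,
                dimnames = list(NULL, c("var", "bin", "left", "right", "pred")))
  p1 <- numeric(length(nodes))
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    w1 <- sum(w[nd$rows][y[nd$rows] == 1L])
    wt <- sum(w[nd$rows])
    tab[i, ] <- c(nd$var, nd$bin, nd$left, nd$right,
                  if (w1 > wt - w1) 1L else 0L)   # tie -> class 0 ('aphasic')
    p1[i] <- if (wt > 0) w1 / wt else 0.5         # leaf class-1 probability
  }
  list(nodes = tab, p1 = p1, gains = gains, gain_var = gain_var)
}

# Route every row of a binned matrix to its leaf in a stored node table.
route_tree <- function(tree, B) {
  tab <- tree$nodes
  n <- nrow(B)
  node_of <- rep(1L, n)
  for (i in seq_len(nrow(tab))) {
    if (tab[i, "var"] == 0L) next
    at <- which(node_of == i)
    if (!length(at)) next
    left <- B[at, tab[i, "var"]] <= tab[i, "bin"]
    node_of[at[left]] <- tab[i, "left"]
    node_of[at[!left]] <- tab[i, "right"]
  }
  node_of
}

# Hard class votes (majority leaf class; used inside the boosting loop).
predict_tree <- function(tree, B) {
  tree$nodes[route_tree(tree, B), "pred"]
}

# Leaf class-1 probabilities (used for the aggregated score variables).
predict_tree_prob <- function(tree, B) {
  tree$p1[route_tree(tree, B)]
}

#' Fit a RUSBoost ensemble
#'
#' Each iteration draws a uniform random sub-sample of the majority class
#' (down to `undersample_ratio` times the minority count), fits a weighted
#' depth-limited tree on the sub-sample, computes the weighted error
#' `eps_t` on the full training set, sets the learner weight
#' `alpha_t = learn_rate * 0.5 * log((1 - eps_t) / eps_t)`, and updates the
#' case weights multiplicatively (up-weighting mistakes) with
#' renormalisation. Iterations with `eps_t >= 0.5` receive `alpha_t = 0`
#' and reset the case weights to uniform. The fit is deterministic given
#' the config seed.
#'
#' @param features case x predictor numeric matrix or data.frame; no
#'   missing values (impute first).
#' @param labels vector of `"aphasic"` / `"normal"` (or a factor with those
#'   levels); both classes must be present.
#' @param config an [ensemble_config()].
#' @param trace keep the full case-weight trajectory (for diagnostics).
#' @return a `rusboost` model.
#' @export
fit_rusboost <- function(features, labels, config = ensemble_config(),
                         trace = FALSE) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (nrow(X) == 0L || ncol(X) == 0L)
    stop("fit_rusboost: empty feature matrix", call. = FALSE)
  if (anyNA(X))
    stop("fit_rusboost: missing feature values; impute before fitting",
         call. = FALSE)
  y <- as.character(labels)
  if (!all(y %in% CLASSES))
    stop("fit_rusboost: labels must be 'aphasic' or 'normal'", call. = FALSE)
  y01 <- as.integer(y == "normal")
  if (length(unique(y01)) < 2L)
    stop("fit_rusboost: both classes must be present in training data",
         call. = FALSE)
  if (nrow(X) < 2L * config$min_leaf)
    stop("fit_rusboost: fewer cases than 2 * min_leaf", call. = FALSE)

  edges <- bin_edges(X, config$n_bins)
  B <- bin_features(X, edges)
  n <- nrow(X)

  with_seed(config$seed, {
    D <- rep(1 / n, n)
    trees <- vector("list", config$n_cycles)
    alpha <- numeric(config$n_cycles)
    epsilon <- numeric(config$n_cycles)
    w_trace <- if (trace) vector("list", config$n_cycles) else NULL

    n1 <- sum(y01 == 1L)
    n0 <- n - n1
    minority <- if (n1 <= n0) 1L else 0L
    min_idx <- which(y01 == minority)
    maj_idx <- which(y01 != minority)
    target_maj <- max(config$min_leaf,
                      round(length(min_idx) * config$undersample_ratio))

    subsample_sizes <- integer(config$n_cycles)

    for (t in seq_len(config$n_cycles)) {
      rows <- if (config$undersample && length(maj_idx) > target_maj) {
        sort(c(min_idx, maj_idx[sample.int(length(maj_idx), target_maj)]))
      } else seq_len(n)
      subsample_sizes[t] <- length(rows)
      tree <- grow_tree(B, y01, D, rows, config$max_splits,
                        config$min_leaf, config$n_bins)
      # Leaf class probabilities re-estimated on the FULL training set
      # (lower variance than the sub-sample, no boosted-weight distortion)
      # under equal class priors — the distribution the balanced
      # sub-sample actually trains on. This keeps the ensemble's
      # minority-respecting decision rule while preserving the score
      # gradation the calibration thresholds select on.
      leaf_of <- route_tree(tree, B)
      for (nd in which(tree$nodes[, "var"] == 0L)) {
        in_leaf <- leaf_of == nd
        n_leaf1 <- sum(y01[in_leaf])
        n_leaf0 <- sum(in_leaf) - n_leaf1
        if (n_leaf1 + n_leaf0 > 0L) {
          r1 <- n_leaf1 / n1
          r0 <- n_leaf0 / n0
          tree$p1[nd] <- r1 / (r1 + r0)
        }
      }
      h <- tree$nodes[leaf_of, "pred"]
      miss <- h != y01
      eps <- sum(D[miss])
      epsilon[t] <- eps
      if (eps >= 0.5) {
        alpha[t] <- 0
        D <- rep(1 / n, n)       # restart: this learner is uninformative
      } else {
        eps_c <- max(eps, 1e-10) # guard the separable case
        alpha[t] <- config$learn_rate * 0.5 * log((1 - eps_c) / eps_c)
        D <- D * exp(ifelse(miss, alpha[t], -alpha[t]))
        D <- D / sum(D)
      }
      trees[[t]] <- tree
      if (trace) w_trace[[t]] <- D
    }

    structure(list(trees = trees, alpha = alpha, epsilon = epsilon,
                   edges = edges, config = config, classes = CLASSES,
                   feature_names = colnames(X) %||% sprintf("x%d", seq_len(ncol(X))),
                   n_features = ncol(X), final_weights = D,
                   subsample_sizes = subsample_sizes,
                   weight_trace = w_trace),
              class = "rusboost")
  })
}

#' @export
print.rusboost <- function(x, ...) {
  cat(sprintf("rusboost ensemble: %d learners (%d informative), %d predictors\n",
              length(x$trees), sum(x$alpha > 0), x$n_features))
  invisible(x)
}

#' Predict per-class scores
#'
#' The raw score of class c is the alpha-weighted mean of the learners'
#' leaf class-c probabilities; scores are normalized so `score_negative +
#' score_positive = 1` for every case. Leaf probabilities (rather than
#' hard learner votes) matter: in a region where the true conditional
#' probability is, say, 0.75, the trees agree on the majority class and a
#' hard-vote fraction would saturate at 1, erasing exactly the confidence
#' information the score thresholds select on. If all learner weights are
#' zero the scores are (0.5, 0.5). The default classification
#' `argmax_class` is the class with the larger score; exact ties go to
#' `'aphasic'`.
#'
#' @param model a fitted `rusboost` model.
#' @param features matrix/data.frame with the training predictor columns.
#' @return data.frame with `score_negative`, `score_positive`,
#'   `argmax_class`.
#' @export
predict_scores <- function(model, features) {
  stopifnot(inherits(model, "rusboost"))
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (ncol(X) != model$n_features)
    stop("predict_scores: expected ", model$n_features,
         " predictors, got ", ncol(X), call. = FALSE)
  B <- bin_features(X, model$edges)
  raw_pos <- numeric(nrow(X))
  for (t in seq_along(model$trees)) {
    if (model$alpha[t] <= 0) next
    raw_pos <- raw_pos + model$alpha[t] * predict_tree_prob(model$trees[[t]], B)
  }
  total <- sum(model$alpha[model$alpha > 0])
  if (total <= 0) {
    s_pos <- rep(0.5, nrow(X))
  } else {
    s_pos <- raw_pos / total
  }
  data.frame(score_negative = 1 - s_pos, score_positive = s_pos,
             argmax_class = ifelse(s_pos > 1 - s_pos, "normal", "aphasic"),
             stringsAsFactors = FALSE)
}

#' Hard-label predictions (argmax class)
#'
#' @param object a fitted `rusboost` model.
#' @param features predictor matrix.
#' @param ... unused.
#' @return character vector of classes.
#' @export
predict.rusboost <- function(object, features, ...) {
  predict_scores(object, features)$argmax_class
}

#' Impurity-based predictor importance
#'
#' Importance of predictor j is the mean over learners of the summed
#' node-probability-weighted Gini impurity decreases of that learner's
#' splits on j: non-negative, and exactly zero for predictors never used
#' in any split.
#'
#' @param model a fitted `rusboost` model.
#' @return named numeric vector, one entry per predictor.
#' @export
predictor_importance <- function(model) {
  stopifnot(inherits(model, "rusboost"))
  imp <- numeric(model$n_features)
  for (tree in model$trees) {
    if (length(tree$gain_var))
      imp <- imp + vapply(seq_len(model$n_features), function(j)
        sum(tree$gains[tree$gain_var == j]), 0)
  }
  setNames(imp / length(model$trees), model$feature_names)
}

#' Serialise / reload an ensemble as JSON
#'
#' Stores trees, learner weights, bin edges and config for exact reload.
#'
#' @param model a `rusboost` model.
#' @param path JSON file path.
#' @return `path` ([rusboost_to_json()]); a `rusboost` model
#'   ([rusboost_from_json()]).
#' @export
rusboost_to_json <- function(model, path) {
  stopifnot(inherits(model, "rusboost"))
  doc <- list(
    config = unclass(model$config), alpha = model$alpha,
    epsilon = model$epsilon, classes = model$classes,
    feature_names = model$feature_names, n_features = model$n_features,
    edges = model$edges,
    trees = lapply(model$trees, function(tr)
      list(n_nodes = nrow(tr$nodes), nodes = as.vector(tr$nodes),
           p1 = tr$p1, gains = tr$gains, gain_var = tr$gain_var))
  )
  jsonlite::write_json(doc, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname rusboost_to_json
#' @export
rusboost_from_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  cfg <- lapply(doc$config, unlist)
  config <- ensemble_config(cfg$n_cycles, cfg$learn_rate, cfg$max_splits,
                            cfg$min_leaf, cfg$n_bins, cfg$undersample_ratio,
                            cfg$undersample, cfg$seed)
  trees <- lapply(seq_len(config$n_cycles), function(t) {
    tr <- doc$trees[[t]]
    nodes <- matrix(as.integer(unlist(tr$nodes)),
                    nrow = as.integer(tr$n_nodes), ncol = 5L,
                    dimnames = list(NULL, c("var", "bin", "left", "right", "pred")))
    list(nodes = nodes, p1 = as.numeric(unlist(tr$p1)),
         gains = as.numeric(unlist(tr$gains) %||% numeric(0)),
         gain_var = as.integer(unlist(tr$gain_var) %||% integer(0)))
  })
  edges <- lapply(doc$edges, function(e) as.numeric(unlist(e)))
  structure(list(trees = trees, alpha = as.numeric(unlist(doc$alpha)),
                 epsilon = as.numeric(unlist(doc$epsilon)), edges = edges,
                 config = config, classes = as.character(unlist(doc$classes)),
                 feature_names = as.character(unlist(doc$feature_names)),
                 n_features = as.integer(unlist(doc$n_features)),
                 final_weights = NULL, weight_trace = NULL),
            class = "rusboost")
}
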