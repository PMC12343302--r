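#' Post-hoc interpretation statistics
#'
#' Rankings of predictor importance across tasks, Wilcoxon rank-sum
#' comparisons of continuous covariates (time post-stroke, age at onset)
#' between the 'predictable' and 'not predictable' groups, and
#' two-proportion z-tests of group composition (e.g. the proportion of
#' women in each group). Importance values take no account of the score
#' thresholding procedure (they describe the underlying ensembles, not
#' which patients end up confidently classified); that caveat is attached
#' to the output.
#'
#' @name interpretation_stats
NULL

#' Rank predictor importance across tasks
#'
#' Ranks use competition ("1224") ranking: tied importances share the
#' smallest rank of the tied block. An all-zero importance vector is
#' flagged degenerate (every predictor ranked 1).
#'
#' @param importance_by_task named list of per-task importance vectors with
#'   identical predictor naming.
#' @param top_k membership cut-off for the cross-task summary.
#' @return list: `table` (task, predictor, importance, rank), `top_k_counts`
#'   (per predictor, number of tasks in whose top-k it appears),
#'   `degenerate_tasks`, and a `caveat` string.
#' @export
rank_importance <- function(importance_by_task, top_k = 10L) {
  nm <- names(importance_by_task[[1]])
  for (imp in importance_by_task)
    if (!identical(names(imp), nm))
      stop("rank_importance: importance vectors disagree on predictor names",
           call. = FALSE)
  degenerate <- character(0)
  rows <- lapply(names(importance_by_task), function(task) {
    imp <- importance_by_task[[task]]
    if (all(imp == 0)) degenerate <<- c(degenerate, task)
    data.frame(task = task, predictor = nm, importance = unname(imp),
               rank = rank(-imp, ties.method = "min"),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  in_top <- tab[tab$rank <= top_k, ]
  counts <- table(factor(in_top$predictor, levels = nm))
  list(table = tab,
       top_k_counts = setNames(as.integer(counts), nm),
       degenerate_tasks = degenerate,
       caveat = paste("Importance reflects split-level impurity decrease in",
                      "the fitted ensembles and takes no account of the",
                      "score-threshold selection of which patients are",
                      "confidently classified."))
}

#' Wilcoxon rank-sum (Mann-Whitney) comparison
#'
#' Two-sided normal approximation with midranks, tie correction and
#' continuity correction. The z statistic is positive when group a's rank
#' sum exceeds its null expectation (group a stochastically larger). For
#' small samples an exact permutation p-value over all group-a/group-b
#' assignments is available.
#'
#' @param values_a,values_b continuous values for the two groups (ties
#'   allowed).
#' @param exact compute the exact enumeration p instead of the normal
#'   approximation (feasible for small groups).
#' @return a `group_comparison` list: `statistic` (z), `p_value`,
#'   `group_sizes`, `group_summaries` (medians), `method`.
#' @export
wilcoxon_ranksum <- function(values_a, values_b, exact = FALSE) {
  if (!length(values_a) || !length(values_b))
    stop("wilcoxon_ranksum: both groups must be non-empty", call. = FALSE)
  n_a <- length(values_a); n_b <- length(values_b)
  pooled <- c(values_a, values_b)
  r <- rank(pooled)
  W <- sum(r[seq_len(n_a)])                    # rank sum of group a
  U <- W - n_a * (n_a + 1) / 2                 # Mann-Whitney U
  mu <- n_a * n_b / 2
  n <- n_a + n_b
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term)
  if (exact) {
    if (tie_term > 0)
      warning("wilcoxon_ranksum: exact enumeration with ties uses midrank U",
              call. = FALSE)
    combs <- utils::combn(n, n_a)
    U_null <- apply(combs, 2, function(ix) sum(r[ix])) - n_a * (n_a + 1) / 2
    p <- mean(abs(U_null - mu) >= abs(U - mu) - 1e-9)
    z <- if (sigma2 > 0) (U - mu) / sqrt(sigma2) else 0
  } else {
    if (sigma2 <= 0) {        # all values identical
      z <- 0; p <- 1
    } else {
      cc <- sign(U - mu) * 0.5                 # continuity correction
      z <- (U - mu - cc) / sqrt(sigma2)
      p <- 2 * pnorm(-abs(z))
      p <- min(1, p)
    }
  }
  structure(list(statistic = z, p_value = p,
                 group_sizes = c(a = n_a, b = n_b),
                 group_summaries = c(a = median(values_a), b = median(values_b)),
                 method = if (exact) "wilcoxon rank-sum (exact enumeration)"
                          else "wilcoxon rank-sum (normal approximation)"),
            class = "group_comparison")
}

#' Two-proportion z-test
#'
#' Pooled-proportion z statistic with two-sided normal p-value; positive z
#' when group a's proportion exceeds group b's. Undefined (flagged, not
#' forced to a number) when the pooled proportion is 0 or 1.
#'
#' @param successes_a,n_a,successes_b,n_b counts per group.
#' @return a `group_comparison` list; `defined = FALSE` with NA statistic
#'   and p when the pooled proportion is degenerate.
#' @export
two_proportion_ztest <- function(successes_a, n_a, successes_b, n_b) {
  if (n_a < 1 || n_b < 1 || successes_a < 0 || successes_b < 0 ||
      successes_a > n_a || successes_b > n_b)
    stop("two_proportion_ztest: need 0 <= successes <= n for both groups",
         call. = FALSE)
  p_a <- successes_a / n_a
  p_b <- successes_b / n_b
  pool <- (successes_a + successes_b) / (n_a + n_b)
  if (pool <= 0 || pool >= 1) {
    return(structure(list(statistic = NA_real_, p_value = NA_real_,
                          defined = FALSE, group_sizes = c(a = n_a, b = n_b),
                          group_summaries = c(a = p_a, b = p_b),
                          method = "two-proportion z-test"),
                     class = "group_comparison"))
  }
  z <- (p_a - p_b) / sqrt(pool * (1 - pool) * (1 / n_a + 1 / n_b))
  structure(list(statistic = z, p_value = 2 * pnorm(-abs(z)), defined = TRUE,
                 group_sizes = c(a = n_a, b = n_b),
                 group_summaries = c(a = p_a, b = p_b),
                 method = "two-proportion z-test"),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: z = %.3f, p = %.4g (n = %d vs %d)\n",
              x$method, x$statistic, x$p_value,
              x$group_sizes[["a"]], x$group_sizes[["b"]]))
  invisible(x)
}

#' Predictability-group covariate comparison table
#'
#' For each task, compares a continuous covariate (by Wilcoxon rank-sum)
#' and a binary composition variable (by two-proportion z-test) between
#' the 'predictable' and 'not predictable' groups derived from a
#' cross-validation decision trace.
#'
#' @param analysis a `cv_analysis`.
#' @param features the feature data.frame used in the run.
#' @param continuous_var feature column for the rank-sum comparison.
#' @param binary_var feature column (0/1) for the proportion comparison;
#'   the reported proportions are of `binary_var == 0` (e.g. `sex` coded
#'   1 = male makes this the proportion of women).
#' @return data.frame: task, rank-sum z and p, proportion z and p, group
#'   percentages and sizes.
#' @export
compare_predictability_groups <- function(analysis, features,
                                          continuous_var = "time_post_stroke",
                                          binary_var = "sex") {
  rows <- lapply(analysis$config$tasks, function(task) {
    grp <- tryCatch(build_predictability_groups(analysis, task),
                    error = function(e) NULL)
    if (is.null(grp) || length(unique(grp)) < 2L)
      return(data.frame(task = task, z_continuous = NA_real_, p_continuous = NA_real_,
                        z_proportion = NA_real_, p_proportion = NA_real_,
                        pct_predictable = NA_real_, pct_not_predictable = NA_real_,
                        n_predictable = NA_integer_, n_not_predictable = NA_integer_))
    idx <- match(names(grp), features$patient_id)
    pred <- grp == "predictable"
    cont <- features[[continuous_var]][idx]
    wr <- wilcoxon_ranksum(cont[pred], cont[!pred])
    bin0 <- features[[binary_var]][idx] == 0
    zt <- two_proportion_ztest(sum(bin0[pred]), sum(pred),
                               sum(bin0[!pred]), sum(!pred))
    data.frame(task = task,
               z_continuous = wr$statistic, p_continuous = wr$p_value,
               z_proportion = zt$statistic, p_proportion = zt$p_value,
               pct_predictable = 100 * mean(bin0[pred]),
               pct_not_predictable = 100 * mean(bin0[!pred]),
               n_predictable = sum(pred), n_not_predictable = sum(!pred))
  })
  do.call(rbind, rows)
}
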