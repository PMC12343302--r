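#' Nested cross-validation pipeline
#'
#' Orchestrates the full procedure: repeated Monte-Carlo 80/10/10
#' train/validation/test splits, stratified by the task's binary outcome;
#' per-task ensemble fitting on the training split; threshold tuning on
#' the validation split; selective classification of the test split; and
#' aggregation of NPV/PPV/coverage as mean +/- SD across repetitions.
#' Analysis 1 uses the whole sample; Analysis 2 first restricts each task
#' to patients whose retrospective self-report indicates a relevant acute
#' impairment.
#'
#' @name pipeline_cv
NULL

#' Cross-validation run configuration
#'
#' @param n_repetitions number of independent re-split repetitions (100 for
#'   table-style reports; the full protocol uses 1000).
#' @param split_fractions train/validation/test fractions, summing to 1.
#' @param stratified stratify splits by the task's binary outcome.
#' @param tasks tasks to run.
#' @param analysis 1 (whole sample) or 2 (acute-impairment filtered).
#' @param seed master seed; every repetition, sub-sample and fit derives
#'   deterministically from it.
#' @param ensemble an [ensemble_config()] (its own seed field is ignored:
#'   per-fit seeds come from the master seed).
#' @param min_classified eligibility floor for threshold candidates.
#' @param max_redraws maximum re-draws of a degenerate split (train or
#'   validation lacking a class) before the task is skipped for that
#'   repetition.
#' @param likert_mapping task -> Likert item map for analysis 2.
#' @return a `run_config` list.
#' @export
run_config <- function(n_repetitions = 100L,
                       split_fractions = c(0.8, 0.1, 0.1),
                       stratified = TRUE, tasks = TASKS, analysis = 1L,
                       seed = 1L, ensemble = ensemble_config(),
                       min_classified = 5L, max_redraws = 10L,
                       likert_mapping = default_likert_mapping()) {
  if (length(split_fractions) != 3L || any(split_fractions <= 0) ||
      abs(sum(split_fractions) - 1) > 1e-8)
    stop("run_config: split_fractions must be three positive numbers summing to 1",
         call. = FALSE)
  if (n_repetitions < 1L)
    stop("run_config: n_repetitions must be >= 1", call. = FALSE)
  if (!analysis %in% c(1L, 2L))
    stop("run_config: analysis must be 1 or 2", call. = FALSE)
  structure(list(n_repetitions = as.integer(n_repetitions),
                 split_fractions = split_fractions, stratified = stratified,
                 tasks = tasks, analysis = as.integer(analysis),
                 seed = as.integer(seed), ensemble = ensemble,
                 min_classified = as.integer(min_classified),
                 max_redraws = as.integer(max_redraws),
                 likert_mapping = likert_mapping),
            class = "run_config")
}

# Random (optionally stratified) partition into train/validation/test.
draw_split <- function(labels_vec, fractions, stratified) {
  n <- length(labels_vec)
  assign <- character(n)
  groups <- if (stratified) split(seq_len(n), labels_vec) else list(seq_len(n))
  for (idx in groups) {
    idx <- idx[sample.int(length(idx))]
    m <- length(idx)
    n_tr <- round(m * fractions[1])
    n_va <- max(0L, min(round(m * fractions[2]), m - n_tr))
    n_te <- m - n_tr - n_va
    assign[idx] <- rep(c("train", "validation", "test"), c(n_tr, n_va, n_te))
  }
  assign
}

split_is_degenerate <- function(assign, labels_vec) {
  for (part in c("train", "validation")) {
    lab <- labels_vec[assign == part]
    if (length(unique(lab)) < 2L) return(TRUE)
  }
  sum(assign == "test") == 0L
}

# Training-median imputation, applied identically to all partitions.
impute_by_train_median <- function(X, train_rows) {
  for (j in seq_len(ncol(X))) {
    if (anyNA(X[, j])) {
      med <- median(X[train_rows, j], na.rm = TRUE)
      if (is.na(med)) med <- 0
      X[is.na(X[, j]), j] <- med
    }
  }
  X
}

#' Run Analysis 1 or 2
#'
#' For every repetition and task: draw a fresh split (re-drawn, up to
#' `max_redraws` times, if train or validation lacks a class); for
#' analysis 2 first restrict to the acute-impairment filter output; drop
#' patients missing that task's outcome; fit the ensemble on the training
#' split; tune thresholds on validation; selectively classify the test
#' split; and record the confidence report plus a per-case decision trace.
#' Fully determined by the master seed.
#'
#' @param features data.frame: `patient_id` plus numeric predictor columns.
#' @param labels data.frame: `patient_id` plus one `"aphasic"`/`"normal"`/NA
#'   column per task.
#' @param config a [run_config()].
#' @param likert integer matrix of self-reports (rows aligned with
#'   `features`), required for analysis 2.
#' @return a `cv_analysis` list: `records` (per repetition x task), `trace`
#'   (per-case decisions), `aggregate` (Table-style summary), `log`.
#' @export
run_analysis <- function(features, labels, config = run_config(),
                         likert = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!"patient_id" %in% names(features))
    stop("run_analysis: features must carry a patient_id column", call. = FALSE)
  if (!identical(features$patient_id, labels$patient_id))
    stop("run_analysis: features and labels must be keyed by the same patient_id order",
         call. = FALSE)
  if (config$analysis == 2L && is.null(likert))
    stop("run_analysis: analysis 2 needs the likert self-report matrix",
         call. = FALSE)
  missing_tasks <- setdiff(config$tasks, names(labels))
  if (length(missing_tasks))
    stop("run_analysis: labels lack task columns: ",
         paste(missing_tasks, collapse = ", "), call. = FALSE)

  X_all <- as.matrix(features[setdiff(names(features), "patient_id")])
  storage.mode(X_all) <- "double"
  ids <- features$patient_id
  rep_seeds <- derive_seeds(config$seed, config$n_repetitions)

  records <- vector("list", config$n_repetitions)
  trace_list <- list()
  log <- list(redraws = 0L, skipped = character(0), empty_tasks = character(0))

  for (r in seq_len(config$n_repetitions)) {
    rec <- with_seed(rep_seeds[r], {
      run_one_repetition(r, X_all, labels, ids, likert, config)
    })
    records[[r]] <- rec$tasks
    trace_list[[r]] <- rec$trace
    log$redraws <- log$redraws + rec$redraws
    log$skipped <- c(log$skipped, rec$skipped)
    log$empty_tasks <- unique(c(log$empty_tasks, rec$empty))
  }

  trace <- do.call(rbind, trace_list)
  structure(list(records = records, trace = trace,
                 aggregate = aggregate_reports(records), config = config,
                 log = log),
            class = "cv_analysis")
}

run_one_repetition <- function(r, X_all, labels, ids, likert, config) {
  task_out <- list()
  traces <- list()
  redraws <- 0L
  skipped <- character(0)
  empty <- character(0)

  for (task in config$tasks) {
    lab_col <- labels[[task]]
    eligible <- which(!is.na(lab_col))
    if (config$analysis == 2L) {
      keep <- apply_acute_impairment_filter(list(likert = likert), task,
                                            config$likert_mapping)
      eligible <- intersect(eligible, keep)
    }
    if (length(eligible) == 0L) {
      empty <- c(empty, task)
      task_out[[task]] <- list(report = NULL, empty = TRUE,
                               n_eligible = 0L)
      next
    }
    lab <- lab_col[eligible]
    X <- X_all[eligible, , drop = FALSE]

    assign <- NULL
    for (try in seq_len(config$max_redraws + 1L)) {
      a <- draw_split(lab, config$split_fractions, config$stratified)
      if (!split_is_degenerate(a, lab)) { assign <- a; break }
      redraws <- redraws + 1L
    }
    if (is.null(assign)) {
      skipped <- c(skipped, sprintf("rep %d task %s", r, task))
      task_out[[task]] <- list(report = NULL, skipped = TRUE,
                               n_eligible = length(eligible))
      next
    }

    tr <- assign == "train"; va <- assign == "validation"; te <- assign == "test"
    Xi <- impute_by_train_median(X, which(tr))
    ens_cfg <- config$ensemble
    ens_cfg$seed <- sample.int(.Machine$integer.max - 1L, 1L)
    model <- fit_rusboost(Xi[tr, , drop = FALSE], lab[tr], ens_cfg)
    val_scores <- predict_scores(model, Xi[va, , drop = FALSE])
    thresholds <- tune_thresholds(val_scores, lab[va],
                                  min_classified = config$min_classified)
    test_scores <- predict_scores(model, Xi[te, , drop = FALSE])
    decisions <- selective_classify(test_scores, thresholds)
    report <- compute_confidence(decisions, lab[te])

    # unconditional (argmax, no abstention) test precision for comparison
    uncond <- compute_confidence(test_scores$argmax_class, lab[te])

    task_out[[task]] <- list(
      report = report, thresholds = thresholds, unconditional = uncond,
      n_eligible = length(eligible),
      n_true_negative = sum(lab[te] == "aphasic"),
      n_true_positive = sum(lab[te] == "normal"),
      total_aphasic = sum(lab == "aphasic"),
      total_normal = sum(lab == "normal"))
    traces[[task]] <- data.frame(
      repetition = r, task = task, patient_id = ids[eligible][te],
      decision = decisions, truth = lab[te],
      score_negative = test_scores$score_negative,
      score_positive = test_scores$score_positive,
      stringsAsFactors = FALSE)
  }
  list(tasks = task_out, trace = do.call(rbind, traces),
       redraws = redraws, skipped = skipped, empty = empty)
}

#' Aggregate repetition records into a Table-style report
#'
#' One row per task: mean +/- SD of test-set NPV and PPV across
#' repetitions (repetitions with an undefined value are excluded from that
#' cell and counted), mean percentage of the true class receiving a
#' classification, and the class totals in the eligible sample.
#'
#' @param records the `records` element of a `cv_analysis` (or a compatible
#'   list of per-repetition, per-task lists).
#' @return data.frame, one row per task.
#' @export
aggregate_reports <- function(records) {
  if (!length(records)) stop("aggregate_reports: no repetitions", call. = FALSE)
  tasks <- unique(unlist(lapply(records, names)))
  rows <- lapply(tasks, function(task) {
    reps <- lapply(records, function(rec) rec[[task]])
    reps <- Filter(function(x) !is.null(x$report), reps)
    if (!length(reps)) {
      return(data.frame(task = task, n_runs = 0L, npv_mean = NA_real_,
                        npv_sd = NA_real_, npv_undefined = NA_integer_,
                        pct_classified_aphasic = NA_real_,
                        total_aphasic = NA_real_, ppv_mean = NA_real_,
                        ppv_sd = NA_real_, ppv_undefined = NA_integer_,
                        pct_classified_normal = NA_real_,
                        total_normal = NA_real_, stringsAsFactors = FALSE))
    }
    npv <- vapply(reps, function(x) x$report$npv, 0)
    ppv <- vapply(reps, function(x) x$report$ppv, 0)
    cov_n <- vapply(reps, function(x) x$report$coverage_negative, 0)
    cov_p <- vapply(reps, function(x) x$report$coverage_positive, 0)
    single <- length(reps) == 1L
    data.frame(
      task = task, n_runs = length(reps),
      npv_mean = mean(npv, na.rm = TRUE),
      npv_sd = if (single) 0 else sd(npv[!is.na(npv)]),
      npv_undefined = sum(is.na(npv)),
      pct_classified_aphasic = 100 * mean(cov_n, na.rm = TRUE),
      total_aphasic = mean(vapply(reps, function(x) x$total_aphasic, 0)),
      ppv_mean = mean(ppv, na.rm = TRUE),
      ppv_sd = if (single) 0 else sd(ppv[!is.na(ppv)]),
      ppv_undefined = sum(is.na(ppv)),
      pct_classified_normal = 100 * mean(cov_p, na.rm = TRUE),
      total_normal = mean(vapply(reps, function(x) x$total_normal, 0)),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Predictability groups from the decision trace
#'
#' A patient is 'predictable' iff, across cross-validation repetitions,
#' strictly more than half of their test-set appearances for the task
#' ended in a non-abstain decision. Patients never appearing in a test set
#' are excluded with a warning.
#'
#' @param analysis a `cv_analysis` (or any object with a compatible
#'   `trace` data.frame).
#' @param task task id.
#' @return named character vector (`"predictable"` / `"not_predictable"`)
#'   indexed by patient_id.
#' @export
build_predictability_groups <- function(analysis, task) {
  trace <- if (is.data.frame(analysis)) analysis else analysis$trace
  tt <- trace[trace$task == task, , drop = FALSE]
  if (!nrow(tt))
    stop("build_predictability_groups: no test appearances for task '",
         task, "'", call. = FALSE)
  appearances <- table(tt$patient_id)
  classified <- table(tt$patient_id[tt$decision != "abstain"])
  frac <- as.numeric(classified[names(appearances)])
  frac[is.na(frac)] <- 0
  frac <- frac / as.numeric(appearances)
  setNames(ifelse(frac > 0.5, "predictable", "not_predictable"),
           names(appearances))
}

#' Decisions per patient for a directional group comparison
#'
#' For a task, tallies each patient's issued test-set decisions and labels
#' them `"normal"` (predicted to recover), `"aphasic"` (predicted not to
#' recover) or `"abstain"` by majority over appearances.
#'
#' @param analysis a `cv_analysis`.
#' @param task task id.
#' @return named character vector indexed by patient_id.
#' @export
majority_decision <- function(analysis, task) {
  trace <- if (is.data.frame(analysis)) analysis else analysis$trace
  tt <- trace[trace$task == task, , drop = FALSE]
  vapply(split(tt$decision, tt$patient_id), function(d) {
    counts <- c(aphasic = sum(d == "aphasic"), normal = sum(d == "normal"))
    if (max(counts) <= length(d) / 2) "abstain"
    else names(counts)[which.max(counts)]
  }, "")
}

#' @export
print.cv_analysis <- function(x, ...) {
  cat(sprintf("cv_analysis: analysis %d, %d repetitions, %d tasks (seed %d)\n",
              x$config$analysis, x$config$n_repetitions,
              length(x$config$tasks), x$config$seed))
  print(x$aggregate, digits = 3)
  invisible(x)
}
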