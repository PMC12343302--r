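#' Synthetic post-stroke aphasia cohorts
#'
#' The patient data this pipeline was designed for (lesion-load predictors
#' plus language-task outcomes) are only available under a data-sharing
#' agreement, so the package ships a generator that reproduces the
#' *statistical structure* the analysis assumes: 116 correlated, bounded
#' lesion-load predictors driven by simulated lesion extents; 8
#' clinical/demographic covariates; per-task binary outcomes with
#' configurable class imbalance; and a latent two-component "predictability
#' mixture" in which a configurable fraction of patients has near-
#' deterministic outcome given their features.
#'
#' @name synthetic_cohort
NULL

# Default per-task fraction of 'aphasic'-range outcomes, matching the
# imbalance typical of a large chronic-phase aphasia research cohort
# (roughly 1:3 at the most imbalanced task to ~1:1 at the most balanced).
DEFAULT_CLASS_BALANCE <- c(
  fluency = 0.254, comp_aud = 0.316, comp_writ = 0.390, repeating = 0.495,
  naming = 0.355, scene_desc = 0.426, reading = 0.354, writing = 0.288
)

#' Cohort generator configuration
#'
#' @param n_patients number of patients (>= 20).
#' @param n_regions number of atlas-region lesion-load predictors.
#' @param n_tasks number of language outcome tasks.
#' @param class_balance per-task target fraction of 'aphasic' cases, each in
#'   (0.05, 0.95); recycled to `n_tasks`.
#' @param predictable_fraction fraction of patients drawn from the low-noise
#'   (highly predictable) mixture component, in \[0, 1\].
#' @param noise_sd_predictable,noise_sd_unpredictable standard deviations of
#'   the latent-performance noise for the two mixture components, on the
#'   unit-variance latent scale; the predictable component must be the
#'   quieter one.
#' @param effect_weights optional `n_tasks x (n_regions + 8)` matrix of
#'   per-task linear weights over standardized features; by default a
#'   deterministic left-lateralised weight pattern is drawn from the seed.
#' @param predictability_coupling correlation (in \[0, 1)) between the
#'   latent membership score and standardized log time post-stroke;
#'   patients assessed later tend to fall in the predictable component,
#'   so predictability is partially learnable from the features.
#' @param likert_fidelity probability that a simulated self-report reflects
#'   the simulated acute impairment rather than a uniform random score.
#' @param no_memory_rate probability a patient reports 1 ("no memory of the
#'   acute period") regardless of impairment.
#' @param missing_rate per-task probability that an outcome score is missing
#'   completely at random.
#' @param seed RNG seed.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_patients,
                          n_regions = 116L,
                          n_tasks = 8L,
                          class_balance = DEFAULT_CLASS_BALANCE,
                          predictable_fraction = 0.5,
                          noise_sd_predictable = 0.3,
                          noise_sd_unpredictable = 3.0,
                          effect_weights = NULL,
                          predictability_coupling = 0.95,
                          likert_fidelity = 0.9,
                          no_memory_rate = 0.05,
                          missing_rate = 0.03,
                          seed = 1L) {
  n_tasks <- as.integer(n_tasks)
  class_balance <- rep_len(as.numeric(class_balance), n_tasks)
  cfg <- list(
    n_patients = as.integer(n_patients), n_regions = as.integer(n_regions),
    n_tasks = n_tasks, class_balance = class_balance,
    predictable_fraction = predictable_fraction,
    noise_sd_predictable = noise_sd_predictable,
    noise_sd_unpredictable = noise_sd_unpredictable,
    effect_weights = effect_weights,
    predictability_coupling = predictability_coupling,
    likert_fidelity = likert_fidelity, no_memory_rate = no_memory_rate,
    missing_rate = rep_len(missing_rate, n_tasks), seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_patients < 20L)
    stop("cohort_config: n_patients must be >= 20", call. = FALSE)
  if (cfg$predictable_fraction < 0 || cfg$predictable_fraction > 1)
    stop("cohort_config: predictable_fraction must lie in [0, 1]", call. = FALSE)
  if (cfg$predictability_coupling < 0 || cfg$predictability_coupling >= 1)
    stop("cohort_config: predictability_coupling must lie in [0, 1)", call. = FALSE)
  if (!(cfg$noise_sd_predictable < cfg$noise_sd_unpredictable))
    stop("cohort_config: noise_sd_predictable must be < noise_sd_unpredictable",
         call. = FALSE)
  if (any(cfg$class_balance <= 0.05) || any(cfg$class_balance >= 0.95))
    stop("cohort_config: class_balance must lie in (0.05, 0.95) per task",
         call. = FALSE)
  if (!is.null(cfg$effect_weights) &&
      !identical(dim(cfg$effect_weights),
                 c(cfg$n_tasks, cfg$n_regions + 8L)))
    stop("cohort_config: effect_weights must be n_tasks x (n_regions + 8)",
         call. = FALSE)
  invisible(cfg)
}

#' Names of the predictor columns (region loads then covariates)
#'
#' Regions come in left/right pairs (`roi_001_L`, `roi_001_R`, ...); an odd
#' region count leaves the final region unpaired on the left.
#' @param n_regions number of atlas regions.
#' @return character vector of length `n_regions + 8`.
#' @export
lesion_feature_names <- function(n_regions = 116L) {
  pair <- ceiling(seq_len(n_regions) / 2)
  side <- ifelse(seq_len(n_regions) %% 2L == 1L, "L", "R")
  c(sprintf("roi_%03d_%s", pair, side),
    "time_post_stroke", "age_at_onset", "handedness", "sex",
    "native_english", "total_volume", "left_volume", "right_volume")
}

task_names <- function(n_tasks) {
  if (n_tasks == length(TASKS)) TASKS else sprintf("task_%02d", seq_len(n_tasks))
}

# Deterministic default effect weights: left-lateralised lesion effects,
# strong left/total volume terms, a recovery benefit of time post-stroke.
default_effect_weights <- function(n_regions, n_tasks) {
  feat <- lesion_feature_names(n_regions)
  p <- length(feat)
  left_cols <- grep("^roi_.*_L$", feat)
  right_cols <- grep("^roi_.*_R$", feat)
  w <- matrix(0, n_tasks, p, dimnames = list(task_names(n_tasks), feat))
  for (t in seq_len(n_tasks)) {
    w[t, left_cols] <- -abs(rnorm(length(left_cols), 0, 0.35))
    w[t, right_cols] <- -abs(rnorm(length(right_cols), 0, 0.08))
    core <- sample(left_cols, 6L)  # task-specific critical regions
    w[t, core] <- w[t, core] - 1.5
    w[t, "left_volume"] <- -1.2
    w[t, "total_volume"] <- -0.6
    w[t, "right_volume"] <- -0.1
    w[t, "time_post_stroke"] <- 0.8
    w[t, "age_at_onset"] <- -0.4
    w[t, "native_english"] <- 0.5
    w[t, "handedness"] <- 0.1
  }
  w
}

#' Generate a synthetic cohort
#'
#' Draws lesion volumes and left-lateralised region loads, demographic
#' covariates, latent per-task performance (a linear function of the
#' standardized features plus mixture-dependent Gaussian noise), t-score
#' outcomes on the usual 50/10 scale, binary labels under per-task cut-offs
#' placing `class_balance` of the sample in the 'aphasic' range, ground-truth
#' conditional outcome probabilities, and noisy 7-point Likert self-reports
#' of acute impairment.
#'
#' @param config a [cohort_config()].
#' @return a `synthetic_cohort` list: `features` (data.frame, `patient_id` +
#'   `n_regions + 8` predictors), `tscores`, `labels`, `bayes_prob` (true
#'   P(normal | features, mixture membership)), `likert`, `acute_impaired`
#'   (ground truth behind the Likert items), `membership` (TRUE for the
#'   low-noise component), `cutoffs`, `config`, `seed_used`.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_patients
  R <- cfg$n_regions
  feat_names <- lesion_feature_names(R)
  tasks <- task_names(cfg$n_tasks)

  w <- cfg$effect_weights %||% default_effect_weights(R, cfg$n_tasks)

  # lesion geometry: log-normal total volume (cm^3) split between
  # hemispheres with a left-dominant share, as in an aphasia cohort
  sdlog <- sqrt(log(1 + (82.7 / 64)^2))
  meanlog <- log(64) - sdlog^2 / 2
  total_vol <- rlnorm(n, meanlog, sdlog)
  left_share <- stats::rbeta(n, 4, 1.5)
  left_vol <- total_vol * left_share
  right_vol <- total_vol - left_vol

  # region loads in (0,1): logistic function of hemispheric lesion extent,
  # a shared patient factor (spatial correlation) and region noise
  sev_l <- log1p(left_vol) / log1p(300)
  sev_r <- log1p(right_vol) / log1p(300)
  u <- rnorm(n)
  side_left <- seq_len(R) %% 2L == 1L
  loads <- matrix(0, n, R)
  for (r in seq_len(R)) {
    sev <- if (side_left[r]) sev_l else sev_r
    z <- -2.5 + 4 * sev + 0.8 * u + rnorm(n)
    loads[, r] <- stats::plogis(z)
  }

  covar <- cbind(
    time_post_stroke = rlnorm(n, log(30), 0.9),      # months
    age_at_onset = pmin(pmax(rnorm(n, 56, 13.3), 18), 90),
    handedness = rbinom(n, 1, 0.874),                # 1 = right-handed
    sex = rbinom(n, 1, 0.665),                       # 1 = male
    native_english = rbinom(n, 1, 0.895),
    total_volume = total_vol, left_volume = left_vol, right_volume = right_vol
  )
  X <- cbind(loads, covar)
  colnames(X) <- feat_names

  Xs <- scale(X)
  Xs[, apply(X, 2, stats::var) == 0] <- 0

  # Mixture membership is coupled to time post-stroke: patients assessed
  # longer after their stroke have more settled outcomes, so predictability
  # is itself (partially) visible in the features rather than an
  # unlearnable coin flip. The coupling preserves an exact fraction rho.
  cpl <- cfg$predictability_coupling
  u <- cpl * drop(Xs[, "time_post_stroke"]) + sqrt(1 - cpl^2) * rnorm(n)
  membership <- rank(u, ties.method = "first") > n * (1 - cfg$predictable_fraction)
  noise_sd <- ifelse(membership, cfg$noise_sd_predictable,
                     cfg$noise_sd_unpredictable)

  tscores <- matrix(NA_real_, n, cfg$n_tasks, dimnames = list(NULL, tasks))
  bayes <- matrix(NA_real_, n, cfg$n_tasks, dimnames = list(NULL, tasks))
  cutoffs <- setNames(numeric(cfg$n_tasks), tasks)
  perf_all <- matrix(0, n, cfg$n_tasks)
  for (t in seq_len(cfg$n_tasks)) {
    perf <- drop(Xs %*% w[t, ])
    perf <- perf / max(sd(perf), 1e-12)  # unit-variance signal
    perf_all[, t] <- perf
    latent <- perf + rnorm(n, 0, noise_sd)
    mu <- mean(latent); s <- sd(latent)
    tscores[, t] <- 50 + 10 * (latent - mu) / s
    cutoffs[t] <- unname(quantile(tscores[, t], cfg$class_balance[t]))
    cut_latent <- mu + s * (cutoffs[t] - 50) / 10
    # P(normal | features, membership): latent >= cut-off
    bayes[, t] <- 1 - pnorm((cut_latent - perf) / noise_sd)
  }

  # MCAR outcome missingness
  for (t in seq_len(cfg$n_tasks)) {
    drop_i <- runif(n) < cfg$missing_rate[t]
    tscores[drop_i, t] <- NA_real_
  }
  labels <- binarize_outcomes(tscores, cutoffs)

  # acute impairment + Likert self-report (4 domains); acute severity is
  # the time-free part of performance in the mapped tasks, so late-assessed
  # recovered patients can still have been acutely impaired
  mapping <- default_likert_mapping(tasks)
  likert <- matrix(NA_integer_, n, length(LIKERT_ITEMS),
                   dimnames = list(NULL, LIKERT_ITEMS))
  acute <- matrix(NA, n, length(LIKERT_ITEMS),
                  dimnames = list(NULL, LIKERT_ITEMS))
  for (it in LIKERT_ITEMS) {
    mapped <- names(mapping)[mapping == it]
    mapped <- intersect(mapped, tasks)
    sev <- if (length(mapped)) {
      -rowMeans(perf_all[, match(mapped, tasks), drop = FALSE]) +
        0.8 * Xs[, "time_post_stroke"]  # undo the chronic recovery benefit
    } else rnorm(n)
    sev <- sev + rnorm(n, 0, 0.5)
    impaired <- sev > quantile(sev, 0.3)  # ~70% acutely impaired
    acute[, it] <- impaired
    sev_rank <- rank(sev) / (n + 1)
    true_score <- ifelse(impaired, pmin(6L, pmax(2L, 7L - ceiling(sev_rank * 7))), 7L)
    noisy <- ifelse(runif(n) < cfg$likert_fidelity, true_score,
                    sample(1:7, n, replace = TRUE))
    noisy[runif(n) < cfg$no_memory_rate] <- 1L
    likert[, it] <- as.integer(noisy)
  }

  structure(list(
    features = data.frame(patient_id = sprintf("P%05d", seq_len(n)),
                          as.data.frame(X), check.names = FALSE),
    tscores = tscores, labels = labels, bayes_prob = bayes,
    likert = likert, acute_impaired = acute, membership = membership,
    cutoffs = cutoffs, effect_weights = w, config = cfg,
    seed_used = cfg$seed
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic_cohort: %d patients, %d predictors, %d tasks (seed %d)\n",
    nrow(x$features), ncol(x$features) - 1L, ncol(x$tscores), x$seed_used))
  frac <- colMeans(x$labels == "aphasic", na.rm = TRUE)
  cat("aphasic fraction per task:\n")
  print(round(frac, 3))
  invisible(x)
}

#' Binarize outcome t-scores against per-task cut-offs
#'
#' A score strictly below its task's cut-off is in the 'aphasic' range; a
#' score at or above it is 'normal'. Missing scores yield missing labels.
#'
#' @param tscores numeric matrix (patients x tasks).
#' @param cutoffs numeric vector, one finite cut-off per task.
#' @return character matrix of `"aphasic"` / `"normal"` / `NA`.
#' @export
binarize_outcomes <- function(tscores, cutoffs) {
  tscores <- as.matrix(tscores)
  if (length(cutoffs) != ncol(tscores))
    stop("binarize_outcomes: need one cutoff per task (got ",
         length(cutoffs), " for ", ncol(tscores), " tasks)", call. = FALSE)
  if (any(!is.finite(cutoffs)))
    stop("binarize_outcomes: cutoffs must be finite", call. = FALSE)
  out <- matrix(NA_character_, nrow(tscores), ncol(tscores),
                dimnames = dimnames(tscores))
  for (t in seq_len(ncol(tscores))) {
    ok <- !is.na(tscores[, t])
    out[ok, t] <- ifelse(tscores[ok, t] < cutoffs[t], "aphasic", "normal")
  }
  out
}

#' Default mapping from outcome tasks to Likert self-report items
#'
#' 'understanding' covers both comprehension outcomes; 'reading' and
#' 'writing' map to themselves; the remaining spoken-production tasks
#' (fluency, naming, scene description, repetition) map to 'speaking'.
#'
#' @param tasks task names to map.
#' @return named character vector task -> Likert item.
#' @export
default_likert_mapping <- function(tasks = TASKS) {
  full <- c(fluency = "speaking", comp_aud = "understanding",
            comp_writ = "understanding", repeating = "speaking",
            naming = "speaking", scene_desc = "speaking",
            reading = "reading", writing = "writing")
  if (all(tasks %in% names(full))) full[tasks]
  else setNames(rep("speaking", length(tasks)), tasks)
}

#' Restrict a cohort to patients reporting a relevant acute impairment
#'
#' Keeps patients whose mapped Likert self-report s satisfies 1 < s < 7:
#' a 7 means the skill was judged perfectly spared at one month
#' post-stroke, a 1 means no memory of the acute period; both are excluded.
#'
#' @param cohort a `synthetic_cohort`, or any list with a `likert` matrix.
#' @param task outcome task id.
#' @param mapping named vector task -> Likert item
#'   (default [default_likert_mapping()]).
#' @return integer indices of the retained patients.
#' @export
apply_acute_impairment_filter <- function(cohort, task,
                                          mapping = default_likert_mapping()) {
  if (!task %in% names(mapping))
    stop("apply_acute_impairment_filter: no Likert mapping for task '",
         task, "'", call. = FALSE)
  item <- mapping[[task]]
  if (!item %in% colnames(cohort$likert))
    stop("apply_acute_impairment_filter: Likert item '", item,
         "' not present in cohort", call. = FALSE)
  s <- cohort$likert[, item]
  which(!is.na(s) & s > 1L & s < 7L)
}

#' Write a cohort to plain-text files
#'
#' Writes `features.csv` (patient_id + predictors), `outcomes.csv`
#' (patient_id + t-scores + Likert items), `truth.csv` (patient_id + true
#' conditional outcome probabilities + mixture membership) and
#' `config.json`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort$features, file.path(dir, "features.csv"), row.names = FALSE)
  out <- data.frame(patient_id = cohort$features$patient_id,
                    cohort$tscores,
                    setNames(as.data.frame(cohort$likert),
                             paste0("likert_", colnames(cohort$likert))),
                    check.names = FALSE)
  write.csv(out, file.path(dir, "outcomes.csv"), row.names = FALSE)
  truth <- data.frame(patient_id = cohort$features$patient_id,
                      setNames(as.data.frame(cohort$bayes_prob),
                               paste0("p_normal_", colnames(cohort$bayes_prob))),
                      predictable = cohort$membership, check.names = FALSE)
  write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  cfg <- cohort$config
  cfg$effect_weights <- NULL  # large; regenerate from seed
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
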