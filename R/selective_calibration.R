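#' Precision-targeted selective classification
#'
#' The ensemble's default behaviour assigns every case to the class with
#' the larger score. This module interferes with that behaviour: a
#' classification is only *issued* when the winning class's normalized
#' score strictly exceeds a per-class threshold, otherwise the case is
#' abstained on. The two thresholds are the model's only tuned
#' hyperparameters; they are chosen on a validation split to maximise each
#' class's precision (PPV for 'normal', NPV for 'aphasic'), independently
#' per class.
#'
#' @name selective_calibration
NULL

#' Per-class score thresholds
#'
#' @param theta_negative cut-off for issuing the 'aphasic' classification.
#' @param theta_positive cut-off for issuing the 'normal' classification.
#' @param min_classified minimum validation cases a candidate threshold
#'   must classify to be eligible during tuning; guards against degenerate
#'   thresholds that classify one lucky case with precision 1.
#' @return a `threshold_pair` list.
#' @export
threshold_pair <- function(theta_negative = 0.5, theta_positive = 0.5,
                           min_classified = 5L) {
  if (any(c(theta_negative, theta_positive) < 0.5) ||
      any(c(theta_negative, theta_positive) > 1))
    stop("threshold_pair: thresholds must lie in [0.5, 1] ",
         "(the argmax class's normalized score is always >= 0.5)",
         call. = FALSE)
  structure(list(theta_negative = theta_negative,
                 theta_positive = theta_positive,
                 min_classified = as.integer(min_classified),
                 failed_negative = FALSE, failed_positive = FALSE),
            class = "threshold_pair")
}

#' Apply thresholds to scored cases
#'
#' A case is classified as its argmax class iff that class's score
#' strictly exceeds that class's threshold; otherwise it is abstained on.
#' A class flagged as calibration-failed always abstains.
#'
#' @param scores data.frame from [predict_scores()].
#' @param thresholds a [threshold_pair()].
#' @return character vector of `"aphasic"` / `"normal"` / `"abstain"`.
#' @export
selective_classify <- function(scores, thresholds) {
  stopifnot(inherits(thresholds, "threshold_pair"))
  dec <- rep("abstain", nrow(scores))
  pos <- scores$argmax_class == "normal"
  issue_pos <- pos & !thresholds$failed_positive &
    scores$score_positive > thresholds$theta_positive
  issue_neg <- !pos & !thresholds$failed_negative &
    scores$score_negative > thresholds$theta_negative
  dec[issue_pos] <- "normal"
  dec[issue_neg] <- "aphasic"
  dec
}

#' Precision and coverage of issued classifications
#'
#' PPV is the fraction of issued 'normal' classifications that are truly
#' normal; NPV likewise for 'aphasic'. Either is `NA` (undefined, never
#' coerced to 0 or 1) when no classification of that polarity was issued.
#' Coverage of a class is the number of classifications *issued for* that
#' class divided by the number of cases *truly in* that class — at very
#' permissive thresholds it can exceed 1, because wrong-class cases are
#' counted in the numerator.
#'
#' @param decisions vector from [selective_classify()].
#' @param truth vector of true classes (`"aphasic"` / `"normal"`).
#' @return a `confidence_report` list: `npv`, `ppv`,
#'   `n_classified_negative`, `n_classified_positive`, `n_abstain`, `n`,
#'   `coverage_negative`, `coverage_positive`, and `defined_npv` /
#'   `defined_ppv` flags.
#' @export
compute_confidence <- function(decisions, truth) {
  if (length(decisions) != length(truth))
    stop("compute_confidence: decisions and truth differ in length",
         call. = FALSE)
  truth <- as.character(truth)
  issued_pos <- decisions == "normal"
  issued_neg <- decisions == "aphasic"
  n_pos <- sum(issued_pos)
  n_neg <- sum(issued_neg)
  ppv <- if (n_pos > 0) sum(truth[issued_pos] == "normal") / n_pos else NA_real_
  npv <- if (n_neg > 0) sum(truth[issued_neg] == "aphasic") / n_neg else NA_real_
  true_pos <- sum(truth == "normal")
  true_neg <- sum(truth == "aphasic")
  structure(list(
    npv = npv, ppv = ppv,
    defined_npv = n_neg > 0, defined_ppv = n_pos > 0,
    n_classified_negative = n_neg, n_classified_positive = n_pos,
    n_abstain = sum(decisions == "abstain"), n = length(decisions),
    coverage_negative = if (true_neg > 0) n_neg / true_neg else NA_real_,
    coverage_positive = if (true_pos > 0) n_pos / true_pos else NA_real_
  ), class = "confidence_report")
}

# Candidate thresholds for one class: the sorted distinct argmax-class
# scores observed in validation, plus the permissive 0.5 floor. Because
# classification requires score > theta, taking theta equal to an observed
# score excludes exactly that score and everything below it.
threshold_candidates <- function(class_scores) {
  sort(unique(c(0.5, class_scores[class_scores >= 0.5])))
}

#' Tune per-class thresholds to maximise validation precision
#'
#' Each class is tuned independently: sweep the candidate thresholds, keep
#' those issuing at least `min_classified` classifications, and pick the
#' one maximising that class's precision, breaking precision ties toward
#' the smaller threshold (larger coverage). If no candidate classifies
#' enough cases the class is marked calibration-failed and will always
#' abstain.
#'
#' @param scores validation scores from [predict_scores()].
#' @param truth validation true classes.
#' @param min_classified eligibility floor for candidates (default 5).
#' @return a [threshold_pair()] with tuning metadata
#'   (`validation_precision` per class).
#' @export
tune_thresholds <- function(scores, truth, min_classified = 5L) {
  truth <- as.character(truth)
  if (length(unique(truth)) < 2L)
    stop("tune_thresholds: validation set must contain both classes",
         call. = FALSE)
  tune_one <- function(class) {
    score <- if (class == "normal") scores$score_positive else scores$score_negative
    is_argmax <- scores$argmax_class == class
    cands <- threshold_candidates(score[is_argmax])
    best <- list(theta = NA_real_, prec = -Inf)
    for (th in cands) {
      issued <- is_argmax & score > th
      n_iss <- sum(issued)
      if (n_iss < min_classified) next
      prec <- sum(truth[issued] == class) / n_iss
      if (prec > best$prec + 1e-12) best <- list(theta = th, prec = prec)
      # ties keep the earlier (smaller) threshold: larger coverage
    }
    best
  }
  neg <- tune_one("aphasic")
  pos <- tune_one("normal")
  tp <- threshold_pair(
    theta_negative = if (is.na(neg$theta)) 1 else neg$theta,
    theta_positive = if (is.na(pos$theta)) 1 else pos$theta,
    min_classified = min_classified
  )
  tp$failed_negative <- is.na(neg$theta)
  tp$failed_positive <- is.na(pos$theta)
  tp$validation_precision <- c(
    aphasic = if (is.finite(neg$prec)) neg$prec else NA_real_,
    normal = if (is.finite(pos$prec)) pos$prec else NA_real_
  )
  tp
}

#' Coverage/precision trade-off curve
#'
#' Evaluates [selective_classify()] + [compute_confidence()] over a grid of
#' thresholds applied to both classes, returning per class and grid point
#' the achieved precision, the coverage, and the number classified.
#' Coverage is exactly non-increasing in the threshold.
#'
#' @param scores scores from [predict_scores()].
#' @param truth true classes.
#' @param grid thresholds in \[0.5, 1\].
#' @return data.frame with columns `class`, `threshold`, `precision`,
#'   `coverage`, `n_classified`.
#' @export
coverage_precision_curve <- function(scores, truth,
                                     grid = seq(0.5, 1, by = 0.025)) {
  if (!length(grid))
    stop("coverage_precision_curve: empty threshold grid", call. = FALSE)
  if (any(grid < 0.5 | grid > 1))
    stop("coverage_precision_curve: grid must lie in [0.5, 1]", call. = FALSE)
  rows <- lapply(sort(grid), function(th) {
    rep <- compute_confidence(
      selective_classify(scores, threshold_pair(th, th)), truth)
    data.frame(
      class = CLASSES, threshold = th,
      precision = c(rep$npv, rep$ppv),
      coverage = c(rep$coverage_negative, rep$coverage_positive),
      n_classified = c(rep$n_classified_negative, rep$n_classified_positive),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.confidence_report <- function(x, ...) {
  fmt <- function(v, d) if (d) sprintf("%.3f", v) else "undefined"
  cat(sprintf("confidence_report: n = %d (%d abstained)\n", x$n, x$n_abstain))
  cat(sprintf("  NPV %s over %d issued 'aphasic' (coverage %.2f)\n",
              fmt(x$npv, x$defined_npv), x$n_classified_negative,
              x$coverage_negative))
  cat(sprintf("  PPV %s over %d issued 'normal'  (coverage %.2f)\n",
              fmt(x$ppv, x$defined_ppv), x$n_classified_positive,
              x$coverage_positive))
  invisible(x)
}
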