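scores_df <- function(pos) {
  data.frame(score_negative = 1 - pos, score_positive = pos,
             argmax_class = ifelse(pos > 0.5, "normal", "aphasic"),
             stringsAsFactors = FALSE)
}

test_that("threshold pair enforces the [0.5, 1] range", {
  expect_error(threshold_pair(0.4, 0.9), "0.5")
  expect_error(threshold_pair(0.9, 1.2), "0.5")
  tp <- threshold_pair(0.7, 0.6)
  expect_s3_class(tp, "threshold_pair")
})

test_that("selective classification issues argmax only above threshold", {
  s <- scores_df(c(0.9, 0.55, 0.2))
  dec <- selective_classify(s, threshold_pair(0.7, 0.6))
  expect_identical(dec, c("normal", "abstain", "aphasic"))

  permissive <- selective_classify(s, threshold_pair(0.5, 0.5))
  expect_false(any(permissive == "abstain"))
  impossible <- selective_classify(s, threshold_pair(1, 1))
  expect_true(all(impossible == "abstain"))
  # an exact 0.5 tie abstains even at the permissive limit (strict >)
  tied <- selective_classify(scores_df(0.5), threshold_pair(0.5, 0.5))
  expect_identical(tied, "abstain")
})

test_that("confidence arithmetic matches direct ratios and flags emptiness", {
  dec <- c(rep("normal", 10), rep("abstain", 2))
  truth <- c(rep("normal", 9), "aphasic", "aphasic", "normal")
  rep1 <- compute_confidence(dec, truth)
  expect_equal(rep1$ppv, 0.9)
  expect_false(rep1$defined_npv)
  expect_true(is.na(rep1$npv))
  expect_equal(rep1$n_abstain, 2L)
  expect_equal(rep1$n_classified_positive + rep1$n_classified_negative +
                 rep1$n_abstain, rep1$n)
  expect_error(compute_confidence(dec, truth[1:5]), "length")
})

test_that("confidence matches the brute-force confusion oracle", {
  withr::with_seed(14, {
    for (i in 1:50) {
      n <- sample(10:40, 1)
      dec <- sample(c("aphasic", "normal", "abstain"), n, replace = TRUE)
      truth <- sample(c("aphasic", "normal"), n, replace = TRUE)
      got <- compute_confidence(dec, truth)
      want <- oracle_confidence(dec, truth)
      expect_equal(got$ppv, want$ppv)
      expect_equal(got$npv, want$npv)
      expect_equal(got$n_classified_positive, want$n_pos)
      expect_equal(got$n_classified_negative, want$n_neg)
    }
  })
})

test_that("threshold tuning maximises validation precision with max coverage", {
  # enumerated example: 4 positive-argmax cases
  s <- scores_df(c(0.9, 0.8, 0.6, 0.55))
  truth <- c("normal", "normal", "aphasic", "aphasic")
  tp <- tune_thresholds(s, truth, min_classified = 2)
  expect_equal(tp$theta_positive, 0.6)   # just below 0.8: classifies the two normals
  expect_equal(unname(tp$validation_precision["normal"]), 1.0)

  # perfectly separable scores: smallest threshold achieving precision 1
  s2 <- scores_df(c(0.95, 0.9, 0.85, 0.15, 0.1, 0.05))
  truth2 <- c(rep("normal", 3), rep("aphasic", 3))
  tp2 <- tune_thresholds(s2, truth2, min_classified = 2)
  expect_equal(tp2$theta_positive, 0.5)
  expect_equal(tp2$theta_negative, 0.5)
  dec2 <- selective_classify(s2, tp2)
  expect_false(any(dec2 == "abstain"))
  expect_equal(compute_confidence(dec2, truth2)$ppv, 1)
})

test_that("infeasible min_classified marks a class calibration-failed", {
  s <- scores_df(c(0.9, 0.8, 0.2))
  truth <- c("normal", "normal", "aphasic")
  tp <- tune_thresholds(s, truth, min_classified = 5)
  expect_true(tp$failed_positive && tp$failed_negative)
  expect_true(all(selective_classify(s, tp) == "abstain"))
  expect_error(tune_thresholds(s, rep("normal", 3)), "both classes")
})

test_that("tuning matches exhaustive enumeration on random instances", {
  withr::with_seed(15, {
    for (i in 1:100) {
      n <- sample(10:60, 1)
      s <- random_scores(n)
      truth <- ifelse(runif(n) < 0.3 + 0.4 * s$score_positive, "normal", "aphasic")
      if (length(unique(truth)) < 2) next
      mc <- sample(1:5, 1)
      tp <- tune_thresholds(s, truth, min_classified = mc)
      want_pos <- oracle_tune_one(s$score_positive, s$argmax_class == "normal",
                                  truth, "normal", mc)
      want_neg <- oracle_tune_one(s$score_negative, s$argmax_class == "aphasic",
                                  truth, "aphasic", mc)
      if (is.na(want_pos$theta)) {
        expect_true(tp$failed_positive)
      } else {
        expect_equal(tp$theta_positive, want_pos$theta)
        expect_equal(unname(tp$validation_precision["normal"]), want_pos$precision)
      }
      if (is.na(want_neg$theta)) {
        expect_true(tp$failed_negative)
      } else {
        expect_equal(tp$theta_negative, want_neg$theta)
        expect_equal(unname(tp$validation_precision["aphasic"]), want_neg$precision)
      }
    }
  })
})

test_that("tuned thresholds carry no signal when labels are independent", {
  withr::with_seed(16, {
    n <- 200
    prev <- 0.6
    precs <- replicate(100, {
      s <- random_scores(n)
      truth <- sample(c("normal", "aphasic"), n, replace = TRUE,
                      prob = c(prev, 1 - prev))
      tune_on <- seq_len(n / 2)
      tp <- tune_thresholds(s[tune_on, ], truth[tune_on], min_classified = 5)
      dec <- selective_classify(s[-tune_on, ], tp)
      compute_confidence(dec, truth[-tune_on])$ppv
    })
    # thresholds tuned on independent labels cannot beat prevalence on
    # fresh cases
    se <- sd(precs, na.rm = TRUE) / sqrt(sum(!is.na(precs)))
    expect_lt(abs(mean(precs, na.rm = TRUE) - prev), max(3 * se, 0.05))
  })
})

test_that("coverage is exactly non-increasing along the curve", {
  withr::with_seed(17, {
    for (i in 1:20) {
      n <- sample(20:80, 1)
      s <- random_scores(n)
      truth <- sample(c("normal", "aphasic"), n, replace = TRUE)
      curve <- coverage_precision_curve(s, truth, grid = seq(0.5, 1, by = 0.05))
      for (cl in c("aphasic", "normal")) {
        cov <- curve$coverage[curve$class == cl]
        expect_true(all(diff(cov) <= 1e-12))
      }
    }
  })
})

test_that("curve endpoints match the permissive and impossible limits", {
  withr::with_seed(18, {
    s <- random_scores(50)
    truth <- sample(c("normal", "aphasic"), 50, replace = TRUE)
  })
  curve <- coverage_precision_curve(s, truth, grid = c(0.5, 1))
  at_half <- curve[curve$threshold == 0.5, ]
  # at 0.5 every non-tied case is classified as its argmax class
  expect_equal(at_half$n_classified[at_half$class == "normal"],
               sum(s$argmax_class == "normal" & s$score_positive > 0.5))
  at_one <- curve[curve$threshold == 1, ]
  expect_true(all(at_one$coverage == 0))
  expect_true(all(is.na(at_one$precision)))
  expect_error(coverage_precision_curve(s, truth, grid = numeric(0)), "empty")
  expect_error(coverage_precision_curve(s, truth, grid = c(0.2)), "0.5")
})
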