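test_that("config invariants are enforced", {
  expect_error(cohort_config(10), "n_patients")
  expect_error(cohort_config(100, predictable_fraction = 1.2), "predictable_fraction")
  expect_error(cohort_config(100, noise_sd_predictable = 3, noise_sd_unpredictable = 1),
               "noise_sd")
  expect_error(cohort_config(100, class_balance = 0.97), "class_balance")
  expect_error(cohort_config(100, effect_weights = matrix(0, 2, 2)), "effect_weights")
})

test_that("generation is deterministic given config and seed", {
  cfg <- cohort_config(60, seed = 9)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c <- generate_cohort(cohort_config(60, seed = 10))
  expect_false(identical(a$features, c$features))
})

test_that("empirical class fractions track the configured balance", {
  co <- generate_cohort(cohort_config(2000, class_balance = 0.25, seed = 7))
  frac <- colMeans(co$labels == "aphasic", na.rm = TRUE)
  expect_true(all(frac >= 0.20 & frac <= 0.30))

  co2 <- generate_cohort(cohort_config(1000, seed = 2))
  frac2 <- colMeans(co2$labels == "aphasic", na.rm = TRUE)
  expect_true(all(abs(frac2 - co2$config$class_balance) < 0.05))
})

test_that("cohort satisfies its structural invariants", {
  co <- generate_cohort(cohort_config(300, seed = 4))
  loads <- as.matrix(co$features[, grep("^roi_", names(co$features))])
  expect_true(all(loads >= 0 & loads <= 1))
  expect_true(all(co$features$left_volume + co$features$right_volume <=
                    co$features$total_volume + 1e-9))
  expect_true(all(co$bayes_prob >= 0 & co$bayes_prob <= 1))
  expect_identical(dim(co$features), c(300L, 125L))  # patient_id + 124
  # labels consistent with t-scores under the stored cut-offs
  expect_identical(co$labels, binarize_outcomes(co$tscores, co$cutoffs))
})

test_that("zero-noise predictable limit makes outcomes near-deterministic", {
  co <- generate_cohort(cohort_config(1000, predictable_fraction = 1,
                                      noise_sd_predictable = 1e-6, seed = 1))
  expect_true(all(pmin(co$bayes_prob, 1 - co$bayes_prob) < 1e-4))
})

test_that("low-noise patients have more extreme outcome probabilities", {
  co <- generate_cohort(cohort_config(1500, predictable_fraction = 0.5, seed = 3))
  extremity <- abs(co$bayes_prob - 0.5)
  m_pred <- mean(extremity[co$membership, ])
  m_unpred <- mean(extremity[!co$membership, ])
  expect_gt(m_pred, m_unpred)
  # stochastic dominance, not just the mean
  expect_gt(median(extremity[co$membership, ]), median(extremity[!co$membership, ]))
})

test_that("binarize_outcomes applies a strict cut-off and propagates NA", {
  ts <- matrix(c(39.9, 40, 40.1, NA), 4, 1)
  lab <- binarize_outcomes(ts, 40)
  expect_identical(as.vector(lab), c("aphasic", "normal", "normal", NA))
  expect_error(binarize_outcomes(matrix(0, 2, 3), c(1, 2)), "cutoff")
  expect_error(binarize_outcomes(matrix(0, 2, 1), NaN), "finite")
})

test_that("binarize_outcomes matches an element-wise comparison oracle", {
  withr::with_seed(11, {
    ts <- matrix(rnorm(50 * 8, 50, 10), 50, 8)
    ts[sample(length(ts), 30)] <- NA
    cuts <- rnorm(8, 45, 3)
    got <- binarize_outcomes(ts, cuts)
    for (i in 1:50) for (j in 1:8) {
      want <- if (is.na(ts[i, j])) NA_character_
              else if (ts[i, j] < cuts[j]) "aphasic" else "normal"
      expect_identical(got[i, j], want)
    }
  })
})

test_that("acute impairment filter keeps exactly the open interval (1, 7)", {
  cohort <- list(likert = matrix(rep(1:7, 4), 7, 4,
                                 dimnames = list(NULL, c("understanding",
                                                         "speaking", "reading",
                                                         "writing"))))
  for (task in c("fluency", "comp_aud", "comp_writ", "repeating",
                 "naming", "scene_desc", "reading", "writing")) {
    kept <- apply_acute_impairment_filter(cohort, task)
    expect_identical(kept, 2:6)
  }
  all7 <- list(likert = matrix(7L, 5, 4,
                               dimnames = list(NULL, colnames(cohort$likert))))
  expect_length(apply_acute_impairment_filter(all7, "fluency"), 0)
  expect_error(apply_acute_impairment_filter(cohort, "nonexistent"), "mapping")
})

test_that("both comprehension tasks share the 'understanding' item", {
  map <- default_likert_mapping()
  expect_identical(unname(map[c("comp_aud", "comp_writ")]),
                   c("understanding", "understanding"))
  expect_identical(unname(map["reading"]), "reading")
})

test_that("lower likert fidelity degrades filter/impairment agreement", {
  agreement <- function(fid, seed) {
    co <- generate_cohort(cohort_config(1200, likert_fidelity = fid,
                                        no_memory_rate = 0, seed = seed))
    kept <- apply_acute_impairment_filter(co, "fluency")
    member <- seq_len(1200) %in% kept
    mean(member == co$acute_impaired[, "speaking"])
  }
  highs <- vapply(1:5, function(s) agreement(0.95, s), 0)
  lows <- vapply(1:5, function(s) agreement(0.4, s), 0)
  expect_gt(mean(highs), mean(lows))
})

test_that("near-deterministic outcomes driven by one predictor are separable", {
  # with rho = 1, near-zero noise and the effect concentrated on left
  # lesion volume, outcomes are (almost) a deterministic threshold on a
  # single feature, so a single depth-limited tree must recover them
  w <- matrix(0, 1, 124,
              dimnames = list("task_01", lesion_feature_names(116)))
  w[1, "left_volume"] <- -1
  acc <- vapply(1:10, function(s) {
    co <- generate_cohort(cohort_config(400, n_tasks = 1, class_balance = 0.3,
                                        predictable_fraction = 1,
                                        noise_sd_predictable = 0.02,
                                        effect_weights = w, seed = s))
    lab <- co$labels[, 1]
    ok <- which(!is.na(lab))
    X <- as.matrix(co$features[ok, -1]); y <- lab[ok]
    n <- nrow(X)
    tr <- seq_len(floor(0.8 * n))
    m <- fit_rusboost(X[tr, ], y[tr],
                      ensemble_config(n_cycles = 1, max_splits = 10,
                                      n_bins = 40, undersample = FALSE,
                                      seed = s))
    mean(predict(m, X[-tr, ]) == y[-tr])
  }, 0)
  expect_gte(mean(acc >= 0.95), 0.8)
  expect_gt(mean(acc), 0.95)
})

test_that("cohort files round-trip as plain CSV", {
  co <- generate_cohort(cohort_config(40, seed = 6))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  feats <- read.csv(file.path(dir, "features.csv"), check.names = FALSE)
  expect_identical(dim(feats), c(40L, 125L))
  expect_equal(feats$left_volume, co$features$left_volume, tolerance = 1e-12)
  outc <- read.csv(file.path(dir, "outcomes.csv"), check.names = FALSE)
  expect_true(all(c("fluency", "likert_speaking") %in% names(outc)))
  truth <- read.csv(file.path(dir, "truth.csv"), check.names = FALSE)
  expect_equal(truth$p_normal_fluency, unname(co$bayes_prob[, "fluency"]),
               tolerance = 1e-12)
})
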