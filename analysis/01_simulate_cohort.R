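#!/usr/bin/env Rscript
# Generate the synthetic study cohort used throughout the analysis scripts.
#
# The generator emulates the statistical shape of a large chronic-phase
# aphasia research cohort: 116 bounded, correlated lesion-load predictors
# driven by simulated lesion extents, 8 clinical/demographic covariates,
# per-task binary language outcomes with realistic class imbalance, and a
# latent mixture in which half the patients have near-deterministic
# outcomes given their features. Writes features/outcomes/truth CSVs under
# results/cohort/.

library(prognoselect)

n_patients <- 1000   # desk-scale stand-in for a ~1400-patient registry
seed <- 20260923

cfg <- cohort_config(n_patients, predictable_fraction = 0.5, seed = seed)
cohort <- generate_cohort(cfg)
print(cohort)

dir.create("results", showWarnings = FALSE)
write_cohort(cohort, "results/cohort")

frac <- colMeans(cohort$labels == "aphasic", na.rm = TRUE)
cat("\nPer-task 'aphasic' fractions (target vs realised):\n")
print(round(rbind(target = cfg$class_balance, realised = frac), 3))
cat("\nCohort written to results/cohort/ (features.csv, outcomes.csv, truth.csv)\n")
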