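---
title: "Precision-optimised selective prognosis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Precision-optimised selective prognosis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prognoselect)
```

## The problem

Post-stroke prognostic models are usually judged by a sample-wide error
metric, which implicitly spreads prediction error evenly over patients. The
clinical intuition runs the other way: some patients' language outcomes are
far more predictable than others'. This package implements the selective
(abstaining) classification procedure that operationalises that intuition:
predict a binary language outcome ('aphasic' vs 'normal' range) per task,
but only *issue* a classification when the model's confidence clears a
tuned bar, so that issued classifications carry high positive and negative
predictive value (PPV/NPV) at the cost of covering only part of the sample.

The pipeline has five stages, each its own module:

1. **Features.** 116 atlas-region lesion loads (the proportion of each
   grey-matter region destroyed by the binarized lesion) plus 8
   clinical/demographic covariates — time post-stroke, age at onset,
   handedness, sex, native-language flag, and total/left/right lesion
   volume: 124 predictors per patient.
2. **Outcomes.** 8 language-task t-scores thresholded into binary classes
   at a normative cut-off; scores strictly below the cut-off are
   'aphasic'-range.
3. **Classifier.** A random under-sampling boosted (RUSBoost) tree
   ensemble, suited to the imbalanced outcome classes, emitting two
   normalized per-class scores per case.
4. **Calibration.** Per-class score thresholds tuned on a validation split
   to maximise each class's precision; cases whose winning score does not
   strictly exceed the threshold are abstained on.
5. **Evaluation.** Monte-Carlo nested cross-validation (repeated 80/10/10
   splits), reporting mean ± SD NPV/PPV and coverage across repetitions.

## The classifier

RUSBoost is binary AdaBoost over depth-limited trees in which each
iteration's tree is trained on a balanced sub-sample: all minority-class
cases plus a uniform random draw of majority-class cases (majority:minority
ratio 1 by default). The weighted error $\varepsilon_t$ and the
multiplicative case-weight updates are computed on the *full* training set,
so undersampling changes only what each weak learner sees, not how the
boosting bookkeeping runs:

$$\alpha_t = \eta \cdot \tfrac12 \ln\frac{1-\varepsilon_t}{\varepsilon_t},
\qquad
D_{i} \leftarrow D_i \, e^{\pm\alpha_t} \;/\; Z_t ,$$

with learning rate $\eta$, up-weighting mistakes and renormalising by
$Z_t$. Iterations with $\varepsilon_t \ge 0.5$ get $\alpha_t = 0$ and reset
the weights to uniform, restarting the boosting chain rather than letting an
uninformative learner corrupt it.

Default hyperparameters follow the conventional defaults for this ensemble
family: 100 learning cycles, learning rate 0.1, at most 10 splits per tree,
minimum leaf size 1, and 10 quantile bins per continuous predictor for the
split search. Trees grow best-first on the weighted Gini criterion; split
ties break toward the lowest predictor index then the lowest bin, making
fits bit-reproducible given the seed. The quantile-bin split search is the
standard accelerated search for this tree family and is implemented in
C++; everything else is R.

**Score semantics.** The two per-class scores are normalized
$\alpha$-weighted means of the trees' *leaf class probabilities*:
$s_{\text{normal}}(x) = \sum_t \alpha_t \, p_t(\text{normal} \mid x) /
\sum_t \alpha_t$, so $s_{\text{aphasic}} + s_{\text{normal}} = 1$ always.
Two alternatives were considered and rejected. Raw boosting margins have a
data- and task-dependent scale, which defeats comparable thresholds.
Hard-vote fractions ($\alpha$-weighted shares of trees voting for each
class) look natural but destroy exactly the information the thresholds
need: in a region where the true conditional probability is 0.75, nearly
every tree agrees on the majority class, so the vote fraction saturates at
1 and a "probably normal" patient becomes indistinguishable from a
"certainly normal" one — exactly the distinction the selective thresholds
exist to draw. Leaf probabilities keep the gradation while the
normalisation keeps every threshold on the same $[0.5, 1]$ scale (the
winning class's score is always at least 0.5), which is what makes the two
tuned thresholds comparable across tasks and serialisable. Leaf
probabilities are re-estimated after each tree is grown, on the full
training set (lower variance than the sub-sample) under *equal class
priors* — the distribution the balanced sub-sample actually trains on.
Estimating them under the raw prevalence instead would silently undo the
under-sampling: every borderline leaf would tip toward the majority class
and the ensemble would lose exactly the minority sensitivity it was built
for. Argmax ties (exactly 0.5/0.5) resolve to 'aphasic' — the
conservative direction clinically — and the rule is fixed so results are
reproducible.

## Threshold tuning

For each class independently, candidate thresholds are the sorted distinct
winning-class scores observed in the validation set, plus the permissive
floor 0.5 — the search is exact and finite rather than a fixed grid.
A classification is issued when the score *strictly* exceeds the
threshold. Among candidates that classify at least `min_classified`
validation cases (default 5), the tuner picks the one maximising that
class's precision, breaking precision ties toward the smaller threshold
(larger coverage). `min_classified` exists because, without a floor, a
threshold just below the single highest validation score trivially achieves
precision 1.0 on one lucky case and generalises terribly; 5 is deliberately
mild and is exposed as configuration. If no candidate reaches the floor,
the class is flagged calibration-failed and always abstains — a flag, not a
silent 0 or 1.

Undefined precision (no classification of a polarity issued) propagates as
`NA` with an explicit `defined_*` flag everywhere, and such repetitions are
excluded from cross-run means with the exclusion counted — never coerced.

Coverage of a class is defined as issued-classification count over the
true-class total. At very permissive thresholds the numerator includes
wrong-class cases, so coverage can exceed 1; this is deliberate and matches
how coverage behaves on the validation trade-off curves, which is also why
those curves are reported alongside the tuned operating point.

## Cross-validation protocol

Repetitions are independent stratified re-splits (Monte-Carlo CV), not a
rotated k-fold: each repetition draws a fresh 80/10/10
train/validation/test partition, stratified by the task's binary outcome.
Stratification is not optional in practice: with a 1:3 class ratio an
unstratified 10% validation split of a few hundred patients is frequently
single-class, which would make precision tuning undefined. Splits where
train or validation still lack a class are re-drawn (bounded at 10
attempts, logged, seed-deterministic); missing features are imputed by the
training-split median, so no test or validation information leaks into the
fit. Threshold tuning sees only validation scores; the test split is
touched exactly once per repetition.

Analysis 1 uses every patient with an outcome for the task. Analysis 2
first restricts to patients whose retrospective 7-point self-report for the
mapped language domain lies strictly between 1 (no memory of the acute
period) and 7 (skill judged perfectly spared), emulating the clinically
relevant population of people who actually had acute symptoms. The
task-to-item mapping is configuration; the default maps both comprehension
outcomes to 'understanding', reading and writing to themselves, and the
four spoken-production tasks (fluency, naming, scene description,
repetition) to 'speaking'. Mapping repetition to 'speaking' is a judgment
call — repetition is a spoken-production task even though it also loads on
auditory short-term memory — and can be overridden.

The 'predictable' group for a task contains patients who received a
non-abstain decision in strictly more than half of their test-set
appearances across repetitions; "exactly half" is not a majority and lands
in the 'not predictable' group.

## The synthetic cohort generator

Patient-level stroke registry data of this kind are shared only under
agreement, so the package ships a generator that reproduces the structure
the method relies on, with defaults chosen once to mirror a large
chronic-phase aphasia cohort:

* total lesion volume log-normal with mean 64 cm³ and SD 83 cm³, split
  between hemispheres by a left-dominant Beta(4, 1.5) share (an aphasia
  cohort is left-lateralised by selection);
* region loads in (0, 1) via a logistic function of hemispheric lesion
  extent, a shared per-patient factor (spatial correlation), and region
  noise;
* covariates: age at onset ~ N(56, 13.3²) (truncated 18–90), time
  post-stroke log-normal (median 30 months), 87% right-handed, 67% male,
  90% native speakers;
* per-task 'aphasic' fractions defaulting to 0.25–0.50, the imbalance
  range typical of the eight language summary tasks;
* latent per-task performance = a linear effect pattern over standardized
  features (left-lateralised by default, with strong left/total volume
  terms, a recovery benefit of time post-stroke and a penalty of age),
  scaled to unit variance, plus Gaussian noise whose SD depends on
  mixture membership: `noise_sd_predictable = 0.3` for the low-noise
  ("predictable") component versus `noise_sd_unpredictable = 3.0`, with
  `predictable_fraction = 0.5` of patients in the low-noise component.
  The 10:1 noise ratio makes predictability a real latent property rather
  than a gradient;
* mixture membership is *coupled to time post-stroke*
  (`predictability_coupling = 0.95`: a rank construction preserving the
  exact fraction while correlating the membership score with standardized
  log time). This is not cosmetic. A classifier only ever sees the
  features, so it can only learn the marginal P(outcome | features); if
  membership were independent of the features that marginal would blur
  the two components together and *no* model — however good — could
  identify the predictable patients. Predictability must be essentially
  feature-measurable for the recovery question to be well-posed, and
  tying it to assessment time matches the pattern that confidently
  classified patients tend to be those assessed longer after their
  stroke;
* t-scores are an affine map of the latent to the usual 50/10 scale; the
  per-task cut-off is placed at the `class_balance` quantile, which is
  also how the binarizer defaults when no normative cut-off is supplied
  (the normative cut-offs themselves are instrument-defined and not
  re-derivable here);
* `bayes_prob` records the true P(normal | features, membership), enabling
  oracle tests no real dataset permits;
* Likert self-reports are noisy functions of the time-free (acute) part of
  the latent severity: the true report is 2–6 when acutely impaired and 7
  when spared, replaced by a uniform draw with probability
  `1 − likert_fidelity` (default fidelity 0.9) and by 1 ("no memory") with
  probability 0.05;
* outcomes go missing completely at random at 3% per task, matching the
  mild per-task attrition of registry samples.

What the generator does *not* emulate: real lesion geometry and its
anatomy-specific correlation structure, longitudinal recovery, informative
missingness, scanner or site effects, and any distribution shift between
research and clinical populations. Tests passing on synthetic cohorts
therefore certify the *procedure* — that tuning generalises, that
abstention buys precision, that the predictable subgroup is recoverable
when it exists — not clinical performance on any real population.

## Numerical choices and degenerate inputs

* Outcome binarization is strict: a t-score exactly at the cut-off is
  'normal' ("below the threshold" means strictly below).
* Lesion binarization is strict (> 0.3) with the conventional 0.3 default;
  binarization is idempotent, and re-thresholding an already-binary image
  warns rather than silently doing nothing meaningful.
* Lesion and atlas grids must match exactly; no resampling is performed,
  because silent interpolation corrupts load values. Hemisphere
  assignment uses the sign of the world x-coordinate of each voxel centre
  (MNI convention: x < 0 left); exact-midline voxels count in the total
  volume only. Atlas regions with zero voxels yield `NA` loads, not 0.
* `eps = 0` on a separable sub-sample is clamped to 1e-10 inside the
  learner-weight formula so a perfect weak learner gets a large finite
  weight instead of an infinite one.
* The Wilcoxon rank-sum comparison uses midranks with the tie-corrected
  normal approximation and continuity correction (the study-scale groups
  are large); an exact enumeration over all assignments is available for
  small groups and doubles as the test oracle. z is signed so positive
  means group a is stochastically larger. The two-proportion z-test uses
  the pooled-variance form; a pooled proportion of 0 or 1 is flagged
  undefined.
* Importance ranks use competition ("1224") ranking so tied predictors
  share the best rank of their block.

## Problem sizes in the shipped scripts and tests

The `analysis/` drivers run a 1000-patient cohort with 25 repetitions —
sizes chosen so the whole workflow re-runs interactively while the means
are already stable; the protocol's full form (100 or 1000 repetitions, a
~1400-patient sample) is a `run_config` change, not a code change. The
test-suite simulations use cohorts of 300–2000 and 1–100 repetitions per
property, scaled to what each check needs.

## Known limitations

* Scores are vote fractions, not calibrated probabilities; thresholds
  transfer across tasks by construction but the scores themselves should
  not be read as risks.
* Precision maximisation ignores coverage except through
  `min_classified`; a coverage-constrained or cost-weighted variant is a
  natural extension and the trade-off curves are emitted to support it.
* Impurity-based importance ignores the thresholding step entirely: a
  predictor can rank highly yet matter little for *which* patients clear
  the confidence bar. The report carries this caveat rather than a fix.
* With very small validation splits the tuner's precision estimates are
  high-variance; `min_classified` mitigates but does not remove this.
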