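# facepref

Does the amount of parental speech a very preterm infant hears during
neonatal intensive care relate to the infant's later attentional preference
for faces? `facepref` implements the full analysis pipeline for that
question, for researchers working with NICU language-environment recordings
(LENA-style adult word counts), caregiver presence diaries, and infant
eye-tracking disengagement tests — together with a synthetic-cohort
simulator so the entire pipeline can be validated without access to
confidential infant data.

## What it computes

**Speech exposure.** For each parent, a two-factor composite over the
active-care window 07:00–22:00:

```
exposure = (words in the parent's channel while present / hours present
            during the recording day)  ×  presence hours over 14 diary days
```

with the study's imputation rules for parents absent on the recording day
(single-mother families → father exposure 0; twins → the co-twin's recorded
value; otherwise the site-specific median).

**Face preference.** Trials of a gaze-disengagement ("overlap") paradigm —
48 trials in four blocks, faces vs phase-scrambled non-face patterns, parent
faces in blocks 2–3 — are judged against four validity criteria (≥75%
central fixation, analyzable data, no premature shift ≤150 ms, shift toward
the distractor) and averaged into each infant's probability of *no*
disengagement per condition. Infants need more than two valid trials in
every condition.

**Inference.** Rank-based throughout: paired Wilcoxon signed-rank with the
`|z|/√N` effect size; per-site z-scoring; partial Spearman correlations
(rank, residualize on covariates, correlate residuals) between exposure and
the face score adjusted for the non-face score, optionally also for
gestational age, maternal education, delivery type, sex, and birth weight;
the parent-vs-unfamiliar-face analysis; and an exhaustive twin-subset
sensitivity analysis (with k twin pairs, all 2^k ways of keeping one twin
per pair).

## Worked example

```r
library(facepref)

cfg <- simulation_config(seed = 2)   # two sites, 63 infants, 7 twin pairs
out <- run_pipeline(cfg, n_boot = 2000)
print(out$results)
```

```
Speech exposure / face preference analysis (n included = 59 )

Face vs non-face no-disengagement: M = 0.56 (SD 0.26) vs 0.28 (SD 0.16)
  z = 5.80, p = 6.46e-09, effect size z/sqrt(N) = 0.76

exposure_total_face_pref: estimate = 0.423 [0.20, 0.59], p = 0.0009378, n = 59
  adjusted for: nonface_score
exposure_total_face_pref_adjusted: estimate = 0.442 [0.22, 0.62], p = 0.0009261, n = 59
  adjusted for: nonface_score, gestational_age_weeks, maternal_education, delivery, sex, birth_weight_g
exposure_parent_face_pref: estimate = 0.233 [-0.06, 0.49], p = 0.07781, n = 59
  adjusted for: unfamiliar_face_score

Twin-subset sensitivity analysis: 32 subsets
  r ranged from 0.409 to 0.456, median 0.431
```

Reading the output: infants disengage far less often from faces (0.56) than
from non-face patterns (0.28) — a strong face preference (effect size 0.76).
The simulated cohort was generated with a latent exposure–preference
correlation of 0.35, and the pipeline recovers a positive adjusted partial
r_s (0.42 in this draw; the sampling SD at n ≈ 60 is about 0.13). Four
infants failed the valid-trial rule, and two twin pairs lost a member to it,
so 5 complete pairs remain and the sensitivity analysis enumerates 2^5 = 32
subsets, all giving similar correlations. `out$exposure`, `out$scores`, and
`out$cohort` hold the stage tables; passing `out_dir=` writes
`exposure.csv`, `scores.csv`, `results.json`, and `report.md`.

Real data enter the same way via `inputs = list(infants, diary, segments,
trials)` or a directory of CSVs (`read_cohort()`); a command-line wrapper
lives at `inst/scripts/facepref-pipeline.R`.

## Package layout

| Where | What |
|---|---|
| `R/simulate.R`, `R/schedule.R` | synthetic cohort, trial schedules, gaze streams |
| `R/exposure.R`, `R/time-utils.R` | interval clipping, presence, word frequency, imputation |
| `R/gaze.R` | stream coding, validity criteria, condition scores |
| `R/stats.R`, `R/analysis.R` | Wilcoxon, partial Spearman, twin subsets, cohort analysis |
| `R/pipeline.R` | orchestration and file IO |
| `vignettes/speech-exposure-face-preference.Rmd` | the methods vignette: models, assumptions, design choices |
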