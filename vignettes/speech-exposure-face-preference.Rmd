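---
title: "Methods: speech exposure, gaze disengagement, and rank-based inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: speech exposure, gaze disengagement, and rank-based inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(facepref)
```

This vignette documents the scientific model behind the package: what each
stage computes, the assumptions it makes, the parameters that matter, and the
choices taken where the underlying study design left the implementation open.

## The problem

Very preterm infants cared for in neonatal intensive care units (NICUs) hear
far less parental speech than term infants at home, and the amount varies
enormously with unit architecture (single-family rooms versus open bays) and
parental presence. The question the pipeline addresses is whether the amount
of parental speech an infant is exposed to during neonatal care is associated
with an early marker of social-cognitive development: the infant's attentional
preference for faces over matched non-face patterns, measured with a gaze
disengagement ("overlap") paradigm at seven months of corrected age.

Because cohort data of this kind are confidential, the package ships a
synthetic-cohort generator with known ground truth. Every downstream stage is
exercised and validated against that generator; the same functions accept real
tables with the same schemas.

## The speech-exposure composite

Exposure is a two-factor composite:

\[
E = \underbrace{\frac{\text{words in the parent's channel while present}}
{\text{hours present during the recording}}}_{\text{word frequency (words/h)}}
\times \underbrace{\text{presence hours over the 14-day diary}}_{\text{dose}}
\]

computed separately per parent and summed for the family total. Word counts
come from a wearable recorder whose software classifies ambient audio into
female and male adult words per segment; presence comes from a caregiver
diary of presence/holding/skin-to-skin intervals. Only the active-care window
07:00--22:00 of each day enters either factor.

Implementation choices where the design is silent:

* **Intervals are half-open `[start, end)` at minute resolution**, so abutting
  intervals never double-count a boundary minute.
* **Channel = role.** Female words are attributed to the mother and male words
  to the father; overlapping-speaker ambiguity is not modelled.
* **Partial overlap.** A segment that only partly overlaps a presence interval
  contributes its words in proportion to the overlap fraction of its duration,
  which is unbiased if words are uniformly spread within a segment
  (segments are 5 min by default, so the assumption is mild).
* **Missing parents on the recording day** are imputed in a fixed precedence:
  a single-mother family's father is zero exposure; a twin's missing parent
  takes the value observed during the co-twin's recording; otherwise the
  site- and role-specific median of observed frequencies is used. The
  `frequency_source` column records which rule fired.
* **Diary coverage.** The package assumes the diary spans the intended 14-day
  period and reports presence as-is; thresholding infants on partial diary
  coverage is left to the user.

`exposure_table()` is verified end-to-end against a brute-force
minute-resolution oracle (per-minute membership counting and per-minute word
apportionment) in the test suite.

## Gaze disengagement scoring

Each trial shows a central stimulus (a face with a neutral, happy, or fearful
expression, or a phase-scrambled non-face control; 9.6° × 10.2°), followed
after a 1000-ms onset asynchrony by a lateral checkerboard distractor at
~12° eccentricity for 2000 ms. The schedule is four 12-trial blocks
(48 trials): six face and six non-face trials per block in randomized order,
parent identity in blocks 2--3, unfamiliar identity in blocks 1 and 4, and
distractor sides balanced 3/3 within every block × stimulus-class cell.

A trial is scored by whether the gaze disengages from the central stimulus
toward the distractor within 150--1000 ms of distractor onset. Four validity
criteria are applied in order: (i) fixation on the central stimulus for at
least 75% of the pre-distractor period, (ii) analyzable data across the
analysis window, (iii) no premature shift (strictly later than 150 ms), and
(iv) shift directed toward the distractor. Disengagement outcomes (0/1) over
valid trials are averaged into the probability of **no** disengagement per
condition, with expressions pooled; an infant enters the analysis only if all
four identity × class conditions have more than two valid trials.

Open points resolved here, all configurable:

* **The 75% denominator** is the pre-distractor period (central onset to
  distractor onset, 1000 ms).
* **The >2-valid-trials rule** is enforced per identity × class condition by
  default (`pooling = "split4"`); applying it to the pooled face/non-face
  conditions only is available as `pooling = "pooled2"`.
* **Dwell time** (the latency-based secondary measure) is right-censored at
  the 1000-ms window end, and no-disengagement trials enter at the 1000-ms
  cap. With 30-Hz video coding, latency resolution is one frame (33.3 ms);
  the premature-shift comparison is a strict `> 150 ms`.

Round-trip fidelity is tested by injecting known outcomes into noise-free
synthetic 30-Hz streams and recoding them: 500/500 outcomes recovered with
latency error at most one frame.

## Statistical layer

All inference is rank-based because disengagement probabilities are bounded
and skewed:

* **Paired Wilcoxon signed-rank** for face versus non-face, with effect size
  \(|z|/\sqrt{N}\). Zero differences are dropped and tied ranks averaged; the
  p-value is exact (signed-rank distribution) when no ties or zeros are
  present and \(N \le 50\), and otherwise uses the tie-corrected normal
  approximation — the same approximation that defines \(z\).
* **Per-site z-scoring** before pooled correlation analyses, removing
  site-level differences in both exposure and disengagement.
* **Partial Spearman correlation** by rank-then-residualize: all variables are
  rank-transformed (average ranks), the ranked exposure and face score are
  residualized on the ranked covariates by least squares, and the residuals
  are Pearson-correlated. With no covariates this reduces exactly to textbook
  Spearman. This deterministic closed-form construction differs from
  probability-scale-residual estimators of partial rank correlation; the two
  agree closely in practice but are not identical. p-values use the
  t-approximation with \(n - 2 - k\) degrees of freedom; confidence intervals
  are seeded bootstrap percentile intervals (2000 case resamples by default),
  since the provenance of printed intervals in this literature is typically
  unstated. The main analysis adjusts the face score for the non-face score;
  the covariate-adjusted variant adds gestational age, maternal education
  (ordinal codes), delivery type, sex, and birth weight. No multiple-testing
  correction is applied, mirroring the analysis design.
* **Twin-subset sensitivity**: with \(k\) complete twin pairs the main
  correlation is recomputed on all \(2^k\) subsets keeping every singleton and
  one member per pair (7 pairs → 128 subsets). Enumeration is capped at
  \(2^{12}\) pairs in `analyze_cohort()`; exhaustive enumeration is only
  meaningful for small family clusters.

## The synthetic cohort generator

The generator emulates the study conditions: two sites with 25 and 38 infants
(7 complete twin pairs), a 14-day diary, one 16-hour recording on diary day 7,
and a 48-trial disengagement test per infant.

* **Latent structure.** Each infant has an exposure score \(z\) (twins share a
  family component, intra-pair correlation 0.8) and a face-preference trait
  \(t\) with \(\mathrm{cor}(z, t) = \rho\) (default 0.35, the
  `rho_exposure_preference` dial). \(z\) loads on log word frequency (0.9) and
  on logit daily presence (0.7); the loadings are set so that the injected
  \(\rho\) approximately equals the rank correlation recoverable from the
  generated tables — the copula exists to control that target. A Gaussian
  copula over (log exposure, trait) gives exact control of the latent rank
  correlation.
* **Site magnitudes.** Word frequencies are log-normal with medians near
  1100 (mothers) and 330 (fathers) words/h at site A and 230 and 14 at
  site B; median daily presence is 8/4 h (site A mothers/fathers) and
  12.5/1 h (site B) within the 15-h window. These echo the contrast between a
  single-family-room unit and an open-bay unit without claiming to reproduce
  any cohort's data-dependent values.
* **Trial outcomes.** Face trials follow
  \(\operatorname{logit}(p_{\text{no-dis}}) = \operatorname{logit}(0.55) +
  1.0\,t + u\) and non-face trials
  \(\operatorname{logit}(0.24) + u\), where \(u\) (SD 0.7) is a general
  attention tendency shared by both conditions and independent of the trait.
  The trait affects face trials only; \(u\) is what the face-given-non-face
  adjustment removes, and without it the non-face condition would show only
  binomial spread, far below what infant data show. Both SDs were derived
  from the printed condition SDs of the motivating cohort before any recovery
  testing.
* **Missingness.** Per-trial coding failure averages 20% with between-infant
  beta variation; mothers/fathers are absent on the recording day with
  probability 0.02/0.20; 5% of families are single-mother families (father
  exposure zero).
* **Latency distribution.** The study design does not state one;
  disengagement latencies are drawn from a log-normal (meanlog log 400 ms,
  sdlog 0.5) truncated to the 150--1000 ms window. This is an explicit
  assumption, not an estimate.
* **Gaze streams.** Optionally the generator emits raw 30-Hz gaze streams
  (`emit_gaze_streams = TRUE`) instead of only coded trials; streams place
  gaze at the centre, jump to the distractor at the injected latency, and add
  Gaussian positional noise (default 0.5°).

What passing tests on this generator do **not** show about real data: the
generator has no drifting calibration, no smooth pursuit or partial shifts,
no within-day autocorrelation in presence, no parent-staff conversation
structure in the word counts, and covariates are independent of the trait by
construction. It validates the *pipeline*, not the biology.

## Validation strategy and problem sizes

The test suite validates each stage against independent brute-force oracles
(minute-resolution exposure recomputation, exact sign-flip enumeration of the
Wilcoxon distribution, direct 0/1-vector score recomputation) and the whole
pipeline by parameter recovery: at the study scale (n = 63, 7 twin pairs) the
median covariate-adjusted partial correlation over 200 simulated cohorts is
compared with the same estimator applied to 10 cohorts of 2000 infants (a
large-sample oracle of the same generating process), and the type-I error of
the adjusted test is checked over 1000 null cohorts. These sizes keep the
whole suite comfortably within a coffee break on a single core while leaving
Monte-Carlo error well below the tolerances tested.

## Known limitations

* The rank-residual partial correlation is not the probability-scale-residual
  estimator; estimates can differ slightly in heavily tied data.
* Bootstrap percentile intervals can undercover near boundary values of
  \(r_s\) at small n.
* The dwell-time cap rule (1000 ms for no-disengagement trials) is one of
  several defensible censoring conventions; conclusions based on dwell time
  should be checked under alternatives.
* Family clustering is handled by exhaustive subset sensitivity, not by a
  mixed model; with many twin pairs a model-based approach would be needed.
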