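---
title: "Atrophy fingerprinting: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atrophy fingerprinting: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adfingerprint)
```

## The procedure

`adfingerprint` implements a normative-modelling workflow for regional brain
morphometry in three steps.

**1. Preprocessing.** Every measurement (cortical thickness in mm, regional
volume in mm³, over an 89-region parcellation: 34 cortical regions, 23
subcortical structures, 22 hippocampal subfields, 10 amygdalar nuclei) is
first *age-corrected* with the slope of an ordinary least-squares regression
of the control cohort's values on age, fitted independently per
(region, hemisphere, metric) key:

$$v' = v - \hat\beta_{\text{age}} \, (a - \bar a_{\text{ctl}}),$$

residualizing every subject — control, case, or exposed — to the control
mean age on the original measurement scale, so that percent differences stay
interpretable. Volumes are then *normalized*: regions parented by the
intracranial volume (ICV) are divided by the subject's ICV; hippocampal
subfields and amygdalar nuclei are divided by the subject's same-hemisphere,
age-corrected whole-hippocampus or whole-amygdala volume; the whole
hippocampus and amygdala are themselves ICV-normalized. Thickness is
age-corrected but never ICV-scaled — it is not a volume and does not scale
with head size. The order (correct, then normalize) is fixed and enforced
through provenance flags.

**2. Fingerprint derivation.** Every key is screened with a two-sided
pooled-variance Student *t*-test between cases and controls (a Welch option
exists but defaults off, matching the classical procedure). Percent change
is $100\,(\bar x_{\text{ctl}} - \bar x_{\text{case}})/\bar x_{\text{ctl}}$,
positive for atrophy, negative for ex vacuo dilatation. A region × metric
pair enters the *fingerprint* only if both hemispheres are significant at
$\alpha = 0.05$ with concordant direction; midline/global structures
(corpus callosum segments, third/fourth ventricle, CSF, brainstem, whole
brain and total gray volumes), which FreeSurfer reports unlateralized, need
only their single test. No multiple-testing correction is applied — that is
the method being reproduced — but the summary reports the expected number
of false-positive keys at $\alpha$ so the risk is visible. Because cortical
regions contribute separate thickness and volume entries, summaries report
both the region×metric and the distinct-region count.

**3. Individual scoring.** Against a control normative reference
(per-key mean and sample SD of the preprocessed control values), each scored
subject receives a z-score per fingerprint entry and hemisphere; an entry is
an *outlier* iff the deviation exceeds `z_threshold` (default 2) SDs **in
the entry's disease direction**, in either hemisphere. Counting
direction-agnostic outliers would credit anti-disease deviations as
pathology, so the direction constraint is deliberate. A subject's
outlier-region count is compared with the control count distribution:
the cutoff is control mean + 2 SD, and `at_risk` requires a strictly
greater count. With control counts of mean 1.78 and SD 1.83 this yields the
familiar 5.44-region threshold.

## Tunable parameters

| parameter | default | role |
|---|---|---|
| `alpha` | 0.05 | per-hemisphere significance for the bilateral filter |
| `z_threshold` | 2 SD | outlier flag per fingerprint entry |
| cutoff rule | mean + 2·SD of control counts | at-risk classification |
| `welch` | `FALSE` | pooled (Student) vs unequal-variance *t* |
| `by_cohort_tag` | `FALSE` | per-scanner-stratum age models |
| `strict` | `FALSE` | error vs log-and-skip on missing fingerprint keys |
| `basis` | `"entries"` | count region×metric entries vs distinct regions |

Raising `z_threshold` can only lower counts (a tested monotonicity
invariant); the cutoff moves with the control count distribution, so the two
knobs interact.

## What the synthetic generator emulates

`default_cohort_config()` states one fixed world:

* **Cohorts.** 114 controls aged uniformly 18–81 (three scanner strata of
  38/50/26), 58 case subjects aged 75.5 ± 6.6 (truncated normal), 46 exposed
  subjects aged 48.4 ± 12.2 truncated to 29–75, all-male. ICV ~
  N(1.5 × 10⁶, 1.4 × 10⁵) mm³.
* **Measurements.** Expected value = head-size scale × baseline ×
  group effect, plus a common (parallel-slope) age trend, also head-size
  scaled for ICV-parent volumes: cortical/subcortical tissue loses
  0.2–0.3 %/yr, ventricular CSF spaces gain 2.5 %/yr. Noise is
  multiplicative lognormal with CV 0.06 (thickness), 0.12 (tissue volumes),
  0.45 (ventricles), 0.25 (hippocampal fissure), so raw values are always
  positive; hemispheres share noise at correlation ρ = 0.8. Regional
  baselines are plausible FreeSurfer-scale magnitudes; they matter only
  through their CVs.
* **Effects.** Multiplicative group effects transcribed from the reported
  case-control and exposed-control percent changes (e.g. entorhinal
  thickness −19.1 %, volume −27 %; fimbria −23.7 %; whole amygdala −24 %;
  inferior-lateral ventricle +124.7 %; lateral ventricle +32.5 %). Subfield
  and nucleus effects are applied to the *fraction* of the parent volume, and
  subfield values are generated as noisy fractions multiplied back onto the
  simulated parent, so parent-normalization in the analysis recovers exactly
  the quantity the effect was stated on. Regions reported only as
  "significantly reduced" without a magnitude carry a nominal 10 % effect;
  unreported regions carry none. The putamen follows the results table
  (+15.3 %, enlarged) where the narrative elsewhere contradicts it.
* **Exposed heterogeneity.** Exposed subjects carry a lognormal severity
  multiplier (sdlog 0.5) on the log-effect: the premise for that cohort is
  that only part of it harbours pathology, and the severity drives the
  cognition block. Cases are modelled as homogeneous (a diagnosed,
  early-stage group). An optional `affected` block instead assigns a known
  fraction of exposed subjects a k-region, s-SD shift in the case
  direction — the configuration the prevalence-recovery acceptance test
  uses, with every assignment recorded in the truth ledger.
* **Cognition.** Per-subtest ANAM throughput Z-scores are generated as
  $z = \mu + (-|r_t|\,u + \sqrt{1-r_t^2}\,\varepsilon)$ with $u$ the
  standardized true burden and $r_t$ the per-subtest target correlations
  (M2S −0.35, CDS −0.31, …). The cohort mean μ = −0.13 makes the
  composite-below-WRAT decline prevalence ≈ 55 %, the stated prevalence for
  that population (with WRAT ~ N(0,1), the difference has SD ≈ 1.07, and
  Φ(0.13/1.07) ≈ 0.55). About 9 % of exposed subjects miss the ANAM battery;
  ~23 % of controls miss the subfield/nucleus family, emulating incomplete
  subfield runs.

What it does **not** emulate: scanner/protocol offsets are available but off
by default; no spatial covariance between neighbouring regions beyond the
parent-child coupling; no nonlinear age trajectories; no sex effects; no
longitudinal change. A green end-to-end test therefore establishes that the
pipeline recovers the stated statistical structure — not that it would be
robust to site effects or non-linear aging in real data.

## Numerical choices and degeneracies

* Slopes come from the closed-form OLS ratio (cov/var); keys with < 3
  control observations get slope 0 with a message.
* The *t*-test, Pearson correlation, z-scores and OLS fits are all checked
  against independent oracles (`t.test`, `cor.test`, normal equations,
  brute-force recomputation) to 1e−10 in the test suite.
* Degenerate situations fail loudly with classed errors (exit code 3 in the
  CLI): zero-SD normative reference, < 3 control profiles for a cutoff,
  rank-deficient interaction designs, missing or non-positive normalization
  denominators.
* Ties at the cutoff are unambiguous because the at-risk comparison is
  strict and counts are integers while the cutoff is generically fractional.
* TSV exports write 17 significant digits so write→read round-trips are
  bit-exact.

## Design decisions that were genuinely open

* **Age-correction formula.** Only the slope is specified by the procedure;
  we residualize to the control mean age, the one choice that leaves control
  means unchanged and keeps percent change on the raw scale.
* **Parent denominators** are hemisphere-matched and age-corrected; mixing a
  corrected numerator with a raw denominator would reintroduce age
  structure.
* **Decline sign.** The source text's literal sentence (WRAT − composite,
  negative = decline) would flag subjects performing *above* their premorbid
  estimate; we define decline as composite < WRAT (current below premorbid)
  for construct validity and flag the discrepancy here.
* **Hippocampal fissure** is parent-normalized like any other subfield even
  though it is a CSF cleft, matching the stated rule; its direction in the
  fingerprint is empirical (dilation), so no harm follows.
* **Interaction regressions** default to age-*un*corrected normalized
  volumes: age is a regressor there, and double age-adjustment would null
  the age term.
* **Control self-scoring.** Scoring reference controls against their own
  full-sample reference biases their counts (and hence the cutoff) low;
  `score_controls_loo()` rebuilds the reference per subject with closed-form
  leave-one-out updates. The naive variant remains the default for
  fidelity; the prevalence-recovery acceptance test uses the LOO cutoff.
* **Age-matched nulls.** With a case cohort ~26 years older than the control
  mean, the sampling error of the control age slope is extrapolated across
  that gap and shared between correlated hemispheres; even under the null
  this inflates bilateral inclusions well above α². This is a property of
  the correction procedure itself, worth knowing before applying the
  pipeline to age-mismatched cohorts; the null-calibration tests age-match
  the cohorts to isolate the filter's own behaviour.

## Known limitations

Region-level analysis only (no vertex-wise or cluster statistics); no
multiple-testing correction by design; the at-risk label is a count
exceedance, not a calibrated probability of disease; uncorrected scanner
heterogeneity is pooled unless `by_cohort_tag` is enabled; and the
41-vs-55 ambiguity in how fingerprint entries are counted (regions vs
region × metric) is surfaced by reporting both rather than resolved.

## A worked run

```{r example, eval = FALSE}
out <- tempfile()
paths <- run_simulate(file.path(out, "sim"), seed = 7)
d <- run_derive(paths[["control"]], paths[["AD"]], file.path(out, "derive"))
fingerprint_summary(d$fingerprint)
s <- run_score(file.path(out, "derive"), paths[["control"]],
               paths[["exposed"]], file.path(out, "score"))
s$classification
```
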