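---
title: "Methods: symptom-reflux association on ambulatory pH monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: symptom-reflux association on ambulatory pH monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refluxsap)
```

## The problem

Prolonged (typically 48-h, catheter-free Bravo-style) esophageal pH
monitoring serves two purposes in the work-up of gastroesophageal reflux
disease (GERD). First, it quantifies distal esophageal acid exposure,
summarised by the DeMeester composite score; a score above 14.7 is the
conventional definition of abnormal acid exposure and a strong predictor of
response to antireflux surgery. Second, because patients press an event
button when they experience a symptom, the recording supports a *temporal*
association analysis between symptoms and reflux episodes. The symptom
association probability (SAP) is the most widely used such index; the
symptom index (SI) and symptom sensitivity index (SSI) are simpler
companions. This package implements the full chain — episode detection,
DeMeester scoring, SAP/SI/SSI — plus synthetic-data generators and the
cohort-level analyses used to ask whether SAP status predicts surgical
outcome in patients who already have abnormal acid exposure.

## Data model and conventions

All times are seconds from recording start and every interval is half-open
`[start, end)`. Each pH sample represents the interval
`[t, t + sample_interval_s)`; "time below pH 4" is the summed length of such
intervals. This sample-carries-interval convention is bit-exact and avoids
interpolation ambiguity. The default sampling interval is 6 s, the common
Bravo telemetry rate; any regular interval is accepted. Posture intervals
(upright/supine) must jointly cover the recording. Meal intervals are
carried in the data model but **not** excluded from any computation by
default; exclusion is a flag (`exclude_meals`), because clinical protocols
differ and no exclusion rule is universal. Recordings of any duration from
2 min up are accepted and their duration recorded.

Symptoms follow the fixed clinical taxonomy: typical = heartburn,
regurgitation, dysphagia; atypical = chest pain, cough, globus, throat
clearing; non-reflux = abdominal pain, nausea; anything else maps to
`other`. A log tracks at most three symptoms, mirroring the three-button
convention of ambulatory systems.

## Reflux episodes and the DeMeester composite

`detect_reflux_episodes()` returns maximal runs of samples below pH 4
(threshold configurable). `merge_gap_s` merges runs separated by short
recoveries; its default is 0 because no merging rule is universally agreed.
The six classic components are computed by `acid_exposure_components()`:
percent time below pH 4 in total, upright and supine; the number of
episodes; the number of episodes of at least 5 min; and the longest episode
in minutes.

The composite formula used here scores each component as
`max(0, (value - mean)/sd + 1)` against reference normals and sums the six
terms, so a profile sitting exactly at the normals scores 6.0 and the score
is monotone in every component. The shipped reference means and standard
deviations are the classic Johnson-DeMeester normal-subject values for 24-h
monitoring. They are *external constants*: they are configurable through
`demeester_normals()`, are documented as imported reference values, and are
never asserted in the test suite — tests rely on the severity thresholds and
algebraic identities instead. Note that episode-count components scale with
recording length, so 48-h recordings may warrant doubled count normals;
this is left to the user because the package cannot know the intended
reference population.

Severity strata use the quoted clinical boundaries with strict upper
comparisons: normal at or below 14.7, mild on (14.7, 20], moderate on
(20, 50], severe strictly above 50. The boundary reading of "14.7-20" as
(14.7, 20] follows directly from abnormality being the strict ">14.7".

## The SAP computation

The recording is divided into consecutive 2-min periods
(`partition_windows()`, half-open, last window possibly short). A window is
**reflux-positive** (`label_reflux_windows()`) if either

* **criterion A**: it contains at least 5 s of pH < 4 contributed by a
  single sub-4 run, or
* **criterion B**: it contains two samples at most 5 s apart whose pH falls
  by more than 1 unit.

Two consequences of the interval convention deserve emphasis. A single sub-4
sample at 6-s sampling covers 6 s and therefore satisfies criterion A; at
coarse sampling the 5-s rule is effectively a one-sample rule. Conversely,
criterion B can never fire at exactly 6-s sampling with its default 5-s
span; the span is a parameter so that finer-sampled traces exercise it. We
deliberately did not widen the span to "one sample" because that would
silently change the stated rule. A run straddling a window boundary counts
toward every window in which its within-window portion reaches 5 s, because
the rule is stated per period.

A window is **symptom-positive** for a given symptom if at least one event
of that symptom falls in it (boundary events belong to the later window).
SAP is computed **per symptom**: each tracked symptom gets its own label
vector, 2x2 table and Fisher exact p-value, with SAP = (1 - p) x 100 and
positivity at SAP >= 95% (p <= 0.05). Only per-symptom tables can produce
the "one/two/three SAP-positive symptoms" patient strata, so the per-symptom
version drives all counting; an "any-symptom" combined SAP is also exposed
for users who want the pooled variant. The patient is SAP-positive if at
least one assessable symptom is SAP-positive. A symptom with zero reported
events is *not assessable*: its forced p = 1 is clinically meaningless, so
it is reported as missing rather than SAP-negative. Sidedness of the exact
test is two-sided by default and configurable to one-sided, documenting a
genuine ambiguity in the clinical literature. Windows are the fixed
consecutive grid containing each event, not the event-preceding window of
the oldest SAP formulation; the latter is out of scope.

SI is the percent of events whose preceding 120 s (configurable lag)
intersects a reflux-positive window, positive at >= 50%. SSI is the percent
of episodes with at least one event between onset and 120 s past the
episode end, positive at >= 10%. Both are missing, never zero, when their
denominator is empty.

## Statistics

`fisher_exact_2x2()` uses the point-probability two-sided convention (sum
of hypergeometric point probabilities no larger than the observed, relative
tie tolerance 1e-7) — the dominant convention, matching base R — rather than
mid-p or tail-doubling variants. `exact_rxc_test()` estimates the
Freeman-Halton style p for r x c tables by margin-preserving Monte Carlo
resampling with a +1/+1 estimator and reported Monte Carlo standard error.
The rank tests use average ranks for ties, no continuity correction, and an
exact enumeration path when the combined sample size is at most 10; these
choices favour determinism and oracle-checkability over agreement with any
particular software default. Significance is alpha = 0.05 throughout with
no multiplicity adjustment, mirroring common subgroup-analysis practice in
the surgical literature; a Holm-adjusted column is available in the
subgroup sweep for users who want it.

## The synthetic world

No patient data ships with the package; generators replace it.

**Traces.** Baseline pH is Gaussian around 6.2 (sd 0.25, so the baseline
essentially never crosses 4 on its own). Episodes arrive as a
posture-dependent Poisson process (defaults 3/h upright, 1/h supine — acid
exposure in surgical candidates is predominantly upright), with lognormal
durations (median 90 s), nadir uniform on [1.0, 3.5], and a 30-s linear
recovery that starts just above pH 4, so the sub-4 extent of each episode
equals its planted `[onset, offset)` exactly after grid snapping. Draws that
would come within twice the recovery time of the previous episode are
thinned, keeping episodes well separated so planted truth is recoverable.
The supine block is 23:00-07:00 with the recording starting at 08:00. These
defaults are a *stated world*: they were chosen once as clinically
plausible and are not tuned to test outcomes.

**Symptom coupling.** Coupling is defined at window level, matching the SAP
estimand: with probability `coupling` an event is placed uniformly inside a
randomly chosen reflux-positive window, otherwise uniformly over the whole
recording. One configuration text could be read as placing uncoupled events
only in reflux-*negative* windows, but that is anti-coupling, not
independence, and would not exercise the conservativeness of the exact test
under the null; `coupling = 0` here means genuine independence.

**Cohorts.** Demographics are drawn by quantile matching (normal for age
and HRQL, lognormal for BMI; the preoperative HRQL has a floor of 1 because
these are symptomatic surgical candidates). DeMeester scores are drawn by
first sampling the severity stratum at the configured mild/moderate/severe
mix and then a truncated lognormal within the stratum, which honours both
the strata percentages and the median/IQR target; every score exceeds 14.7,
the cohort's inclusion criterion. SAP positivity is Bernoulli(0.72) with
the 1/2/3-positive-symptom split at 221:164:45; tracked symptoms are
sampled with prevalence weights resembling clinical frequency. The outcome
is a single Bernoulli logit: base favorable rate 0.82 plus
`sap_effect_log_odds` (default 0 — the null world) for SAP-positive
patients. Satisfaction and PPI freedom are generated so their conjunction
equals the favorable flag while hitting marginal rates of 87.4% and 91.7%;
infeasible rate combinations are rejected by name. Missingness is applied
last and independently per outcome field (satisfaction ~32%, PPI status
~1.3%, postoperative HRQL ~48%), reproducing the differing complete-case
denominators a registry produces. Exact distributional fidelity beyond
medians, IQRs and the stated percentages is a non-goal.

What a green test establishes, therefore, is that the pipeline behaves
correctly *in this world*: exact-test conservativeness and power at the
stated coupling levels, planted-truth recovery, and null calibration of the
cohort comparison. Real recordings differ in ways the generator does not
model — pH drift, sensor dropout, meal artefacts, symptom-report
unreliability — so green tests do not certify clinical performance.

## Cohort analyses

`outcome_flags()` defines favorable outcome as satisfaction AND freedom
from PPI (missing if either is missing) and the HRQL response as at least
50% improvement from baseline, boundary inclusive; a baseline of 0 makes
the ratio undefined and is flagged, not silently dropped.
`compare_groups()` builds the SAP-positive vs SAP-negative tables —
median (IQR) with Mann-Whitney for continuous variables, n (%) with Fisher
for binary ones — on per-variable complete cases with explicit
denominators. `sap_count_analysis()` tests favorable outcome across the
0/1/2/3 SAP-positive-symptom groups with the Monte Carlo exact r x c test
(the source analyses do not name their 4-group test; Kruskal-Wallis on the
binary outcome is a cruder alternative the user can run directly).
`symptom_type_analysis()` compares outcomes by SAP status within each
individual symptom and each category, restricted to patients tracking it.
`subgroup_sweep()` ships the nine standard subgroups (age < 40, age >= 70,
female, male, BMI >= 30, mild reflux, severe reflux, Nissen, partial);
`hrql_split_subgroups()` adds the preoperative-HRQL median split for users
who want the larger set sometimes described as 14 subgroups. Percentages
are reported to one decimal with half-up rounding.

One documented inconsistency in published tables of this design: a
baseline-comparison row can label ~93% of patients "mild objective reflux"
while the cohort summary puts the mild stratum ((14.7, 20]) at ~7%. The
package implements the stratum definition; the discrepant row cannot be the
mild stratum and is not reproduced.

## Numerical and degenerate-input choices

* Exact-test tie comparisons use a 1e-7 relative tolerance.
* Tables with an empty margin give p = 1 (no information), not an error.
* Zero-duration posture strata yield 0% with a warning.
* All generators are pure functions of their config, including the seed;
  the caller's RNG state is never disturbed.
* Windowing arithmetic uses half-open intervals everywhere; an event on a
  boundary belongs to the later window, deterministically.

## Known limitations

Impedance-pH metrics (non-acid reflux), the event-preceding-window SAP
variant, the Ghillebert probability estimate, binomial SAP approximations
and multivariable outcome modelling are out of scope. The DeMeester
composite formula in circulation differs slightly between vendors; the
clamped z + 1 form used here keeps the published thresholds exact but is
one of several reasonable reconstructions, which is why the normals object
is fully configurable.
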