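---
title: "Decision Process Matrices: model, segmentation and synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision Process Matrices: model, segmentation and synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpmtrace)
```

## The representation

A Decision Process Matrix (DPM) records one diagnostic episode as a
totally ordered sequence of *units*. Four unit kinds exist: a **CUE**
introduces a condensed, meaningful unit of clinical information (from
history-taking, physical examination, imaging/laboratory tests,
literature, or other sources); an **OPTION** introduces a suspected
diagnosis; a **CONFIDENCE** unit rates one option — optionally in
response to one cue — on the anchored 9-point scale from −4
(*practically impossible*) to +4 (*practically certain*); the single
closing **FINAL** unit names the final diagnosis or several differential
diagnoses. Order indices are consecutive from 1; simultaneity is not
representable, mirroring how an observation protocol serializes events.

Two semantics are worth spelling out because they are easy to get wrong:

* **One cell per rating unit.** A confidence rating justified by *k*
  cues during option generation is stored as *k* consecutive CONFIDENCE
  units with equal level, one per (option, cue) cell. This is what makes
  the unit numbering of the worked example come out right (3 cues + 2
  options + 6 cells = 11 generation-phase units) and keeps the matrix
  rendering a pure cell lookup.
* **Exclusion is a flag, not a level.** Options are ruled out at ratings
  anywhere between −4 and +2 in observed data, so exclusion is an
  explicit boolean on the terminal CONFIDENCE unit rather than a
  threshold on the level. An option named by FINAL and also
  exclusion-flagged is a contradiction and fails validation.

Unrated options ("place markers" that never received a rating) are legal
and classified UNDETERMINED; the validator reports them as warnings, not
violations, since a finished trace may genuinely contain them.

## Phase segmentation

The three-phase pattern — option generation, option verification, final
determination — is described in the literature by example rather than by
algorithm, so the package fixes a deterministic boundary rule:

> phase 3 is the FINAL unit; phase 2 begins at the first CUE whose order
> index exceeds that of the first OPTION; phase 1 is everything before.

This rule exactly recovers the worked example's boundaries (first option
at unit 04, first subsequent cue at unit 12, hence phases 1–11 / 12–45 /
46). Options introduced during verification are phase-2 members; they do
not reopen phase 1. Two degenerate shapes make a trace non-conforming:
no option before the final determination, and no cue after the first
option (an empty verification phase, as in the minimal cue–option–
rating–final case). Non-conforming traces are flagged with a note
(`no-option-before-final`, `empty-phase-2`) and never rejected — real
cohorts contain such cases, and all statistics that need a conforming
partition restrict themselves to the phases that exist.

## Statistics

Cohort description uses arithmetic means, sample standard deviations
(n−1 denominator, matching common statistical software defaults) and
min–max ranges. Proportions are computed over their applicable subsets:
the share of final diagnoses rated +4 is over final diagnoses, the share
of exclusions rated −4 over excluded options. One conventional metric
is ambiguous: a mean number of options "added during verification" can
be taken over all cases or only over cases with at least one addition
(the two differ by the 55% of cases with none). `cohort_summary()`
therefore reports both (`added_options_mean_all`,
`added_options_mean_conditional`) rather than choosing.

Effect sizes use Cohen's d with the pooled standard deviation and no
small-sample (Hedges) correction; its 95% interval uses the large-sample
standard error `√((n₁+n₂)/(n₁n₂) + d²/(2(n₁+n₂−2)))` and a normal
quantile. Correlation significance uses the exact-null t transformation
`t = r√((n−2)/(1−r²))` on n−2 degrees of freedom, two-sided; Spearman's
rs is the Pearson coefficient of mid-ranks with the same transform,
which is an approximation to the permutation null. The test suite
compares both against exhaustive permutation enumerations at n ≤ 8 and
observes agreement within 0.022 in p; we assert a 0.05 band, the error
one should expect of the t approximation at such sample sizes.
Coefficients within 1e−12 of ±1 are treated as degenerate (p = 0, with a
warning) to keep floating-point rank correlations of perfectly monotone
data from producing spurious tiny p-values.

## The synthetic cohort generator

No public dataset of recorded DPMs exists, so the generator is the
package's instrument for testing every other module at cohort scale. Its
defaults are a fixed calibration point chosen to emulate an
emergency-department resident cohort: 3.2 options (SD 1.8, range 1–9)
and 7.9 cues (2.9, 3–17) per case, 2.3 options from 1.9 cues in phase 1,
87% of final diagnoses already mentioned in phase 1, additions during
verification in 45% of cases, initial ratings centred at 1.76 (0.81,
−2…+3), final-diagnosis terminal ratings at 3.56 (0.71, +1…+4) with 67%
at +4, excluded-option terminal ratings at −2.50 (2.08, −4…+2) with 54%
at −4, 20% time-pressure and 15% stress prevalence, physician experience
of 23–69 months (mean 41) correlating −0.35 with verification-phase cue
count, and case similarity (1–6, present in 46/55 of cases) correlating
+0.31 (Spearman) with final confidence. These defaults are the study
conditions of the package's calibration checks, not tuning knobs.

Design choices, in the order they bite:

* **Count marginals** are discretized truncated normals: integer k in
  [min, max] gets mass Φ(k+½; μ, σ) − Φ(k−½; μ, σ), renormalized. Any
  two-parameter bounded family would fit summary statistics of this
  shape; this one keeps calibration transparent. Truncation shifts the
  mean, so μ is re-solved by `uniroot` until the pmf expectation equals
  the target (machine-precision calibration; σ stays nominal and the
  realized SD is slightly below nominal when the bounds cut deep).
* **Coupled indicators.** "Final diagnosis in phase 1" (F) and "any
  phase-2 addition" (A) are logically entangled with the option count
  n: n = 1 forces F and forbids A; n above the phase-1 cap (6) forces
  A; F = false presupposes A. Drawing both independently would miss
  both targets, so the constructor derives conditional laws from the
  option-count pmf — P(F | n ≥ 2) and P(A | F, 2 ≤ n ≤ 6) — such that
  the unconditional probabilities come out at exactly 0.87 and 0.45.
  Infeasible combinations are config errors, not silent drift.
* **Endpoints before trajectories.** Terminal confidence levels are the
  calibration surface, so they are drawn first from their endpoint
  distributions (point mass at the extreme imposed first, the
  truncated-normal remainder re-calibrated so the overall mean still
  hits its target). The initial rating is then drawn *conditioned* on
  the required monotone direction (initial ≤ terminal for the final
  option, ≥ for excluded ones). This preserves the graded endpoint
  marginals exactly and lets the initial-rating marginal absorb the
  conditioning distortion — which turns out to be small (pooled initial
  mean ≈ 1.75 against the 1.76 target at n = 5000).
* **Trajectories** interpolate linearly in scale steps across an
  option's rating slots and round to integers, yielding monotone
  non-decreasing paths for finals and non-increasing paths for
  exclusions. Verification-phase rating slots are assigned one per cue,
  rotating over the options mentioned so far; each non-final option
  receives its exclusion-flagged terminal rating in a closing block
  before the final determination, so every option has a defined
  terminal level.
* **Covariate correlations by rank matching.** Experience values are
  drawn from their own marginal and then *reordered* against the
  verification-cue counts (normal-score rank matching in the
  Iman–Conover spirit, followed by greedy pair swaps until the target
  correlation is within 0.005 or the swap budget is exhausted);
  similarity is matched to final confidence on the rank scale the same
  way. Permutation leaves marginals untouched; at cohort sizes below a
  few hundred the achievable precision is limited by discreteness, which
  is why the correlation checks run at n ≥ 1000.
* **Reproducibility.** Each case is generated from an RNG substream
  derived from the config seed by counter, so case i is identical
  whether the cohort has 5 or 5000 cases; the covariate-matching pass
  has its own substream. Two runs with the same config are
  byte-identical after serialization.

What the generator does *not* emulate: diagnosis semantics (options are
synthetic tokens, so diagnosis-text concordance cannot be studied),
resident-level clustering (experience is drawn per case, not per
physician), non-conforming traces (every generated case is three-phase
conforming by construction, whereas real cohorts contain exceptions),
and any dependence of cue sources on the diagnosis. Passing calibration
tests therefore show that the analysis pipeline recovers known
parameters from well-formed cohorts — not that it is robust to the
messiness of observational traces.

## Numerical and interface choices

* Confidence levels serialize as signed integers; verbal anchors are
  presentation-only.
* The JSON dialect (`dpm-1`) rejects unknown fields instead of ignoring
  them, so fixtures stay canonical and version drift is caught at parse
  time; the writer is deterministic (fixed field order, units sorted by
  order index), which is what makes `json → csv → json` byte-identical.
* The CSV dialect stores one unit per row with cue/option definitions
  inline on their introducing rows; metadata travels as `#key=value`
  lines. Non-consecutive numbering is a parse error carrying the row
  number.
* Matrix rendering attaches a cue-less confidence unit to the most
  recent preceding cue — the layout choice that reproduces the
  worked-example grid (18 cue rows × 3 option columns).
* Problem sizes in the test suite: calibration checks run on a 5000-case
  cohort (3-standard-error bands around each configured value);
  round-trip and conformance properties on 1000 cases; exhaustive
  permutation oracles at n ≤ 8, the scale at which full enumeration is
  exact and cheap. These sizes bound Monte-Carlo error well below the
  tolerances they guard.

## Known limitations

The observation protocol that produces real DPMs (what counts as one
meaningful cue, how confidence is elicited without disturbing the
patient encounter) is outside the package's scope — DPMs arrive as
data. Verbal probability anchors are not equidistant, so treating the
scale as interval-valued in means and effect sizes is a modelling
convenience inherited from the field's practice. The Spearman p-value is
approximate under heavy ties. And the generator's calibration point is a
single cohort; users studying other settings should re-parameterise
`generator_config()` rather than reuse the defaults.
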