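---
title: "Measuring delay discounting by EMA: models, scoring and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring delay discounting by EMA: models, scoring and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emadd)
```

## The measurement problem

Delay discounting is usually summarized by the rate $k$ of the hyperbolic
decay model

$$V = \frac{A}{1 + kD},$$

where $A$ is a delayed reward, $D$ its delay, and $V$ the immediate amount
judged subjectively equivalent (the indifference point). Binary-choice
batteries such as the Monetary Choice Questionnaire (MCQ) bracket $k$
between the indifference rates of the items a respondent switches between;
they need many items, and respondents steeper than the steepest item all
receive the same ceiling score. A continuous item instead lets the
respondent *report* the indifference point directly on a slider, so each
single response identifies $k$ in closed form:

* a **time-selection** item fixes $V$ and $A$ and records the longest
  acceptable wait $D$, giving $k = (A/V - 1)/D$;
* a **monetary-selection** item fixes $A$ and $D$ and records the immediate
  amount $V$, giving the same expression;
* an **MCQ** item fixes all three quantities; its indifference rate is
  $k_{\text{indiff}} = (A - V)/(VD)$ and the binary choice indicates on
  which side of it the personal rate lies.

Per-person scale scores are geometric means of per-item rates, and all
statistics operate on $\ln k$. The natural log is used throughout (the
base is a pure convention; it cancels in correlations and rescales
regression coefficients).

## Item banks and unit conventions

The default banks mirror the deployed instrument: seven time-selection
items with immediate amounts $V \in \{50, 70, 10, 80, 40, 30, 99\}$ against
$A = \$100$, answered on a 0–52-week slider, and seven monetary-selection
items with delays of 1 year, 1 month, 6 months, 3 months, 2 weeks, 1 week
and tomorrow, answered on a \$1–\$99 slider.

The canonical time unit is the **day**. Verbal delays map as 1 year = 364
days (exactly 52 weeks, so the "1 year" item and the 52-week slider ceiling
agree), 6 months = 182, 3 months = 91, 1 month = 30, and tomorrow = 1. The
deployed time slider's floor is taken to be one day: a reported wait of
zero days carries no finite rate, so such responses are clamped to 1 day at
scoring time and flagged `clamped` rather than discarded (the instrument's
minimum positive resolution). Instrument descriptions that quote a
"52-day" maximum are read as 52 *weeks* — 52 days would contradict the
1-year item — but both slider bounds are ordinary arguments of
`time_selection_bank()`, so either reading can be configured.

The binary MCQ bank defaults to 7 items (descriptions of the instrument
vary between 7 and 8 items; the bank length is a parameter, not a
commitment). The exact delays are chosen so the indifference rates are
distinct and spread roughly log-evenly across $3\times10^{-5}$–$0.15$ per
day, the range human cohorts occupy; since only ranges of the original
grid are documented, the default grid here is a faithful parameterization,
not a transcription.

## MCQ consistency scoring

The scoring of a binary response pattern is the classical Kirby-style
consistency maximizer. Candidate rates are the geometric means of adjacent
sorted indifference rates, plus one candidate below the smallest (geometric
mean with half of it) and one above the largest (geometric mean with twice
it). Each candidate predicts "immediate" for items whose indifference rate
it exceeds; the candidate predicting the most observed choices wins, and
ties are broken by the geometric mean of all maximizing candidates. A test
sweeps all $2^7$ response patterns against a brute-force dense-grid search
to confirm the candidate set never misses the global consistency maximum.

## Quality control

Screening reproduces the two-stage exclusion pipeline of EMA discounting
studies, in this order:

1. **Straightliners** — every continuous response in a phase at the slider
   minimum (`straightline_min`) or every response at the maximum
   (`straightline_max`). "Consistently" means *all* items: 6 of 7 at the
   bound is retained.
2. **3-SD outliers** — per-person scores standardized within each
   (phase, scale) group in a single pass; $|z| > 3$ is flagged. No
   iterative re-standardization.
3. **Analytic sample** — participants retained in *both* phases on all
   screened scales.

Standardization applies to $\ln k$ by default. On the raw scale $k$ is
strongly right-skewed, so a 3-SD rule would be driven by the long right
tail; the log scores are near-normal and make "3 SDs" meaningful. An
`on = "raw"` switch exists for sensitivity analysis, and because "the SD of
the responses" admits a per-item reading too, `level = "item"` standardizes
each item's rates separately and flags a participant whose response to any
single item exceeds the threshold. Straightliner removal
precedes the SD pass so that degenerate extreme scores cannot inflate the
SD against which genuine outliers are judged.

A structural fact worth knowing: on bounded sliders the attainable score
range is itself bounded (a time-scale log score cannot exceed the value
implied by answering every item at 1 day), and for the default cohort the
upper bound sits only about 2 SD above the mean. Extremely steep
discounters therefore surface as straightliners rather than as 3-SD
outliers — the two exclusion categories genuinely overlap at the slider
edges, and the flag reported is the one whose rule fires first
(straightlining).

## Psychometric analyses

**Item-total correlations** are Pearson correlations between each item's
log rate and the full-scale log score, which *includes* the item (the
full scale is the quantity the abbreviated scale must reproduce); a
corrected item-excluded variant is available via `include_item = FALSE`.
Items with $r$ below the informativeness cutoff are flagged. The cutoff
defaults to 0.5: in practice informative continuous items correlate with
the scale at $r \gtrsim 0.85$ while the degenerate clamp-prone item falls
below $\approx 0.4$ (or has no variance at all), so any cutoff in a wide
band makes the same decision; 0.5 sits in the middle of that band and is
configurable.

**Test-retest reliability** and **convergent validity** are plain Pearson
correlations of log scores across phases and instruments, with listwise
deletion and pairwise $n$ reported. The package also exposes the
classical-test-theory prediction
$r = \rho\,\sigma^2/(\sigma^2 + \tau^2)$ (`predicted_retest_r()`), used as
a quantitative oracle against the simulator, whose generative $\rho$,
$\sigma$ and item noise $\tau_{\text{item}}$ are known (a scale averaging
$m$ items has score noise $\tau_{\text{item}}/\sqrt{m}$).

**Abbreviation** draws, for each subset size $N$, random $N$-item subsets
without replacement (independent across the 100 default iterations, all
governed by one seed) from the *informative* items, and correlates the
subset log score with the full-scale log score. The full-scale denominator
defaults to every item of the scale — i.e. subsets of the 6 informative
time items are compared against the original 7-item score — because that is
the score the full instrument would have produced; `full_items` lets the
analyst use the 6-item denominator instead, and the report records which
was used. Requesting $N$ equal to the full length is allowed purely as a
self-check (it must return $r = 1$).

## Endorsement regressions

Per-survey binary endorsements (past-hour use and craving of alcohol,
cannabis, tobacco) collapse to per-person percentages of *completed*
surveys. Each (predictor scale, outcome) pair is fit by OLS:

```
pct ~ log_k + age + sex + surveys_completed
```

with continuous predictors mean-centered (centering changes only the
intercept — a property asserted numerically in the tests), sex as a single
indicator (first factor level is the reference, stated in the printout),
and age continuous by default or as a factor if supplied pre-binned.
Percentages are modeled on the 0–100 scale, so coefficients read as
adjusted mean differences in percentage points per unit $\ln k$. No
multiplicity correction is applied by default, matching single-study
reporting conventions; Benjamini–Hochberg is available via `p_adjust`.
Rank-deficient designs abort naming the collinear columns.

## The synthetic cohort generator

Because the kind of data this pipeline consumes is rarely shareable, the
simulator is a first-class module: every analysis is validated against
cohorts with known ground truth.

Each agent carries latent phase-1/phase-2 log rates from a bivariate
normal. Defaults, chosen once to represent a realistic steeply-discounting
convenience cohort and to exercise the slider geometry:

* $\mu = \ln(0.08)$ per day, $\sigma = 1.0$. This places the central
  time items' ideal responses well inside the 1–364-day slider while the
  \$99 item's ideal wait $(100/99 - 1)/k$ falls below one day for ~98% of
  agents — mechanically reproducing the designed-in degeneracy of a
  near-zero immediate–delayed difference. A median of 0.08/day is steep
  but within the range reported for community and substance-using samples.
* Between-phase latent correlation $\rho = 0.8$: discounting is a
  moderately stable trait over months.
* Item-level log-normal noise, independent across items and occasions,
  with $\tau_{\text{time}} = 0.5$ and $\tau_{\text{monetary}} = 0.9$; the
  monetary instrument is deliberately noisier, reflecting its weaker field
  performance. No within-survey correlation of item noise is modeled —
  the simplest structure consistent with the analyses.
* MCQ choices follow a logistic rule on
  $(\ln k - \ln k_{\text{indiff}})/0.5$.
* Ideal responses are clamped to the slider and rounded to its resolution
  (1 day / \$1). `resolution = 0` disables rounding — a check mode in which
  noiseless unclamped scoring must recover the latent rate *exactly*.
* Study shape: $n = 97$, one phase-1 baseline, one phase-2 baseline, 18
  follow-ups with per-survey completion probability $15/18$ (~16 of 19
  surveys completed on average). Endorsements are Bernoulli per completed
  survey with logit base rates of 4–8% and log-odds slopes per unit latent
  $\ln k$ of 0.7/0.6 (tobacco use/craving), 0.25/0.3 (alcohol), 0
  (cannabis) — a positive tobacco link, a weak alcohol link, and a true
  null for falsification.

**Contamination presets.** `"contaminated"` plants 2 minimum- and 1
maximum-straightliners plus 5 outlier agents; `"null"` zeroes all
endorsement slopes. Outlier agents sit at $\mu - 7\sigma$ (extreme-patient)
and respond *model-consistently, without item noise*: planted contaminants
are fixture objects whose positions should be deterministic. The patient
side is used because of the slider-saturation fact above — only there do
extreme agents remain interior to the sliders (their \$-responses reach
97–99 but not all items hit the bound) while still standing out at
$|z| > 3$ after the planted mass itself inflates the group SD. This keeps
the planted exclusions exactly recoverable: 3 straightliners + 5 SD
outliers = 8 exclusions, with the flag types matching the planted
behaviors.

**What the simulator does not emulate** — and hence what passing tests do
not establish about real data: humans are not exact hyperbolic evaluators
(framing, magnitude and date-vs-delay effects are absent); item noise is
symmetric and log-normal with no serial or within-survey structure;
time-of-day and withdrawal dynamics of discounting are not modeled;
endorsement processes have no temporal autocorrelation; and demographics
are independent of the trait. The validation battery shows the *pipeline*
is correct and well-calibrated under its stated assumptions, not that the
instrument is valid in any particular population.

## Numerical choices and degenerate inputs

* Inversion is closed-form; a property test requires forward-then-invert
  round trips to relative error $< 10^{-10}$ over random unclamped pairs.
* Zero-variance groups: SD screening emits a warning and flags nobody;
  a constant item yields an "r undefined" record rather than `NA`
  silently propagating.
* Geometric means reject empty and non-positive inputs; the log of the
  geometric mean is computed as the mean of logs (the two routes are
  asserted to agree in tests).
* MCQ ties (several candidates attaining the maximum consistency) resolve
  to the geometric mean of the maximizing candidates.
* Re-screening an already screened sample can re-flag the tails of a
  clean normal distribution at 3 SD (a property of any fixed-quantile
  rule, not a bug); it never re-creates contamination-level ($z \ge 5$)
  flags, which the tests assert.

## Problem sizes used in validation

The shipped validation battery runs cohorts of $n = 97$ (the default study
size) for distributional and emergent-structure checks, $n = 500$ for
exact recovery and attenuation checks (20 seeded replicates), and 100
seeded replicates of $n = 120$ for regression CI coverage and type-I
calibration — sizes at which Monte-Carlo error is well below the tested
margins while the whole suite stays comfortably fast on a laptop.

## Known limitations

* The hyperbolic form is assumed, not tested; exponential or
  quasi-hyperbolic alternatives and area-under-curve scoring are out of
  scope.
* Momentary (within-person) association models are not provided; the
  regression stage is cross-sectional at the person level and makes no
  causal or temporal claims.
* The MCQ scorer targets short single-magnitude banks; 27-item
  magnitude-tier subscores are out of scope.
* Clamp-induced degeneracy is detected (flags, undefined-r reports) but
  not corrected; censored-likelihood scoring of clamped responses would be
  a natural extension.
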