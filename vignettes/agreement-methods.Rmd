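---
title: "Measuring between-population agreement on moral-argument applicability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring between-population agreement on moral-argument applicability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moralconcord)
```

## The measurement model

The pipeline targets argument-attribution surveys. A participant is
shown a dichotomous moral question, answers yes or no, and is then
shown one argument per moral concern (drawn at random from that
concern's wordings) and asked to tick every argument that applies to
their own position, and then every argument that applies to the
opposite position. The built-in taxonomy contains eight concerns
(harm, fairness, ingroup, authority, purity, liberty, violence,
government) with three wordings each; a catch-all "some other reason"
option is recorded but never scored, because the quantity of interest
is defined over the eight concerns.

For concern $mc$ and issue position $isspos$, the applicability score

$$A_{mc,isspos} = \frac{\#\{\text{respondents ticking an argument of } mc
\text{ for } isspos\}}{\#\{\text{respondents judging } isspos\}}$$

is a proportion of *individuals*, so both perspectives pool: every
respondent to an item contributes exactly one judgment to each of the
item's $2 \times 8$ cells, whether they judged a position as their own
side or the other side. Scores are kept as exact count ratios until
export; the pooling identity (the pooled score is the judgment-weighted
average of subgroup scores, exactly) is enforced by tests. Ticks are
recorded at the concern level; the specific wording shown is stored for
provenance only, since scores are defined per concern, not per wording.

## Agreement: the concordance correlation coefficient

Two populations' score vectors are compared with Lin's concordance
correlation coefficient,

$$\mathrm{CCC} = \frac{2 s_{12}}{s_1^2 + s_2^2 + (m_1 - m_2)^2},$$

with biased ($1/n$) moment estimators. The factor 2 follows Lin's
definition; with $\geq 432$ paired cells in any realistic design the
$1/n$ versus $1/(n-1)$ choice is numerically immaterial, but it is
fixed and documented so results are exactly reproducible. Conventions
for degenerate inputs: two equal constant vectors give 1, two unequal
constant vectors give 0 (zero covariance over a positive denominator).
The implementation is checked against an independent
covariance/variance-based oracle to $10^{-12}$ on fuzzed inputs, along
with the structural properties $|\mathrm{CCC}| \le |r| \le 1$, symmetry,
permutation invariance, and strict decrease under location shifts.

The 95% interval for the CCC maps the estimate through $\tanh^{-1}$,
applies Lin's asymptotic standard error (which involves the Pearson
correlation and the standardized location shift
$u = (m_1-m_2)/\sqrt{s_1 s_2}$), and back-transforms; this keeps the
interval inside $[-1, 1]$. Its coverage is verified by simulation on
bivariate-normal data with a known population CCC. A participant-level
bootstrap interval (`ccc_ci_boot()`) is also provided: it resamples
participants, not cells, and so respects the fact that one respondent
contributes to many cells. Neither method is claimed to reproduce any
particular published interval.

## The random-split null

The substantive null hypothesis is *perfect population-level
agreement*: with infinite samples the two populations' score vectors
would coincide (CCC = 1). Finite samples guarantee an observed CCC
below 1, so 1 is the wrong reference value. Under the null the two
samples are exchangeable draws from one population, which licenses the
resampling test implemented in `random_split_null()`:

1. pool the participants of both samples;
2. repeatedly (B = 1000 by default) split the pool uniformly at random
   into two subsamples of the original sizes — at participant level,
   so all of a person's judgments move together;
3. recompute both score tables, pair them, and record the CCC.

The mean of the B split CCCs is the *expected CCC under perfect
agreement*, and the p-value is the proportion of split CCCs strictly
below the observed CCC (ties count as not lower; a conservative
$(r+1)/(B+1)$ variant is available by flag and off by default). Under
exchangeability the observed CCC's rank among the splits is uniform,
so the test holds its size; this calibration, and the growth of power
with the between-group discrepancy, are verified empirically in the
test suite (200 replicate studies for size, 50 per discrepancy level
for power, with B = 200).

For supporter-vs-opponent comparisons the partition differs per item
(someone agreeing with you on one issue may disagree on another), so a
single global split is not exchangeable with the observed one.
`stratified_split_null()` re-splits respondents independently within
each item, preserving the item's two side sizes. Orientation matters
there: "vector 1" for an opinion is always the side that *holds* it,
so for negative-position cells the roles of the two split sides swap —
exactly mirroring how the observed supporter/opponent vectors are
built from own-side and other-side judgments. A "population"
orientation (side 1 is always vector 1) is the default for
cross-population uses. When the strata coincide with a global split,
the stratified null's distribution matches the global one in
expectation (tested).

Replicate score tables are computed on a participants-by-cells tick
matrix with column sums, which makes B = 1000 splits on a realistic
study take well under a second; the result is contractually identical
to recomputing the tables naively, and a test asserts exactly that.

## The synthetic survey generator

`simulate_study()` emulates the study design so that every downstream
stage can be validated against known ground truth:

* **Latent truth.** One probability $\theta$ per (opinion, concern)
  cell, drawn from `theta_prior`. The default Beta(0.8, 1.6) is
  right-skewed — most arguments apply weakly to most opinions, some
  apply strongly — which matches the qualitative shape of observed
  applicability distributions. `concern_offsets` shift whole concerns
  on the log-odds scale (e.g. to make fairness and liberty the most
  generally applicable concerns).
* **Group discrepancy** $\tau$: each group's $\theta$ receives
  independent zero-mean normal noise with standard deviation $\tau$ on
  the log-odds scale. The log-odds scale keeps $\theta$ in (0, 1) and
  is symmetric around the base value; $\tau = 0$ is the null of
  perfect agreement. Scores at exactly 0 or 1 are clamped to
  $[10^{-6}, 1-10^{-6}]$ before the transform.
* **Distinctiveness** (`compress`): a group's $\theta$ can be pulled
  toward the grand mean by a factor $\lambda \in (0, 1]$, emulating a
  population that differentiates less sharply between opinions; it
  produces a regression slope below 1 and per-concern variance ratios
  near $\lambda^2$.
* **Perspective discrepancy** $\kappa$: extra per-judgment log-odds
  noise when a respondent judges the side opposite their own.
  $\kappa = 0$ means opponents recognize supporters' justifications
  exactly; $\kappa > 0$ lowers the supporter/opponent CCC below
  demographic-split CCCs from the same data.
* **Design arithmetic.** Each participant judges a fixed number of
  items drawn uniformly without replacement; own answers are Bernoulli
  with a per-item prevalence drawn from `opinion_prevalence`
  (default Beta(2, 2): both answers usually have holders, with
  moderate spread — per-item answer prevalences are not part of the
  published design, so a centered, weakly informative choice is used).
  Presets reproduce the three reference designs: `us_like` (98 items,
  568 participants, 19 items each — about 110 raters per item),
  `uk_like` (108 items, 903 participants, 12 each — about 100) and
  `shared_27` (27 items, 223 participants, 12 each — about 99).
  Items-per-participant is a constant per design; only the average is
  known from the published studies, and a fixed count keeps the
  rating-per-item accounting exact.
* **Demographics** default to a Study-1-like composition (59% women,
  age $\approx \mathcal{N}(39, 12)$ clipped to 18–80, uniform 0–10
  left-right score with a derived binary ideology, 53/47 education,
  Wordsum $\sim$ Binomial(10, 0.75) so the customary threshold of 8
  splits the sample roughly in half). Demographics are independent of
  ticks by construction.

What the generator does *not* emulate: item content and wording
effects on opinions, participant drop-out and varying item counts,
correlated tick behavior within a respondent beyond the shared
$\theta$, and any systematic demographic effect on applicability.
Passing tests therefore demonstrate that the estimator and test behave
correctly *under the design's sampling process*, not that any
particular real population satisfies the null.

## Splits and the opinion-based analysis

`split_spec()` fixes the partition rules: women/men; younger/older by
sample median with median-valued participants assigned to the younger
side (a deterministic rule; no published threshold exists);
liberal/conservative from the binary attribute; left (0–3) vs right
(7–10) on the 11-point scale with moderates (4–6) excluded; higher vs
lower education; verbal ability at the Wordsum threshold (8 or higher
vs 7 or lower); and named country/population pairs. Participants
missing an attribute are excluded from that split only.

The opinion-based analysis compares, for each opinion, its holders'
own-side scores with the opposite holders' other-side scores. Opinions
where either side has fewer than `min_holders` holders are dropped and
reported — the threshold defaults to 5 and is a prominent, logged knob
because no principled exclusion rule is published; analyses should
report which opinions were dropped and why. The observed CCC is
computed from perspective-filtered score tables and, as a structural
cross-check, must equal the value produced by the stratified-null
machinery on the observed assignment (tested to $10^{-12}$).

## Numerical and scale choices

* Quartiles and boxplot fences use linear interpolation
  (`quantile()` type 7); whiskers reach the most extreme values within
  1.5 IQR of the box, values between 1.5 and 3 IQR outside the box are
  outliers, beyond 3 IQR extreme outliers.
* All randomness flows through explicit integer seeds
  (`withr::with_seed`), making studies, splits and reports
  byte-reproducible; report files are written with a deterministic
  column order.
* Test problem sizes are chosen to keep the full suite to a few
  minutes while leaving comfortable statistical margins: size
  calibration uses 200 replicate studies of 2 × 60 participants on 27
  items (11 items per participant, about 49 raters per item) with
  B = 200 splits; power uses 50 replicates per discrepancy level;
  oracle fuzzing uses 1,000 instances.

## Known limitations

The asymptotic CI relies on approximate normality of the transformed
CCC and degrades for very small cell counts; use the bootstrap
interval there. The expected CCC is defined only by simulation — no
analytic approximation is provided. The stratified null treats items
as independent strata; it does not model participant-level correlation
*across* items under opinion splits (the same limitation applies to
the published procedure it implements). Real survey phenomena such as
inattentive responding, order effects, and argument-wording effects
beyond a simple additive log-odds term are out of scope.
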