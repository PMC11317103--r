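---
title: "Methods: passive food-safety surveillance from consumer reviews"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: passive food-safety surveillance from consumer reviews}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foodsig)
```

## The surveillance problem

Regulatory inspection of food businesses is sparse and reactive, especially
where inspection records are not public. Consumer review platforms generate
a continuous, if noisy, stream of observations about the same
establishments. `foodsig` implements a passive-surveillance framework over
that stream: given restaurant reviews that an upstream aspect-based
sentiment tool has already labelled as hygiene-positive or
hygiene-negative, it screens out low-quality signal (copied reviews, chance
fluctuation), establishes whether a restaurant's hygiene complaints
outweigh its hygiene praise, quantifies how severe the complained-about
deficiencies are, and maps the result for a regulator.

The package treats sentiment labels as *input*: the upstream labeller is
prior work with its own validation, and `foodsig` neither trains nor
re-implements it. A rule-based fallback labeller exists for unlabelled
records but is deliberately crude and marked lower-fidelity in the run
output.

## Signal chain

For each restaurant with at least 1,000 lifetime reviews and more than two
years of listing history (both configurable; the defaults mirror the
eligibility rule the framework was developed under), over a 12-month
assessment window:

1. **Duplicate screen.** All within-restaurant pairs of hygiene reviews are
   compared on three authorship metrics: type-token ratio (lexical
   diversity of each review), Jaccard similarity of unique word sets, and
   the number of shared bigrams. A pair is flagged as same-author when
   Jaccard ≥ 0.6 or shared bigrams ≥ 3; flagged pairs are grouped into
   connected components and only the earliest review of each component is
   kept. If more than half of a restaurant's hygiene reviews are removed
   this way, the restaurant's data is judged unusable and it is excluded
   from assessment with a logged reason.
2. **Temporal screen.** Monthly negative-hygiene counts are tested against
   expectations proportional to monthly review totals with a Pearson
   chi-square goodness-of-fit statistic on `months − 1` degrees of
   freedom. `p < 0.05` reads as *genuine* temporal clustering, and months
   with standardized residual above 2 are annotated as spikes; otherwise
   the fluctuation is attributed to chance. The verdict annotates the
   assessment; it does not veto it.
3. **Causality Assessment Index.**
   `CAI = n_negative / n_positive` over the cleaned window. `CAI > 1`
   (strictly) raises the causality flag: complaints outnumber praise on
   hygiene and the signal is treated as a genuine concern. With no
   positives but some negatives the index is infinite (flag raised); with
   no hygiene reviews at all it is not assessable.
4. **Severity Assessment Score.** Negative reviews are classified by a
   keyword lexicon into eight sub-aspects derived from the Indian
   regulatory inspection checklist (cleanliness of the dining area,
   food handling, food packaging, pest control, external objects in food,
   upkeep of infrastructure, undercooked/rotten/smelly food, plus
   self-reported health outcomes, the one category added beyond the
   checklist because direct health outcomes signal emergency-level risk).
   `SAS = Σ counts × weights`, graded into five bands:
   ≤5 LOW, 6–10 SLIGHTLY_HIGHER, 11–15 HIGH, 16–20 HIGHER, >20 HIGHEST.
   Severity is only graded once causality is established.

Every input review ends the run in exactly one disposition —
`non-hygiene`, `hygiene-positive`, `hygiene-negative`,
`excluded-duplicate`, or `unlabeled-skipped` — which makes conservation
checkable and the whole run auditable.

## Design decisions worth recording

**Chi-square convention.** The temporal screen is a one-sample
goodness-of-fit of the category's monthly counts against expectations
proportional to monthly totals, with `months − 1` degrees of freedom. On
the bundled eight-month illustration series this reproduces the
framework's published worked statistic for the positive stream (≈ 5.02,
p ≈ 0.66) where a 2×k homogeneity layout would not; that is why this
convention is the default and the tested one.

**Calibration null.** The goodness-of-fit statistic re-estimates the
overall complaint proportion from the series itself, so its reference
distribution is the *conditional* one: the window total allocated across
months in proportion to review totals (a multinomial). The type-I
calibration test simulates exactly that null and observes rejection rates
near 0.05. Under unconditional month-wise binomial sampling the same
statistic is conservative by a factor of roughly `1 − p` (the omitted
failure cells of the homogeneity table), a property worth knowing when
interpreting "chance" verdicts on very high complaint proportions: the
screen under-rejects there rather than over-rejects.

**Severity gate.** Severity is graded when `CAI > 1`, strictly. The
boundary `CAI = 1` (complaints exactly balancing praise) does not
establish causality.

**Two weight presets.** The default weights (2, 3, 2, 1, 3, 3, 2, 4 in
canonical sub-aspect order; sum 20) follow the checklist-proportional
assignment. The published worked examples are internally consistent with
these weights for the casual-dining column only; the other columns imply
cleanliness and upkeep at 1 point. Both readings ship
(`subaspect_weights("default")` and `subaspect_weights("alternate")`),
both are tested against the columns they explain, and they are never
silently merged.

**Grade-band edges.** The verbal banding leaves gaps at 5–6 and 10–11;
the worked example grading a score of exactly 5 as low risk fixes the
reading as inclusive upper edges (≤5, ≤10, ≤15, ≤20). Edges are
configurable.

**Duplicate resolution.** The framework excludes duplicated data as noise
without stating a keep rule; `foodsig` keeps the earliest review of each
flagged component, on the view that the first report is the original
observation and later near-copies are amplification.

**Exclusion rule.** A restaurant is dropped from assessment only for a
data-quality failure — duplicate exclusion removing more than 50% of its
hygiene reviews — not for a chance temporal verdict. A chance verdict
means no spike annotation; the CAI is still computed from the window
totals.

**Tokenization.** Lowercase, strip non-alphanumerics, split on
whitespace. Published word counts for the illustration sentence pair are
not reproducible under any standard policy (the counting rule behind them
is unstated), so the printed unique/total ratios are verified as ratio
arithmetic, while the structural claim that the pair shares zero bigrams
is verified on the actual sentences under this tokenizer.

**Lexicon matching.** Sub-aspect classification is normalized
phrase-in-text matching with a stem-prefix rule per token ("rat" matches
"rats"). It is auditable and exactly recallable on generated data, at the
cost of occasional false hits from prefix collisions in free text; it
stands in for the manual two-reader classification the framework was
developed with and is not claimed to replicate human judgment beyond the
exemplar phrases.

**Geo privacy jitter.** Exported map points are displaced by a uniform
random bearing and a uniform random distance of 5–10 m (seeded). Metres
convert to degrees with WGS84 degree-length formulas; at a 10 m radius
the flat-earth approximation error is sub-centimetre, so displacement
distances verify against ellipsoidal geodesic distance.

## The synthetic suburb

Because the framework's original review corpus is not publishable, the
package ships a seeded generator (`suburb_scenario()`,
`generate_scenario()`) that emulates the data regime the framework was
developed under, with exact ground truth:

- 156 listed restaurants, 93 of which clear the 1,000-review bar, split
  63/2/4/13/11 across casual dining, fine dining, buffet, quick service,
  and food truck/dhaba;
- 12 monthly review batches per restaurant, Poisson volumes with
  category-specific means (25–50), or fixed totals for exact-replication
  tests;
- about 20% of reviews touch hygiene; at baseline half of those are
  negative, putting negative-hygiene reviews at ~10% of all reviews — the
  illustration series' baseline months;
- planted features with recorded truth: deficient restaurants (negative
  share 0.75, i.e. complaints outnumber praise 3:1, concentrated on two
  sub-aspects), spike months (the negative share of all reviews
  multiplied, capped, mimicking an incident month where complaints reach
  ~50% of the stream), and duplicate clusters (verbatim or
  token-mutated copies, dated after their original).

Negative review texts embed one short lexicon trigger in a random salad
drawn from a ~90-word filler vocabulary that is checked to be disjoint
from every trigger and cue. Two consequences, both deliberate: the
lexicon classifier's recall on generated data is exactly 1 (planted
counts equal recovered tallies, which the tests assert), and independent
reviews essentially never collide on the same-author metrics, so
duplicate flags on generated data are the planted ones. Fixed sentence
templates are used only for non-hygiene reviews, which the duplicate
screen never touches.

What the generator does *not* emulate: real linguistic variation,
sarcasm, reviewer demographics, platform rating dynamics, or sentiment
labeller error (labels are generated directly from the planted truth).
Passing tests therefore demonstrate that the screening, scoring and
reporting machinery recovers planted signal faithfully — not that the
upstream labeller is accurate on real text.

## Problem sizes and determinism

The test suite runs the full pipeline on suburbs of 4–20 restaurants and
the generator's full 156-listing default where only profiles are needed;
the calibration test uses 2,000 simulated series; the sensitivity check
runs 50 seeded replicates of an 8-restaurant scenario with five strong
plants and one verbatim duplicate cluster. All randomness flows through
explicit seeds; reports and GeoJSON exports are byte-identical under
identical inputs, config and seed.

## Known limitations

- CAI is a ratio of labelled counts; it inherits any bias in the upstream
  sentiment labels and is undefined without hygiene reviews.
- The chi-square screen is approximate at small monthly counts (expected
  cells below 1 warn); it tests proportionality, not seasonality or
  trend.
- Substring/stem matching will mislabel negations ("no rats at all") and
  creative spellings; multi-label counting means one florid complaint can
  raise SAS through several sub-aspects.
- The same-author thresholds were chosen to separate verbatim copies from
  the bundled different-author illustration pair; they are configurable
  and should be re-examined for other languages or much longer reviews.
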