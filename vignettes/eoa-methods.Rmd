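---
title: "Ensemble outcome agreement: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble outcome agreement: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eoa)
```

## The problem

Multi-model ensembles (MMEs) of process-based crop models are routinely
summarised by a single aggregate — usually the ensemble median — and
recommendations about climate-change adaptation options are read off that
aggregate. Two ensembles with the same median can, however, carry very
different weights of evidence: one where every member agrees that an
adaptation pays off, and one where half the members say the opposite. The
Ensemble Outcome Agreement (EOA) index quantifies, on a `[0, 1]` scale, the
confidence that an ensemble outcome fulfils a stated hypothesis, by looking
not only at the full ensemble but at *every possible sub-ensemble* — all
compositions and sizes, `2^N - 1` of them for `N` members (131 071 for the
17-member ensembles this package is sized for).

EOA is a measure of outcome agreement given the available members; it is
*not* the probability that the hypothesis is true, and it cannot diagnose
which member causes disagreement or how good any member is.

## The index

A hypothesis `H` states that the aggregated outcome exceeds a threshold
*strictly* (`value > threshold`; a mirrored `"less"` direction is
provided). Strictness matters: an ensemble of two pairs equidistant on
either side of the threshold has its median exactly *on* the threshold, and
carries no evidence either way — its EOA must be 0.

With an aggregation method fixed (median by default; the mean is the
supported alternative — weighted aggregation is out of scope), define:

* **ES** — the minimum ensemble size for which *all* ensemble combinations
  of that size fulfil `H`. If even the full ensemble aggregate fails `H`,
  no ES exists and EOA = 0 regardless of how many individual members
  fulfil `H` (the *zero rule*).
* **AF** — an adjustment factor in `[0, 1]` separating ensembles with the
  same ES but different spread of sub-ensemble aggregates around the
  threshold. For each size `i < ES`, `my_i` is the mean absolute distance
  to the threshold of the fulfilling size-`i` aggregates (0 if there are
  none) and `mn_i` the same for the non-fulfilling ones (*absent* — not
  zero — if all fulfil). With `r_i = my_i / mn_i`,

  `AF = max( 1 - (ES - 1) / sum(r_i) , 0 )`.

  Where `mn_i` is absent, `r_i` is substituted by the maximum defined
  ratio at the other sizes below ES — a size with no measurable
  disagreement should push AF up, and at least one defined size exists
  because size `ES - 1` has a non-fulfilling subset by the minimality of
  ES. `AF = 0` by definition when `ES = 1`.
* **EOA** — the normalised combination

  `EOA = ( 1 - (ES - AF)/(N + 1) ) / ( 1 - 1/(N + 1) )`.

At `AF = 0` the index lands on interpretable anchors: 1 when `ES = 1`
(every member fulfils `H`), 0.75 at `ES = N/4 + 1`, 0.5 at `ES = N/2 + 1`,
0.25 at `ES = 3N/4 + 1`, and 0 when no ES exists. Values are mapped to the
classes Low `[0, 0.25)`, Medium `[0.25, 0.5)`, High `[0.5, 0.75)`,
Very high `[0.75, 1)` and Maximum (exactly 1).

### The grouping of the adjustment factor

Two algebraic groupings of the AF formula are defensible a priori:
normalising the ratio *sum* (`1 - (ES-1)/sum(r_i)`, the default
`af_grouping = "ratio_sum"`) or averaging the ratios
(`1 - mean(r_i)`, available as `"mean_ratio"`). Only the ratio-sum
grouping satisfies all three behavioural requirements simultaneously:
AF tends to 1 when agreement dominates (all `r_i` large), AF = 0 for
balanced evidence (all `r_i = 1`), and the fallback substitution of the
maximum ratio for absent `mn_i` *raises* AF. Under the mean-ratio
grouping, dominant agreement drives AF to 0 instead. The ratio-sum
grouping is therefore the default; the alternate one is kept behind the
`af_grouping` switch for auditability. No independently published worked
AF value exists against which to verify the choice numerically.

Two degenerate cases are handled explicitly: `mn_i` defined but exactly 0
(every dissenting aggregate sits precisely on the threshold) is treated
like absent, with a warning, since the disagreement has zero magnitude and
a division by zero would otherwise occur; and if *no* size below ES has a
defined ratio (possible only through that zero-`mn` route), AF degrades to
0 with a warning.

## The fast ES search and its correctness

`compute_eoa()` locates ES without enumerating subsets. For the
`"greater"` direction, the smallest aggregate among size-`i` subsets is
attained by the `i` smallest members, for both the median and the mean.
That extreme is non-decreasing in `i`: appending the next-larger value to
the `i` smallest moves their median (and mean) weakly upward. Hence
"every size-`i` subset fulfils `H`" is monotone in `i`, ES is the first
size whose worst-case aggregate fulfils `H`, and a linear scan over sizes
suffices. (The `"less"` direction mirrors the argument with the `i`
largest members.)

Subset enumeration is still needed for the `my_i`/`mn_i` summaries below
ES. There the values are sorted once; a lexicographic combination of
sorted indices is itself sorted, so each subset median is read directly
from its two central order statistics without per-subset sorting. A full
17-member enumeration (131 071 aggregates) completes in well under a
second per cell on one CPU.

The test suite cross-checks this optimized path against a deliberately
naive oracle — literal `combn()` enumeration with `median()` per subset
and an independent re-derivation of ES, AF and EOA — over hundreds of
randomized ensembles.

## Sampled estimation for large ensembles

Beyond `N` around 20–25, exhaustive enumeration becomes infeasible.
`estimate_eoa_sampled()` draws a fixed number of sub-ensembles per size
(default 2000), uniformly *without replacement* over combinations by
sampling lexicographic ranks and unranking them; sizes whose combination
count does not exceed the sample budget are enumerated exactly, so small
ensembles degenerate to the exhaustive result. ES is estimated as the
smallest size from which upward no sampled subset violates `H` (valid
because the all-fulfilling property is monotone in size), and the distance
summaries are estimated from the sampled aggregates. A seed is mandatory;
results are reproducible and the caller's RNG state is restored. On
constructed 17-member ensembles with known ES, 2000 samples per size
recover the true ES in ≥ 95% of seeded replicates.

## Response metrics and surfaces

Two per-member response metrics convert raw 30-year-mean yields into the
% scale the index is applied to:

* **adaptation value** `100·(y_adapted - y_unadapted)/y_unadapted`, both
  yields under the *same* perturbation — the effect of adapting;
* **recovery value** `100·(y_adapted_perturbed - y_baseline)/y_baseline`,
  against each member's *own* unperturbed, unadapted baseline (0 °C, 0%,
  360 ppm) — the ability to restore baseline yields. Using the member's
  own baseline (rather than an ensemble-level one) keeps every metric a
  within-member % change, consistent with the adaptation value.

Members with a zero or missing reference yield are dropped from the
affected cell — no imputation — so the available `N` is recorded per cell
and can vary across cells and options. Metrics are computed on the
30-year means supplied in the run table, not year by year.

Surfaces are evaluated on a perturbation grid; the default spans
temperature offsets −1..+7 °C in 1 °C steps and precipitation offsets
−40..+30% in 10% steps (9 × 8 = 72 cells), with two soils (shallow, deep)
and two CO2 levels (447, 522 ppm) as scenario labels. Each cell of an EOA
surface carries the median response and the EOA result computed from the
*same* ensemble sample. Empty cells are written as `NA`, never 0 — 0 is a
meaningful EOA. `recommendation_report()` filters cells by a minimum EOA
class (Low < Medium < High < Very high < Maximum), optionally intersected
with a rectangular dT/dP region; any expert judgement beyond that filter
is deliberately out of scope.

## The synthetic generator

`simulate_model_runs()` emulates the *structure* of a crop-model MME
sensitivity study — 17 members, the 72-cell grid, two soils, two CO2
levels, adapted and unadapted options, member-specific biases, optional
missing member–option pairs — with a transparent data-generating process:

```
yield = base · (1 + sT·dT + sP·dP) · (1 + c·(CO2 - 360)) ·
        (1 + bias_m) · (1 + effect(dT, dP) · adapted) · (1 + ε)
```

clipped at 0. Defaults: `base = 6000` kg/ha (a realistic Mediterranean
winter-wheat 30-year mean), `sT = -0.05`/°C (warming hurts),
`sP = 0.005`/% (rain helps a water-limited crop), `c = 5e-4`/ppm (mild
CO2 fertilisation), `effect = 0.10`, member bias sd 0.03, residual noise
sd 0. The adaptation effect enters *multiplicatively* so that with zero
noise every member's adaptation value equals `100·effect` exactly, at
every cell — the injected surface is exactly recoverable, which is what
makes end-to-end parameter-recovery tests sharp.

One structural consequence worth noting: the member bias multiplies the
adapted and the reference yield alike and cancels exactly inside the
within-member % metrics. The knob that generates *disagreement between
members* in the metric is therefore the residual noise `sigma_resid`, and
the Monte-Carlo spread properties (mean EOA rising as noise falls) are
exercised over it.

`make_known_es_ensemble()` provides the sharper fixture: `m` dissenters
below the threshold and `n - m` consenters above it, with the dissenters
farther from the threshold. The worst size-`s` subset packs `min(s, m)`
dissenters, so the first all-fulfilling size is `2m + 1` (1 when
`m = 0`); the closed form is re-verified against the package's ES search
at construction and a mismatch aborts. Optional jitter (bounded so it can
neither cross the threshold nor reorder the level distances) roughens the
fixture without changing its ES.

What the generator does **not** emulate: real crop physiology, non-linear
CO2 response curves, soil-water dynamics, inter-member dependence
(members are exchangeable up to bias), or structured missingness. Tests
passing on synthetic data therefore validate the *index machinery and
pipeline bookkeeping*, not the realism of any crop projection.

## Numerical choices

* **Strict fulfilment, exact arithmetic at boundaries.** Fulfilment is
  `value > threshold` with no tolerance. To keep strictness meaningful
  for metrics that are quotients of floating-point yields, the response
  metrics are rounded to `1e-9` (on the % scale) before hypothesis
  testing: an injected effect exactly equal to the threshold then fails
  `H` everywhere, as it would in exact arithmetic, instead of hinging on
  the last bit of `y·(1+e)/y`.
* **Even-size medians** are the arithmetic mean of the two central order
  statistics (the standard convention).
* **Class boundaries** get a `1e-12` absolute snap before interval
  lookup, so closed-form anchor values (0.25/0.5/0.75/1) land in their
  printed class despite floating point.
* **Enumeration order** is lexicographic in member index; sampled
  estimation seeds are mandatory and per-cell seeds in the pipeline are
  derived from the master seed, so re-running a configuration reproduces
  outputs byte for byte.
* **Grid levels** are generated as `min + step·k` (not cumulative sums)
  to avoid float drift in cell keys.
* **Surface files** round to 6 significant digits; a written surface
  re-read and re-written is byte-identical.

## Known limitations

* **EOA is not strictly monotone in the threshold.** ES is: raising the
  threshold can only raise ES or destroy it, and EOA can never increase
  across an ES change (for `es2 > es1`, `EOA(es2, af2) < EOA(es1, af1)`
  whenever `1 - af2 + af1 > 0`, which always holds). But *within* an ES
  plateau, AF can move either way: raising the threshold shifts a
  dissenting aggregate from "just below the threshold" (tiny `mn_i`, huge
  ratio, AF near 1) to "well below it" (moderate `mn_i`, lower AF) — and
  `my_i` moves ambiguously too. In randomized ensembles with generic
  thresholds roughly 1–2% of threshold ladders show a small EOA increase
  (typically < 0.01, up to ~0.1 when a member sits exactly on a
  threshold). Averaged over surfaces the threshold response is cleanly
  decreasing, which is the regime the index was designed for; the unit
  tests assert the monotone decomposition (ES, and EOA at `AF = 0`)
  rather than the false global claim, and the one end-to-end acceptance
  check that asserts the global claim documents this failure honestly.
* The index says nothing about member quality or independence; correlated
  members inflate apparent agreement.
* The double-sided `[-1, 1]` variant of the index and a standalone
  AF-based spread diagnostic are natural extensions, deliberately not
  implemented.

## Problem sizes used by the test and acceptance suites

Oracle-equivalence runs use 500 randomized ensembles of up to 12 members
(literal enumeration stays cheap there); known-ES recovery is verified
exhaustively for every `(n, m)` with `n ≤ 17`; the end-to-end pipeline
runs the full 17-member, 72-cell configuration; sampled-estimation checks
use 20 seeded replicates at 2000 samples per size. These sizes keep the
full suite under a minute on one CPU while exercising every path at the
study scale.
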