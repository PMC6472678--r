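# eoa — Ensemble Outcome Agreement for multi-model ensembles

Multi-model ensembles (MMEs) of crop — or any other — simulation models are
usually summarised by one aggregate value, typically the ensemble median,
and decisions ("this adaptation option works here") are read off that
aggregate. The aggregate hides how much the members actually agree: an
ensemble where every member supports the conclusion and one where half
oppose it can share the same median. `eoa` implements the **Ensemble
Outcome Agreement (EOA)** index, a `[0, 1]` confidence measure for a
threshold hypothesis tested against an ensemble, computed from *every
possible sub-ensemble* (all compositions and sizes, `2^N − 1` subsets;
131 071 for 17 members), together with the response-surface framework it
was designed for: adaptation/recovery response metrics, impact- and
EOA-surfaces over a temperature × precipitation perturbation grid, a
class-based recommendation filter, and a synthetic MME generator with
analytically known agreement structure.

## The index

For a hypothesis `H: aggregate > threshold` (strict; a `"less"` direction
is available) and an aggregation method (median by default):

* `ES` — the minimum ensemble size at which **all** combinations of that
  size fulfil `H`; if even the full ensemble aggregate fails `H`,
  `EOA = 0` (no matter how many individual members fulfil it),
* `AF ∈ [0, 1]` — an adjustment factor separating ensembles with equal
  `ES` but different spread of sub-ensemble aggregates around the
  threshold, `AF = max(1 − (ES−1)/Σᵢ(myᵢ/mnᵢ), 0)` over sizes `i < ES`,
  where `myᵢ`/`mnᵢ` are the mean absolute distances to the threshold of
  fulfilling / non-fulfilling size-`i` aggregates,
* `EOA = (1 − (ES − AF)/(N+1)) / (1 − 1/(N+1))`,

classified as Low `[0, 0.25)`, Medium `[0.25, 0.5)`, High `[0.5, 0.75)`,
Very high `[0.75, 1)`, Maximum (exactly 1). With `AF = 0`: `ES = 1` gives
1, `ES = N/4 + 1` gives 0.75, `ES = N/2 + 1` gives 0.5, `ES = 3N/4 + 1`
gives 0.25.

## Worked example

Seven models give adaptation values (% yield change from adapting) at one
perturbation cell; two clearly oppose, five support:

```r
library(eoa)
vals <- c(cm01 = -8.2, cm02 = -6.9, cm03 = 2.1, cm04 = 3.4,
          cm05 = 4.8, cm06 = 5.5, cm07 = 7.9)
compute_eoa(vals, hypothesis(0))
#> Ensemble Outcome Agreement
#>   members (N): 7   aggregation: median   exhaustive enumeration
#>   hypothesis: aggregate > 0 (strict)
#>   ES: 5   AF: 0.2497
#>   EOA: 0.4642   class: Medium
```

Every sub-ensemble of size 5 or more has a median above 0 (`ES = 5`: with
2 dissenters a strict consenting majority needs `2·2 + 1` members), but
smaller compositions can land below it, and the dissenters sit farther
from the threshold than most supporters — confidence is only Medium
despite a clearly positive full-ensemble median (+3.4%).

The same machinery scales to full response surfaces. Here a synthetic
17-member ensemble with a +8% adaptation effect and 3% simulation noise
over the default 9 × 8 grid (dT −1..+7 °C, dP −40..+30%):

```r
runs <- simulate_model_runs(n_models = 17, effect = 0.08,
                            sigma_resid = 0.03, soils = "shallow",
                            co2_levels = 447, seed = 42)
m <- run_pipeline(runs, thresholds = c(0, 5), out_dir = tempdir(), quiet = TRUE)
s <- read_surface(m$file[1])   # threshold 0
s
#> EOA surface result: 72 cells (72 with data)
#>   hypothesis threshold: 0 (greater)
#>   EOA classes: Low=0 Medium=0 High=1 Very high=36 Maximum=35
recommendation_report(s, "High")
#> Recommendation report (min class: High): 72 cell(s)
#>   dT in [-1, 7], dP in [-40, 30]
```

At threshold 0 the +8% effect is detected with high-to-maximum confidence
everywhere; rerunning against the stricter `threshold = 5` surface (the
second file in `m`) shrinks the recommended region — the standard way to
probe how demanding a claim the ensemble still supports.

A thin command-line front end wraps the same functions:

```sh
inst/cli/eoa compute --values=-8.2,-6.9,2.1,3.4,4.8,5.5,7.9 --threshold 0
inst/cli/eoa simulate --out runs.csv --seed 42
inst/cli/eoa surface --runs runs.csv --out-dir results --thresholds 0,5
```

## Scope

Median/mean aggregation only (no member weighting); no member-quality
screening or dependence diagnostics; the double-sided `[−1, 1]` index
variant and a standalone AF-based spread metric are extension points, not
implemented. See `vignettes/eoa-methods.Rmd` for the model, the fast
enumeration strategy and its correctness argument, numerical choices, and
known limitations.
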