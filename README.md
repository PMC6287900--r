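# ncmscea

Lifetime cost-effectiveness analysis of China's New Rural Cooperative
Medical Scheme (NCMS), the insurance program covering essentially all of
rural China, against a no-insurance comparator — for health economists and
policy analysts who want the full decision model as tested, reusable code
rather than a point-and-click artifact.

## The model

A two-arm, three-state Markov cohort model follows a hypothetical cohort of
20-year-old rural residents in annual cycles to age 100. States are
*normotensive*, *hypertensive* (absorbing among the living, with utility
0.92 vs 0.98 and an annual medical cost of Int$392) and *dead* (no excess
mortality from hypertension). The program arm applies:

- published sex- and age-band-specific effects on mortality (signed, per
  1,000 population per year, added to the background annual death
  probability and clamped to [0, 1]);
- a risk ratio of 0.98 on the annual probability of becoming hypertensive;
- an annual per-resident expenditure increment
  `HE1 − HE1/(1+g)` ≈ Int$136 (national `HE1` = 359, growth `g` = 0.61);
- a labor-productivity offset
  `Δp_offfarm · wage + Δhours_farm · agri_hourly` per alive person-year
  (bands 30–49 and 50+), entered as a negative cost.

Costs and QALYs are discounted at 3%/year in 2013 international dollars.
The incremental cost-effectiveness ratio `ICER = ΔC/ΔQ` is judged against a
willingness-to-pay threshold of three times per-capita GDP
(3 × 12,353 = Int$37,059/QALY). One-way sensitivity analyses sweep every
parameter across its low/high bounds (`tornado()`); the probabilistic
sensitivity analysis (`run_psa()`) samples all 19 uncertain inputs from
independent triangular distributions and reports means, 95% percentile
intervals, cost-effectiveness-plane quadrant probabilities and the
acceptability curve.

The background life table and hypertension-incidence schedule used by the
original analysis are not redistributable; the bundled schedules (marked
`_synthetic` in `inst/extdata/`) are Gompertz–Makeham / logistic stand-ins
from the package's synthetic-data module. Absolute results under the
stand-ins differ from the published tables (see the vignette's discussion);
the qualitative verdict is the same.

## Worked example

```r
library(ncmscea)
p <- default_parameters()
run_base_case(p)
```

```
Base-case cost-effectiveness analysis
  no-NCMS   cost Int$   2,168   effectiveness 27.78 QALYs
  NCMS      cost Int$   3,866   effectiveness 27.78 QALYs
  incremental cost Int$1,698, incremental effectiveness 0.01 QALYs
  ICER Int$318,067/QALY, WTP Int$37,059/QALY -> not_cost_effective
```

Under the synthetic demographic world, insuring one resident for life
costs Int$1,698 more than no insurance (discounted), buys a QALY gain
that displays as 0.01 (the ICER uses the unrounded value), and at
Int$318,067 per QALY gained is far above the Int$37,059 threshold — the
program is classified not cost-effective at base case.

```r
run_psa(p, n = 10000, seed = 20130101)
```

```
Probabilistic sensitivity analysis: 10000 draws (seed 20130101, Mersenne-Twister)
  mean dCost Int$1840 (95% PI -4324, 8183)
  mean dQALY -0.0024 (95% PI -0.2278, 0.1766)
  ICER (ratio of means) Int$-777315/QALY
  at WTP Int$37,059/QALY:
    dominant              13.1%
    cost_effective        13.5%
    not_cost_effective    25.9%
    qaly_loss             47.4%
```

Parameter uncertainty is dominated by the wide mortality-effect intervals:
almost half the draws lose QALYs, and only ~27% of draws are dominant or
cost-effective at the threshold. `one_way(p, "growth_rate")`,
`tornado(p)` and `convention_sweep(p)` decompose which inputs drive this;
`run_full_analysis(p, n, seed, out_dir)` writes the base case, tornado,
PSA scatter, CEAC, quadrant table and a run manifest as plotting-ready
CSV/JSON.

## Acceptance script

`scripts/acceptance.R` reruns the whole pipeline from scratch against the
installed package — base-case model, full tornado, 10,000-draw PSA and the
convention sweep — and writes its JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
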