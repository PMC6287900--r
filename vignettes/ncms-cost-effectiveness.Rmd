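---
title: "Modelling the lifetime cost-effectiveness of rural health insurance in China"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the lifetime cost-effectiveness of rural health insurance in China}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncmscea)
```

## The question and the model

China's New Rural Cooperative Medical Scheme (NCMS) insures essentially the
entire rural population. Whether the health it buys is worth its cost is a
classic value-for-money question, and `ncmscea` answers it with the standard
decision-analytic machinery: a two-arm, three-state Markov cohort model
followed over the lifetime of a hypothetical cohort of 20-year-old rural
residents (ages 20 to 100, one-year cycles).

The three health states are *normotensive*, *hypertensive* and *dead*.
Hypertension is the quality-of-life channel: hypertensive person-years carry
a lower health-related quality-of-life weight (0.92 versus 0.98) and an
annual medical cost (Int$392). The model's structural assumptions are
deliberately simple:

* hypertension is absorbing among the living — once hypertensive, a person
  stays hypertensive, losing utility and incurring hypertension costs for
  the rest of their life;
* hypertension carries no excess mortality — both living states face the
  same annual death probability;
* the dead state is absorbing and earns nothing; anyone alive at 100 exits
  the model with no terminal reward.

The insurance program acts through four channels:

1. **Mortality.** Published program effects on the age-standardized
   mortality rate (signed, per 1,000 population per year, by sex and age
   band 20–44 / 45–59 / 60+) are added to the background annual death
   probability and clamped to $[0,1]$. Several of these effects have wide
   supports spanning zero — the program may plausibly have *increased*
   mortality in some groups — and the model keeps those intervals intact.
2. **Hypertension.** A risk ratio (0.98; 0.95–1.00) multiplies the annual
   probability of becoming hypertensive in the program arm.
3. **Program cost.** The post-program total health expenditure per rural
   resident, $HE_1$, and the expenditure growth rate $g$ attributable to
   the program give the annual per-resident increment
   $HE_1 - HE_1/(1+g)$ (`cost_decomposition()`); with the national
   $HE_1 = 359$ Int\$ and $g = 0.61$ this is ≈ Int\$136 per alive member
   of the program arm per year. It is charged to *everyone alive* in the
   program arm, because it is defined per rural resident, not per patient.
4. **Labor productivity.** The program raises the probability of off-farm
   work and hours worked in agriculture. `labor_gain()` monetizes this as
   $\Delta p_{\text{off-farm}} \cdot w_{\text{annual}} +
   \Delta h_{\text{farm}} \cdot w_{\text{agri}}$ per person-year, with
   band-specific effects for ages 30–49 and 50+, zero below 30 (the
   published effects start at 30). The gain enters the program arm as a
   negative cost (a societal offset).

Hypertension medical costs accrue in **both** arms; the program's savings
on that channel emerge endogenously from its lower prevalence rather than
being entered as a separate parameter.

Costs, benefits and QALYs are discounted at 3% per year (0–5% in
sensitivity analyses) and expressed in 2013 international dollars (the PPP
rate of 3.55 CNY/Int$ is carried for reporting only). The
willingness-to-pay threshold is three times per-capita GDP:
$3 \times 12{,}353 = 37{,}059$ Int\$/QALY (`wtp_threshold()`).

## Cycle mechanics and conventions

Within each cycle, death is applied first — from both living states, with
the same probability, which is what keeps mortality state-independent —
then hypertension onset among the surviving normotensives. Newly
hypertensive individuals earn hypertensive utility and cost from the
*next* cycle (onset at cycle end), consistent with start-of-cycle reward
accrual.

The reward-timing convention is isolated in `cycle_conventions()`:

* `"start"` (default): rewards on start-of-cycle occupancies, discount
  exponent $t$ with $t = 0$ at age 20;
* `"end"`: rewards on end-of-cycle occupancies, exponent $t + 1$;
* `"half"`: half-cycle correction — mean of start and end occupancies,
  exponent $t$.

All mortality inputs are sex-specific but the modelled cohort is not. The
package therefore runs male and female cohorts separately and averages
outcomes with configurable weights (`econ$sex_weight_male`, default
0.5/0.5). Because the reference results this model follows do not state
either convention, `convention_sweep()` reruns the base case under every
timing and a grid of sex weights so the closest convention can be
identified against any reference numbers. The sex weight matters a great
deal here: the female 60+ mortality effect is +1.05 per 1,000 (harmful at
base), so a female-only cohort loses QALYs under the program while a
male-only cohort gains enough to approach the threshold.

## Incremental metrics

`incremental()` forms Δcost and ΔQALY on unrounded values; the ICER is
their quotient and is undefined when ΔQALY is exactly zero. Display
rounding (costs to Int$1, QALYs to 0.01, ICER to Int$1) happens only in
print methods — which is why a displayed pair like Int$825 / 0.01 QALYs
need not equal the displayed ICER's quotient.

`classify()` partitions the cost-effectiveness plane into the four
reporting categories used throughout: *dominant* (QALY gain at
non-positive cost), *cost-effective* (ICER at or below the threshold —
the boundary is inclusive), *not cost-effective* (above it) and
*qaly_loss* (any non-positive QALY change, pooled regardless of cost,
matching the four-way quadrant reporting convention). A zero ΔQALY is
classified `qaly_loss`; this keeps the four labels a true partition, at
the cost of labelling the measure-zero "equal effect, cheaper" boundary
as a loss.

Net monetary benefit is $\lambda \cdot \Delta Q - \Delta C$. For positive
QALY gains, NMB > 0 coincides exactly with {dominant, cost-effective}.
Note that a QALY-*losing* draw with a large cost saving also has positive
NMB; the acceptability curve (`ceac()`, fraction of draws with NMB > 0)
therefore equals P(dominant) + P(cost-effective) *plus* that southwest
overlap, not the two-class sum alone.

## Sensitivity analyses

**One-way.** `one_way()` pins one parameter at its low and high bound
(all else base) and reruns the full two-arm model; `tornado()` does this
for all 19 uncertain inputs and ranks by ICER span, treating cost-saving
endpoints as $-\infty$ and QALY-losing endpoints as $+\infty$ so
parameters whose range crosses either extreme rank as maximally
influential, with the original enumeration as a stable tie-break.

**Probabilistic.** `run_psa()` samples every uncertain input
independently from a triangular distribution with the low/base/high
values as support and mode — the distribution family the uncertainty
specification implies, sampled by the closed-form inverse CDF
(`sample_triangular()`). Independence is deliberate: no correlation
structure is specified for these inputs. Negative samples are allowed
wherever a support includes them (the six mortality effects); truncating
at zero would artificially deflate the harm tail and bias the ICER. The
six mortality effects are sampled as six independent triangulars over
their interval bounds.

Reproducibility contract: draws consume R's default Mersenne-Twister
stream parameter-by-parameter in `param_ids()` order (the enumeration
mirrors the model-input table and must not be permuted); identical
`(parameters, n, seed)` give bit-identical results, and the generator
name is recorded in the result. Summary intervals are equal-tailed
2.5/97.5 percentiles of the draws (R quantile type 7). The summary ICER
is the ratio of means, never the mean of per-draw ratios, which is
unstable when ΔQALY draws cross zero — as they do here.

## The synthetic demographic stand-ins

The background schedules the model needs — an age- and sex-specific
annual death probability for 2013 rural China and an age-specific annual
probability of becoming hypertensive — come from supplementary material
that is not redistributable with this package. The bundled CSVs (marked
`_synthetic` in their filenames) are parametric stand-ins from the
`synthetic_data` module:

* **Mortality**: a Gompertz–Makeham hazard
  $h(a) = \lambda + \alpha e^{\beta a}$ with defaults
  $\lambda = 10^{-4}$, $\alpha = 3 \times 10^{-5}$, $\beta = 0.09$ and a
  female/male hazard ratio of 0.8, converted to annual probabilities
  $q(a) = 1 - e^{-h(a)}$. These defaults put life expectancy at age 20 in
  the mid-50s of remaining years, the plausible range for rural China in
  2013, and are validated to keep $q < 1$ through age 99.
* **Incidence**: a logistic curve
  $p(a) = p_{\max} / (1 + e^{-s(a - a_{0})})$ with defaults
  $p_{\max} = 0.05$ per year, midpoint $a_0 = 55$, steepness
  $s = 0.08$ — under 0.5%/year at 20 rising towards 4–5%/year past 70,
  the shape cohort studies of hypertension onset report. The schedule is
  interpreted as annual *incidence* (the transition probability the
  engine needs), not prevalence; the same curve is used for both sexes, a
  documented simplification.

`synthesize_parameter_set(seed, jitter)` combines these schedules with
the published model-input values, each base value perturbed by a seeded
uniform offset of at most `jitter` times its low–high width and clamped
into its bounds — which preserves every ordering invariant by
construction and leaves degenerate (point-mass) inputs untouched. With
`jitter = 0` it reproduces the bundled fixture exactly.

**What a green test does and does not establish.** The synthetic world
exercises every code path with realistic shapes: tests prove the engine
matches explicit transition-matrix powering, conserves occupancy to
1e-12, discounts and classifies correctly, and that the PSA is
deterministic and statistically faithful to its triangular inputs. It
does *not* reproduce the reference analysis's published numbers, because
those depend on the exact 2013 life table and incidence schedule: with
the stand-ins, the base case lands at ΔC ≈ Int$1,698 and
ICER ≈ Int$318,000/QALY versus the published Int$825 and
Int$71,480/QALY — the same qualitative verdict (not cost-effective at
Int$37,059/QALY) from a different demographic world. Notably, the
published per-arm discounted QALYs (≈14.2 over ages 20–100) are well
below what any plausible 2013 life table yields when discounting starts
at age 20 (≈28–30), suggesting an additional unpublished accounting
convention; the convention sweep over timing and sex weights cannot
close that gap, so replication of the reference tables is bounded by
what was published.

## Numerical choices and degenerate inputs

* Probabilities are clamped to $[0,1]$ after every adjustment; the
  additive mortality effect is per-1,000, matching the published
  coefficient scale.
* Occupancy conservation is enforced by construction and tested to
  1e-12; cost components sum to the arm total to 1e-9.
* Degenerate triangulars ($a=b$) are point masses; a degenerate
  parameter contributes zero one-way span and sorts to the bottom of the
  tornado.
* The growth-rate domain is $g > -1$; $HE_1 > 0$. Violations raise
  domain errors before any cycle runs.
* Schedules must cover every age in $[\text{start}, \text{end})$;
  validation fails fast, naming the offending field, before cycle 0.

## Limitations

Beyond the synthetic-schedule caveat above: no individual-level
microsimulation (cohort fractions only), no hypertension-attributable
mortality, no reversion from hypertension, no correlation between
sampled parameters, no expected-value-of-perfect-information analysis,
and no currency conversion — everything is carried in 2013 international
dollars. Regional heterogeneity enters only through the low/high
expenditure bounds (the Beijing and Guizhou variants).
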