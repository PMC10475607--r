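---
title: "Methods: phase-wise micro-costing, sensitivity and scale-up scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase-wise micro-costing, sensitivity and scale-up scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(costkit)
```

## The costing model

costkit implements the costing of a clinic-delivered behavioral
intervention from a health-systems perspective: only costs borne by the
healthcare system are counted, never patient or societal costs. The input
is a *cost ledger* — one row per priced resource — plus four global
parameters: the annual discount rate, the patient cohort used as the
unit-cost denominator, the INR/USD exchange rate, and the annual
operational minutes of a facility resource.

Two complementary aggregations are computed:

* **Top-down (financial) view** — `phase_summary()` sums
  `unit_price × quantity × apportionment_fraction` over the items of a
  phase (development, pretest, training), reporting each line's proportion
  of the phase total and the unit cost per cohort patient. This mirrors
  how development and training expenditure is recorded: as aggregate
  administrative spend, not per-patient activity.
* **Bottom-up (activity-based) view** — `unit_delivery_cost()` resolves
  every delivery-phase item to a cost per patient served and sums them.

A delivery item resolves along one of two paths:

1. `per_patient = TRUE`: the price is already per patient; the item
   contributes `unit_price × quantity × apportionment_fraction` directly.
2. Otherwise the item must carry `staff_minutes_per_patient`. Its annual
   cost — the purchase price annualized over the useful life for a capital
   good, the price itself (read as INR/year) for a recurrent resource —
   is divided by the annual operational minutes and multiplied by the
   minutes the resource is engaged per patient. This is the standard
   opportunity-cost valuation of staff time and shared capital.

### Capital annualization

A capital purchase of price $P$ with useful life $L$ years becomes an
equivalent annual cost $P / A(r, L)$ with the annuity factor

$$A(r, L) = \frac{1 - (1+r)^{-L}}{r}, \qquad A(0, L) = L,$$

the present value of one rupee per year for $L$ years at rate $r$ with
payments in arrears — the usual health-economics convention. The defining
property, tested to $10^{-9}$ relative error against an explicit
discount-sum loop, is that the annualized stream re-discounts to exactly
the purchase price. A straight-line option (`method = "straight_line"`,
$P/L$) is available for comparison but off by default: annualization with
a stated discount rate implies the annuity method.

### Key parameters

| Parameter | Default | Why |
|---|---|---|
| `discount_rate` | 0.03 /year | HTAIn reference-case rate for Indian health-economic evaluation |
| `cohort_size` | 100 patients | per-clinic denominator; the study enrolled 200 patients across two clinics and its printed unit costs divide by 100 |
| `exchange_rate` | 74 INR/USD | the rate implied by the published INR/USD pairs (they vary 73.0–74.1 line to line, so USD figures are reported but never treated as authoritative) |
| `annual_operational_minutes` | 240 × 480 = 115,200 | 240 working days/year of 8 working hours; exposed because no operational-time figure is published, so every result that flows through the per-minute path is config-sensitive |

## Rounding and report conventions

Internal arithmetic is never rounded. At report boundaries, rupee figures
round **half-up** to integer INR (`round_half_up()`; 0.5 away from zero,
unlike R's banker's rounding), USD and proportions to 2 dp. Two
conventions are deliberate and load-bearing:

* **Delivery proportions divide by the rounded total** (272), not the
  exact component sum (272.15). This is the only denominator that
  reproduces all five published proportions (27.94 / 9.56 / 3.68 / 58.82
  / 0.06) simultaneously.
* **Scenario figures round once, at the final per-patient figure.**
  190.43 → 190, 176.81 → 177, 107.1075 → 107 all reproduce; rounding any
  intermediate would break them. The cumulative "total with training" sums
  the two already-rounded figures (173 + 1206 = 1379), matching the
  published table's construction.

The built-in ledger's development components sum to 659,444 INR against a
printed total of 659,447; the package stores the components and treats the
printed total as a rounded aggregate (tests allow the table's own ±3 INR
slack). Both published development views are exposed: with the pretest
line (659,444) and the headline figure without it (647,824 vs. printed
647,827). The printed pretest proportion (1.77%) computes to 1.76% under
any denominator choice; the computed value is reported.

## One-way sensitivity analysis

`one_way_dsa()` varies one parameter at a time. A parameter targets either
a single delivery component (its per-patient cost is replaced by the bound
value, all others at base) or `"total"`, the overall package cost, modelled
as a multiplicative factor on the *reported* (integer-rounded) per-patient
total — so ±20% on the base case 272 gives 217.6–326.4, reported 218–326.
Both modes exist because published tornado diagrams for this kind of
analysis mix whole-package and per-component parameters.

Bounds: explicit `low`/`high` pass through; otherwise a symmetric
`spread` (default ±20%) around the base. For a component entering the
total additively, the exact output range is $0.4 \times$ the component's
base cost — a closed form the tests verify against a brute-force rebuild
of every perturbed total. Tornado rows sort by descending range; ties
break lexicographically by parameter name so output is deterministic.

The published sensitivity range for the delivery cost is 184–326 INR per
patient. The upper bound is exactly the +20% whole-package case. The lower
bound 184 cannot arise from any symmetric ±20% variation (272 × 0.8 =
217.6); it must come from parameter-specific lower bounds that are not
published. The package therefore ships the ±20% default, accepts explicit
bounds for users who have them, and makes no attempt to reverse-engineer
the 184.

## Scale-up scenarios

The scenario models partition delivery components into a *shareable* pool
(divided across a counseling group: human resource, capital, dedicated
phone line — 102.15 INR on the built-in ledger) and a *discountable* pool
(bulk procurement: pamphlets, SMS & follow-up calls — 170 INR). This
partition is the unique one that back-fits every published scenario cell
exactly, and it is an argument (`scenario_config()`), not a constant.

* Scenario I: cost(g) = non-shareable + shareable / g; strictly decreasing
  in g with limit = the non-shareable sum.
* Scenario II: cost(d) = total − d × discountable; affine with slope
  −discountable.
* Scenario III: unit training cost × (1 − d); the discount abstracts the
  savings from folding training into routine in-service programs.
* Scenario IV: shareable/g + (1 − d) × discountable (+ any component in
  neither pool at base), plus the discounted training cost.

The published grid tabulates groups of 5/10/15/20; group size is free, so
the 8–10-patient groups discussed for practice are equally computable.

## Budget impact

`project_costs()` books costs at year start: year 1 carries the initial
training undiscounted, year $t$ the factor $(1+r)^{-(t-1)}$; a refresher
training falls in every year $t > 1$ with $t-1$ divisible by the refresher
interval, and every year carries `annual_patients × unit_delivery_cost`.
The year-start convention and the training frequency are configuration,
not constants, because the operational guidelines that fix them in
practice vary by program. With a constant annual cost $C$ and no training,
the discounted sum collapses to $C\,(1 + A(r, H-1))$ — the closed form the
tests use as oracle. No published multi-year figures exist to reproduce,
so this module is validated purely against its closed forms and a
brute-force per-year loop.

## Synthetic ledgers and what the tests show

`generate_ledger()` draws randomized ledgers that emulate the resource
structure of a real clinic ledger: development/pretest/training lines,
capital goods with useful lives (3–10 years) and per-patient usage
minutes, salaried roles with contact minutes, and per-patient consumables.
Prices are drawn log-uniformly (consumables three decades lower) to mimic
the paise-to-lakh span of real ledgers, and all drawn values are rounded
to the granularity the CSV format carries, so serialization is lossless.
Ground truth — exact unit cost, component costs, phase totals, scenario
curves, DSA ranges — is computed at generation time with separate
loop-based arithmetic (including a loop-based annuity), so it is an
independent oracle for the pipeline.

What passing the synthetic suite shows: the aggregation, annualization,
scenario and sensitivity arithmetic is exact over a wide random family of
ledgers (100 seeds in the recovery suite, at $10^{-9}$ relative
tolerance). What it does not show: anything about data quality of a real
ledger — apportionment statistics, salary estimates and time-per-patient
figures are inputs here, and their measurement error dominates real
uncertainty, which is exactly why the one-way sensitivity analysis exists.

Problem sizes throughout the test suite are desk-scale by design — ledgers
of a dozen to a few dozen items, 100 recovery seeds — because the method
is closed-form arithmetic whose correctness does not depend on scale; the
full suite runs in seconds.

## Degenerate inputs and edge policies

* Empty ledger / absent phase: zero totals, empty line-item tables;
  proportions are `NA` (not 0/0).
* `group_size = 1`, `discount = 0`: every scenario recovers the base case.
* A delivery item with neither a per-patient price nor usage minutes is a
  configuration error naming the item, not a silent zero.
* Validation reports all violations at once (`validate_ledger()`) instead
  of stopping at the first; writing an invalid ledger is refused.
* Indian digit grouping ("4,91,040") is accepted when reading money
  fields, never emitted.

## Limitations

* Single cost year: no inflation indexing or cost-year conversion.
* No probabilistic sensitivity analysis; only one-way deterministic.
* No effectiveness modelling — scenario results are cost-side only, so
  nothing here is a cost-effectiveness ratio.
* USD conversion is a courtesy display; acceptance of any result should
  rest on the INR figures.
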