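# costkit

Micro-costing and scale-up scenario analysis for health interventions
delivered in routine clinics, written for health economists and program
managers who need per-patient cost estimates, sensitivity ranges and
scale-up projections from a line-item cost ledger.

The package grew out of the costing of a culturally tailored tobacco
cessation package delivered at two district noncommunicable-disease (NCD)
clinics in Punjab, India, and ships that study's complete cost ledger as a
built-in fixture. Everything is general: any multi-phase ledger with the
same structure runs through the same pipeline.

## What it computes

**Phase-wise micro-costing.** A cost ledger holds one row per priced
resource item, classified by phase (development, pretest, training,
delivery), cost class (capital vs. recurrent) and cost behavior (fixed vs.
variable), with an apportionment fraction for shared resources. Development
and training costs are aggregated top-down (financial costing); the
per-patient delivery cost is built bottom-up (activity-based costing).

**Capital annualization.** A capital purchase of price *P* with useful life
*L* years is converted to an equivalent annual cost *P / A(r, L)* using the
annuity factor

&nbsp;&nbsp;&nbsp;&nbsp;*A(r, L) = (1 − (1 + r)^−L) / r*,&nbsp;&nbsp;*A(0, L) = L*

at annual discount rate *r* (default 3%, the HTAIn reference-case rate).
Annual costs become per-minute costs over the facility's operational
minutes (default 240 days × 480 min), and staff time is valued as
opportunity cost from gross salaries.

**One-way deterministic sensitivity analysis.** Each cost input is varied
between explicit bounds, or ±20% when none are known, with all others at
base; outputs are ranked into a tornado table/diagram and an overall range.

**Scale-up scenarios.** (I) group counseling divides the shareable pool
(human resource, capital, dedicated phone line) by the group size;
(II) bulk procurement discounts the pamphlets and SMS/call pool;
(III) integrated training discounts the unit training cost;
(IV) the cumulative combination of I and II.

**Budget impact.** Multi-year projection of training (initial + refresher)
and delivery costs at clinic capacity, discounted to present value.

## Worked example

```r
library(costkit)

ledger <- table2_fixture()          # the published tobacco-cessation ledger
validate_ledger(ledger)$ok          # TRUE

b <- unit_delivery_cost(ledger)
b
#> <unit_cost_breakdown> total INR 272.15, reported 272 (USD 3.68)
#>        component                                         label   cost proportion
#> 1 human_resource                                Human Resource  76.00      27.94
#> 2        capital Capital Cost (Building, Furniture, Equipment)  26.00       9.56
#> 3      pamphlets                               Pamphlets (IEC)  10.00       3.68
#> 4      sms_calls                  SMS and Follow-up calls (HR) 160.00      58.82
#> 5     phone_bill                          Dedicated Phone Bill   0.15       0.06
```

The per-patient delivery cost is 272 INR (the sum 272.15 rounded half-up),
dominated by SMS & follow-up calls (58.82%) and counselor time (27.94%).
Phase totals and unit costs per 100-patient cohort:

```r
phase_summary(ledger, "development", include_pretest = TRUE)$total  # 659444
phase_summary(ledger, "development")$total                          # 647824 (headline, excl. pretest)
phase_summary(ledger, "training")$unit_cost                         # 1340 INR/patient
```

Scale-up scenarios (published grid):

```r
scenario_grid(ledger)
#>        scenario axis per_patient_cost
#> 1       I_group  5.0              190
#> 2       I_group 10.0              180
#> 3       I_group 15.0              177
#> 4       I_group 20.0              175
#> 5       II_bulk  0.1              255
#> ...
```

Counseling in groups of 10 brings the delivery cost from 272 to 180 INR per
patient; the cumulative optimistic scenario (groups of 20, 40% bulk
discount) reaches 107 INR:

```r
cumulative_scenario(b, 1340, group_size = 20,
                    discount = 0.40)$implementation$per_patient_cost  # 107
```

One-way sensitivity with ±20% on the overall package cost:

```r
res <- one_way_dsa(ledger, dsa_parameter("Overall package cost", "total"))
c(res$overall_min, res$overall_max)   # 218 326
```

A command-line front end over the same functions lives at
`inst/cli/costkit.R` (`validate`, `fixture`, `cost`, `dsa`, `scenario`,
`bia`, `synth` verbs).

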