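# ckdmarkov

Chronic kidney disease (CKD) affects roughly one in ten UK adults, and its
end-stage — dialysis and kidney transplantation — dominates both the NHS cost
of the disease and the quality-of-life burden on patients. `ckdmarkov` is a
population-level cost-utility modelling package for analysts asking which
system-wide CKD interventions are worth paying for: it projects the whole UK
adult population through the CKD pathway and prices the consequences.

## The model

The core is a deterministic Markov cohort model with 16 health states:

- an **at-risk** state (adults without kidney disease),
- **undiagnosed CKD G1–G4** and **diagnosed CKD G1–G5** (stage 5 is always
  diagnosed; undiagnosed patients progress faster because they are less
  likely to be treated),
- **dialysis**, **transplantation** (acute tunnel state + post-acute),
- **cardiovascular disease** (acute tunnel state + post-acute),
- an absorbing **death** state.

The closed cohort of 53 million adults is advanced in quarterly cycles over a
10-year horizon, `x_{t+1} = x_t P_t`, where each row-stochastic `P_t` is
assembled from stated quarterly transition probabilities, life-table mortality
scaled by per-state relative risks on the rate scale, and the residual-mass
rule (leftover probability stays in the state; tunnel states instead exit to
their post-acute state). Annual probabilities are converted with the standard
rate transformation `p_q = 1 - exp(ln(1 - p_a)/4)`.

Four interventions are expressed declaratively as rate-scale multipliers on
named transition cells, with linear or step phase-in:

1. **Earlier diagnosis** — a calibrated multiplier on undiagnosed→diagnosed
   transitions (stages 1–3) hitting a target reduction in the undiagnosed
   population attributable to underserved communities;
2. **Better CKD management** — closing the ACEi/ARB treatment gap, a blended
   multiplier `(1-gap) + gap·RR` on diagnosed G3→G4;
3. **SGLT-2 inhibitor uptake** — uptake-weighted risk ratios on diagnosed
   G4→G5 and G4→acute CVD;
4. **Pre-emptive transplantation** — a step multiplier on G5→transplantation
   with a fixed programme cost.

Each scenario accrues discounted (3.5%/yr) direct NHS costs and QALYs per
state per cycle, yielding incremental cost-effectiveness ratios
(ICER = ΔC/ΔQ) against baseline, the QALY **interaction factor** of the
combined interventions, a **capacity-constrained** scenario (dialysis and
transplant activity capped at 6%/yr compound growth), and a one-way tornado
sensitivity analysis.

Real parameter tables for a model of this kind come from proprietary
registry and trial literature and are rarely publicly deposited, so the
package ships a seeded synthetic generator that emulates their structure
(row-stochastic tables on the model graph, a 53-million-person initial
distribution, stage-monotone costs and utilities), plus an individual-level
microsimulation used as an independent oracle for the cohort engine.

## Worked example

```r
library(ckdmarkov)

pset <- generate_parameter_set(seed = 1)   # synthetic S1-S6-style inputs
grid <- run_scenario_grid(pset)            # baseline, 4 interventions, combined

economics_table(grid)[, c("scenario", "display_cost", "display_qalys", "display_icer")]
#>     scenario display_cost display_qalys display_icer
#> 1   baseline  55264885664     360331352           NA
#> 2  diagnosis     10856305          5667         1916
#> 3 management   -214090923          9256       -23129
#> 4      sglt2   -269790235          2043      -132063
#> 5 transplant   -129430463          9898       -13076
#> 6   combined   -605375185         26957       -22457

round(grid$interaction_factor, 1)
#> [1] 92.5
```

Row 1 is the baseline absolute burden: £55.3 billion discounted direct costs
and 360 million QALYs over 10 years. The remaining rows are incremental
versus baseline: on this synthetic parameter set every intervention gains
QALYs, and all but earlier diagnosis are cost-saving (negative ICER with
positive ΔQALYs = dominant). The combined package gains 26 957 QALYs — 92.5
QALYs more than the four interventions sum to individually, the interaction
factor. Patient counts follow the same shape:

```r
patient_count_table(grid)[, c("scenario", "dialysis_prevalence_y10", "deaths_total")]
#>     scenario dialysis_prevalence_y10 deaths_total
#> 1   baseline               197190.85  5009250.672
#> ...
#> 7 difference               -10302.89    -5686.452
```

i.e. the combined interventions avert ~10 300 dialysis patients in year 10
and ~5 686 deaths over the decade. `run_analysis(pset, out_dir)` writes these
tables as CSV together with a manifest of input hashes;
`one_way(pset)` produces the tornado.

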