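---
title: "Methods: a population-level Markov model of CKD burden and interventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a population-level Markov model of CKD burden and interventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ckdmarkov)
```

## The model and its assumptions

`ckdmarkov` projects a closed cohort of 53 million UK adults through 16
health states in quarterly cycles over a 10-year horizon (40 cycles). The
states cover the full CKD pathway: an at-risk state, undiagnosed CKD G1–G4,
diagnosed CKD G1–G5, dialysis, transplantation (acute and post-acute),
cardiovascular disease (acute and post-acute), and death. Three structural
assumptions matter most:

* **Closed population.** New CKD arises only as a transition from the
  at-risk state; there is no demographic inflow, ageing or migration. This
  makes conservation of the 53-million total an exact invariant, tested to
  1e-6 persons across all 40 cycles.
* **Stage 5 is always diagnosed.** There is no undiagnosed G5 state;
  undiagnosed G4 patients who progress arrive directly in diagnosed G5.
* **Undiagnosed patients progress faster.** They are less likely to receive
  treatment, so their stage-progression probabilities must be at least the
  diagnosed counterparts. The synthetic generator enforces this by
  construction and the file loader warns when a user-supplied table
  violates it.

Two states are *tunnel states* — transplantation (acute) and CVD (acute) —
occupied for exactly one cycle. Their exact mechanics are a design
decision: we split exits between death (per the mortality
model) and the mandated post-acute state, i.e. the tunnel's residual mass
goes to its exit rather than to a self-loop.

### Event ordering and mortality

Within a cycle, all transitions compete inside a single matrix
multiplication; there is no sequencing of death before or after progression.
This is standard cohort-model practice and keeps every row stochastic.

Only death is age-dependent. Because the cohort itself is not
age-structured, mortality uses a fixed age-weighted mean of the life table's
annual probabilities, `q̄ = Σ w_a q_a`, with weights equal to the adult age
distribution at model start, held constant over the horizon. Per-state
relative risks act on the *rate* scale: `p_death = 1 − exp(−(−ln(1−q̄))·rr/4)`.
The rate scale keeps the result a valid probability for any `rr ≥ 0`;
applying relative risks to probabilities directly can exceed 1 (a dialysis
relative risk of 10 on an annual q̄ of 1% would already be fragile).

### Probability conversion

Annual probabilities convert to quarterly via the constant-rate chain
`r = −ln(1 − p_a)`, `p_q = 1 − exp(−r/4)`. The inverse identity
`1 − (1 − p_q)^4 = p_a` then holds to machine precision (we assert 1e-12
over a dense grid of the domain `[0, 1 − 1e-9]`); `p_a = 1` is a domain
error since the rate is infinite.

### Row construction: residuals, rescaling, degenerate inputs

A transition row is assembled as: death probability from the mortality
model; stated exits from the parameter table; residual mass to the
self-transition (tunnel states: to the mandated exit). If death plus stated
exits exceed 1 — possible when an intervention inflates a cell or a user
supplies an aggressive table — the non-death entries are rescaled
proportionally to fit `1 − p_death` (a competing-risk rescale) with a
warning. The rescale is deterministic and preserves the ratios between
exits, which makes it testable. Structural zeros (cells outside the model
graph) are errors at build time, named by the offending pair. An extreme
relative risk that would push the quarterly death probability to 1 is
capped at `1 − 1e-9` with a warning.

## Interventions as schedule transformations

Interventions are declarative: a set of target cells, a multiplier, a ramp.
All multipliers act on the rate scale, `p' = 1 − (1 − p)^m`, so that (a) any
`m ≥ 0` yields a valid probability and (b) interventions sharing a cell
compose multiplicatively on rates — the composition rule the combined
scenario uses. One consequence worth knowing: a "doubling" (`m = 2`) of a
cell with `p = 0.01` gives 0.0199, not 0.0200; for the small probabilities
involved the distinction is negligible, and the rate convention buys
closure under composition.

Ramp shapes are a design decision: the endpoints ("over the time horizon")
are specified by the scenarios, the shapes are not. We use linear-in-cycle
ramps (`ramp(t) = t/40`) for diagnosis, management and SGLT-2 uptake, and a
step ramp (full effect from cycle 1) for the transplantation programme,
which is an operational change rather than a gradual uptake. Cycle indexing:
the matrix requested for cycle `t` (t = 1..40) advances occupancy from
`t−1` to `t`, so `ramp(0) = 0` (no effect at model start) and
`ramp(40) = 1` (full effect at the final cycle).

Intervention parameters, defaults, and units:

| parameter | default | meaning |
|---|---|---|
| `diagnosis_reduction` | 0.25 | target proportional reduction of the underserved undiagnosed (stages 1–3) population over the horizon |
| `bame_undiagnosed_fraction` | 0.15 | share of the undiagnosed population attributable to the targeted communities; required input, tracked as a fixed fraction |
| `treatment_gap` | 0.36 | diagnosed patients indicated for ACEi/ARB but untreated |
| `progression_rr` | 0.70 | treated-vs-untreated G3→G4 progression ratio; a required input (the fixture documents its assumed value) |
| `sglt2_eligible` | 0.188 | eligible share of the diagnosed G4 population |
| `cv_rr`, `renal_rr` | 0.75, 0.75 | SGLT-2 risk ratios for CVD events and renal progression; kept separate because the evidence for each differs |
| `transplant_increase` | 1.0 | proportional increase in pre-emptive transplants |
| `transplant_cost` | £149 000/yr | outreach programme cost |
| `annual_growth_cap` | 0.06 | constrained-scenario compound growth cap |

The diagnosis intervention is *calibrated*: its multiplier is found by
`uniroot` (bracket expanded from [1, 2] up to 1e6, tolerance 1e-10) so that
re-projecting the modified schedule reduces the tracked undiagnosed
population by exactly the target at cycle 40; an unreachable target reports
the maximum achievable reduction instead of silently under-delivering.
Because the underserved share is tracked as a fixed fraction of the
undiagnosed stages 1–3 population, it cancels in the calibration ratio —
the fraction matters for interpretation, not for the root.

### The capacity-constrained scenario

The base case assumes all demand for kidney replacement therapy is met. The
constrained scenario caps *activity* at a 6%/yr compound growth trajectory
from reference levels taken from the uncapped baseline: dialysis on
occupancy (a stock of treatment slots), transplantation on quarterly inflow
(a flow of procedures). When a cap would be exceeded, every inbound cell
into the capped state is scaled by one common factor in [0, 1] chosen so
the cap binds exactly; redirected patients wait in their source state (an
extra cycle in diagnosed G5, typically). The schedule becomes
occupancy-dependent but remains deterministic in (cycle, occupancy).

## Economics

Costs (quarterly, GBP, 2022 prices) and utilities (annual EQ-5D-3L weights)
attach to states. Defaults, from published UK sources: the at-risk state
costs nothing but shares the stage 1–2 utility of 0.85 (CKD is
asymptomatic before stage 3); undiagnosed G1/G2 cost nothing (untreated),
undiagnosed G3/G4 cost the same as diagnosed (similar healthcare contact);
dialysis costs £8 595.16/quarter plus £1 840.18 transport; the ~£60/yr
primary-care add-on for stages 1–5 is already inside the state costs and is
not re-added. Death carries zero cost and utility.

Accrual is end-of-cycle with no half-cycle correction (cycle 0 accrues
nothing) — a deliberate single-convention choice so every reported number
is reproducible one way. Both costs and QALYs discount at 3.5%/yr,
compounded quarterly from model start: `df(t) = 1.035^(−t/4)`. Fixed
intervention costs spread evenly across quarters. Incremental comparisons
report the signed ICER even when negative, with a dominance flag alongside
(negative ICER + positive ΔQALYs = dominant); a zero ΔQALY leaves the ICER
undefined rather than infinite. The *interaction factor* is the combined
package's ΔQALYs minus the sum of the individual ΔQALYs — on the synthetic
fixture it is positive and sign-stable across seeds, consistent with the
interventions reinforcing each other upstream and downstream of the same
pathway.

## Sensitivity analysis

The tornado is one-way and relative: each of seven default parameters is
set to `value·(1 ± δ)` (δ = 20%, except 7% for the transplantation
intervention, whose live donor pool is a small subset of overall transplant
numbers) and the combined-vs-baseline ICER recomputed from scratch — two
full re-runs per parameter, no shared state, so permuting the parameter
list cannot change the result. The seven defaults are the four intervention
effects, the two baseline G5 exit probabilities (to dialysis and to
transplantation), and CKD incidence; the list is fully user-overridable via
accessor paths (`param/...`, `cell/from/to`, `cost/state`,
`utility/state`). Perturbed probabilities are clipped to `[0, 1)` with a
warning.

## What the synthetic generator does and does not emulate

Transition tables of this kind are assembled from registry and trial
literature and are rarely publicly deposited, so the generator produces
*structurally* faithful inputs: row-stochastic quarterly
tables on the model graph, drawn as annual probabilities within ±10% bands
around literature-scale central values and converted via the rate chain;
undiagnosed progression inflated ×1.3 over diagnosed; a 53-million-person
initial distribution with 10% CKD prevalence, 44% of stages 1–4
undiagnosed, empty tunnel and CVD post-acute states, and kidney replacement
populations of realistic magnitude (30 000 dialysis, 40 000 transplanted);
an abridged five-band life table with an age-weighted mean annual mortality
of ~0.9%; and the default cost/utility set verbatim. The
transplant-post→dialysis graft-failure edge is a structural default and
removable.

It does **not** reproduce any published table's numeric values, so passing tests
demonstrate the *machinery* — conservation, calibration, capping,
accounting identities, oracle agreement — not the published point
estimates. Real data would add age structure, secular trends in incidence,
and capacity feedbacks the generator deliberately omits.

## Validation against the microsimulation oracle

The cohort engine is cross-validated against an individual-level
microsimulation: n = 100 000 individuals sampled from the initial
distribution and advanced by categorical draws from the same matrices
(realised as one multinomial draw per occupied state per cycle, which is
distributionally identical for exchangeable individuals and much faster).
Agreement is asserted per state per cycle within 4 binomial standard
errors, using the pooled proportion (the mean of the cohort and
microsimulation estimates) inside the standard error — the usual
two-sample form, which avoids a zero denominator for states the cohort
leaves almost empty. At n = 100 000 over 40 cycles the maximum z-statistic
on the fixture is typically below 3.

## Problem sizes and determinism

All simulations are small by construction: a 16×16 matrix over 40 cycles
projects in well under a second, the full scenario grid (baseline, four
interventions, combined, both scenarios) in ~1 s, the seven-parameter
tornado in ~5 s, and the 100 000-individual microsimulation in well under a
second, so the entire test suite and the acceptance script run in seconds
on one CPU. Every stochastic component (the generator, the
microsimulation) is seeded; everything else is deterministic, and report
files regenerate byte-identically from the same inputs.

## Known limitations

* No age or sex structure; mortality uses one averaged life-table rate.
* No half-cycle correction; results are convention-dependent at the margin.
* No probabilistic sensitivity analysis — the one-way tornado quantifies
  influence, not joint parameter uncertainty.
* Only direct NHS costs; no societal or indirect costs.
* The constrained scenario redirects unmet demand into waiting in-state; it
  does not model waiting-list dynamics or excess mortality while waiting
  beyond the source state's own mortality.
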