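---
title: "Methods: the AI-triage cost-benefit model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the AI-triage cost-benefit model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdcba)
```

## The decision problem

Suspected Parkinson's disease (PD) in patients aged 65+ is conventionally
confirmed with dopaminergic PET imaging. PET is costly, takes hours per
visit, and a fraction `u` of patients forgo it because of out-of-pocket
burden. The intervention modelled here inserts AI software that reads
susceptibility-weighted MRI for nigrosome-1 signal loss before any PET
decision: AI-negative patients without burden skip PET; AI-positive
patients with burden are routed into reimbursable PET they would
otherwise have forgone. The model is a one-period classification
economy: a single year, no disease progression, no mortality, no
queueing.

## Cohort structure

A national cohort of `n_total = n_PD / r` assessed patients (with `r`
the PD diagnostic rate among the suspected population) is split by five
binaries: PD status, economic burden (`u`), AI-arm assignment (adoption
`a`), AI/MRI detection (sensitivity `Se`, specificity `Sp`), and PET
detection (`Se_PET`), giving 24 mutually exclusive patient types
(`patient_types()`); types 13–24 are the conventional arm and accrue no
marginal costs or benefits. The published record constrains only the
8-way collapse of this classification (PD status × burden × AI call),
exposed as `subgroup_counts()`; the full 24-way expected partition
(`expected_type_counts()`) additionally factorises PET outcomes with
`Se_PET`/`Sp_PET` under independence and is documented as an
extrapolation.

## The term engine

Eighteen additive terms price the difference between the arms, each a
product of a cohort count (`n_PD`, `n_nonPD`, `n_total`), stratum
probabilities (`u` or `1-u`, `a`, test accuracies), and exactly one unit
cost. `term_definitions()` prints the full table. Unit inputs and
defaults (bundled Korean set): PET scan 735 USD; AI read 7.06 USD
(10,000 KRW at 1,416.54 KRW/USD); annual treatment cost 4,062 USD after
early and 4,753 USD after delayed diagnosis; and for the societal
perspective a time value of `persons × wage × employment × hours` =
2 × 14.6 × 0.396 × 4 USD per avoided/incurred PET visit plus
2 × 18.2 USD transport. The US set (PET 2,587; AI 100; treatment
24,439/30,439 USD) runs under the healthcare-system perspective, which
forces the seven non-medical terms (MB5–MB7, MC8–MC11) to zero.

### Formula variants

The model ships two term sets. `as_printed` transcribes the published
formula table verbatim. That table does not regenerate its own result
table for five terms: the tabulated values require MC1 to carry
`(1 − Se)` rather than `Se`, and MC8–MC11 to carry `Se × Se_PET` rather
than `(1 − Se) × Se_PET`. `table_consistent` applies exactly those five
corrections and is the default everywhere, because the tabulated results
are the quantities the analysis is accountable to; the verbatim set is
retained for transparency and the CLI logs the reconciled terms whenever
the default is active. Two of the published inputs are also carried in
both a printed and an unrounded form (`korea.yaml` vs
`korea_unrounded.yaml`: AI cost 7 vs 10,000/1,416.54 USD, AI specificity
0.917 vs 0.9167). Either file reproduces the published net benefit to
≤ 0.03%; the subgroup counts are reproduced exactly by the printed
specificity, so `subgroup_counts()` examples use `korea.yaml`.

### Aggregation

`NB = Σ MB − Σ MC` and `B/C = Σ MB / Σ MC`. Under the default
`published` aggregation the cost sum excludes MC10: at `r = 0.5` the two
transportation cost terms MC10 and MC11 are numerically identical, and
the published net benefit and B/C ratio are recovered only when one of
the pair is counted. Which twin is dropped is a convention — they cannot
be distinguished at that diagnostic rate. `all_terms` sums all eleven
costs for users who prefer the literal total. Negative nets are allowed
(no flooring) so sensitivity sweeps can cross zero; a zero cost side
reports an undefined (NA) B/C ratio rather than an error. Internal
arithmetic is never rounded; presentation uses half-up rounding
(`round_half_up()`, matching the printed tables) with B/C to two
decimals.

## Scenario machinery

**Adoption sweeps.** Every term is linear in `a`, so
`NB(a) = (a/a0) NB(a0)`; `adoption_sweep()` tabulates the standard 30 /
65 / 100% scenarios.

**One-way sensitivity.** `one_way_sensitivity()` re-evaluates the net
over a grid of one parameter, all else fixed, reporting ratios to the
base case. Since every term is linear in `u` or `1 − u`, the net is
affine in `u` and changes sign at most once.

**Break-even AI price.** The net is affine in `c_AI` with slope `−S`,
`S = a(n_total(1−u) + n_PD·u + n_nonPD·u) = a·n_total`, giving the
closed form `c* = (NB(c0) + S·c0)/S`, verified internally to a residual
below 1e-9 relative. `c*` can be negative (the strategy cannot break
even at any non-negative price); the verification therefore bypasses the
non-negativity constraint on `c_AI`. With no AI usage (`S = 0`) the
break-even price is undefined and returned as `NA`. The bundled Korean
configuration yields a break-even near 324 USD; a previously circulated
figure of 226 USD for that configuration is not recoverable from any
variant/aggregation combination of this model and is deliberately not a
package claim, whereas the US figure (≈ 1,507 USD) reproduces.

**Long-term projection.** `project_long_term()` re-evaluates the
one-year model per calendar year with that year's adoption and cohort
size. Defaults: linear adoption ramp from the base rate to 80% over 10
years then flat (a transparent diffusion baseline; a logistic S-curve
reaching the same target is available since real uptake is often
nonlinear), constant cohort, and a 0% discount rate (the one-year terms
carry no time preference; long-horizon users can set a conventional 3–5%
rate). Cumulative values are prefix sums of the (discounted) annual
nets. Because the prevalence-growth series any real projection needs is
setting-specific and not bundled, the projection is a parameterised
engine, not a reproduction of any particular published trajectory.

## The microsimulator

`simulate_cohort()` samples `n` patients with the exact independence
structure the closed forms assume: PD status ~ Bernoulli(`r`), burden ~
Bernoulli(`u`), AI arm ~ Bernoulli(`a`), AI call ~ Bernoulli(`Se`) for
PD and Bernoulli(`1 − Sp`) otherwise, PET detection ~
Bernoulli(`Se_PET`). One generator is seeded per cohort and each patient
consumes six uniforms in fixed field order, so cohorts are
bit-reproducible. Each term becomes an event-level accrual rule
(benefits positive, costs negative); the table-consistent MC9/MC11
factors apply the PD-test sensitivities to the burdened non-PD stratum,
so the simulator draws a dedicated auxiliary Bernoulli(`Se`) indicator
for those triggers — this keeps every term's Monte-Carlo expectation
exactly equal to its closed form, which is the point of the module: a
stochastic oracle, not a richer disease model. The same uniform is read
against `Se_PET` for accrual triggers and against `1 − Sp_PET` for the
realized PET outcome used only in type assignment. Aggregates are scaled
to `n_total` and reported with a standard error from the per-patient
variance.

What passing microsim tests show: the closed forms and the event rules
describe the same joint distribution. What they do not show: anything
about real patients — correlations between disease, burden and adoption
are assumed away, treatment-cost differences are a single annual
increment, and AI accuracy is held at trial values.

## Numerical choices and problem sizes

Validation rejects out-of-range inputs by field name; probabilities live
in [0, 1] (`r` strictly positive), counts and money are non-negative.
Config round trips are bit-identical (YAML written at 17 significant
digits, JSON likewise). The test suite exercises the oracle equivalence
of the term engine against a literal product transcription at 1e-9
relative tolerance on randomized parameter sets, collinearity and
linearity properties at 1e-9–1e-12, bisection against the closed-form
break-even at 1e-6, and microsim convergence per term within 3–4
binomial standard errors at cohorts of 4×10^5–10^6 sampled patients —
sizes chosen so the whole suite runs in seconds while leaving Monte-
Carlo noise well below the tolerances tested.

## Known limitations

One-period model: no progression, mortality, capacity constraints or
repeat testing. The 24-type PET factorisation is an extrapolation beyond
the published aggregates. The projection engine's defaults are
deliberately neutral (constant cohort, no discounting) and will not
match any specific national forecast without user-supplied growth
inputs. The five-term formula reconciliation is a documented judgement
call: the package follows the tabulated values, not the printed
formulas, and keeps both sets inspectable.
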