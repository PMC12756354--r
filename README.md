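# pdcba

Cost–benefit analysis of AI-assisted MRI triage for Parkinson's disease
(PD) diagnosis.

## The problem

Confirming early idiopathic PD often requires dopaminergic imaging
(FDG-PET), which is expensive, time-consuming and unevenly accessible;
some patients forgo it entirely for financial reasons. Deep-learning
software can instead read susceptibility-weighted MRI for nigrosome-1
signal loss (the "swallow-tail sign") and triage who actually needs the
confirmatory PET scan. `pdcba` implements a decision-analytic model that
prices this triage strategy against the conventional PET-first pathway
for a one-year national cohort, for health-economics and HTA audiences.

## The model

A cohort of `n_total = n_PD / r` suspected patients (`r` the PD
diagnostic rate) is partitioned by five binaries — true PD status,
economic burden for PET (rate `u`), AI-arm assignment (adoption rate
`a`), AI/MRI detection (Se, Sp), PET detection (Se_PET) — into 24
mutually exclusive patient types. The marginal economy of the AI arm is
the sum of 18 additive terms, each a product of a cohort count, pathway
probabilities and a unit cost, e.g.

```
MB1 = n_PD (1-u) a (1-Se) c_PET          avoided PET scans (AI-negative PD, no burden)
MB2 = n_nonPD (1-u) a Sp c_PET           avoided PET scans (correctly excluded non-PD)
MC3 = n_total (1-u) a c_AI               AI licensing fees
MB4 = n_PD u a Se Se_PET c_delayed       delayed-treatment costs avoided
...
```

Decision metrics are the **net benefit** `NB = Σ MB − Σ MC` and the
**benefit–cost ratio** `Σ MB / Σ MC`. Every term is linear in `a` and in
each unit cost, which yields a closed-form break-even AI price
`c* = (NB(c0) + S·c0)/S` with `S = a·n_total` the AI-applied scan
volume. Two bundled country parameterisations are included: South Korea
(societal perspective, time and transport costs included) and the United
States (healthcare-system perspective, direct medical costs only). A
patient-level Monte-Carlo microsimulator samples individual trajectories
with the same statistical structure and cross-validates every closed
form. See the methods vignette (`vignettes/pdcba-methods.Rmd`) for the
full term table, the formula-variant reconciliation and the aggregation
convention.

## Worked example

```r
library(pdcba)
korea <- read_parameters(pdcba_example("korea_unrounded.yaml"))
pd_cba(korea, adoption = 0.3)
#> AI-triage cost-benefit scenario - South Korea (unrounded inputs)
#>   perspective: societal | adoption: 30% | variant: table_consistent | aggregation: published
#>   Total benefit: 28,747,518 USD
#>   Total cost:    19,459,230 USD
#>   Net benefit:   9,288,288 USD
#>   B/C ratio:     1.48
```

A 30%-adoption AI strategy saves the Korean system ≈ 9.29 million USD
net in one year, returning 1.48 USD per USD spent. The US model gives
76.0M USD at 30% adoption (B/C 1.36) and a break-even AI price of
≈ 1,507 USD per scan:

```r
usa <- read_parameters(pdcba_example("usa.yaml"))
break_even_ai_cost(usa)
#> [1] 1506.621
```

The triage effect on PET utilisation:

```r
subgroup_counts(read_parameters(pdcba_example("korea.yaml")))
#> Cohort subgroups - South Korea (printed inputs)
#>   total assessed: 97,776
#>     count pct_of_total
#> A1 32,271        33.0%
#> A2  1,951         2.0%
#> B1 31,381        32.1%
#> ...
```

B1 (31,381 patients, 32.1%) are non-PD patients the AI correctly rules
out of PET; C1 (13,830) are burdened PD patients who gain PET access;
A2 (1,951) are missed PD cases; D2 (1,217) are unnecessary scans from
false positives. Scenario tooling: `adoption_sweep()`,
`one_way_sensitivity()`, `project_long_term()`, `simulate_cohort()`,
and `render_table4()` for the side-by-side country table. A thin CLI
wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/pdcba.R", package="pdcba"))') \
  reproduce --out results/
```

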