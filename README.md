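# phoscea

Cost-effectiveness of second-line **lanthanum carbonate (LC)** versus
continued **calcium-based phosphate binders (CB)** for hyperphosphatemia
in chronic kidney disease (CKD), from the Spanish public-payer
perspective (EUR, 2013). The package is for health economists and
nephrology HTA analysts who want a fully reproducible, testable
re-implementation of this published decision model — every input,
convention and assumption exposed as data, not buried in a spreadsheet.

## The model

A decision tree splits a cohort of 1,000 predialysis patients by
first-line CB response (44.5%); under the second-line strategy,
non-responders receive LC (38.3% respond) and trial failures switch
back to CB after 8 weeks. Each subgroup then runs through a three-state
Markov cohort model (predialysis → dialysis → death; annual cycles,
40-year cap, half-cycle correction, 3% discount). Serum phosphorus (SP)
drives the clinical benefit: mortality is adjusted by SP-stratified
relative risks, `p = 1 − (1 − p₀)^RR`, and progression to dialysis by
`RR = 1.19^max(0, SP − 4.6)` per mg/dL above target. Costs cover drugs
(LC €1,702/€2,042 per year predialysis/dialysis; CB average €49/€93)
and dialysis (€42,556 per patient-year, charged in the base case only
for dialysis time attributable to faster progression — dialysis in
added life years is an unrelated future cost). Strategies are compared
by incremental cost, QALYs, dominance, ICER and net monetary benefit
(NMB = λ·ΔQALY − ΔCost, λ = €30,000/QALY).

The one input with no published value — dialysis baseline annual
mortality — is set by a documented calibration
(`calibrate_dialysis_mortality()`, see `analysis/01_calibration.R`).

## Worked example

```r
library(phoscea)
params <- load_parameters(system.file("extdata", "params_basecase.yaml",
                                      package = "phoscea"))
ce <- run_ce(params)
print(ce)
#> Cost-effectiveness: second-line LC vs continued CB
#>   QALYs (cohort):   CB 4435.1   LC 4620.7   delta 185.56
#>   Total cost (EUR thousand): CB 6,178   LC 2,705   delta -3,474
#>   Dialysis-free years gained: 132.7
#>   ICER per QALY: dominant
#>   NMB at EUR 30,000/QALY: EUR 9,040 thousand
```

Reading: over the lifetime horizon the LC strategy delays dialysis by
132.7 discounted patient-years per 1,000 patients. Those avoided
dialysis years save more than LC's extra drug cost, so LC is cheaper
*and* more effective — a dominant strategy (no ICER is quoted for
dominance). Per patient that is 4.621 vs 4.435 QALYs and €2,705 vs
€6,178.

Scenario and probabilistic analyses:

```r
run_scenarios(base = params)       # S1-S10 one-way scenarios
psa <- run_psa(params, psa_spec(n_iterations = 1000), seed = 1)
print(psa)
#> PSA: 1000 iterations (seed 1)
#>   LC dominant in 98.9% of iterations
#>   cost-effective at EUR 30,000/QALY: 99.7%
```

The numbered drivers under `analysis/` run the full workflow
(`01_calibration.R`, `02_base_case.R`, `03_scenarios.R`, `04_psa.R`)
and write their tables under `results/`.

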