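# cefapop

Population pharmacokinetics of intravenous cefazolin and Monte Carlo
derivation of an fT>MIC-based PK/PD susceptibility cutoff.

## The problem

Cefazolin is the standard prophylactic antibiotic for dogs undergoing
surgery, given as a 25 mg/kg intravenous bolus. Like all beta-lactams it
kills time-dependently: efficacy tracks the fraction of the dosing
interval during which the *free* (unbound) serum concentration exceeds
the pathogen's minimum inhibitory concentration (fT>MIC), with ≥50% of
the interval the usual target. Setting a susceptibility-testing
breakpoint for a whole patient population therefore needs two things: a
population pharmacokinetic model that captures between-subject
variability in an all-comer clinical caseload, and a Monte Carlo
simulation that asks, for each candidate MIC, whether 90% of that
population attains the target under the clinical regimen. The largest
MIC that passes is the PK/PD cutoff.

`cefapop` implements that entire workflow for the two-compartment IV
bolus setting, plus a synthetic study generator that emulates the
perioperative canine study design (78 dogs, 2–11 samples per dog at
nominal times between 5 and 480 min), so every stage is testable without
clinical data. It is aimed at pharmacometricians and veterinary clinical
pharmacologists who want a transparent, fully scripted version of this
analysis chain.

## The model

Disposition: two-compartment with bolus input, parameterized as central
and peripheral volumes V1, V2 (L/kg), serum clearance CL and
intercompartmental clearance Q (L/kg/min); hybrid slopes

    beta  = ½[(Q/V1 + Q/V2 + CL/V1) − √((Q/V1 + Q/V2 + CL/V1)² − 4(Q/V2)(CL/V1))]
    alpha = (Q/V2)(CL/V1)/beta

Statistics: exponential between-subject variability on all four
parameters with a full 4×4 omega covariance (η jointly normal,
CV% = 100·√(exp(ω²)−1)); combined residual error
C = f·(1+ε₁) + ε₂; covariates as power terms on scaled continuous
values ((BW/20)^θ, age/8, creatinine/0.9, surgery time/80) and linear
indicator terms for health status, breed and sex. Estimation is a
FOCE-type conditional (Laplace) approximation with interaction,
minimized by quasi-Newton over log typical values, log-Cholesky omega
factors and log residual SDs. Covariate selection is stepwise under BIC
thresholds 6.635 (add) / 10.823 (delete); precision comes from a
subject-level nonparametric bootstrap; model adequacy from a visual
predictive check. The PTA engine draws 2500 subjects from the fitted
population, computes each subject's total time above MIC/f_u (f_u =
0.64) under 25 mg/kg q6h × 4 over 24 h, and reports the times attained
by 90% and 95% of subjects per MIC, plus the cutoff.

## Worked example

```r
library(cefapop)

ds <- generate_study(generator_config(n_subjects = 30), seed = 42)
ds
#> Study dataset: 30 subjects, 252 observations, 30 dose events
#>   time range 5-480 min; 10 observation(s) below LOQ

fit <- fit_popmodel(ds)
fit
#> Population PK estimate (two-compartment IV bolus)
#>   tvV1 0.1394 L/kg | tvV2 0.1421 L/kg | tvCL 0.003462 L/kg/min | tvQ 0.006285 L/kg/min
#>   BSV (CV%): V1 52.1 | V2 18.5 | CL 34.1 | Q 32.3
#>   sigma: prop 0.2516, add 0.3167 ug/mL
#>   OFV 1668.089 | BIC 1755.912 | 16 parameter(s) | 242 observation(s) | converged: TRUE

draws <- simulate_population(fit, n_subjects = 2500, seed = 7)
pta_table(draws, pta_config())
#> Probability of target attainment (time above MIC/fu)
#>   mic threshold time_q90 pct_q90 time_q95 pct_q95
#>  0.25     0.391   1207.8    83.9   1065.3    74.0
#>  0.50     0.781   1043.0    72.4    919.3    63.8
#>  1.00     1.560    883.2    61.3    780.6    54.2
#>  2.00     3.120    720.8    50.1    640.1    44.5
#>  4.00     6.250    557.1    38.7    495.8    34.4
#>  8.00    12.500    390.3    27.1    343.2    23.8
#> PK/PD cutoff: 2 mg/L (>= 50% of a 1440-min horizon in 90% of subjects)
```

The study here is simulated (30 dogs for speed; `generator_config()`
defaults to the full 78-dog design). The fit returns the typical values
(e.g. clearance 0.00346 L/kg/min), the between-subject CV% per
parameter, the residual SDs, and the objective (−2 log-likelihood) with
its BIC. The PTA table reads, for each MIC, the total-serum threshold
(MIC/0.64), the time above it attained by at least 90% (and 95%) of the
simulated population in minutes and as a percent of 24 h; at MIC
2 mg/L, 90% of subjects stay above threshold for 50.1% of the day, so
2 mg/L attains the 50% target and is the cutoff.

Other entry points: `stepwise_search()` (covariate model building),
`bootstrap_popmodel()` (precision), `vpc()` (predictive check),
`empirical_bayes()` / `gof_tables()` (diagnostics), and
`run_pipeline()` which chains everything from one seeded configuration
and writes stamped result tables plus a machine-readable summary.

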