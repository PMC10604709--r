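# adapopk

Population pharmacokinetics of adalimumab for therapeutic drug monitoring
in inflammatory bowel disease (IBD).

Adalimumab trough concentrations between 8 and 12 mg/L predict mucosal
healing, but exposure is highly variable: clearance rises steeply as serum
albumin falls and roughly 5.5-fold once anti-adalimumab antibodies (AAA)
appear. Model-informed precision dosing fits a population pharmacokinetic
model to each patient's sparse trough history and forecasts the next
trough from the patient's empirical Bayes estimates (EBEs). `adapopk`
implements that workflow as an R package:

* a one-compartment model with first-order subcutaneous absorption and
  linear elimination,
  `C(t) = D·ka / (V(ka − ke)) · (e^(−ke·t) − e^(−ka·t))`, superposed over
  arbitrary dose histories (stable through the flip-flop point `ka ≈ ke`);
* the covariate model
  `CL/F = CLpop · (1 + AAA·θ_AAA) · (ALB/3.77)^θ_ALB` with the published
  parameter sets built in (`reference_params()`, `final_params()`);
* Laplace-approximate population estimation (`pkfit()`) with lognormal
  interindividual variability on CL and V, combined or proportional
  residual error, optional informative lognormal priors (MAP), analytic
  inner derivatives and curvature-based standard errors;
* likelihood-ratio covariate selection (forward/backward at p < 0.01),
  case-resampling bootstrap validation;
* the full evaluation suite: leave-last-trough-out bias (MPE) and
  imprecision (RMSPE) with bootstrap comparison intervals,
  prediction-corrected VPC, numerical predictive check, NPDE, and a
  clinical-impact table of true/false positives against the 8–12 mg/L
  target;
* a synthetic-cohort generator (`cohort_design()`, `simulate_cohort()`)
  emulating the sparse trough-monitoring design (54 subjects, 160/80 mg
  induction, 40 mg every other week, 2–4 troughs each), so the whole
  pipeline runs and is tested without patient data.

## Worked example

```r
library(adapopk)

## a synthetic cohort at the study design, generated from the published
## final model, with the last trough of each subject held out
sim    <- simulate_cohort(cohort_design(seed = 42), final_params())
cohort <- hold_out_last(sim$cohort)

fit <- pkfit(cohort)   # ka and the AAA effect fixed; ML estimation
fit
#> Population PK fit (Laplace ML estimation)
#>   54 subjects, 150 observations; OFV = 607.859; converged
#>          estimate rse_pct     lo95     hi95 fixed
#> cl_pop    0.03647  10.586  0.02963  0.04487 FALSE
#> v_pop     7.99915  35.879  3.95949 16.16028 FALSE
#> ka_pop    0.00625      NA       NA       NA  TRUE
#> cov_aaa   4.50000      NA       NA       NA  TRUE
#> cov_alb  -2.91829  19.239 -4.01872 -1.81785 FALSE
#> omega_cl  0.56140  12.115  0.44274  0.71186 FALSE
#> omega_v   0.54300  52.466  0.19418  1.51843 FALSE
#> err_add   0.00000      NA       NA       NA  TRUE
#> err_prop  0.51441   8.043  0.43939  0.60224 FALSE
```

The estimates sit close to the generating values (CL/F 0.0312 L/h, albumin
exponent −2.33, ω_CL 0.667, proportional error 0.547); the wide interval on
ω_V reflects that trough-only data barely identify volume variability —
the same reason the original analysis stabilised it with an informative
prior:

```r
fit_map <- pkfit(cohort, priors = pk_priors("omega_v", 0.48, 0.19))
```

Predictive performance against the held-out troughs:

```r
pairs <- leave_last_out(cohort, fit)
c(bias = mpe(pairs), imprecision = rmspe(pairs))
#>        bias imprecision
#>  -0.7217225   2.4276450
```

A negative bias of −0.7 mg/L means the model slightly underpredicts the
held-out troughs on this cohort; imprecision of 2.5 mg/L is the root mean
square forecast error. `bootstrap_performance()` attaches 95% intervals and
between-model difference tests, `pcvpc()` / `npc()` / `npde()` provide the
simulation diagnostics, and `impact_table(pairs)` classifies the forecasts
against the 8–12 mg/L window.

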