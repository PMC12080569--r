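# dapapkpd

Population pharmacokinetic–pharmacodynamic (PK-PD) modelling of once-daily
oral dapagliflozin — an SGLT2 inhibitor used in type 2 diabetes — and its
HbA1c-lowering effect, built for the real-world study design this class of
analysis is run on: ~85 outpatients, 5 mg once daily for a year, trough-only
plasma sampling and HbA1c at visits around months 1, 3, 6, 9 and 12.

The package is aimed at pharmacometricians and biostatisticians who want a
fully scripted, testable version of this analysis: structural models,
estimation, covariate selection, model qualification and dose simulation are
ordinary R functions operating on data frames, so every stage can be rerun,
perturbed and verified on synthetic cohorts with known truth.

## The models

**PK** — one-compartment, first-order absorption, multiple oral dosing, with
absorption rate constant (ka = 57.4 /day) and apparent volume
(V/F = 73.9 L) fixed (trough-only data cannot identify them) and a
body-weight power covariate on apparent clearance:

    CL/F = theta_CL * (BW / 77.0)^theta_BW,   CL/F_i = CL/F * exp(eta_i)

Body weight may drift during treatment; the weight in force (last
observation carried forward) sets the elimination rate of each dose, keeping
the superposition analytic. Residual error is proportional.

**PD** — HbA1c turnover (indirect response) with an Emax drug effect and a
5.0 % normoglycaemic floor:

    dH/dt = kin - Efc(C) * (H - 5.0)/(8.0 - 5.0) - kout * H
    Efc(C) = Emax * C / (EC50 + C),  kout = ln2 / t_half,  kin = kout * H(0)

Emax is the maximal lowering rate for a reference patient at 8.0 % HbA1c;
the scaling term makes the response self-limiting as HbA1c falls. Each
patient's baseline fixes H(0); the HbA1c half-life carries the random
effect; residual error is additive.

**Estimation** is first-order conditional (FOCE/Laplace with interaction)
approximate marginal likelihood, with the PD model fitted sequentially on
the post hoc individual PK parameters (IPP). Covariate selection is
stepwise (forward p < 0.01, backward p < 0.001 on -2LL). Qualification uses
prediction-corrected visual predictive checks and a nonparametric
(subject-resampling) bootstrap.

## Worked example

```r
library(dapapkpd)

spec  <- cohort_spec(seed = 104)            # 85 virtual patients, study design
tab   <- generate_event_table(draw_cohort(spec), spec)

pk_fit <- fit_pk(exclude_blq(tab))          # FOCE, BW power model on CL/F
tidy(pk_fit)
#>   parameter  estimate      se cv_pct reported
#> 1 theta_cl   229.     3.58      1.57  229.
#> 2 theta_WT     0.372  0.103    27.7     0.372
#> 3 omega2_cl    0.0177 0.00318  18.0    13.3
#> 4 sigma_prop   0.381  0.0166    4.35   38.1

pd_fit <- fit_pd(tab, pk_fit)               # sequential turnover-model fit
tidy(pd_fit)
#>   parameter    estimate       se cv_pct reported
#> 1 t_half        18.5     4.95     26.7   18.5
#> 2 emax           0.0273  0.0210   77.0    0.0273
#> 3 ec50          18.3    29.3     160.    18.3
#> 4 omega2_thalf   0.895   0.242    27.1  120.
#> 5 sigma_add      0.231   0.00893   3.86   0.231
```

The cohort was generated at the published estimates (CL/F 229.3 L/day,
exponent 0.41, IIV 13.9 %, sigma 39.8 %; t_half 16.1 d, Emax 0.034 %/day,
EC50 23.7 ng/mL, IIV 103.9 %, sigma 0.24 %), so the `estimate` column can be
read as a recovery check: clearance, its variability and both residual
errors come back tightly; the wide CV% on EC50 is the honest answer for a
single-dose-level, trough-only design — see the identifiability section of
the methods vignette (`vignettes/dapagliflozin-hba1c-model.Rmd`).
`reported` gives the conventional scales (IIV as CV %, proportional error
as %).

One-year dose scenarios on a 1000-subject virtual population:

```r
sc5  <- simulate_scenario(5,  spec = cohort_spec(n_subjects = 1000, seed = 1))
sc10 <- simulate_scenario(10, spec = cohort_spec(n_subjects = 1000, seed = 1))
sc5
#> <pkpd_scenario> 5 mg once daily, 1000 subjects, 365 days
#>   end of treatment: median 6.59% (5-95%: 5.77-7.51)
sc10
#> <pkpd_scenario> 10 mg once daily, 1000 subjects, 365 days
#>   end of treatment: median 6.53% (5-95%: 5.71-7.47)
compare_scenarios(sc5, sc10)
#> <scenario_comparison> 10 vs 5 mg: end-of-treatment median difference -0.061 HbA1c %
```

Starting from a median baseline of 6.8 %, a year of 5 mg brings the median
HbA1c to ~6.6 % and doubling the dose buys less than 0.1 % more — the 5 mg
dose already sits high on the Emax curve. `autoplot(sc5, sc10)` overlays the
trajectories; `run_vpc()`, `run_bootstrap()` and `stepwise_select()` cover
qualification and covariate screening, and `run_pipeline()` drives all
stages from a YAML config (a thin CLI wrapper lives in `inst/cli/`).

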