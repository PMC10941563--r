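# lactpbpk

Physiologically based pharmacokinetic (PBPK) assessment of drug exposure in
breastfed infants, built around primaquine (PQ) as the worked case.

## The problem

Primaquine is the drug that clears the dormant liver stage of *Plasmodium
vivax* malaria, but treatment guidelines withhold it from lactating women
because of the theoretical risk of hemolysis in a G6PD-deficient nursing
infant. The question the package addresses is quantitative: given the
mother's 0.5 mg/kg once-daily regimen, how much primaquine does a breastfed
infant — or a neonate, for whom no clinical data can be collected — actually
receive through milk, and what plasma exposure does that produce? The
audience is pharmacometricians and clinical pharmacologists who want an open,
testable lactation-PBPK pipeline rather than a closed commercial simulator.

## The model

The pipeline chains five quantitative components:

**Plasma protein binding.** PQ binds α₁-acid glycoprotein (AAG). A
single-site, non-saturable model, bound/free = *K*ₐ·[AAG], is anchored at the
observed fu = 0.33 at the pregnancy AAG of 0.6 g/L, so

  fu(AAG) = 1 / (1 + *K*ₐ·AAG),  *K*ₐ = (1 − fu_ref)/(fu_ref·AAG_ref).

**Milk-to-plasma partition.** A phase-distribution model: the unbound,
un-ionized base equilibrates between plasma (pH 7.4) and the skim and fat
phases of milk,

  M/P = (1 − f_fat)·S + f_fat·F,
  S = fu_p·(1 + 10^(pKa − pH_milk)) / ((1 + 10^(pKa − pH_plasma))·fu_skim),
  F = fu_p·f_unionized(pH_plasma)·10^(0.99·logP − 0.88),

with the milk/plasma binding-protein scalar calibrated once against the
predicted M/P of 0.47 in mature milk (pH 7.2, 4% fat) and then frozen.

**Infant daily dose arithmetic.** IDD = M/P · maternal C_avg · intake/1000
(μg/kg/day at 150 mL/kg/day intake), RIDD = 100·IDD/maternal dose, with the
daily dose split over six feeds 4 h apart.

**A lumped PBPK engine.** First-order oral absorption passes through a
well-stirred liver (first-pass availability F_h = Q_h/(Q_h + fu_b·CL_int)),
then two-compartment disposition with well-stirred hepatic elimination
CL_h = Q_h·fu_b·CL_int/(Q_h + fu_b·CL_int). Per subject, each pathway's
intrinsic clearance scales as

  CL_int = CL_int,adult (L/h per kg liver) × liver mass × hepatic capacity
           maturation × enzyme ontogeny fraction,

with MAO-A carrying 90% and CYP2D6 10% of adult clearance. The two free
adult parameters (total CL_int and V_c/kg) are calibrated to the observed
day-14 maternal exposure (Cmax 129 ng/mL, AUC 988 ng/mL·h).

**Virtual populations and trials.** Age/sex anthropometry from the published
pediatric growth polynomials, allometric liver mass and blood flow, AAG and
enzyme maturation curves, and lognormal between-subject variability, run as
"10 trials of N subjects" mirroring each clinical study design.

A synthetic-data module generates sparse, noisy, LLOQ-censored "observed"
datasets and closes the loop: recover the IDD from synthetic milk samples and
re-simulate the infant.

## Worked example

```r
library(lactpbpk)

# binding: pregnancy -> postpartum unbound fraction
bm <- affinity_from_fu(0.33, 0.6)
fu_at_aag(bm, 0.7)
#> [1] 0.2968516

# milk transfer at mature-milk composition (pH 7.2, 4% fat)
pq <- primaquine_parameters()
mp_ratio(pq, milk_preset("mature"), postpartum_fu(pq))$mp_ratio
#> [1] 0.47

# dose arithmetic
idd_from_cumulative(0.127, 14)   # highest IDD, ug/kg/day
#> [1] 9.071429
ridd(2.98, 500)                  # relative infant daily dose, %
#> [1] 0.596

# calibrate the mother model and run a 10 x 20 infant study
cal <- calibrate_adult()
cal$achieved
#>     cmax      auc
#> 128.9999 988.0000
mother <- run_trial_set(scenario_mother_lactation(cal))
infant <- run_trial_set(scenario_infant(cal, idd = 2.98))
infant
#> Virtual study 'infant_idd_2.98': 10 trials x 20 subjects (seed 202)
#>   pooled Cmax  ng/mL : median 0.1509 [p5 0.09284, p95 0.2439]
#>   pooled AUC ng/mL*h : median 2.908 [p5 1.602, p95 4.941]
relative_exposure(infant, mother)
#>  cmax_pct   auc_pct
#> 0.1198371 0.3044093
```

The last numbers are the point of the analysis: a breastfed infant receiving
the average milk-derived daily dose reaches a median Cmax around 0.15 ng/mL —
roughly a thousandth of the mother's, below the 1–2 ng/mL assay limit, and a
relative Cmax of ~0.12%, far below the 10% RIDD safety threshold.

## The analysis workflow

The `analysis/` directory holds the numbered drivers of the full study, each
a thin narrative script over the package functions, writing its tables under
`results/`:

1. `01_dose_arithmetic.R` — binding and IDD/RIDD desk arithmetic
2. `02_milk_transfer.R` — M/P calibration, fat and pH sensitivity
3. `03_calibrate_maternal.R` — adult model calibration
4. `04_maternal_trials.R` — 10×20 maternal virtual study
5. `05_children_verification.R` — school-age verification cohorts
6. `06_infant_exposure.R` — infant exposure at average and highest IDD
7. `07_neonate_scenarios.R` — neonates under MAO-A ontogeny assumptions
8. `08_sensitivity_aag.R` — four-fold AAG sensitivity scans
9. `09_synthetic_recovery.R` — synthetic-data full-loop IDD recovery

Each accepts `--seed <int>`; every run is reproducible from its seed and
config.

## Vignette

`vignettes/lactation-pbpk-methods.Rmd` documents the model equations and
assumptions, the maturation and variability defaults with their rationale,
the numerical choices, what the synthetic data do and do not emulate, and the
known limitations.
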