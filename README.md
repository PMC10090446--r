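# polybpk

Nonparametric population pharmacokinetics and Monte Carlo dosing
simulation for intravenous polymyxin B in critically ill patients.

Polymyxin B is a last-line antibiotic against carbapenem-resistant
gram-negative infections. Critically ill patients — with low serum
albumin, high APACHE-II scores and unstable renal function — clear and
distribute the drug very differently from healthy subjects, and the
therapeutic window is narrow: efficacy requires a total-drug
AUC/MIC ≥ 50 (free-drug fAUC/MIC ≈ 20 at an unbound fraction of 0.42),
while steady-state AUC₀₋₂₄ₕ > 100 mg·h/L signals nephrotoxicity risk.
This package implements, end to end, the workflow used to characterise
that trade-off from sparse therapeutic-drug-monitoring data:

* **Structural model** — one/two-compartment intravenous-infusion
  disposition, `dX₁/dt = R(t) − (CL/Vc + Q/Vc)X₁ + (Q/Vp)X₂`,
  `dX₂/dt = (Q/Vc)X₁ − (Q/Vp)X₂`, solved in closed form (spectral matrix
  exponential per infusion segment), with the steady-state identity
  `AUC_ss,24h = daily dose / CL`.
* **Residual error** — multiplicative polynomial model
  `SD = C₀ + C₁C + C₂C² + C₃C³` scaled by a fitted process-noise factor
  γ.
* **Population estimation** — nonparametric adaptive-grid (NPAG) maximum
  likelihood: the population distribution of (CL, Vc, Q, Vp) is a set of
  support points with weights, refined over shrinking grids, with EM
  weight optimisation and per-cycle golden-section re-estimation of γ.
* **Covariates** — Cockcroft–Gault creatinine clearance, OLS screening of
  posterior estimates, power-law effects
  (`CL = CL₀(ALB/31.45)^−0.95`, `V = V₀(age/68)^0.95`) and stepwise
  selection by the Δ(−2LL) > 6.63 (χ², df 1, p < 0.01) **or** R²pop
  improvement rule.
* **Validation** — goodness-of-fit tables with weighted residuals,
  subject bootstrap, 80/20 data-splitting, visual predictive check.
* **Dosing simulation** — Monte Carlo probability of target attainment
  over regimens I–V (100/75/60/50/40 mg q12h), MIC 0.25–4 mg/L, three
  albumin strata × three ages, with efficacy and toxicity targets.
* **Synthetic cohorts** — a generator emulating the study design
  (22 subjects, 64 samples, 37.5% troughs / 35.9% peaks / 26.6%
  mid-interval, dosing 50–150 mg over 1–2 h infusions q12h) with known
  ground truth, so the whole pipeline is testable without patient data.

See `vignettes/polymyxin-poppk-methods.Rmd` for the modelling details and
design choices.

## Worked example

```r
library(polybpk)

# simulate a study-like cohort with known truth
gen <- generate_cohort(cohort_design(), seed = 1)
gen$cohort
#> pk_cohort: 22 subjects, 64 observations (0 BLQ)

# fit the two-compartment base model
fit <- run_npag(gen$cohort, model_spec(2),
                control = npag_control(n_init = 400, max_cycles = 30,
                                       seed = 1))
fit
#> NPAG fit: 40 support points, gamma = 0.404, -2LL = 105.57 (cycle budget reached)

fit_metrics(fit, gen$cohort)
#> -2LL 105.57  AICc 116.61  BIC 126.37  R2(pop) 0.602  R2(post) 0.984  [n=64, k=5]
#>   parameter     mean  median      sd cv_pct shrinkage_pct
#> 1        CL   0.8964  0.8716  0.5012  55.91        0.8295
#> 2        Vc  15.1972  8.4803 17.7325 116.68       20.9849
#> 3         Q   6.3700  3.4302  7.3401 115.23       18.0128
#> 4        Vp 104.1903 96.3566 62.3831  59.87        6.1614
```

The fitted γ (0.40 here) is the process-noise multiplier on the assay-error
polynomial; −2LL/AICc/BIC are the model-comparison indices; R²pop and
R²post are the squared correlations of observations with population and
individual-posterior predictions (population predictions are poor under
sparse sampling, individual ones good — exactly the pattern such designs
produce); CV% is the between-subject variability of the fitted
nonparametric distribution and shrinkage measures how much posterior
means contract toward the population centre.

Dosing analysis from the published final model (no fit artifact needed):

```r
rep <- dosing_report(published_model(), n = 1000, seed = 1)
subset(rep$table, scenario == "normal/age68" & mic == 1)
#>      scenario regimen maintenance_dose mic pta_efficacy pta_toxicity
#>  normal/age68       I              100   1        1.000        0.991
#>  normal/age68      II               75   1        1.000        0.927
#>  normal/age68     III               60   1        1.000        0.748
#>  normal/age68      IV               50   1        0.991        0.501
#>  normal/age68       V               40   1        0.949        0.242
subset(rep$recommendations, mic == 1)
#>         scenario mic recommended
#>  ultra_low/age34   1          II
#>  ultra_low/age68   1         III
#>  ...
#>     normal/age68   1           V
```

Reading: normal-albumin patients have the *lowest* clearance under the
albumin-on-CL power law, hence the highest exposures — at MIC 1 mg/L
every regimen down to 40 mg q12h attains the efficacy target, while
100 mg q12h exceeds the toxicity limit in ≈99% of simulated patients (it
is a "toxic limit dose" for this stratum). The recommendation per cell is
the smallest maintenance dose with efficacy PTA ≥ 0.9 and toxicity
PTA < 0.9; low-albumin strata need larger doses (II–IV), and at MIC
4 mg/L no regimen qualifies ("none attainable").

A YAML-configurable pipeline (`pipeline_config()`, `cmd_simulate()`,
`cmd_fit()`, `cmd_covariates()`, `cmd_validate()`, `cmd_pta()`) chains
these stages and writes CSV/JSON artifacts with a run manifest.

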