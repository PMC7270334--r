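# dosedesign

Optimal-control design of personalized oral dosing schedules from
patient-specific pharmacokinetic/pharmacodynamic (PK/PD) models, with
imatinib in chronic myeloid leukemia (CML) as the worked case.

## Who this is for

Quantitative pharmacologists and computational oncologists who want to turn
(i) demographic covariates and (ii) longitudinal tumor-burden measurements
into concrete, discrete, integer-milligram dosing schedules — and to
compare those schedules against the standard regimen in silico before
anyone prescribes anything.

## What it computes

**PK.** One-compartment oral absorption with first-order elimination. A
dose $D_i$ at time $t_i$ contributes the Bateman term
$C_i(t) = \frac{f D_i k_a}{v (k_a - k_e)} (e^{-k_e(t-t_i)} - e^{-k_a(t-t_i)})$,
and profiles superpose. Clearance and volume carry demographic covariates
(body weight, sex, age): $CL = \theta_a + \theta_1 \frac{BW-\overline{BW}}{\overline{BW}} + \theta_2 q - \theta_2(1-q) + \theta_3 \frac{AGE-\overline{AGE}}{\overline{AGE}}$,
$v = \theta_b + \theta_4 q - \theta_4(1-q)$, with $q=1$ for males.

**Tumor dynamics.** A two-compartment leukemia model (cancer stem cells
feeding differentiated cells) solved in closed form. Burden series in log10
scale are fitted with two intersecting lines (`fit_biphasic()`, a 1-day
breakpoint scan); the late slope $\beta$ yields the patient's CSC death
rate $d_1 = (2a_1 - 1)p_1 - \beta/\log_{10}(e)$.

**PD.** Emax effect $E(C) = E_{max} C^n/(EC_{50}^n + C^n)$; a cohort-level
conversion constant $K$ from $\langle d_1 \rangle = K \langle E \rangle$;
patient-specific $EC_{50,j} = \bar C_j (K E_{max}/d_{1,j} - 1)^{1/n}$.

**Optimizer.** A chopped random Fourier-basis correction to the standard
dosing rate, one randomized frequency per "super-iteration", amplitudes by
Nelder–Mead, every candidate scored as the discretized integer-mg schedule
it prescribes, under one of three cost functionals: distance to an optimal
target, a step-penalized lower-bound target, or a tumor-burden + AUC
trade-off weighted by $\phi = W_1/W_2$.

**Robustness.** Intra-patient variability (per-time-point uniform noise on
$k_a$, $CL$ or $v$; quadratic law $b + a\sigma^2$) and systematic
absorption-rate error sweeps on a fixed schedule.

See `vignettes/dose-optimal-control.Rmd` for the full methods account.

## Worked example

Design a 14-day, 1-dose/day imatinib schedule for an average male patient
that keeps blood concentration above the clinical 0.57 mg/L lower bound:

```r
library(dosedesign)

pk <- pk_model(average_patient("M"))
pk
#> One-compartment oral-absorption PK model
#>   patient: average-m (M, 50 y, 70.0 kg)
#>   ka = 0.610 1/h, f = 0.98, CL = 15.10 L/h, v = 409.0 L (ke = 0.0369 1/h)

std <- standard_schedule(days = 14)                  # 400 mg/day
100 * fraction_time_above(std, 0.57, pk = pk)        # 97.0 %

prob <- control_problem(pk, cost = "lower_bound", target = 0.57, days = 14)
res <- optimize_schedule(prob, optimizer_config(), seed = 1)
res
#> Optimized dose schedule (lower_bound cost, seed 1)
#>   best cost 133.4677 (reference 211.0846; 8 super-iterations)
#> Dose schedule: 14 doses over [0, 336] h (total 5177 mg)
#>   t =   0,  24,  48,  72,  96, 120, 144, 168 h
#>   D = 543, 442, 480, 355, 282, 322, 377, 298 mg ...

100 * fraction_time_above(res$schedule, 0.57, pk = pk)   # 99.7 %
auc(std, pk); auc(res$schedule, pk)                      # 344.1 vs 319.2 mg·h/L
```

Reading: the standard regimen spends the first days below the target while
concentration builds from zero (97.0% coverage). The optimizer front-loads
day 1 (543 mg) and tapers to a maintenance level, achieving full coverage
after the sub-hour absorption ramp (99.7% of the whole horizon, i.e. 100%
at integer precision) at *lower* total exposure (AUC 319 vs 344 mg·h/L).

Fitting a tumor-burden series and extracting patient-specific PD:

```r
s <- generate_burden_series(burden_spec(noise_sd = 0.1, seed = 3))
summary(fit_biphasic(s))
#> Biphasic log10 decay fit (2 segments) for patient syn-001
#>   slope1 = -0.010002, slope2 = -0.0010033 log10/day
#>   breakpoint = 295.2 days (split scanned at day 270)
#>   R^2 = 0.9957 (pooled residuals, n = 31)
#>   rightmost slope beta = -0.0010033 +/- 2.4e-05 log10/day
#>   implied CSC death rate d1 = 0.3353 1/day (a1 = 0.87, p1 = 0.45)
```

Higher-level commands (`report_diagnosis()`, `report_burden_fits()`,
`report_adjustment()`, `report_robustness()`) run these stages over cohorts
and emit JSON/CSV reports; `inst/cli/dosedesign.R` wraps them for shell use
(`optimize-diagnosis`, `fit-burden`, `optimize-adjust`, `robustness`,
`simulate-cohort`).

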