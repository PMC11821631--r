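# tmgtwitch

Analysis of electrically evoked muscle twitches recorded simultaneously as
knee-extension **torque** (dynamometer, Nm) and **tensiomyographic (TMG)
radial muscle-belly displacement** (mm), under the interaction of
post-activation potentiation and fatigue.

A brief maximal voluntary contraction transiently *potentiates* a
subsequent twitch; prolonged effort *fatigues* it. The package is built for
protocols that track both signals across an exercise session — two
baseline twitches, one twitch after each exercise set, and repeated
twitches during recovery — and asks whether the TMG displacement
parameters can detect the potentiated or fatigued state that the peak
twitch torque defines.

## What it computes

| Stage | Functions | Output |
|---|---|---|
| Session simulation | `sim_config()`, `simulate_cohort()`, `write_cohort()` | per-subject torque/trigger/displacement traces with a configurable potentiation→fatigue trajectory |
| Signal extraction | `detect_triggers()`, `filter_twitch()`, `twitch_peak_torque()`, `displacement_params()`, `extract_mvic()` | `Pt` (Nm), `Dm` (mm), `Td`, `Tc` (ms), MVIC (Nm) |
| Derived metrics | `vc_parameters()`, `fatigue_index()`, `percent_change_table()` | contraction velocities `Vc0_10`, `Vc0_90`, `Vc10_90`, `Vcnorm`; FI (%) |
| Reliability | `reliability_table()`, `icc_a1()`, `hedges_g()`, `sem_mdc()` | bias, effect size, ICC(A,1), SEM(%), MDC(%) per parameter |
| Inference | `rm_anova()`, `bonferroni_vs_baseline()`, `flag_extremes()`, `interpolate_missing()`, `pearson_assoc()` | sphericity-corrected F tests, adjusted post hocs, correlations |
| Diagnostics | `classify_change()`, `build_contingency()`, `accuracy_metrics()`, `clopper_pearson()`, `roc_auc()`, `diagnostic_table()` | Sn/Sp/PPV/NPV/DE/YI with exact CIs, AUROC |
| Orchestration | `run_pipeline()` | all result tables + JSON summary, bit-reproducible from one seed |

The statistical core, in the field's standard notation:

- **SEM** = SD·√(1 − ICC), over all scores of both baseline trials;
  **MDC** = SEM·1.96·√2.
- **ICC(A,1)**: two-way model, absolute agreement, single rating, from the
  subject × rating mean squares.
- **Hedges' g** = J·(m₁ − m₂)/s̄ with s̄ the average of the two SDs and
  J = 1 − 3/(4(n−1) − 1).
- **Responder rule**: |Δ from baseline| strictly greater than the
  parameter's MDC ⇒ potentiated (increase) or fatigued (decrease).
- **DE** = Sn·prev + Sp·(1 − prev) (= overall accuracy);
  **YI** = Sn + Sp − 1; AUROC is the rank-based (Mann–Whitney)
  probability with half-credit ties.

## Worked example

```r
library(tmgtwitch)
library(dplyr)

cfg    <- sim_config(seed = 2024)          # 16 subjects, default protocol
cohort <- simulate_cohort(cfg)
params <- extract_parameters(cohort) |> add_vc_parameters()

reliability_table(params, parameters = c("Pt", "Dm", "Td", "Tc")) |>
  select(parameter, g, icc, sem, sem_pct, mdc, mdc_pct)
#>   parameter     g   icc   sem sem_pct   mdc mdc_pct
#> 1 Pt         0     1     0.56    2.57  1.54    7.11
#> 2 Dm         0.02  0.93  0.38   10.7   1.04   29.6
#> 3 Td        -0.22  0.34  6.87   29.0  19.0    80.5
#> 4 Tc         0     0.9   0.7     3.21  1.95    8.89
```

Peak twitch torque is the most reliable parameter (SEM ≈ 2.6% of its
mean, so a change of ± 1.5 Nm is already detectable), while the delay
time `Td` is so noisy that only changes beyond ≈ 80% of its mean would
count. The longitudinal test on `Pt`:

```r
long <- tidyr::pivot_longer(params, Pt, names_to = "parameter",
                            values_to = "value")
rm_anova(long, value, subject, timepoint)
#> Within-subjects RM-ANOVA (huynh-feldt correction)
#> F(1.12, 16.86) = 75.328, p = 7.006e-08, partial eta^2 = 0.834
```

The exercise changes `Pt` massively (it rises ~44% after the first set,
falls ~33% by the last). Whether TMG parameters *detect* those states:

```r
rel <- reliability_table(params)
diagnostic_table(params, rel, timepoints = c("Set1", "Post1")) |>
  filter(parameter %in% c("Dm", "Tc")) |>
  select(timepoint, parameter, condition, sn, de)
#>   timepoint parameter condition      sn    de
#> 1 Set1      Dm        potentiated  0.19  0.19
#> 2 Set1      Tc        potentiated  0     0
#> 3 Post1     Dm        fatigued     0.06  0.06
#> 4 Post1     Tc        fatigued     0     0
```

With the default displacement coupling of 0.5 — displacement responding
half as strongly as torque — and realistic trial-to-trial noise, the TMG
parameters detect almost none of the torque-defined responders. Raising
`displacement_coupling` toward 1 in `sim_config()` restores their
sensitivity, which is the package's simulator-level reproduction of the
muscle-length/signal-to-noise explanation for poor TMG diagnostic
accuracy.

Plot helpers: `plot_trajectory(params, "Pt")`, `autoplot(rel)`,
`autoplot(diag_tbl)`.

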