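---
title: "Methods: twitch torque and TMG displacement under potentiation and fatigue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: twitch torque and TMG displacement under potentiation and fatigue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(tmgtwitch)
library(dplyr)
```

## The measurement problem

A single electrical stimulus applied over a muscle evokes a twitch. Two
signals describe it: the torque the limb produces (recorded by a
dynamometer, in Nm) and the radial displacement of the muscle belly
(recorded by a tensiomyography (TMG) sensor, in mm). Prior voluntary
contractions change the twitch: a few maximal contractions transiently
*potentiate* it (larger twitch), while prolonged effort *fatigues* it
(smaller twitch). The two phenomena coexist, and a twitch measured during
or after exercise reflects their net balance.

`tmgtwitch` implements the complete analysis chain for a protocol in which
sixteen subjects perform 60 maximal voluntary isometric knee extensions
(two sets of five, five sets of ten), with twitches recorded twice at
baseline (`Pre1`, `Pre2`), after each set (`Set1`–`Set7`) and repeatedly
during 15 minutes of recovery (`Post0`–`Post15`). The chain comprises:

1. a synthetic-session generator, so that every downstream stage is
   testable without access to raw laboratory recordings;
2. signal extraction: stimulus-triggered twitch identification, zero-phase
   Butterworth filtering, peak twitch torque `Pt`, the TMG parameters
   `Dm`, `Td`, `Tc`, and rolling-median MVIC torque;
3. derived contraction-velocity metrics (`Vc0_10`, `Vc0_90`, `Vc10_90`,
   `Vcnorm`) and the MVIC fatigue index;
4. test–retest reliability of the baseline twitches: bias, Hedges' g,
   ICC(A,1), SEM and the minimal detectable change (MDC);
5. longitudinal inference: extreme-value screening, interpolation of
   interior gaps, sphericity-corrected repeated-measures ANOVA and
   Bonferroni post hocs against baseline;
6. MDC-based responder classification and diagnostic accuracy of the TMG
   parameters against `Pt` as the reference test, including exact binomial
   intervals and the rank-based AUROC.

## The twitch waveform model

The generator models a twitch as a delayed bi-exponential pulse,

$$x(t) = A\,\frac{e^{-(t-d)/\tau_{decay}} - e^{-(t-d)/\tau_{rise}}}{c},
\qquad t \ge d,$$

rescaled by $c$ so its maximum equals the amplitude $A$. This is the
standard parsimonious twitch description — a fast rise, a slower
relaxation, and an electromechanical delay $d$ — and it has the virtue
that everything the extraction stage estimates (`Dm`, `Td`, `Tc`, peak
time) is analytically checkable: the unscaled pulse peaks at
$t^\ast = d + \frac{\tau_r \tau_d}{\tau_d - \tau_r}\ln(\tau_d/\tau_r)$,
and at a fixed ratio $\tau_d/\tau_r$ all crossing times scale linearly
with $\tau_r$. The generator exploits that scaling to solve for
$(\tau_r, d)$ such that a displacement waveform has exactly the requested
delay time (10% crossing) and contraction time (10–90% rise), at a fixed
decay/rise ratio of 6. Torque waveforms use slower physiological time
constants ($\tau_r \approx 25$ ms, ratio 4.8) with mild per-subject
jitter.

## What the generator emulates — and what it does not

Baseline parameters are drawn per subject from truncated normal
distributions matching the observed baseline cohort: `Pt` 19.47 ± 8.49 Nm,
`Dm` 3.06 ± 1.86 mm, `Td` 20.45 ± 9.96 ms, `Tc` 21.64 ± 2.41 ms (the SDs
act as between-subject spread). Within-subject (trial-to-trial) noise is
multiplicative lognormal on the realised parameter values, which keeps
them positive; its per-parameter coefficients of variation default to the
observed relative standard errors of measurement (2.6% for `Pt`, 12.3%
for `Dm`, 25.5% for `Td`, 3.7% for `Tc`), so the simulated test–retest
reliability is of the same order as the reported one.

Peak twitch torque follows a deterministic trajectory multiplier:
1 at both baselines, $1.441$ after the first set (+44.1%), declining
linearly across sets to $0.671$ after the last set (−32.9%), then
recovering linearly in minutes to $0.736$ fifteen minutes later (−26.4%).
The three anchors are the observed cohort-mean changes; the linear
interpolation between them is a modelling choice — the data constrain
only the anchors and monotonicity.

The displacement amplitude receives an attenuated version of the same
multiplier, $1 + \kappa(m - 1)$ with coupling $\kappa \in [0, 1]$
(default 0.5). This one knob encodes the study's central observation:
displacement responds less to the exercise than torque does. $\kappa$ is
a free simulator parameter, not an estimate from data; sweeping it is how
the package turns the signal-to-noise explanation of poor TMG diagnostic
accuracy into a testable mechanism (see below). Timing parameters carry
noise but no systematic trajectory — exercise-induced shortening of
`Td`/`Tc` is deliberately not modelled, so simulated timing parameters
are uninformative responders by construction.

MVIC traces are trapezoids (0.4 s ramps, 2 s plateau); only the first and
last contraction are generated, which is what the fatigue index
`FI = 100 (first − last)/first` requires. Per-subject FI targets are
truncated-normal draws from 39.8% ± 11.5%. The trigger channel carries a
1 ms rectangular pulse at the stimulus, mirroring the monophasic 1 ms
square stimuli of the hardware.

Additive Gaussian noise on the raw traces is available
(`torque_noise_sd`, `displacement_noise_sd`) but defaults to zero: the
amplitude-level lognormal channel is the primary noise source, and clean
traces make the noiseless-retest contract exact — with
`within_subject_sd = 0`, `Pre1` and `Pre2` recordings are identical and
the downstream ICC is exactly 1. Raise the trace-level SDs to probe how
extraction degrades with sensor noise.

Not emulated: calcium kinetics, fibre-type composition, sex differences,
electrode placement, stimulation-intensity titration, or co-activation
("second peak") artefacts. Passing tests therefore show the *pipeline* is
correct and the *mechanism* is coherent, not that real muscles behave
like bi-exponential pulses.

## Signal extraction choices

**Sampling rate.** Defaults to 1000 Hz. At that rate the 501-sample
rolling-median window spans ≈ 0.5 s, a physically sensible smoother for a
5 s contraction plateau.

**MVIC.** The MVIC of a contraction is the maximum of a centred rolling
median (window 501 samples) over window centres where the raw torque
exceeds 20 Nm. Only full windows count; a trace that never exceeds the
floor yields `NA` (a flag, not an error). The median suppresses
single-sample spikes that a rolling mean would absorb.

**Filtering.** Twitch torque is low-pass filtered with a 4th-order
Butterworth design at 15 Hz, applied forward and backward. Zero-phase
application preserves peak timing (a single pass would delay the peak);
the cost is that the effective magnitude response is squared. The
forward–backward pass uses odd-reflection padding with steady-state
initial conditions, so constants pass through exactly (DC gain 1 to
better than $10^{-9}$) and edge transients never reach the analysis
window.

**Peak torque.** `Pt` is the filtered maximum within 300 ms after the
stimulus minus the pre-stimulus baseline (mean of the 50 ms preceding the
stimulus). Baseline subtraction makes `Pt` invariant to constant offsets.
The filter slightly biases the absolute peak of a fast twitch, but the
bias is multiplicative and identical across timepoints for a fixed
waveform shape, so percent changes from baseline are unaffected.

**Displacement parameters.** `Dm` is the height of the first
post-stimulus local maximum whose topographic prominence exceeds
`max(noise_floor, 5% of the global maximum)`, falling back to the global
maximum when no local peak qualifies (earliest sample wins ties). `Td` is
the time from stimulus to the first upward crossing of `0.1 Dm`; `Tc`
runs from that crossing to the first upward crossing of `0.9 Dm`.
Crossings are located by linear interpolation between samples: at 1 kHz,
integer-sample resolution would add ±1 ms quantisation to `Td` and `Tc`,
which is material against a `Tc` SEM of 0.8 ms. A maximal displacement
below `min_displacement` (default 0.1 mm) flags the twitch as
"no displacement detected" — the analogue of a sensor that records
nothing — and interior gaps it leaves in the longitudinal matrix are
filled by `interpolate_missing()`, each missing value taking the mean of
its nearest observed neighbours (boundary gaps are an error).

## Statistical conventions

**Velocity formulas.** `Vc0_90` is computed as
$0.9\,Dm/(Td+Tc) \times 1000$: it is defined as the mean rate from the
stimulus to 90% of `Dm`, and that interval has duration `Td + Tc`. The
identity `Vc10_90 = Dm × Vcnorm` holds to machine precision and is
tested.

**Effect sizes.** Hedges' g standardises by the *average* of the two SDs
and applies the small-sample correction $J = 1 - 3/(4(n-1)-1)$. This
choice reproduces the published baseline `Pt` effect of 0.01; a
difference-SD standardisation would give ≈ 0.13 instead. The CI is a
normal approximation using the paired-design variance
$(1/n + g^2/2n)\,2(1-r)$; the published CI strings for these effects are
not internally consistent (some do not even contain the point estimate),
so the package computes a self-consistent interval rather than matching
them.

**ICC.** ICC(A,1) — two-way model, absolute agreement, single rating —
from the mean squares of the subject × rating decomposition, with the
standard F-based confidence interval for that coefficient. Bands: < 0.5
poor, 0.5–0.75 moderate, 0.75–0.9 good, > 0.9 excellent.

**SEM and MDC.** $SEM = SD\sqrt{1 - ICC}$ with SD taken over all scores
of both baseline trials; $MDC = SEM \times 1.96 \times \sqrt{2}$;
relative versions divide by the grand mean of all baseline scores. The
ratio `mdc/sem` is therefore exactly $1.96\sqrt 2$ for every parameter.

**Extreme values.** Tukey fences at 3 × IQR with type-7
(linear-interpolation) quartiles — the rule names the method, not the
quartile convention, so the convention is fixed and documented here.

**Repeated-measures ANOVA.** One-way within-subjects decomposition;
partial $\eta^2 = SS_{time}/(SS_{time}+SS_{error})$. Sphericity is
corrected by default with the Huynh–Feldt epsilon (computed by debiasing
the Greenhouse–Geisser estimate, truncated at 1). Greenhouse–Geisser
applied unconditionally is also available, but it is conservative
precisely when sphericity holds: in a 2000-replicate null simulation
(16 subjects × 8 timepoints, iid normal) its rejection rate at
$\alpha = 0.05$ is ≈ 0.028, whereas Huynh–Feldt is ≈ 0.048. Since both
corrections produce the fractional degrees of freedom seen in practice
and only one is calibrated, Huynh–Feldt is the default. With two
timepoints both epsilons are 1 and $F = t^2$ of the paired t-test,
which is tested to $10^{-8}$.

**Post hocs.** Paired t-tests of each post-baseline timepoint against
`Pre2`, Bonferroni-adjusted with family size equal to the number of
post-baseline comparisons for that parameter (configurable).

**Diagnostic accuracy.** A subject is *potentiated* when the change from
baseline strictly exceeds the parameter's MDC, *fatigued* when the
decrease strictly exceeds it ("exceeds" is read strictly; a change equal
to the MDC is "unchanged"). The same rule applies to every parameter,
including `Td` and `Tc` whose physiological potentiation response is a
decrease — faithfulness to the uniform published rule beats physiological
plausibility here, and an optional `direction_map` can invert selected
parameters. From the 2 × 2 table against the `Pt` reference:
`Sn = tp/(tp+fn)`, `Sp = tn/(fp+tn)`, predictive values analogously,
`DE = Sn·prev + Sp·(1−prev)` (algebraically the overall accuracy
`(tp+tn)/total`, which is also the computed fallback when an empty margin
leaves Sn or Sp undefined — at the first set, where every reference
subject is positive, DE reduces to Sn), and `YI = Sn + Sp − 1`. Ratios
with empty denominators are `NA`, never silently zero. Every proportion
carries an exact Clopper–Pearson interval (Beta-quantile form); the
Youden interval combines the Sn and Sp endpoints, which reproduces the
published interval strings.

**AUROC.** Rank-based (Mann–Whitney) with half-credit ties, scored on the
percent change from baseline, oriented per condition (for fatigue, more
negative change scores higher). The published AUROC column is mutually
inconsistent with its own single-threshold sensitivities and
specificities (some entries appear orientation-flipped), so the package
documents its orientation convention and does not chase those numbers.

## The mechanism experiment

The package's qualitative claim mirrors the study's interpretation: when
the displacement response is attenuated relative to torque (long muscle
length, low signal-to-noise), MDC-based TMG classification must lose
sensitivity. This is directly simulable: sweeping `displacement_coupling`
over {0.1, 0.5, 1.0} on a fixed-seed cohort monotonically increases the
pooled post-exercise sensitivity of the amplitude-derived TMG parameters,
and with $\kappa = 1$ and low noise their classifications agree with the
`Pt` classification for ≥ 95% of subjects. The timing parameters are
excluded from the agreement check because the generator gives them no
trajectory (see above); their simulated sensitivity is near zero by
construction, as it was in practice.

## Problem sizes and numerical choices

Simulation-based tests use cohorts of 5–16 subjects at 1 kHz with 600 ms
twitch windows; the null-calibration check uses 2000 replicates of a
16 × 8 matrix; oracle-equivalence checks run the exhaustive rolling-median
reference on 200 random traces of 150–800 samples (plus one 5000-sample
trace at the default 501 window). These sizes make the whole suite run in
under a minute on one core while leaving every statistical check
well-powered. Tie-breaks and degenerate inputs are handled explicitly:
zero-variance differences flag the paired t as degenerate rather than
erroring; zero total variance flags the ICC as undefined; constant
vectors produce no extreme-value flags (zero IQR collapses the fences);
single-class label vectors flag the AUROC as undefined.

## Known limitations

* The measurement schedule is configurable because the protocol
  description and the stated number of repeated measurements cannot both
  be exactly right; the default (2 baselines, 7 sets, 9 recovery points)
  is an interpretation and is documented as such.
* The generator's linear set-to-set and minute-to-minute interpolation
  between trajectory anchors is a smoothness assumption, not an estimate.
* Reported ICC point estimates, the fatigue-index distribution of a
  specific cohort, and the published AUROC column depend on raw
  subject-level data and are not recoverable from printed summaries; the
  package covers them with property-based and calibration checks instead.
* Vcnorm's published longitudinal analysis involved an unspecified
  transformation after extreme-value screening; the pipeline exposes the
  screening rule but applies no automatic transformation.
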