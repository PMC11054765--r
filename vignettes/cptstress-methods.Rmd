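---
title: "Methods: cumulative plantar tissue stress from four sensor streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cumulative plantar tissue stress from four sensor streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cptstress)
```

## The model

Cumulative plantar tissue stress (CPTS) quantifies the daily mechanical
dose delivered to a plantar ulcer site in people treated with a removable
offloading device. Per monitoring day $d$ and condition
$c \in \{\text{in-device}, \text{non-device}\}$:

$$\mathrm{CPTS}^{(1)}_d = \frac{1}{1000}\sum_c \mathrm{PTI}_c \times s_{c,d},
\qquad
\mathrm{CPTS}^{(2)}_d = \frac{1}{1000}\sum_c \mathrm{PTI}_c \times s_{c,d}
\times \mathrm{TSR}_c,$$

where $\mathrm{PTI}_c$ is the ulcer-site pressure–time integral (kPa·s) of
a representative step in condition $c$, $s_{c,d}$ the number of strides
taken that day in condition $c$, and $\mathrm{TSR}_c$ the thermal stress
response, a dimensionless surrogate for plantar shear. The division by
1000 converts kPa·s to MPa·s, so day values are MPa·s and the participant
summary — the arithmetic mean over *valid* days — is MPa·s/day. Model 2
requires thermography in both conditions; where no thermal camera is used
the pipeline reports model 1 and marks model 2 unavailable rather than
imputing.

The model's central assumptions: a single per-condition PTI measured in a
clinic walking trial represents every free-living step in that condition;
strides are the only weight-bearing activity that contributes (standing is
explicitly out of scope); and the Celsius-ratio TSR transfers from the
instrumented walking trial to all walking in that condition.

### Thermal stress response

$$\mathrm{TSR} = \frac{(T_{post}-T_{pre})/T_{pre}\,\big|_{\text{index}}}
{(T_{post}-T_{pre})/T_{pre}\,\big|_{\text{contra}}}$$

with all temperatures in °C, exactly as the quantity is defined in this
literature. Because the denominator of each relative change is a Celsius
value, the ratio is **not invariant under adding a constant to all four
temperatures**; we implement it as printed and flag the property rather
than "fixing" it (a Kelvin version would change the published magnitudes,
which are ≈ 0.4–1.5 in °C form). Negative values — index foot cooling
while the contralateral warms — are physically meaningful and propagate
into model 2 with a warning. A contralateral change of zero makes the
ratio undefined and raises a typed error.

## Per-stream processing and its parameters

**Plantar pressure.** Two dialects: a 99-sensor capacitive insole sampled
at 50 Hz (walking trials, in-device and in-footwear conditions) and a
pressure platform with 4 sensors/cm² at 100 Hz (single-contact barefoot
trials, 2-step protocol, four repeats averaged). Stance phases are maximal
runs with total vertical force ≥ `force_threshold_n` (default 35 N ≈ 5% of
a 700 N body weight) lasting ≥ 0.1 s, as half-open frame-index intervals.
Walking trials drop `trim_steps = 2` gait-initiation/termination steps per
end and require ≥ 12 midgait steps, else the trial is rejected as invalid.
The regional pressure curve reduces the ulcer-site mask per frame by
`max` (the cluster-peak convention of insole software; an area-weighted
`mean` is available since the field's conventions differ here); PPP is the
curve's maximum, PTI its trapezoidal integral. Trial-level PPP/PTI are
**means** over midgait steps — maxima are more outlier-sensitive at 12–16
steps per trial; both reductions are exposed. The platform ulcer mask is
all cells within 10 mm of the configured ulcer coordinate; the radius is a
design choice, as region size has no published standard at this lesion
scale.

**Weight-bearing activity.** The stride source is either pre-extracted
stride events or trunk acceleration (100 Hz, ±6 g). The built-in stride
detector is a deliberate stand-in for proprietary monitor firmware and is
validated only against synthetic ground truth: vertical channel,
0.5–3 Hz 2nd-order Butterworth band-pass (forward–backward), peaks
≥ 0.3 g at least 0.4 s apart. Monitor wear is detected as windows whose
vector-magnitude standard deviation reaches 0.01 g. A **valid day** has
≥ 12 h of monitor wear; fewer than 4 valid days is a "non-adherent
participant" outcome, not a silent number. We count *strides* (full gait
cycles) throughout and label outputs accordingly, because adherence is
defined on strides; the literature sometimes reports "steps" for the same
monitor output.

**Adherence.** The in-device temperature logger samples every 15 min.
Wear detection is a stand-in rule built on threshold hysteresis with slope
assists: wear starts at the first sample with temp ≥ 27 °C, or ≥ 25 °C
rising ≥ 0.5 °C/sample (donning appears first as a steep rise through the
hysteresis band); wear ends at the first sample below 25 °C, or falling
≥ 2 °C/sample (doffing appears first as a steep fall from skin
temperature). The published wear-time algorithm this stands in for is
described outside this package's sources and is not reproduced. The
fall-slope assist exists because a pure "first sample below the off
threshold" rule lags a true doffing event by ~45 min under a 30-min
relaxation time constant — worse than the sensor's own 15-min resolution —
which systematically misclassifies evening strides; with the slope assist,
recovered boundaries sit within two samples of the truth on noise-free
synthetic logs. Boundaries snap to sample timestamps; intervals are
half-open $[on, off)$, so a stride exactly at an `off` boundary is
non-device, the in-device + non-device counts partition the total by
construction, and shifting all clocks by a constant changes nothing. Log
gaps over 2 h split any spanning interval with a warning. Adherence is
100 × (in-device strides / total strides) over valid days.

## The synthetic cohort generator

The generator is the package's substitute for unavailable participant
data, and its defaults are the study conditions it emulates: parameter
ranges are the interquartile ranges of the published cohort quantities
(adherence 26.6–68.7%, 1015–12456 strides/day, in-device PTI
60.0–74.7 kPa·s, footwear PTI 67.2–86.3 kPa·s, barefoot PTI
235.7–626.1 kPa·s, TSR 0.30–1.07 in-device and −0.15–2.54 non-device),
drawn uniformly. Monitoring lasts 7 days; the device is worn in one daily
block (on 07:00–09:00, off 19:00–21:00); the activity monitor is worn
13–16 h/day so days are valid; strides happen between 06:00 and 23:00.
A configurable fraction of participants is labelled healed, with their
stride mean scaled by 0.5 so healed participants carry a lower cumulative
dose — matching the direction reported clinically, and giving the
cohort-level comparison something real to find. Cohorts can mix styles:
"AU" participants carry thermography and in-footwear non-device trials;
"NL" participants have no thermal stream and barefoot platform trials.

Design choices worth knowing:

- **Half-sine stances.** Each generated stance is
  $p(t) = P\sin(\pi t/T)$ on the ulcer-mask sensors, because its PTI has
  the closed form $2PT/\pi$ — an analytic oracle for the whole pressure
  chain. $P$ is the condition's target peak pressure and $T$ is chosen to
  hit the target PTI, snapped to an even number of samples so the sampled
  peak equals $P$ exactly. The manifest records the *achieved* analytic
  values; trapezoidal integration at device rates recovers them within 2%
  (the residual is threshold tail-clipping plus discretisation).
- **First-order temperature relaxation** toward a 32 °C skin set-point
  while worn and 21 °C ambient otherwise, time constant 30 min, integrated
  exactly across wear-state changes. No published thermal model exists for
  these sensors; this is the minimal dynamic that makes threshold-based
  wear detection non-trivial. Set-points and the time constant are
  configuration, not inference.
- **Bout placement.** Strides are placed in bouts (mean 30 strides,
  1.1 s cadence) rather than uniform scatter — closer to gait, and a
  harder test of interval-intersection code. Each day a fraction equal to
  the true adherence (rounded to the nearest stride) is placed inside the
  wear schedule, so realised adherence is exact up to 1/(daily strides).
- **Day boundaries at local midnight**, absolute timestamps throughout,
  one declared timezone (UTC) — the simplest auditable convention.
- The generator writes the activity stream as stride events plus
  monitor-wear intervals; raw week-long 100 Hz acceleration is simulated
  on demand (`simulate_acceleration()`) for short windows, which is where
  the stride and wear detectors are validated.

What the generator does **not** emulate: anatomically realistic pressure
maps, posture and standing, device changes mid-study, sensor hardware
failures beyond log gaps, circadian or day-to-day drift in PTI or TSR, and
correlated noise. Passing recovery tests therefore demonstrates that the
fusion machinery is correct and unbiased under the stated conditions — not
that the stand-in detectors match proprietary algorithms on real signals.

## Statistical layer

Group comparisons on small cohorts use the Mann–Whitney U test with effect
size $r = |z|/\sqrt{n_A+n_B}$, labelled by the conventional half-open
bands ($\geq 0.1$ small, $\geq 0.3$ moderate, $\geq 0.5$ large). The
z-score uses the tie-corrected variance and a 0.5 continuity correction.
The two-tailed asymptotic p adds the Edgeworth kurtosis term (the U
distribution is symmetric, so this is the first correction), using the
exact fourth central moment of untied U,
$\mu_4 = \frac{mn(N+1)}{240}\left[5mn(m+n) + 3mn - 2(m+n) -
2(m^2+n^2)\right]$, which we verified against full enumeration for all
$m,n \le 7$. The refinement matters at desk scale: across *every*
achievable U for group sizes 3–8, the plain continuity-corrected normal
deviates from exact enumeration by up to 0.037 (mid-range p-values, where
the discrete distribution is coarsest), while the corrected form stays
within 0.020. For groups of two the exact p has granularity 1/3 and no
continuous approximation tracks it; the default `method = "auto"`
therefore uses exact enumeration whenever samples are untied and
$n \le 20$, reserving the asymptotic path for larger or tied data.

Categorical comparisons use Pearson's chi-square **without** continuity
correction, dropping all-zero rows and columns before computing degrees of
freedom — the convention under which the printed p-values of the kind of
baseline tables this package targets reproduce to three decimals (Yates
correction does not reproduce them). Medians and quartiles use
$(n{+}1)$-based weighted-average interpolation (`quantile` type 6, the
HAVERAGE convention of common clinical software), configurable because the
convention cannot be pinned down from printed values alone. No
multiplicity adjustment is applied, matching the analysis style this
reproduces. Completion accounting uses a closed reason taxonomy
(complete, non-adherent participant, technical issue, combination,
participant refusal, drop-out); pipeline failures map onto it instead of
raising, and a factor blocked by an upstream failure inherits the
upstream reason.

## Numerical conventions and degenerate inputs

- Interval sets are disjoint, ordered, half-open; point-in-interval uses
  a boundary bisection, so classification is O(log k) per stride.
- Stance indices are half-open `[start, end)`; a detected single-pulse
  duration is within one sample of the truth.
- All identical values across both Mann–Whitney groups: z = 0, r = 0,
  p = 1. Zero pooled variance with equal means in the t-test: t = 0,
  p = 1. Empty regions, empty series, zero total strides, PTI missing for
  a condition with non-zero strides: typed errors, never NA propagation.
- Reruns with the same seed and configuration are byte-identical,
  including the written cohort files.

## Problem sizes

The test suite and the acceptance script exercise: a 20-participant
synthetic cohort (7 monitoring days, ~1000–12500 strides/day, 15
participants with thermography and 5 without) for parameter recovery;
16-step walking trials and 4-repeat platform trials for the pressure
chain; 100–200-stride windows of 100 Hz acceleration for the detectors;
and the full enumeration sweep (all achievable U, group sizes 3–8, 665
configurations) for test calibration. Recovery outcomes at these sizes:
median adherence error ≈ 1 percentage point (temperature noise
SD 0.3 °C), stride counts exact, median CPTS error ≈ 1–2% against the
manifest's analytic values.

## Known limitations

The stride and wear detectors are stand-ins validated on synthetic ground
truth only. A single clinic-measured PTI per condition ignores
within-condition variability of free-living gait. The 15-min temperature
sampling bounds adherence resolution; misclassification concentrates at
don/doff boundaries and grows when short non-wear windows abut long wear
blocks. TSR as implemented inherits the translation-variance of the
Celsius-ratio definition. None of the feasibility phenomena that dominate
real deployments of this sensor set — refusals, lost sensors, device
changes — are modelled beyond the reason taxonomy that reports them.
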