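---
title: "Quantifying patient-ventilator interaction from EAdi and pressure waveforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying patient-ventilator interaction from EAdi and pressure waveforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventsync)
```

## The problem

During assisted mechanical ventilation the ventilator should pressurize the
airway while the patient's diaphragm is active, and stop when the effort
ends. Pneumatic waveforms (airway pressure `P_V`, flow) show what the
machine did; the electrical activity of the diaphragm (EAdi, in uV,
recorded by an esophageal electrode array) shows what the patient intended.
`ventsync` compares the two: it detects the timing of every neural effort
and every delivered assist, scores the timing discrepancies on a normalized
scale, and condenses a recording into a single interaction index plus a
bedside-style dashboard.

## Event detection

Both channels are scanned causally at the sampling rate (100 Hz by
default).

**Neural events.** A running nadir is tracked since the last event. When
EAdi rises to `nadir + threshold` (threshold 0.5 uV by default; 0.25 and
1.0 uV are the other supported settings), an onset `EAdi_ON` is emitted at
the nadir the increase started from — operationally, the most recent local
minimum before the crossing. The burst peak is then followed, and the
termination `EAdi_OFF` is the first post-peak sample where the signal falls
below 70% of the peak (`eadi_termination_fraction`). A burst whose descent
never reaches the termination level before the next rise is closed at the
inter-burst minimum and flagged `merged`; a 100 ms refractory period
suppresses immediate re-triggering, and a burst must rise at least the
threshold above its own onset amplitude to count.

**Ventilator events.** The same scan runs on airway pressure with a strict
`> 3` cmH2O rise criterion measured from the running pre-breath nadir
(PEEP-relative, so the detector is invariant to the PEEP setting). The
onset `PS_ON` is the beginning of the continuous pressurization rise; PEEP
is estimated as the median pressure over the 200 ms before the onset, and
the termination `PS_OFF` is the first post-peak sample below
`PEEP + 0.70 x (peak - PEEP)`. The original description specifies only
"a decrease" for the termination; the symmetric 70% rule was adopted
because it mirrors the neural criterion, and it is configurable
(`paw_termination_fraction`).

**Defragmentation.** Subventilatory fragments are removed before scoring:
neural events with burst area strictly below 0.15 uV*s and pressure events
below 1.5 cmH2O*s (areas by trapezoid integration above the onset
amplitude / above PEEP, clipped at zero). Events exactly at the minima are
retained, matching the strict "less than" wording of the rule.

## Scoring

For each interior neural effort *i* (the first and last efforts lack
complete periods and are excluded) two detection periods are built:

* inspiratory: from `EAdi_OFF(i-1)` to `EAdi_OFF(i)`, divided at
  `EAdi_ON(i)`;
* expiratory: from `EAdi_ON(i)` to `EAdi_ON(i+1)`, divided at
  `EAdi_OFF(i)`.

An assist whose `PS_ON` falls in the inspiratory period of effort *i*
(half-open interval, onsets exactly at the period start belong to the
earlier effort) is that effort's candidate assist. The **trigger error** is
the signed position of `PS_ON` in the period: `-100 x (divider - PS_ON) /
(divider - start)` in the early segment, `+100 x (PS_ON - divider) / (end -
divider)` in the late segment. The **cycle-off error** is the analogous
position of `PS_OFF` in the expiratory period. Both are clamped to
[-100, 100]; a `PS_OFF` past the next neural onset clamps to +100.

Categories follow the breath taxonomy: one overlapping assist per effort is
`paired`; two or more overlapping assists in one period are
`multiple_assist_during_eadi` (double triggering — each assist is scored
separately); an assist spanning two or more neural onsets is
`multiple_eadi_during_assist`; an effort with no assist is
`eadi_without_assist` (wasted effort); an assist that ends before the
neural onset of the effort whose period contains it never interacts with a
burst and is `assist_without_eadi` (auto-triggering). The last rule
deserves a note: because detection periods tile the interior of the record,
a mid-expiration auto-trigger always lands in *some* effort's period, where
a literal reading of the pairing rule would score it as an extreme early
trigger error. Operationally an assist with no overlap with any neural
burst is complete dissociation, so it is classified asynchrony with both
errors set to 100%.

Classification uses the +/-33% synchrony box (inclusive): events with both
absolute errors at most the limit are `synchrony`, other finite-error
events are `dyssynchrony` (including large negative trigger errors, kept
finite for symmetry of the display), and the dissociation categories are
`asynchrony` at 100/100. The **NeuroSync index** is the pooled mean of the
absolute trigger and cycle-off errors over all events. Pooling (rather than
averaging per-event means first) is the adopted reading of "averaging the
absolute values of the errors for all events"; the two coincide whenever
every event carries both errors, which is always the case here.

## Comparison indices

`asynchrony_counts()` implements the classical flow/pressure definitions:
ineffective efforts (an abrupt expiratory pressure drop >= 0.5 cmH2O with
the flow deflecting toward inspiration and no assist within 300 ms),
double-triggering (expiratory gap shorter than half the mean inspiratory
time, first cycle patient-triggered), auto-triggering (no >= 0.5 cmH2O dip
in the 300 ms before `PS_ON`), and short/prolonged cycles (inspiratory time
below half / above twice the record mean). The index is
`100 x events / (ventilator cycles + ineffective efforts)`. The dip depth
and window are configurable because the source description does not print
them. The flow condition is implemented as a signed deflection toward
inspiration: while expiratory flow is ongoing this equals a decrease of
|flow|, and it still captures efforts that occur after expiratory flow has
decayed to zero. `ai_colombo()` is the EAdi-verified asynchrony fraction:
dissociation events plus double-trigger pairs over all events.

On simulations with timing errors only, the NeuroSync index grows with the
injected delay while the EAdi-verified fraction stays at zero — timing
errors are invisible to asynchrony counting; only dissociation moves both.
The acceptance suite checks exactly this pattern.

## Breathing pattern and reliability

Neural and ventilator frequencies use the onset-to-onset span
(`60 x (n - 1) / span`), which is unbiased for partial records; tidal
volume is the trapezoid integral of positive flow over each assist.
Histograms default to 2 breaths/min, 0.05 L, 1 cmH2O and 1 uV bins.

`icc()` computes two-way intraclass correlation coefficients from the ANOVA
mean squares. The default is ICC(2,1) — two-way random effects, absolute
agreement, single measure — the standard choice for inter-rater and
inter-method reliability when no form is stated; consistency and
average-measure variants are selectable. The test suite verifies the mean
squares against `stats::aov()` to 1e-9.

## The simulator

`simulate_psv()` generates pressure-support breathing with known ground
truth. Defaults describe a typical adult: neural inspiratory time 0.9 s
(CV 8%), expiratory time 1.6 s (CV 8%), EAdi peaks 12 uV (CV 15%) on a
0.5 uV tonic baseline, PEEP 5 cmH2O, 12 cmH2O support with a 150 ms rise,
trigger delay 100 +/- 20 ms, cycle-off delay 150 +/- 30 ms, single-
compartment mechanics (R = 12 cmH2O/L/s, C = 0.04 L/cmH2O) yielding tidal
volumes near 0.5 L, and band-limited measurement noise (0.2 uV EAdi,
0.1 cmH2O pressure). Per breath, draws occur in a fixed order (inspiratory
time, expiratory time, peak, category uniform, trigger delay, cycle-off
delay) from one seeded generator, so ground truth is reproducible.

Modelling choices worth knowing:

* The EAdi burst rises over 75% of the inspiratory time (linearly or as a
  raised cosine) and decays linearly so that the 70%-of-peak crossing falls
  exactly at the intended `EAdi_OFF`; onsets and peaks are snapped to the
  sample grid so intended event times are exactly representable.
* Patient-triggered assists are preceded by a 0.7 cmH2O pressure dip
  (deep enough to exercise the 0.5 cmH2O pneumatic rule); wasted efforts
  keep the dip but omit the pressurization; auto-triggers omit both the
  EAdi burst and the dip.
* Double triggering ends the first cycle at 55% of the effort and
  re-triggers at 70%, so the first cycle's pressurization area stays
  clearly above the defragmentation minimum.
* Noise is band-limited (80 ms moving average on EAdi, 50 ms on pressure)
  because both signals are processed envelopes, not raw white-noise
  channels; EAdi is clipped at zero.

What the simulator does **not** emulate: ECG contamination and its
replacement artifacts, electrode-array motion, leaks and nonlinear
mechanics, sighs/coughs, and reverse triggering. Passing the recovery and
reliability tests therefore demonstrates correctness of the detection and
scoring logic under controlled morphology, not clinical performance on raw
patient signals.

`expected_index()` is the analytic counterpart: it maps the delay
distributions through the piecewise early/late normalization (numerically
integrated against the normal density over the mean segment lengths) and
mixes in the dissociation categories at 100%. Monte-Carlo means of the
simulated true index agree with it within sampling error; the test suite
checks this at 200 replicates.

## Numerical conventions

* Time is absolute seconds from record start; events are reported as times,
  never sample indices, so results are sampling-rate independent.
* Threshold comparisons: neural onset crossing is `>=`, pressure rise and
  defragmentation are strict, the synchrony box is inclusive — each choice
  pins down behavior exactly at a printed limit.
* Ties in the running nadir move forward, so on a flat baseline the onset
  lands at the last baseline sample before the rise.
* Merged-burst closures reopen one sample after the inter-burst minimum so
  consecutive event times stay strictly ordered (detection-period bounds
  are strict inequalities).
* Grid uniformity is enforced to a relative tolerance of 1e-6 on the
  spacing; negative EAdi samples are clipped to zero with a logged count.

## Problem sizes used by the tests

The recovery check runs 20 noiseless records of 50 breaths; the
reliability check runs 20 records of 30 breaths at the default noise with
trigger/cycle-off delays spread over 0-0.45 s, comparing automatic
detection against scoring from ground-truth annotations (ICC(2,1) > 0.9);
detector-vs-reference equivalence uses 200 random records of up to 2,000
samples. These sizes keep the full suite near a minute while leaving every
code path exercised.

## Known limitations

* With fewer than three neural efforts no detection periods exist and no
  events can be scored.
* The manual-analysis route accepts cursor times but there is no
  interactive placement tool; annotation files stand in for it.
* The pneumatic dip rule inherits the fragility of fixed-threshold
  detection: occasional false ineffective efforts on noisy recordings are
  expected, which is precisely the motivation for the EAdi-referenced
  index.
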