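---
title: "Automated pure-tone audiometry in silico: calibration, staircase and agreement methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated pure-tone audiometry in silico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(puretone)
```

## What the package models

`puretone` implements the software core of an automated pure-tone
audiometer covering standard and extended high frequencies
(0.125–16 kHz), entirely without audio hardware: the calibration algebra
that ties hearing level (dB HL) to digital signal amplification and to
sound pressure level (dB SPL); the gated tone-burst stimulus; the
Hughson–Westlake adaptive staircase with automated threshold validation;
simulated psychometric listeners that stand in for human participants;
and the Bland–Altman analysis used to quantify agreement between two
audiometers measuring the same ears.

## Calibration model

For each test frequency the device stores a RETSPL (the SPL that
corresponds to 0 dB HL on the reference transducer) and a reference
digital amplification `ref_amp` — the amplification at which the device
outputs 0 dB HL. Digital amplification runs from 5 to 100 dB in 5-dB
steps (0 dB is digital silence, so 5 dB is the quietest presentable
signal; 100 dB is digital full scale, amplitude 1, via
$a = 10^{(A-100)/20}$). The three maps are linear in dB:

* `amplification = ref_amp + level_hl`,
* `spl = retspl + level_hl`,
* measurable range `[5 − ref_amp, 100 − ref_amp + 5]` dB HL, where the
  `+5` is the recording rule for a no-response ceiling: when a listener
  gives no response at the loudest presentable level, the recorded
  threshold is that level plus 5 dB.

```{r}
tab <- default_calibration()
measurable_range(tab, c(1000, 8000, 16000))
```

The packaged table reproduces the published per-frequency calibration
for the DT-770 Pro transducer. Two numerical notes:

* **The 8 kHz range.** The published range at 8 kHz is printed as
  [−15, 90], which is inconsistent with its own reference amplification
  of 15 dB (that implies [−10, 90], as at 0.75–4 kHz). The package
  derives every range from the formula rather than hard-coding the
  printed row, so it reports [−10, 90] at 8 kHz and matches the printed
  interval exactly at the other 14 frequencies.
* **Extrapolated RETSPLs.** At 0.125, 14 and 16 kHz the conventional
  70 dB HL calibration point is not reachable before digital
  saturation; the RETSPL is instead extrapolated from the SPL measured
  at maximum amplification
  (`retspl = measured_spl − (100 − ref_amp)`), and those rows are
  flagged `extrapolated`.

Post-hoc recalibration against a reference device
(`adjust_calibration()`) shifts each frequency's reference
amplification by its mean measured deviation rounded to the nearest
multiple of 5 dB. Ties round half away from zero, which treats positive
and negative deviations symmetrically; the convention only matters at
exactly ±2.5 dB modulo 5.

### Amplitude convention

Digital amplitude is applied as the sine's *peak* scale factor. The
source convention describes amplification 100 dB as "RMS value 1",
which a full-scale sine cannot reach without clipping; since every
calibration constant was measured through the same chain, the fixed
3.01 dB RMS-vs-peak convention difference is absorbed by the RETSPL
values and never changes a hearing level. Amplification 0 is
special-cased to exact silence (the log map would otherwise give
$10^{-5}$).

## Stimulus

A trial presents a train of five tone bursts: 50 ms fade-in, 200 ms
plateau, 50 ms fade-out, 100 ms silent pause — 400 ms per beep, 2000 ms
in total, rendered at 48 kHz. The fade shape is a raised-cosine
(Hann-flank) gate, the standard audiometric choice because it bounds
spectral splatter; linear ramps are available via
`fade_shape = "linear"`. The sine starts at phase 0 at each beep onset
so renders are bit-reproducible; segment lengths are rounded to the
nearest sample, and pause samples are exact zeros. WAV export is mono
32-bit float (lossless for the rendered samples) or 16-bit PCM.

```{r}
wf <- render_calibrated(tab, 1000, 40)
wf
```

## The staircase and its validation rules

The adaptive track is a pure state machine
(`new_staircase()` / `next_level()` / `update_staircase()`), decoupled
from audio and timing, which makes it exhaustively testable. Rules:

* start at 40 dB HL; a detection lowers the next level by 10 dB, a miss
  (no press, or a press after the 2000 ms response window) raises it by
  5 dB; levels clip to the presentable range;
* trials are separated by a pause drawn uniformly from 2000–4000 ms;
* *descending start* (first trial detected): the threshold is validated
  after two inversions of direction — an omission then a correct
  detection — for both device variants;
* *ascending start* (first trial missed): one inversion (the first
  correct detection) for the `elios` variant, three inversions for the
  `aupiometer` variant ("double validation");
* a miss at the loudest presentable level terminates the track and
  records that level plus 5 dB with `ceiling` status;
* the validated threshold is the level of the correct detection that
  completes the required inversion count — the ascending detection
  level, consistent with Hughson–Westlake practice.

Three behaviours are deliberate design choices where the procedure
description is silent:

* **Floor.** Only the ceiling is defined by the source procedure. A
  second consecutive detection at the range minimum records the minimum
  with a `floor` flag (an omission below the floor is impossible, so a
  threshold at or below the minimum can never validate normally).
* **Trial cap.** `max_trials = 50` aborts a pathological track with
  `aborted` status and a missing threshold; the physical procedure has
  no cap, but a simulation harness needs one.
* **Stop-on-press.** The `elios` variant stops the stimulus at the
  press while the `aupiometer` plays the full 2000 ms train. This
  affects trial duration only, never level sequencing, so in simulation
  it is cosmetic; the variants genuinely differ only in the
  ascending-start inversion count.

For a deterministic step listener (responds iff level ≥ T) the track
provably returns `ceiling(T / 5) * 5` clipped to the range; the test
suite brute-forces this over every grid threshold, every frequency and
both variants.

## Simulated listeners

Human participants are replaced by a psychometric observer:
$P(\mathrm{press}) = \gamma + (1 - \gamma - \lambda)\,
\Phi\!\big((L - T_f)/\sigma\big)$ with guess rate $\gamma$ (default
0.01), lapse rate $\lambda$ (default 0.02) and spread $\sigma$ (default
4 dB; a logistic link is available). Latency is log-normal (median
600 ms, log-SD 0.35); a press later than the 2000 ms window is scored
as "too late", so late misses emerge from the latency distribution
rather than a separate parameter. Setting $\sigma = 0$, $\gamma =
\lambda = 0$ gives the deterministic reference observer.

The panel generator emulates the validation study design: 16
participants × 2 ears, split 7 young / 9 elderly (the study's median
split at 37 years), all meeting the clinical normal-hearing inclusion
criterion (thresholds below 25 dB HL from 0.25 to 8 kHz, resampling
violators). Elderly ears additionally carry extended-high-frequency
loss: a per-ear severity drawn uniformly on [20, 65] dB HL applied
through a ramp (25% at 10 kHz, 50% at 12.5 kHz, 85% at 14 kHz, 100% at
16 kHz). The ramp shape and severity floor are engineering choices —
the study constrains only the 65 dB HL maximum at 14–16 kHz and the
young/elderly separation at those frequencies — and they produce the
qualitative presbycusis signature: elevated thresholds at and above
12.5 kHz, frequent ceilings at 16 kHz where the measurable range tops
out at 55 dB HL.

The two-device study runner measures every ear on device A (true
thresholds) and device B (thresholds shifted by a per-frequency
calibration offset), adds independent Gaussian session noise (SD 3 dB)
to each ear × device × frequency track, and counterbalances device
order across participants. i.i.d. per-track noise is the simplest
structure that reproduces Bland–Altman spread; frequency-correlated
session effects (fatigue, earphone refitting) are deliberately not
modelled.

```{r, eval = FALSE}
spec <- panel_spec()
panel <- generate_panel(spec, tab, seed = 1)
paired <- run_two_device_study(panel, tab, spec = spec, seed = 2)
summarize_agreement(agreement_by_frequency(paired))
```

## Agreement analysis

`bland_altman()` orients differences as A − B, uses the sample SD
(n − 1; conventional for the small per-frequency samples), and places
the 90% limits of agreement at bias ± 1.64 SD. The published constant
1.64 is used verbatim rather than the exact $z_{0.95} = 1.6449$;
`loa_multiplier(0.90, exact = TRUE)` gives the exact value. The
across-frequency summary reports both the unweighted mean ± SD of the
per-frequency statistics (the presentation used for the human study)
and a pooled analysis of all differences, because the two aggregations
answer slightly different questions and the source presentation does
not fully pin down the pooled variant. Differences of 15 dB or more in
absolute value are reported as an outlier rate and never removed.

## What the simulations do and do not show

The deterministic-listener results are exact and exhaustive: the
staircase, calibration algebra and agreement arithmetic are verified
against closed-form oracles. The stochastic results characterise the
procedure, not human hearing: with $\sigma = 4$ dB the staircase's
ascending-detection rule validates one 5-dB step above the true
threshold on its most likely path (a miss at T followed by a detection
at T + 5), and a single lapse during the supra-threshold descent can
validate ~15 dB high because a descending start needs only two
inversions. Per-track recovery error therefore has SD ≈ 5–6 dB with a
right tail, and a zero-offset two-device study shows ~89% of paired
differences within ±10 dB — slightly wider than the ~90% reported for
real listeners, suggesting real participants behave somewhat more
consistently near threshold than this listener parameterisation.
Attention drift, conductive pathology, tinnitus interference and
transducer placement variability are not modelled.

Problem sizes used throughout (chosen to characterise the estimators
well): 50 seeded replicate studies of 32 ears × 2 devices × 15
frequencies for agreement properties, and 100 seeded tracks per
frequency for threshold-recovery properties.

## Reproducibility

Every stochastic entry point (`generate_panel()`, `run_session()`,
`run_two_device_study()`, the CLI subcommands) takes a seed and is
bit-reproducible given it; a session consumes a single RNG stream
covering inter-trial intervals, psychometric draws and latencies.
`scripts/acceptance.R` recomputes the calibration headline numbers from
an installed copy of the package.
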