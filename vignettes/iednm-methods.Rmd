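---
title: "Methods: IED detection and thermal-modulation analysis in iednm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IED detection and thermal-modulation analysis in iednm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iednm)
```

## Scope and model

`iednm` implements an offline analysis chain for interictal epileptiform
discharges (IEDs) recorded with surface microelectrode (µECoG) arrays
while the cortex is heated by near-infrared laser light (infrared
neuromodulation, INM), together with a synthetic-data generator that
stands in for animal recordings. The chain is: protocol timeline →
(synthetic) recording → filter chain → sliding-window adaptive-threshold
detection → five per-event features → 40-s binning and baseline
normalisation → trial-similarity statistic.

Two stimulation protocols are modelled. Both start with a 120-s baseline
(`PCtrl`) and then repeat an ON/OFF cycle `n_trials` times: ISP1 uses
120 s ON + 240 s OFF, ISP2 uses 240 s ON + 240 s OFF. The laser drive is
continuous (0 Hz) or pulsed at 1/10/100/1000 Hz with a fixed 50% duty
cycle. All downstream binning uses 40-s bins aligned to t = 0, so one
baseline-plus-cycle trajectory has 3 + 9 = 12 bins (ISP1) or
3 + 12 = 15 bins (ISP2).

## The synthetic world

The generator's defaults are the package's stated experimental
conditions; they were chosen once, from the reported protocol values where
available and from field-typical magnitudes elsewhere, and are not tuned
to test outcomes.

**Background.** Each channel is 1/f ("pink") noise (RMS 35 µV, flattened
below 2 Hz), a 50 Hz line component (20 µV, random phase per channel),
and a 28–80 Hz gamma-band component (RMS 6 µV) whose amplitude is
multiplied by `gamma_boost` (default 1.5) during laser-ON. An 80–120 Hz
narrowband artifact (RMS 15 µV) is present whenever the laser drive is
on, gated by the pulse square wave for pulsed protocols. Noise is
synthesized spectrally (shaped white noise), so recordings are
bit-reproducible given a seed.

**Events.** Two IED morphologies are generated on a 300-ms support:
type-2 is a monophasic sharp negative Gaussian spike (10 ms FWHM,
N/P2P = 1 by construction); type-1 adds a slow positive wave (FWHM
70 ms, delayed 55 ms, 0.35 relative amplitude) after an equally fast
negative spike, giving N/P2P ≈ 0.74. Making both fast components 10 ms
wide is a deliberate choice: the types are distinguished by the slow
wave and the N/P2P ratio, while both carry comparable energy into the
30–300 Hz detection band — a spike twice as wide would fall below the
detector's mean-peak threshold whenever sharper events share a window,
which is a property of the threshold formula, not of the biology being
emulated. Event times follow a renewal process whose mean rate equals
the configured rate (`base_rate_hz`, default 0.5 Hz per channel,
multiplied by `on_rate_factor` = 1.2 during ON) with a hard 350-ms
minimum spacing so 300-ms segments never overlap; centres keep 175 ms
from the recording edges. Injected P2P is the site group's mean
amplitude (600/500/420/350 µV for Group#1–4) times the group's ON
factor (0.75/0.80/0.85/0.90 by default) while the laser is on. There is
no per-event amplitude jitter by default, so ground-truth phase ratios
are exact; measured variability comes from the additive background.

**What the generator does not emulate.** Volume conduction and
across-channel correlation of events, non-stationary background, drifting
electrode impedance, behaviourally driven artifacts, or any biophysical
coupling between temperature and excitability. A green end-to-end test
therefore establishes that the chain recovers what the generator put in,
at realistic SNR — not that the biological effect sizes are correct.

**Temperature.** Cortical temperature at two sensors (near/far from the
optrode) follows first-order exponential relaxation toward
baseline + ΔTmax during ON (τ_heat = 25 s) and toward baseline during
OFF (τ_cool = 35 s), sampled at 6 Hz. The continuous-wave maxima are
3.0 °C (near) and 1.5 °C (far); pulsed protocols scale both by a lookup
(1 Hz → 1.6/3, 1 kHz → 1.5/3, 10/100 Hz log-interpolated between those
endpoints, linear interpolation for other frequencies). τ_heat = 25 s
makes a 120-s ON phase reach 99.2% of its asymptote, so the configured
maxima are reproduced within the stated 2%. During OFF phases of slow
pulsed protocols (0 < f ≤ 10 Hz) a smoothed fluctuation (SD 0.05 °C, a
value without direct literature support) is added, weighted by how far
the trace has relaxed toward baseline — ambient-air convection matters
at low cortical temperatures — so the fluctuation never inflates the
cycle maximum.

## Preprocessing

The filter chain is a second-order 50 Hz IIR notch (Q = 30; only the
order is prescribed by the source methods), a second-order Butterworth
2–300 Hz band-pass, and a second-order Butterworth 80–120 Hz band-stop,
applied in that order. Because the analysis is offline, filters run
zero-phase (forward–backward), which doubles the effective order and
preserves event morphology — N/P2P is a downstream feature, so group
delay or phase distortion would bias it. A causal mode is available via
`filter_config(zero_phase = FALSE)`. No DSP package is available in the
target environment, so the designs (bilinear-transform Butterworth,
standard IIR notch) are implemented in the package and verified against
coefficients frozen from an independent reference implementation.
Forward–backward filtering uses odd-symmetric end padding (1500 samples
by default, > 8 decay constants of the slowest pole at 2 kHz) instead of
exact steady-state initialisation. The pipeline's heavy path applies the
identical squared-magnitude response in the frequency domain (one FFT
per channel); both paths agree on detections and features to well below
the tolerances used in tests, and `analyze_recording(filter_method =
"time")` selects the strict time-domain path.

Channels are grouped by distance from the central aperture: the four
nearest usable sites form Group#1 and the remaining usable sites split
into Groups#2–4 in distance order, ties broken by channel index. Bad
channels are an input mask (such recordings routinely lose half the sites, flagged by
visual inspection; automatic bad-channel detection is out of scope).

## Detection

Per channel, the 2–300 Hz signal is band-passed to 30–300 Hz
(second-order Butterworth, zero-phase) and squared. A 10-s window slides
with 0.25-s overlap. In each window the threshold is

> (mean of qualifying strict local maxima of the squared signal +
> mean of the squared window) / 2,

with threshold = +∞ (no detections) when no maxima qualify. Runs of
supra-threshold samples separated by less than 50 ms are fused; each
run's centre is one event; detections duplicated across the 0.25-s
overlap are removed (centre distance < 150 ms); events whose 300-ms
segment would cross a recording edge are dropped rather than padded.

**The peak floor.** "Qualifying" is the package's resolution of a
genuinely open point: on any stochastic background the mean of *all*
local maxima of the squared signal sits near 1.5× the in-band noise
power, and since the whole construction is scale-invariant the detector
would fire on background at every noise amplitude. `iednm` therefore
requires candidate maxima to exceed `peak_floor_sigma²` (default 5.5²)
times the robust in-band noise power `median(squared)/0.4549` (the
median of χ²₁ normalises the median of a squared Gaussian to its
variance). The median is essentially unaffected by sparse large events,
so the floor keeps scale invariance, leaves the threshold formula and
its hand-checked value untouched, yields zero detections on
background-only windows, and admits events down to ≈5.5 in-band SDs.
`peak_floor_sigma = 0` recovers the literal all-maxima reading.

The detection-accuracy harness scores windows by relative count error,
`accuracy = 100·(1 − mean_w |n_auto − n_true| / max(n_true, 1))`,
clipped to [0, 100]. The synthetic benchmark draws 100 independent 10-s
windows with 0–8 events each and one SNR per window from U(5, 8)
(SNR = P2P / 2·background RMS). Drawing SNR per window rather than per
event reflects the within-focus amplitude homogeneity of drug-induced
discharges over a 10-s stretch; with strongly heterogeneous amplitudes
in one window, the mean-peak threshold necessarily loses the weakest
events — a documented property of the method, not a bug.

## Features and binning

Per detected event, on its 300-ms 2–300 Hz segment: (1) peak-to-peak
amplitude; (2) N/P2P — the segment is centred on its own mean first
(filtered signals are zero-mean by construction; centring keeps the
feature defined on any input), then |min|/(max − min); (3) 2–8 Hz and
(4) 28–80 Hz band power as fractions of 2–300 Hz power, from a single
Hann-tapered periodogram of the full segment (Welch averaging would
destroy the 2–8 Hz resolution of a 300-ms segment); band edges are
half-open [low, high). (5) The IED rate is the event count per 40-s bin.
Per-bin feature values are means over the bin's events; empty interior
bins are filled by linear interpolation between the nearest non-empty
bins (constant extension at the ends) so the normalised trajectories are
defined everywhere; an entirely empty series is an error, not a guess.

Thermal phases are segmented per ON/OFF cycle at 90% of the observed
cycle elevation: heating-up from laser onset to the first crossing,
steady-maximum until the first drop below that level after laser OFF,
thermal-drop to cycle end. The 90% level uses the *observed* cycle
maximum — the only quantity available from a measured trace — not the
model asymptote; for τ = 30 s and a 120-s ON phase the crossing is at
64.5 s, slightly earlier than the 69.1 s an infinite-ON approximation
would give. Cycles rising less than 0.1 °C are flagged undefined.

## Statistics

For each (feature, pulse frequency, site group), each trial contributes
an X array: the three PCtrl bins (recorded once per session, shared by
all trials) followed by the trial's cycle bins — 12 elements for ISP1,
15 for ISP2 — normalised so the last PCtrl bin equals exactly 1.
Similarity is computed per rat against the grand average of all arrays
of the condition: `rho_r = Pearson(grand average, rat r's trial
average)`, negatives truncated to zero, and the statistic is the mean
over rats. The aggregate p-value is the arithmetic mean of the per-rat
two-sided Pearson-test p-values (n = array length) — a reporting
convention, not a combined inference; results with p < 0.05 are flagged
significant. Categories: ρ < 0.4 weak, 0.4 ≤ ρ < 0.8 moderate, ρ ≥ 0.8
strong. Truncation makes reversed trial-to-trial changes *reduce* the
reported similarity instead of cancelling against positive ones, and
implies ρ computed with truncation is never below the untruncated value.

Design points decided here: the grand average includes the rat under
comparison (`leave_one_out = TRUE` excludes it); "all pairwise
combinations" is read as one pair per rat (`by_trial_pairs = TRUE` gives
the per-trial alternative); constant arrays are excluded with a warning
rather than assigned ρ = 0, distinguishing "no variance" from
"anti-correlated". Exact scale invariance of ρ holds for a common
positive rescaling of all arrays once normalisation is re-applied; an
affine shift changes ratio-normalised trajectories and is not an
invariance of the statistic. No multiple-testing correction is applied
across the feature × frequency × group grid; raw p-values are reported.

## Numerical and engineering choices

* Default sampling rate 2 kHz (configurable to 20 kHz): every analysis
  band lies below 300 Hz, and desk-scale runtimes stay in seconds per
  recording. The default cohort uses 8 channels per rat (the four
  Group#1 sites plus four farther sites).
* Recordings shorter than one window are processed as a single truncated
  window with a warning; degenerate windows (all-zero, constant) give an
  infinite threshold and no detections.
* Per-rat seeds are derived as `seed + 7919·rat`, keeping every derived
  seed well below 2³¹ for small master seeds.
* Outputs are plain CSV/JSON; recordings live in memory as S3 objects.
  HDF5 and YAML interfaces were dropped because the target environment
  provides neither binding.

## Known limitations

The similarity statistic's p-value aggregation is a convention; the
benchmark establishes detector performance only under the generator's
stationary Gaussian background; the thermal model is a two-parameter
relaxation with no spatial structure; and IED type labels exist only in
the ground truth — the detector does not classify types, mirroring the
analysis it reimplements.
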