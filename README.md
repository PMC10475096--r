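# iednm

Detection and thermal-modulation analysis of interictal epileptiform
discharges (IEDs) in micro-electrocorticography (µECoG) recordings.

## The problem

Infrared neuromodulation (INM) heats a small patch of cortex with
continuous or pulsed near-infrared laser light. In acute drug-induced
epilepsy models this heating changes measurable properties of the
interictal discharges — their amplitude, negative-peak sharpness,
spectral content and rate. Quantifying those changes requires a chain of
standard but fiddly steps: filtering wideband multichannel signals,
detecting discharges with an adaptive threshold, extracting per-event
features, binning them against the stimulation protocol, normalising to
baseline, and measuring how consistently the trajectories repeat across
trials and animals. `iednm` packages that chain, together with a
synthetic µECoG generator with ground truth so every stage is testable
without animal data. It is aimed at electrophysiologists and methods
developers who need a reproducible reference implementation of this
analysis.

## The method in brief

* **Protocols.** `PCtrl` (120 s baseline) + n × (ON + OFF) cycles:
  ISP1 = 120 s ON + 240 s OFF, ISP2 = 240 s ON + 240 s OFF; laser pulsed
  at 0 (continuous), 1, 10, 100 or 1000 Hz with 50% duty cycle.
* **Preprocessing.** 50 Hz notch (order 2, Q 30) → Butterworth band-pass
  2–300 Hz (order 2) → Butterworth band-stop 80–120 Hz (order 2), all
  zero-phase. Channels grouped by distance from the central aperture
  (Group#1 = the four sites beside the optrode).
* **Detection.** Per 10-s window (0.25 s overlap) on the squared
  30–300 Hz signal: threshold `T = (mean(qualifying local maxima) +
  mean(squared window)) / 2`; supra-threshold runs (fused below 50 ms)
  are events; segments are ±150 ms of the 2–300 Hz signal. Candidate
  maxima must exceed a robust floor of (5.5 σ̂)², σ̂² =
  median(squared)/0.4549, which keeps background-only windows silent
  while preserving the threshold formula and its scale invariance.
* **Features.** P2P amplitude; N/P2P = |min|/(max − min) after mean
  centring; 2–8 Hz and 28–80 Hz band-power fractions of 2–300 Hz power
  (single Hann periodogram); IED count per 40-s bin.
* **Statistics.** Per trial, an X array = 3 PCtrl bins + one cycle
  (12 bins ISP1, 15 ISP2), normalised so the last PCtrl bin = 1.
  Similarity ρ = mean over rats of Pearson(grand-average array, rat
  average array) with negatives truncated to 0; ρ < 0.4 weak,
  0.4–0.8 moderate, ≥ 0.8 strong; mean per-rat test p-value, significant
  below 0.05.

## Worked example

```r
library(iednm)

## a continuous-wave ISP1 session on one virtual rat
protocol <- build_protocol("ISP1", pulse_frequency_hz = 0, n_trials = 2)
rec <- simulate_recording(protocol, effect_model(), n_channels = 4,
                          fs = 2000, seed = 5)
rec
#> <ied_recording> 4 channel(s) x 840.0 s at 2000 Hz, 1753 ground-truth event(s)
#> protocol: ISP1 pulse 0 Hz, 2 trial(s)

## preprocess -> detect -> featurise every channel
events <- analyze_recording(rec)
nrow(events)
#> [1] 1752

## detection accuracy against the ground truth, 10-s windows
win <- data.frame(start_s = seq(0, 830, 10), end_s = seq(10, 840, 10))
evaluate_detection(events$center_time_s, rec$ground_truth, win)
#> [1] 99.9504

## normalised per-trial trajectories and ON-phase suppression
xa <- simulate_cohort(n_rats = 2, protocol = protocol, n_channels = 4,
                      fs = 2000, seed = 1)$xarrays
on_suppression(xa, protocol)           # % P2P reduction during laser ON
#> [1] 22.28534
similarity_table(xa, features = "p2p_uv", groups = "Group#1")
#>   feature   group       rho      p_value category n_pairs significant
#> 1  p2p_uv Group#1 0.9997056 1.741819e-17   strong       2        TRUE
```

The suppression (~22%) recovers the generator's ON-phase amplitude
factor of 0.75 (the additive background floor biases the detected ratio
slightly upward), and the near-unity ρ reflects two virtual rats sharing
one effect model.

`run_pipeline(out_dir, ...)` performs the same steps for a whole cohort
and writes `events.csv`, `xarrays.csv`, `similarity.csv`,
`trajectory.csv` and a structured `log.jsonl` (plus optional trajectory
PNGs), skipping stages whose outputs already exist.

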