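---
title: "Quantifying thalamic recruitment by cortical epileptiform discharges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying thalamic recruitment by cortical epileptiform discharges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrecruit)
```

## The problem

In acute thalamocortical (TC) slices bathed in zero-Mg²⁺ solution, focal
epileptiform discharges arise in neocortex and, over tens of minutes, begin
to recruit thalamus into generalized, synchronous discharges. `tcrecruit`
implements the analysis chain needed to quantify that recruitment from paired
recordings — two-minute calcium-imaging movies of hundreds of cells in one
area alongside kHz-rate whole-cell membrane-potential traces in the other —
and a synthetic two-area generator that makes every stage testable with full
ground truth.

The pipeline stages are:

1. **Onset inference** — per-cell firing onsets from fluorescence.
2. **Event detection** — population discharges in onset rasters; membrane
   depolarization discharges in voltage traces.
3. **Coupling analysis** — cross-area discharge matching, coupling
   reliability (CR), lag statistics, threshold-aligned timelines, and
   fractions of imaged cells correlated with a remote voltage trace.
4. **Circuit correlation** — intracortical pairwise correlations before vs
   after recruitment, with a permutation stationarity filter and
   distance-binned spatial profiles.
5. **Intensity coupling** — per-discharge cortical recruitment fraction vs
   thalamic depolarization area, correlated per field of view (FOV).

## Models and estimators

### Calcium forward model and onset inference

Fluorescence is modelled as a first-order autoregressive (AR(1)) process:
a spike adds a transient of amplitude $A$ that decays as
$\exp(-\Delta t/\tau)$ per frame, with $\tau$ = `calcium_decay_s` (default
1.0 s, an order-of-magnitude match for a synthetic calcium dye at room
temperature). `infer_spike_signal()` inverts this model: a slow per-cell
baseline (running 20th percentile over a 30 s window, robust to
discharge-dense epochs) is removed, the kernel is deconvolved as
$s_t = f_t - \gamma f_{t-1}$ with $\gamma = e^{-1/(r\tau)}$, and the result
is clipped at zero. Residuals the noise model explains without activity are
zeroed: the floor is the larger of `noise_scale` (default 3) robust noise
SDs — estimated from the first differences of the baseline-subtracted trace
— and 5% of the cell's peak signal; the relative term suppresses
interpolation ripple of the estimated baseline, which would otherwise
produce spurious sub-percent "activity" on clean traces.

`binarize_onsets()` thresholds each cell's signal at median + `k_mad` × MAD
(default `k_mad = 3`, the conventional robust threshold) and marks one onset
per rising edge. One onset per threshold crossing is a deliberate reading:
the source analyses assign "a firing onset per discharge", and a rising edge
is the closest operational equivalent that needs no knowledge of discharge
boundaries.

### Population and voltage discharge detection

`detect_circuit_events()` counts, per frame, the distinct cells with an
onset within a trailing window (`window_frames = 1` by default — the
strictest reading of "simultaneous onsets") and opens an event when the
count reaches `ceiling(threshold_fraction × n_cells)`. The default fraction
follows the published population-size rule — 0.25% of cells below 400
cells, 0.33% at 1100, interpolated linearly between — taken verbatim even
though it implies a required count of only a few cells; whether those
percentages stand for 25%/33% cannot be resolved from the text, so both are
reachable through `threshold_fraction`.

`detect_ephys_discharges()` subtracts a 30 s running-median baseline and
takes maximal intervals above `amp_thresh_mv` (default 5 mV) lasting at
least `min_dur_s` (0.2 s), merging events closer than `merge_gap_s`
(0.5 s). These parameters are explicit because the underlying detection
protocol is not specified quantitatively; all are echoed into the pipeline
run log.

### Matching, CR, and lags

`match_discharges()` pairs each cortical discharge with at most one
overlapping thalamic discharge, greedily by descending interval overlap
with earlier-cortical-onset tie-breaks — a deterministic, auditable rule
for the underspecified "overlap was used" instruction. CR is the matched
fraction of cortical discharges (`coupling_reliability()`); the signed lag
is thalamic onset minus cortical onset, so positive lags mean cortex leads.
`lag_statistics()` reports the median lag and the fraction of strictly
positive lags (zero lags count as not leading). The generator draws lags
from a log-normal parameterized by its median (`lag_median_s`, default
0.066 s, matching the tens-of-milliseconds cortico-thalamic delay) and a
log-scale spread — positive support with a right skew.

`align_timeline()` reproduces the population-timeline construction: each
slice's CR (or fraction-of-correlated-cells) series is shifted so the first
sampled point at or above 0.5 sits at time 0, then all points pool into
contiguous 20-minute bins with mean and SEM. No interpolation is used:
recordings are 5–10 minutes apart, and the crossing is a sampled recording.

### Correlated cells

`fraction_correlated_cells()` downsamples the remote voltage trace by
per-frame averaging and computes, per cell, the Pearson correlation over
the full recording with a one-sided test for $r > 0$. A cell is correlated
when $p < 0.05$ **and** $|r| > 0.1$ — both printed clauses are kept even
though, jointly, the one-sided sign rule makes the absolute-value gate
equivalent to $r > 0.1$.

### Stationarity filter

Bleaching-like drifts masquerade as correlation changes, so cells whose
event-aligned signal strength trends in time are excluded. Per event $i$ at
time $t_i$,

$$z(t_i) = \frac{F(t_i) - \langle F_b\rangle}{\sigma_{F_b}},$$

with the baseline mean and SD taken over the 2 s preceding the event
(sample SD, $n-1$ denominator — a convention the analysis needs fixed and
the source leaves open; the same convention is used for every SEM in the
package). $F(t_i)$ is the single frame nearest $t_i$. The least-squares
slope of $z(t_i)$ on $t_i$ is compared with the slopes of `n_shuffles`
(default 1000, seeded) permutations of $z$ across the fixed event times;
the cell is kept when the slope lies within the 10th–90th shuffle
percentiles. With six or fewer events all $n!$ permutations are enumerated
exactly. By construction this discards about 20% of perfectly stationary
cells — the price of the percentile rule, and a property the test suite
checks. A rounding-scaled tolerance widens the band by ~$10^{-10}$
relative units so that analytically tied slopes (e.g. a constant series)
are never discarded on accumulation noise.

### Pairwise correlations and spatial profiles

Correlations are computed on *filtered* traces. The filter identity is not
specified at the source, so the package uses, and logs, a 30 s
running-median detrend followed by a 3-frame centered moving average —
removing the slow drift the stationarity filter targets and high-frequency
shot noise. `pairwise_correlations()` takes at least two recordings per
condition, includes only cells active in at least one detected event before
*and* after recruitment and passing the stationarity filter, concatenates
each condition's filtered traces, and reports one Pearson r per pair per
condition. `before_after_test()` summarises per-pair differences with a
two-sided paired Wilcoxon signed-rank test — the source names no test, and
signed-rank is the distribution-free choice consistent with the rank-sum
tests used elsewhere. `spatial_profile()` bins pairs into 100-µm distance
bins; the SEM divides by the square root of the number of *unique cells* in
the bin rather than the pair count, since one cell enters many pairs.

When testing for a distance trend on synthetic data, bins beyond the FOV
side length are excluded: in a square FOV those distances are reachable
only by corner pairs, so the bins hold a handful of pairs and their means
are dominated by sampling noise.

### Intensity coupling

Cortical discharge intensity is the fraction of *ever-active* cells (any
onset in any recording from the FOV) recruited during the discharge;
thalamic intensity is the trapezoid area of the depolarization above the
running-median baseline, clipped below at zero so hyperpolarizing
excursions cannot cancel signal. The measurement window is the cortical
discharge interval extended to the matched thalamic offset when later,
because thalamus lags cortex and truncating at the cortical offset would
bias the area low. Both conventions are configuration, logged per run.
`intensity_correlation()` reports the per-FOV Pearson r with a two-sided
p-value; the pairing counts as correlated when $p < 0.05$.

## The synthetic generator

`generate_event_schedule()` draws cortical discharges from a renewal
process — exponential waiting times at `event_rate_hz` on top of a 2 s
refractory floor, since discharges are well separated — and recruits
thalamus per event with probability `coupling_schedule(t)`, a function of
absolute experiment time (step schedules emulate the characteristic sudden
recruitment). Per-cell participation is distance-correlated through a few
Gaussian spatial hotspots per event (`spatial_corr_length_um`, default
100 µm): nearby cells see the same hotspots and co-participate. Each
discharge also draws one **intensity factor** shared by both areas
(`event_intensity_range`, default 0.4–1) that scales every cell's
participation probability; strong discharges therefore recruit more
cortical cells *and* drive larger thalamic depolarizations, giving the
cross-area intensity coupling the intensity analysis is designed to detect
while keeping even the weakest coupled discharges above the 5 mV detection
threshold at study-scale (≥250-cell) populations.

`render_fluorescence()` applies the AR(1) kernel to the spike schedule,
adds Gaussian noise, and gives a `bleach_fraction` of cells a linear
baseline ramp; `render_ephys()` renders one rise–plateau–decay envelope per
discharge with peak amplitude equal to participation × `discharge_amp_mv`,
shifted by the event's lag in thalamus. Within a session
(`simulate_session()`), cell coordinates and the identity of drifting cells
are fixed — one FOV — while schedules and noise are redrawn per recording.
All randomness derives from a single seed through fixed per-stage offsets,
so generation is bit-reproducible and stages can be regenerated
independently.

What the generator does **not** emulate: motion and scan-path artifacts,
indicator saturation and nonlinear dF/F, spike bursts within a discharge,
inhibitory dynamics, wave-like discharge propagation inside an area, and
state-dependent noise. Passing tests therefore demonstrate correctness of
the estimators under the stated statistical structure, not robustness to
every pathology of real recordings.

## Numerical choices

- Time is absolute seconds from experiment start; frames and samples map to
  times as `start + (i - 1)/rate`; intervals are half-open, and matching
  requires strictly positive overlap.
- Event merging treats separations within 1 ns of the merge gap as *not*
  mergeable, so frame-grid arithmetic cannot flip a boundary case.
- Frame-average downsampling nudges sample times by 1 ns before binning so
  samples nominally on a frame edge land in the later (half-open) frame.
- Recordings export to CSV with 17 significant digits and re-import through
  the correctly rounded base parser, so containers round-trip bit-exactly.
- Degenerate inputs warn and degrade explicitly: constant traces are "not
  correlated", zero-SD baselines skip the event, empty frame bins carry the
  previous value, and CR/lag statistics refuse (rather than zero) empty
  inputs.

## Problem sizes in the test suite

The suite exercises the study conditions at desk scale: 250-cell FOVs for
detection-dependent analyses, two-minute recordings at 10 Hz imaging and
1 kHz electrophysiology, six-slice step-schedule cohorts for the aligned CR
timeline, 20 simulated slices (~50 discharges each) for intensity coupling,
~2,400 matched discharges for lag recovery, and 1,000 simulated cells for
the stationarity-filter calibration. These sizes give each property
comfortable statistical margin while keeping the default test run fast.

## Limitations

- The onset-inference stage is a first-order non-negative deconvolution; it
  recovers onset *times* (the quantity all downstream stages consume), not
  calibrated spike counts.
- The literal 0.25%/0.33% population threshold implies required counts of a
  few cells and is sensitive to single-cell false positives at high noise;
  users who read those figures as 25%/33% can set `threshold_fraction`.
- Greedy maximum-overlap matching is one admissible resolution of
  discharges that overlap several candidates; alternatives (maximum-weight
  assignment) differ only on pathological geometries with very long
  events.
- CR from a single recording rests on few discharges (often < 10), so
  recording-level CR carries binomial noise of order 0.1; the aligned
  timeline averages over slices for that reason.
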