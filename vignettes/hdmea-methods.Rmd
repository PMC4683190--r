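---
title: "Detection, localization and classification of extracellular spikes on dense MEAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detection, localization and classification of extracellular spikes on dense MEAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdmea)
```

High-density active-pixel MEAs record extracellular voltage on thousands of
electrodes arranged on a square grid (the geometry this package defaults to:
64 x 64 electrodes at 42 µm pitch, 7-8 kHz per channel). At these densities
a spike is small — often only 2-3 frames and 1-4 electrodes carry useful
signal — and both noise level and baseline vary strongly between channels
and over time. `hdmea` implements a complete detection stack built for this
regime: a streaming single-channel detector with incremental baseline and
noise tracking, a multi-electrode detector that interpolates signals onto
virtual channels between electrodes and localizes events at sub-electrode
resolution, a ground-truthed synthetic benchmark, and a rank-based
correlation classifier that separates events participating in network
activity from uncorrelated (noise-like) events.

## Incremental baseline and variability tracking

Every channel carries two state variables updated at each frame from the
corrected sample `x` (raw voltage minus the per-frame median across all
channels, which removes common-mode interference):

* the baseline `b` rises by `0.25 v` when `x > b + v` and falls by `0.5 v`
  when `x < b - v`. The asymmetry makes `b` settle below the median — in
  equilibrium where up- and down-crossings balance 2:1, empirically near
  the 35th-40th percentile on Gaussian input — so that positive
  deflections, which carry no spike information here, barely disturb it;
* the variability `v` (the negative-side noise spread, the unit in which
  all thresholds and amplitudes are expressed) shrinks by `f_v/f_s`
  (0.03125 µV per frame) when `x` lies in `(b - v, b]` *or* at or below
  `b - 6v` — the latter branch stops spikes from inflating the noise
  estimate — and grows by the same amount for `x` in `(b - 5v, b - v]`.

Both conditions are evaluated on the pre-update state; `v` is floored at
0.1 µV to keep amplitude normalization finite.

**Initialization.** The `v` dynamics are bistable: if `v` starts far below
the channel's noise spread, almost every sample falls in the
spike-compensation branch and `v` collapses to the floor, flooding the
stream with giant spurious "events". A start at or above the noise scale is
safe, because from above `v` converges down to its equilibrium. The
detectors therefore buffer the first 128 frames of each channel and start
from the median (for `b`) and 1.4826 x MAD (for `v`); this happens inside
the 0.5 s burn-in during which no events are emitted. `init_frames = 0`
restores a fixed-value start for controlled experiments.

## Single-channel (online) detection

A detection episode opens when the corrected signal falls below
`b - θ v` (default θ = 6) and its deepest sample is the candidate peak.
Three shape criteria then apply:

1. the summed baseline-subtracted voltage, in units of `v`, from the
   threshold crossing to `τ_ev` (0.27 ms) past the peak must exceed
   `θ_ev` = 10.5 — a minimum depolarization area that rejects single-sample
   noise excursions;
2. no deeper minimum may occur within `τ_event` (1 ms) after the peak
   (a deeper follower voids the earlier candidate);
3. the event is flagged *repolarizing* if some frame within `τ_event`
   after the peak exceeds `b + θ_b v` (θ_b = 0), a biphasic-shape
   indicator stored with each event.

Amplitudes are recorded as `(b - x_peak)/v`. Note that the baseline steps
are an appreciable fraction of `v` per frame, so `b` sags during a spike;
the area criterion operates on the running estimates, which is why its
effective severity grows slightly with event width. Events within 1 ms on
the same electrode are reduced to the largest (refractory rule), and a
spatio-temporal lockout (60 µm, +/-0.5 ms) removes the same spike detected
on neighbouring electrodes.

Millisecond windows are converted to frames by rounding half-up at the
actual sampling rate (1 ms is 8 frames at 7563 Hz, 7 at 7000 Hz).

## Interpolating detection

To recover spikes whose charge is split between electrodes, two weighted
signals are formed each frame from the baseline-subtracted traces:

* **five-channel**, on the real grid: the centre channel contributes
  `w_cs/(3 + w_cs)` (default w_cs = 4, weights 4/7 and 1/7) and the three
  of its four neighbours with the largest absolute amplitude contribute
  `1/(3 + w_cs)` each. At array borders the weights of the present
  channels are renormalized to sum to one.
* **four-channel**, on a virtual grid centred between electrodes: the mean
  of the three largest-amplitude values of the surrounding 2 x 2 block.

Discarding the lowest amplitude makes the detector behave like four
implicit templates per location and suppresses single-electrode outliers.
The variability estimate is combined with identical weights, so the
normalized signal stays in units of `v`. Before thresholding, the
interpolated signal is boxcar-averaged over 0.4 ms (3 frames; the
smoothing is applied to the interpolated signal — smoothing before
interpolation would give near-identical results since both operations are
linear except for the amplitude ranking), and the minimum over two
consecutive frames absorbs sub-frame timing offsets between channels.

Each channel also maintains a coupling coefficient `h` that learns, at
1/f_s per frame, how much of the channel's fluctuation follows the global
median increment; `x - g - h (g - g')` removes common-mode residue that
plain median subtraction leaves on channels with coupling gain away from
one. Sign agreement of the increments drives the update; zero increments
leave `h` unchanged.

A local minimum below `-θ` (default 5) becomes an event if no deeper
minimum follows within `τ_event` at the same location and none of the
eight neighbouring locations (four real, four virtual) holds a deeper
minimum within +/-`τ_coinc` (0.27 ms). Exact ties prefer the real grid
over the virtual one, then the lower index, so any single source fires
exactly one of the nine candidate locations.

## Localization

For every event a raw cut-out of 9 channels (3 x 3 block) or 12 channels
(3 x 4 block around a virtual detection, with the 2 x 2 core row-centred)
spanning 1 ms before to 2.2 ms after the peak is reduced to per-channel
amplitudes: snippets are normalized by the recording-averaged variability
(with the averaged `h` scaling the global-median increment), a per-channel
baseline is the median of a composite array — stored online baseline,
earliest pre-peak frames, post-peak tail — and the amplitude is the
maximum of baseline minus the smoothed signal within two frames of the
peak. The smoothing kernel is `(1/6, 1/3, 1/3, 1/6)`, a unity-gain 4-tap
low-pass that accommodates the smaller, slower deflections on distant
electrodes. The running averages of `v` and `h` up to the event time stand
in for whole-recording averages; past the burn-in the difference is
negligible and the detector stays single-pass.

Boundary channels get a surrogate amplitude (available-neighbour count
times 1/8 of their median amplitude); amplitudes are floored at zero, the
20th percentile is subtracted, and off-centre channels that dominate their
one-pitch neighbourhood are clipped to 1/2 (detection channels) or 1/3
(others) of the neighbourhood sum. The location estimate is an iterated
barycentre: subtract the median amplitude, clip at zero, compute the
centre of mass; then twice re-weight amplitudes with the distance taper
`2 - r/d_pitch` (clipped to [0, 1], then to [-0.1, 1], so channels beyond
two pitches count slightly negatively) and recompute. Degenerate cut-outs
return the detection location with amplitude zero; the final barycentre is
clipped to the cut-out bounding box and guarded against near-zero weight
sums (fall back to the previous pass). The reported amplitude is half the
final amplitude sum — the centre electrode carries about half of it.

This estimator deliberately trades a bias towards electrode centres for a
much smaller spread of estimates from the same source; the benchmark
quantifies both (median error well below half a pitch at high amplitude,
~80% of displacements pointing centre-ward).

## Duplicate removal

Within a spatio-temporal lockout (+/-0.5 ms; 60 µm for online, 42 µm for
interpolating detections, which use their localized coordinates) only the
largest-amplitude event survives. Suppression is greedy in descending
amplitude with ties broken by earlier frame then lower channel index —
deterministic, idempotent, order-independent, and equal to the quadratic
reference implementation on every tested instance.

## The synthetic benchmark

Real recordings from this class of hardware are not redistributable, so
the benchmark builds its own ground truth.

**Waveform.** A parametric biphasic "distorted sine": a squared-sine
trough of ~0.4 ms full width followed by a shallower area-balancing
overshoot, exactly zero-mean and normalized to a trough of -1. The
continuous form is evaluated at 16 sub-frame lags so that lag `l + 16`
equals lag `l` shifted by one frame.

**Attenuation.** Electrodes have an effective 16.8 x 16.8 µm² area inside
which a source appears at full amplitude; outside, the potential falls off
as `a0 · r_offset/(ρ + r_offset)` with `r_offset` = 8.4 µm (one fifth of a
pitch, modelling the minimum source-electrode resistance) and `ρ` the
Euclidean distance to the effective area. The far field follows 1/r; a
literal variant with squared length terms in the denominator is available
behind `squared_form` for comparison, but decays quadratically and is not
the default.

**Noise.** The generator emulates an empty-chip recording with five
components, each tied to a physical noise source: (i) per-channel Gaussian
noise with a log-normal channel-to-channel rms spread (sd 0.15) — pooled
amplitudes are then heavy-tailed even though single channels are
near-Gaussian, matching how broad chip-wide voltage histograms arise from
channel variability; (ii) 2% "noisy" channels at three times the rms;
(iii) half of the fast-noise power in a temporally correlated AR(1)
component with a ~1 kHz corner — amplifier and electrode-interface noise
is strongly colored, and a white-noise surrogate would hand any band-pass
comparison detector an unrealistic matched-filter advantage; (iv) a
chip-wide common-mode fluctuation (10 µV rms, in-band, per-channel
coupling gains ~N(1, 0.1)) of the kind that motivates global-median
subtraction in the first place; and (v) a slow AR(1) baseline drift
(2 µV, φ = 0.999). Channel sds are calibrated so the pooled rms meets the
26 µV target within 5%. A per-sample Student-t option (`heavy_tail_df`)
exists; it is not the default because polynomial single-sample tails push
the false-positive amplitude threshold at 0.1 Hz far above any plausible
spike amplitude, which makes every detector look equally useless rather
than discriminating between them.

**Insertions.** Templates are inserted into 3 x 3-electrode patches whose
centres are spaced four electrodes apart (64 patches on a 32 x 32 grid),
with all combinations of 16 sub-electrode positions (a 4 x 4 grid from the
electrode centre to the cell corner), 16 sub-frame lags and the requested
amplitudes, one insertion per 256 frames per patch in seeded-shuffled
order. Patch schedules are staggered by `spacing/n_patches` frames:
simultaneous insertion into every patch would deflect more than half of
all channels at once, and the per-frame median would then subtract the
inserted spikes themselves — an artifact of the benchmark, not of any
real recording, where the whole point of the median is that true spikes
are sparse across 4096 channels.

**Scoring.** Detections match insertions within 3 frames and half an
electrode diagonal, temporally closest first, one-to-one. ROC curves are
computed per patch by sweeping an amplitude threshold over the detector's
own false positives (rates per channel: patch false positives divided by
duration and the nine patch electrodes), and summarized as the area under
the curve up to 0.1 Hz per channel, normalized to [0, 1]; curves ending
below 0.1 Hz extend horizontally. The comparison baseline is a
conventional detector — 0.1-2 kHz 3-pole Bessel band-pass, threshold at a
multiple of the per-channel noise SD estimated robustly on the
insertion-free start of the recording.

What passing this benchmark does and does not show: the synthetic noise
reproduces the rms, channel heterogeneity, spectral shape, common-mode
and drift structure of an empty chip, but none of the biological
confounds of real tissue — overlapping spikes from nearby neurons,
electrode drift over minutes, bursts of true events, or template shapes
outside the parametric family. Detector rankings on it reflect how the
methods exploit array structure, not their behaviour on any particular
preparation.

## Correlation classifier

The classifier exploits the assumption that in these preparations true
spikes are at least weakly correlated through the network while electrode
noise is not; it explicitly does not claim that uncorrelated events are
noise.

*Units and references.* Events are grouped into units (channels for
single-electrode detections; 3 x 3 bins of a 192 x 192 raster for
interpolating detections — a resolution at which the best-aligned block
captures >80% of a pitch-diameter activity spot, verified by numeric
integration in `bin_block_coverage()`). Reference units are local maxima
of activity (rate maxima within 42 µm, or density maxima on a finer
320 x 320 raster smoothed with a 15 µm cone kernel, separated by at least
15 µm, collecting events within 21 µm). The 10 most active reference
units are excluded as suspect.

*Rank axis.* All events plus a clock unit (one reference event every 4
frames, bounding the real-time reach of rank windows) are ordered in
time; Poisson surrogate events — uniform in population rank, 0.1 Hz per
non-reference unit, never into reference units — are interleaved. Ranks
replace times, which compensates rate fluctuations and irregular
intervals.

*Links.* For each unit-reference pair further apart than 42 µm, the
number of event pairs within `τ_corr/2` ranks (τ_corr = 100 by default;
the value is an analysis parameter, not a measured constant) is compared
with the Poisson expectation `τ_corr n_i n_j / Σ n_k`. Pairs with
significantly *fewer* coincidences than chance (one-sided p < 1e-6) are
removed from the statistics — units following an entirely different
activity pattern would otherwise make everything else look correlated —
and pairs with a significant excess are linked. The excess criterion is
implemented as a one-sided Poisson test at the 0.1 level: under this
reading independent Poisson pairs link in under 10% of cases while
burst-sharing pairs link almost always, which is the behaviour the
classifier needs; a weaker "more than expected" reading would link half
of all independent pairs.

*Correlation index.* Per event: the fraction of reference events within
`τ_corr/2` ranks that come from units linked to the event's unit, times
the fraction of mutually linked pairs among those linked units (1 when at
most one is present; a pair counts as linked in either direction). No
coactive reference events gives index 0.

*Unit classification.* Per unit, a combined statistic cumulates amplitude
ranks along the CI ordering and surrogate-referenced CI values along the
amplitude ordering, each half normalized to end at 1/2 so the total is an
empirical uniform CDF under independence. A one-sided Kolmogorov-Smirnov
test (p < 0.01, deficit direction — uncorrelated events have low CI *and*
low amplitude, so the statistic under-accumulates early) decides whether
a boundary exists; if so it is placed at the maximum of the deviation
normalized by the Brownian-bridge standard deviation `2√(k(N-k)/N)`,
which removes the bias towards N/2. Otherwise a conservative per-event
estimator is averaged: the surrogate CI cdf minus the unit's own CI cdf,
renormalized by the remaining mass and clipped to [0, 1] — exactly 0 when
the distributions coincide (ties included), 1 only when they do not
overlap. Reference units receive no surrogates and are flagged rather
than classified.

*Per-event probabilities.* Real and surrogate events are merged and
sorted by CI; the local surrogate fraction around each real event is
computed in a sliding window of half-width L with reflective boundaries,
with L the smallest value at which no renormalized fraction exceeds 1.1
(large windows for noisy units, small ones when CI separates sharply).
Scaled to sum to the unit's estimated uncorrelated count and clipped to
[0, 1], this gives each event its probability of being uncorrelated.

## Spatial activity profiles

For each event, unit vectors towards all events within an annulus
(82-1092 µm) and +/-30 event ranks are pooled on a 17.5 µm grid; a
336 µm sliding-window mean is subtracted (the raw direction field is
dominated by the chip's centre of activity) and the residual is scaled so
that magnitude 1 equals three standard deviations of the random-walk null
(per-component SD `√(N/2)` for N pooled unit vectors). A literal reading
of "normalized by 1/(3N)" is dimensionally inconsistent with a
standard-deviation interpretation and was rejected. The point-proximity
analysis reports event density beyond distance x from the nearest anchor
point, normalized against a homogeneous surrogate, plus the mutual
association of smoothed density maxima and anchors.

## Problem sizes and numerical choices

The packaged acceptance computations use: a 32 x 32 grid (64 patches),
five amplitudes from 120 to 200 µV and 60 s of 26 µV-rms noise for the
detector comparison; a 16 x 16 grid with six amplitudes from 60 to 200 µV
(56 s) for localization; 200 units x 15 min rasters for the classifier;
and 1e6 frames for the percentile-tracking check. These sizes, chosen as
a desk-scale version of a full-array experiment, give bootstrap-stable
orderings and thousands of matched events per amplitude band.

Degenerate inputs are defined throughout: empty recordings and event
tables pass through; flat signals produce no events; all-constant
cut-outs localize to the detection point with amplitude zero; units
without surrogates are flagged; ties break deterministically (earlier
frame, lower index, real grid before virtual). Barycentre weight sums
below 1e-6 fall back to the previous pass. Detector state lives behind
external pointers, so event streams are bit-identical across chunkings
and reruns.

## Known limitations

The spike template and attenuation model are parametric stand-ins; no
claim of waveform fidelity to any preparation is made. The localization
bias towards electrode centres is inherent to the median-subtract-clip
barycentre and is reported, not corrected. The conservative classifier
estimator underestimates correlated activity when the real and surrogate
CI distributions overlap partially (it is exact at the two extremes); on
burst-synchronized rasters with a 20% noise admixture it overestimates
the per-unit noise fraction by a stable ~9 percentage points, which the
acceptance computation reports.
Reference units are never classified. The HDF5 container variant of the
raw-recording reader is not implemented in this build; the flat binary +
JSON sidecar format is the native interchange.
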