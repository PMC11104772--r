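---
title: "Methods: CBF estimation, bead-flow tracking and permutation inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CBF estimation, bead-flow tracking and permutation inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`ciliaflow` quantifies two readouts of ependymal ciliary function:
the ciliary beat frequency (CBF) of the ventricular wall from high-speed
brightfield video, and the speed of near-wall cerebrospinal-fluid flow
from fluorescent-microbead time-lapse movies. Both feed a two-group
permutation test. This vignette records the models, the tunable
parameters, and the numerical and design choices, including where a
choice was genuinely open.

# CBF from ROI brightness traces

## Model

Beating cilia sweep through a small image window periodically, so the
mean brightness of a window over the ciliated layer is (approximately) a
noisy sinusoid at the beat frequency, possibly on a slow drift. The
estimator is therefore: sample square ROIs inside an ependymal-layer
mask; average the `size²` pixels of each ROI per frame; detrend; taper;
take the one-sided periodogram; report the frequency of the maximal
in-band bin.

The periodogram is normalized by the window power,
$P(f_k) = c_k \, |X_k|^2 / \sum_n w_n^2$ with $c_k = 2$ except at DC and
Nyquist, so that with a rectangular window a unit-amplitude bin-centered
sinusoid of length $N$ carries its full energy $N/2$ in a single bin and
Parseval's identity holds (`sum(power) == sum(x²)`); both are enforced by
tests against a naive $O(N^2)$ DFT.

## ROI placement

The placement contract mirrors the bench protocol: 16–20 ROIs of
11×11 px, centers at least 30 px apart (Euclidean, center-to-center; an
`edge` separation mode is available for the stricter edge-to-edge
reading), every footprint pixel inside the mask. Placement is seeded
random sequential adsorption: valid centers (those whose whole footprint
is mask-true, computed from an integral image) are drawn uniformly;
each accepted center removes all candidates closer than the separation.
Rejected draws never change the accepted set, so this is
distributionally identical to naive draw-and-reject sampling with an
unbounded attempt budget, while terminating exactly when the pool jams.
If the pool jams below `n_min` the result is flagged `under_sampled`;
an empty feasible set is an error. A user CSV of centers can replace the
sampler to reproduce manually chosen ROIs.

## Parameters

| knob | default | unit | why |
|---|---|---|---|
| `roi$size` | 11 | px | window matched to a few cilia tufts |
| `roi$min_sep` | 30 | px | near-independent ROIs |
| `roi$n_min`–`n_max` | 16–20 | — | per-video sampling effort |
| `band_hz` | (5, 100) | Hz | murine ependymal CBF sits well inside; excludes DC drift and low-frequency flicker |
| `window` | hann | — | controls leakage for non-bin-centered beat frequencies; `rect` retained for oracle checks |
| `detrend` | linear | — | removes photobleaching-like drift; `mean` available |
| `snr_min` | 20 | — | QC threshold, see below |

No zero-padding is applied; the spectral resolution `frame_rate/N` is
reported with every estimate, and estimates are accurate to that bin
width, not beyond.

## QC threshold

An ROI passes QC when the peak in-band power divided by the median
in-band power reaches `snr_min`. The periodogram of white noise has
exponentially distributed bins, so its max/median over $m$ in-band bins
concentrates near $\ln m / \ln 2 \approx 7$ for $m \approx 100$ — a
threshold of 3–5 would pass pure noise almost surely. The default of 20
sits far above that null (noise exceeds it with probability
$\sim m\,e^{-20\ln 2} \approx 10^{-4}$) and orders of magnitude below
genuine beating, which measures $10^4$–$10^5$ in simulation. QC-failed
ROIs are reported with a flag, never silently dropped.

# Bead-flow tracking

Detection smooths each frame with a Gaussian of `sigma_px` (default 2 px,
matched to a ~2 µm bead imaged over a few pixels), finds strict
8-neighbourhood local maxima, and keeps peaks above
`median + max(threshold_rel·(max − median), noise_floor·mad)` of the
smoothed frame. The first term is the relative contrast threshold
(invariant to global intensity rescaling); the second is a robust noise
floor (default 8 robust SDs) without which a background-only frame would
always yield detections, since any frame's maximum exceeds a fraction of
itself. Centroids are refined to sub-pixel precision by intensity-weighted
mean over a `(2·ceil(sigma)+1)²` neighbourhood.

Linking is greedy mutual-nearest-neighbour between consecutive frames
with a displacement gate `max_disp_px`; ambiguous mutual matches break by
smaller displacement, then lower index. Beads in this assay are sparse,
which favours this simple deterministic scheme over global assignment;
there is no gap closing, so a missed detection splits a track. Tracks
shorter than `min_len` (default 3) points are discarded. Speed is the
mean frame-to-frame displacement scaled by `pixel_size/interval` (path
speed, matching pointwise manual tracking); `speed_mode = "net"` gives
end-to-end displacement over elapsed time instead. With per-frame
positional jitter $\sigma_j$ the path speed is biased upward by
$\approx \sigma_j^2/d$ per step of length $d$ px; at the defaults
(0.3 px jitter, steps of 2–12 px) this stays under ~2%, within the 5%
recovery tolerance the tests enforce.

# Permutation inference

The two-group test reassigns the pooled per-ROI frequencies (or
per-track speeds) to groups of the original sizes. Monte-Carlo p-values
use add-one smoothing, $p = (1 + k)/(1 + B)$ with $B$ the iteration
count (default 10,000), the standard conservative estimator that never
returns 0. When the number of distinct reassignments
$\binom{n}{n_a} \le 200{,}000$ the test silently switches to full
enumeration and returns the exact rational $p = k/m$ without smoothing.
Two-sided tests compare absolute values of the statistic; comparisons
use a $10^{-12}$ slack so that floating-point ties (e.g. after shifting
all values by a constant) count as ties.

The default exchange unit is the individual measurement, matching the
"n = X ROIs from Y videos" reporting grain; because ROIs within a video
are correlated, this overstates the effective sample size, so a
video-level block permutation (`exchange_unit = "video"`) is provided.
No multiple-testing correction is applied — the module runs one test per
comparison.

# Synthetic ground truth

The ciliary simulator renders
$I(r,c,t) = \text{baseline} + A(r,c)\sin(2\pi f t/\text{rate} +
\mathbf{k}\cdot(r,c)) + \varepsilon$, clipped to $[0,1]$: a single shared
beat frequency, a linear phase gradient (the metachronal wave), a static
smooth random amplitude field supported on a horizontal band (the
ependymal layer and its mask), and additive Gaussian camera noise. The
parameter guard `baseline ± (amplitude + 3σ) ∈ [0,1]` keeps clipping
negligible so spectra stay interpretable. Defaults are 1000 frames at
1000 Hz on a 200×240 px frame — large enough to hold ~20 ROIs at 30 px
separation — with amplitude 0.2, baseline 0.5 and noise SD 0.05. The
bead simulator advects Gaussian spots at commanded speeds with per-axis
positional jitter on a noisy background, one frame per 200 ms, and
reports exact centers (and frame exits) as truth. Both simulators are
pure functions of their seed.

What the simulators deliberately do not model: frequency heterogeneity
within a field (all pixels share one $f$), Poisson photon statistics
(noise is Gaussian; variance checks stay analytic), drift and focus
changes, bead size variation, and out-of-plane motion. Passing the
recovery tests therefore shows the estimators are correct for their
stated signal model, not that they are robust to every artefact of real
acquisitions; robustness to mixed frequencies can be probed by
concatenating videos with different `cbf_hz`.

Scenario presets `wt_like` (28 Hz) and `ko_like` (34 Hz) are arbitrary
fixtures placed inside the murine ependymal range to give a clear 6 Hz
contrast; they are not measurements of any real cohort.

# Validation scale and numerical choices

The test suite exercises, at desk scale chosen as a compromise between
coverage and turnaround: a recovery grid of true CBF 10–60 Hz × noise SD
{0, 0.05, 0.1} on 64×64 px videos (1000 frames at 1000 Hz, ≥3 ROIs per
cell, median error ≤ 1 bin; exact recovery at σ = 0 for bin-centered
tones); a 10+10-video cohort contrast at full 200×240 px scale; 400 null
replicates of the 10,000-iteration test (type-I error within the
binomial band around 0.05); 1,000 seeded ROI samplings with exhaustive
constraint checks; and bead speeds 10–60 µm/s at 0.3 px jitter (per-bead
error ≤ 5%). `scripts/acceptance.R` re-runs the same computations from
scratch under a caller-supplied seed.

Other numerical conventions: intensities normalize to [0,1] by the
integer type maximum on load and round-trip through 16-bit TIFF within
1/65535; coordinates are 0-based (row, col) with odd windows spanning
center ± (size−1)/2; spectral ties break toward the lower frequency; a
flat spectrum yields `cbf_hz = NA` with `passed_qc = FALSE`; all stage
seeds derive from one run seed via a fixed 32-bit modular hash, so stages
are independently reproducible and any one stage can be replayed.

# Known limitations

ROI-level exchange ignores within-video correlation (see above); the
tracker handles neither gaps nor merges, so crowded or blinking beads
fragment; the ependymal mask is an input, not a segmentation; CBF
estimates are limited to the dominant spectral peak — waveform shape,
phase maps and metachronal wavelength are out of scope.
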