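# ciliaflow

Quantitative analysis of ependymal ciliary motility and near-wall
cerebrospinal-fluid (CSF) flow from microscopy video, in R.

Ependymal cells lining the brain ventricles carry motile cilia whose
coordinated beating propels CSF along the ventricular wall; disturbed
beating is linked to hydrocephalus and ventriculomegaly. Two classic
bench assays probe this system:

- **Ciliary beat frequency (CBF)** — high-speed video (~1000 frames/s) of
  beating cilia is sampled with small regions of interest (ROIs) confined
  to the ependymal layer; each ROI's mean-brightness trace is Fourier
  transformed and the dominant spectral peak is the beat frequency.
- **Bead flow assay** — fluorescent microbeads released over the exposed
  ventricular wall are filmed at 5 frames/s (one frame every 200 ms) and
  their speed (μm/s) measures the ependymal-driven flow.

`ciliaflow` implements both ends to end, plus the group statistics and the
synthetic ground truth needed to validate them:

1. **ROI spectral analysis** — seeded placement of 16–20 ROIs (11×11 px,
   centers ≥30 px apart, footprints inside the layer mask), per-ROI
   detrending, Hann-tapered one-sided periodogram
   `P(f_k) = c_k |X_k|² / Σw²` (so a rect-windowed unit sinusoid carries
   its energy N/2 in one bin), and in-band peak picking with a
   peak/median SNR quality filter.
2. **Bead tracking** — Gaussian-matched spot detection with sub-pixel
   centroids, greedy mutual-nearest-neighbour track linking, and path
   speed `v = mean‖Δx‖ · px/Δt`.
3. **Permutation test** — two-group comparison by random reassignment of
   pooled measurements (default 10,000 iterations, add-one-smoothed
   `p = (1+k)/(1+B)`), switching automatically to exhaustive enumeration
   (exact `p = k/m`) when `choose(n, n_a) ≤ 200,000`.
4. **Simulators** — metachronally beating ciliary fields
   `I = baseline + A(r,c)·sin(2πft + k·(r,c)) + ε` and constant-velocity
   bead movies with positional jitter, bit-reproducible from a seed.

## Worked example

```r
library(ciliaflow)

# Simulate a high-speed ciliary video (1000 frames @ 1000 Hz, true CBF 28 Hz)
sim <- simulate_cilia_video(cilia_scenario("wt_like", seed = 1))
cfg <- analysis_config(list(seed = 2))
tab <- analyze_video(sim$stack, sim$mask, cfg, video_id = "demo")
head(tab[, c("roi_id", "cbf_hz", "snr", "passed_qc")])
#>   roi_id cbf_hz      snr passed_qc
#> 1      1     28 169605.6      TRUE
#> 2      2     28 117494.9      TRUE
#> 3      3     28 139754.8      TRUE
mean(tab$cbf_hz[tab$passed_qc])
#> [1] 28
```

Every QC-passing ROI recovers the simulated 28 Hz beat to the spectral
resolution (frame_rate/N = 1 Hz here). Comparing a 28 Hz and a 34 Hz
cohort (10 videos each, 16–20 ROIs per video):

```r
wt <- simulate_cbf_cohort(10, cilia_scenario("wt_like"), cfg, seed = 101)
ko <- simulate_cbf_cohort(10, cilia_scenario("ko_like"), cfg, seed = 202)
out <- compare_cbf_tables(wt, ko, labels = c("WT", "KO"))
out$test
#> Permutation test (mean_diff, WT vs KO): observed = -6, p = 9.999e-05 (10000 iterations)
out$summary
#>   group n_rois n_videos mean_cbf_hz sem_cbf_hz
#> 1    WT    200       10          28          0
#> 2    KO    200       10          34          0
```

The observed mean difference equals the simulated −6 Hz contrast and the
permutation p-value is at the Monte-Carlo floor `1/(B+1)`. Bead movies
work the same way:

```r
bs <- simulate_bead_movie(bead_sim_params(n_beads = 3,
                                          speed_um_s = c(10, 30, 50),
                                          seed = 5))
track_beads(bs$stack)$speeds
#>   track_id n_points speed_um_s region_label
#> 1        1       25   9.993855           NA
#> 2        2       25  30.131788           NA
#> 3        3       25  50.074877           NA
```

File-based entry points (`run_cbf`, `run_beads`, `run_permtest`,
`run_simulate`) read TIFF stacks with JSON metadata sidecars, write CSV
tables plus a `run_manifest.json` (config hash, seed, input checksums),
and are byte-reproducible for a fixed config and seed. A thin CLI wrapper
lives at `inst/scripts/ciliaflow`.

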