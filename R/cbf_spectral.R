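#' Detrend a brightness trace
#'
#' Removes the slow component of an ROI trace before spectral analysis:
#' "mean" subtracts the sample mean, "linear" subtracts the least-squares
#' line. Either way the output has zero mean (to within 1e-10), so spectral
#' power at DC does not mask the beat frequency.
#'
#' @param trace a `RoiTrace` (or bare numeric vector).
#' @param method "mean" or "linear" (default).
#' @return the detrended trace, same class as the input.
#' @export
detrend_trace <- function(trace, method = c("linear", "mean")) {
  method <- match.arg(method)
  x <- if (inherits(trace, "RoiTrace")) trace$values else trace
  if (length(x) < 2L) stop_ciliaflow("trace too short to detrend")
  if (method == "mean") {
    y <- x - mean(x)
  } else {
    t <- seq_along(x) - 1
    fit <- stats::lm.fit(cbind(1, t), x)
    y <- unname(fit$residuals)
  }
  if (inherits(trace, "RoiTrace")) {
    trace$values <- y
    trace
  } else y
}

hann_window <- function(n) {
  # symmetric Hann (matches signal::hanning); n >= 2
  as.numeric(signal::hanning(n))
}

#' One-sided power spectrum of a trace
#'
#' Applies a taper, takes the real-input discrete Fourier transform and
#' returns the one-sided power spectrum from DC to Nyquist. Power is
#' normalized by the window power (sum of squared taper values) so that a
#' rect-windowed unit-amplitude bin-centered sinusoid concentrates its
#' full energy (N/2 for unit amplitude) in a single bin, and the rect
#' spectrum satisfies Parseval: the sum of one-sided power equals the
#' trace energy.
#'
#' @param trace a detrended `RoiTrace` (or numeric vector plus
#'   `frame_rate_hz`).
#' @param window "hann" (default; controls leakage for non-bin-centered
#'   beat frequencies) or "rect".
#' @param frame_rate_hz sampling rate, required when `trace` is a bare
#'   vector.
#' @return an object of class `PowerSpectrum` with fields `freqs_hz`,
#'   `power`, `n_samples`, `window_name`, `frame_rate_hz`.
#' @export
power_spectrum <- function(trace, window = c("hann", "rect"),
                           frame_rate_hz = NULL) {
  window <- match.arg(window)
  if (inherits(trace, "RoiTrace")) {
    x <- trace$values
    fr <- trace$frame_rate_hz
  } else {
    x <- as.numeric(trace)
    fr <- frame_rate_hz
    if (is.null(fr)) stop_ciliaflow("frame_rate_hz required for bare traces")
  }
  n <- length(x)
  if (n < 8L) stop_ciliaflow("trace too short for a spectrum (need >= 8)")
  w <- if (window == "hann") hann_window(n) else rep(1, n)
  X <- stats::fft(x * w)
  nb <- n %/% 2L + 1L
  p <- Mod(X[seq_len(nb)])^2 / sum(w^2)
  scale2 <- rep(2, nb)
  scale2[1] <- 1
  if (n %% 2L == 0L) scale2[nb] <- 1  # Nyquist bin is unpaired
  p <- p * scale2
  structure(list(freqs_hz = (seq_len(nb) - 1) * fr / n,
                 power = p,
                 n_samples = n,
                 window_name = window,
                 frame_rate_hz = fr),
            class = "PowerSpectrum")
}

#' Dominant in-band frequency of a power spectrum
#'
#' Picks the ciliary beat frequency as the frequency of the maximal power
#' among bins with `band[1] < f <= band[2]`. Quality control: `snr` is the
#' peak power divided by the median in-band power; the estimate passes QC
#' when `snr >= snr_min` and the peak power is strictly positive. A flat
#' (all-zero) spectrum yields `cbf_hz = NA` and `passed_qc = FALSE`. Ties
#' break toward the lower frequency.
#'
#' @param spec a `PowerSpectrum`.
#' @param band_hz numeric c(low, high) search band (default c(5, 100): well
#'   clear of DC drift yet far above murine ependymal beat frequencies).
#' @param snr_min QC threshold on peak/median in-band power (default 20).
#'   The periodogram peak/median of pure white noise concentrates near
#'   ln(nbins)/ln 2 (about 7 for ~100 in-band bins), so the threshold must
#'   sit well above that to exclude non-beating ROIs; genuine beating gives
#'   ratios several orders of magnitude larger.
#' @param roi_id optional identifier carried into the result.
#' @return an object of class `CbfEstimate` with fields `roi_id`, `cbf_hz`,
#'   `peak_power`, `snr`, `passed_qc`, `band_hz`, `freq_resolution_hz`.
#' @export
dominant_frequency <- function(spec, band_hz = c(5, 100), snr_min = 20,
                               roi_id = NA_integer_) {
  stopifnot(inherits(spec, "PowerSpectrum"), length(band_hz) == 2L)
  nyq <- spec$frame_rate_hz / 2
  if (band_hz[1] < 0 || band_hz[2] <= band_hz[1] || band_hz[1] >= nyq)
    stop_ciliaflow("band must satisfy 0 <= low < high with low < Nyquist")
  sel <- spec$freqs_hz > band_hz[1] & spec$freqs_hz <= min(band_hz[2], nyq)
  if (sum(sel) < 3L)
    stop_ciliaflow("band contains fewer than 3 frequency bins")
  pw <- spec$power[sel]
  fq <- spec$freqs_hz[sel]
  i <- which.max(pw)  # first maximum = lowest frequency on ties
  peak <- pw[i]
  med <- stats::median(pw)
  if (peak <= 0) {
    cbf <- NA_real_; snr <- 0; qc <- FALSE
  } else {
    cbf <- fq[i]
    snr <- if (med > 0) peak / med else Inf
    qc <- snr >= snr_min
  }
  structure(list(roi_id = roi_id, cbf_hz = cbf, peak_power = peak,
                 snr = snr, passed_qc = qc, band_hz = as.numeric(band_hz),
                 freq_resolution_hz = spec$frame_rate_hz / spec$n_samples),
            class = "CbfEstimate")
}

#' Full per-video CBF analysis
#'
#' Composes the pipeline for one video: sample mask-confined ROIs, extract
#' each mean-brightness trace, detrend, take the power spectrum, and pick
#' the dominant in-band frequency. One row is emitted per ROI, including
#' QC-failed ROIs (flagged, never silently dropped). Deterministic for a
#' fixed config seed.
#'
#' @param stack a `VideoStack`.
#' @param mask a `LayerMask`.
#' @param config an [analysis_config()] list (defaults used when omitted).
#' @param video_id identifier copied into every output row.
#' @param rois optional pre-placed list of `RoiSpec` (e.g. from
#'   [read_rois_csv()]); when given, the sampler is skipped.
#' @return data.frame with columns video_id, roi_id, center_row, center_col,
#'   cbf_hz, peak_power, snr, passed_qc, freq_resolution_hz, band_low_hz,
#'   band_high_hz, seed.
#' @export
analyze_video <- function(stack, mask, config = analysis_config(),
                          video_id = NA_character_, rois = NULL) {
  config <- analysis_config(config)
  if (is.null(rois)) {
    rois <- sample_rois(mask,
                        n_min = config$roi$n_min, n_max = config$roi$n_max,
                        size = config$roi$size, min_sep = config$roi$min_sep,
                        seed = stage_seed(config$seed, "roi"),
                        separation_mode = config$roi$separation_mode)
  }
  rows <- lapply(seq_along(rois), function(i) {
    tr <- extract_trace(stack, rois[[i]])
    tr <- detrend_trace(tr, config$detrend)
    sp <- power_spectrum(tr, config$window)
    est <- dominant_frequency(sp, band_hz = config$band_hz,
                              snr_min = config$snr_min, roi_id = i)
    data.frame(video_id = video_id, roi_id = i,
               center_row = rois[[i]]$center_row,
               center_col = rois[[i]]$center_col,
               cbf_hz = est$cbf_hz, peak_power = est$peak_power,
               snr = est$snr, passed_qc = est$passed_qc,
               freq_resolution_hz = est$freq_resolution_hz,
               band_low_hz = config$band_hz[1],
               band_high_hz = config$band_hz[2],
               seed = config$seed)
  })
  do.call(rbind, rows)
}
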