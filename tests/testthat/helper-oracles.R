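# Independent oracles and tiny fixture builders shared across tests.

# Naive O(N^2) one-sided power spectrum straight from the DFT definition;
# deliberately avoids stats::fft so it can cross-check power_spectrum().
naive_dft_power <- function(x, window = "rect") {
  n <- length(x)
  w <- if (window == "hann") {
    0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  } else rep(1, n)
  xw <- x * w
  nb <- n %/% 2 + 1
  k <- 0:(nb - 1)
  M <- exp(-2i * pi * outer(k, 0:(n - 1)) / n)
  p <- Mod(as.vector(M %*% xw))^2 / sum(w^2)
  s <- rep(2, nb); s[1] <- 1
  if (n %% 2 == 0) s[nb] <- 1
  p * s
}

# Least-squares line fit by the normal equations (oracle for detrending).
normal_eq_line <- function(x) {
  t <- seq_along(x) - 1
  n <- length(x)
  b <- (n * sum(t * x) - sum(t) * sum(x)) / (n * sum(t^2) - sum(t)^2)
  a <- mean(x) - b * mean(t)
  a + b * t
}

# A stack whose frame t is a constant plane c_values[t].
constant_stack <- function(c_values, shape = c(20L, 20L),
                           frame_rate_hz = 100) {
  frames <- array(rep(c_values, prod(shape)),
                  dim = c(length(c_values), shape))
  video_stack(frames, frame_rate_hz)
}

# A pure sinusoidal trace at freq_hz sampled at rate_hz.
tone_trace <- function(freq_hz, n, rate_hz, amplitude = 1, phase = 0) {
  amplitude * sin(2 * pi * freq_hz * (0:(n - 1)) / rate_hz + phase)
}

# Render one Gaussian spot on a zero background (detection fixture).
spot_frame <- function(shape, r0, c0, sigma = 2, peak = 1) {
  r <- outer((seq_len(shape[1]) - 1 - r0)^2,
             (seq_len(shape[2]) - 1 - c0)^2, "+")
  peak * exp(-r / (2 * sigma^2))
}

# Exhaustive pairwise ROI-set constraint check; returns violation count.
roi_violations <- function(rois, mask, min_sep) {
  if (inherits(mask, "LayerMask")) mask <- mask$mask
  v <- 0L
  for (roi in rois) {
    h <- (roi$size - 1L) %/% 2L
    rs <- (roi$center_row - h):(roi$center_row + h)
    cs <- (roi$center_col - h):(roi$center_col + h)
    if (min(rs) < 0 || min(cs) < 0 ||
        max(rs) > nrow(mask) - 1 || max(cs) > ncol(mask) - 1) {
      v <- v + 1L
    } else if (!all(mask[rs + 1L, cs + 1L])) {
      v <- v + 1L
    }
  }
  k <- length(rois)
  if (k >= 2) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      d <- sqrt((rois[[i]]$center_row - rois[[j]]$center_row)^2 +
                  (rois[[i]]$center_col - rois[[j]]$center_col)^2)
      if (d < min_sep) v <- v + 1L
    }
  }
  v
}

# Small, fast cilia scenario for end-to-end tests.
small_cilia_params <- function(cbf_hz = 25, noise_sigma = 0.05, seed = 3,
                               frame_count = 1000L) {
  cilia_sim_params(frame_count = frame_count, shape = c(64L, 64L),
                   cbf_hz = cbf_hz, noise_sigma = noise_sigma,
                   band = c(8L, 55L), seed = seed)
}

small_roi_config <- function(seed = 11L) {
  analysis_config(list(roi = list(n_min = 4L, n_max = 6L, min_sep = 15),
                       seed = seed))
}

# Seed-scoped evaluation for fixture construction inside tests.
with_seed_for_test <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}
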