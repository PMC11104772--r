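test_that("detrending removes constants, lines, and matches the normal equations", {
  expect_equal(detrend_trace(rep(0.7, 50), "mean"), rep(0, 50))
  ramp <- 0.2 + 0.003 * (0:99)
  expect_lt(max(abs(detrend_trace(ramp, "linear"))), 1e-10)
  # sinusoid + ramp: linear detrend leaves the residual of the LS line
  x <- tone_trace(7, 200, 100, amplitude = 0.3) + 0.1 + 0.002 * (0:199)
  resid <- detrend_trace(x, "linear")
  expect_equal(resid, x - normal_eq_line(x), tolerance = 1e-10)
  expect_lt(abs(mean(resid)), 1e-10)
  expect_error(detrend_trace(0.5), "short")
})

test_that("a bin-centered rect-windowed tone puts all its energy in one bin", {
  x <- tone_trace(28, 1000, 1000)
  sp <- power_spectrum(x, "rect", frame_rate_hz = 1000)
  expect_length(sp$power, 501)
  expect_equal(max(sp$freqs_hz), 500)
  i <- which(sp$freqs_hz == 28)
  expect_equal(sp$power[i], 500)  # trace energy N/2 for unit amplitude
  expect_true(all(sp$power[-i] < 1e-10 * sp$power[i]))
})

test_that("power_spectrum matches the naive DFT oracle for both windows", {
  set.seed(5)
  for (n in c(64, 100, 257)) {
    for (win in c("rect", "hann")) {
      x <- stats::rnorm(n)
      x <- x - mean(x)
      got <- power_spectrum(x, win, frame_rate_hz = 500)$power
      want <- naive_dft_power(x, win)
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
})

test_that("rect spectrum satisfies Parseval and all-zero traces give zero power", {
  set.seed(6)
  for (n in c(128, 255)) {
    x <- stats::rnorm(n)
    sp <- power_spectrum(x, "rect", frame_rate_hz = 100)
    expect_equal(sum(sp$power), sum(x^2), tolerance = 1e-9)
  }
  spz <- power_spectrum(rep(0, 64), "rect", frame_rate_hz = 100)
  expect_true(all(spz$power == 0))
  expect_error(power_spectrum(rep(0, 4), frame_rate_hz = 100), "short")
})

test_that("dominant_frequency finds tones, bounds leakage, and flags flat spectra", {
  sp <- power_spectrum(tone_trace(28, 1000, 1000), "rect",
                       frame_rate_hz = 1000)
  est <- dominant_frequency(sp, band_hz = c(5, 100), snr_min = 3)
  expect_equal(est$cbf_hz, 28.0)
  expect_true(est$passed_qc)
  expect_equal(est$freq_resolution_hz, 1)

  # non-bin-centered tone: error bounded by one bin width (1000/1024 Hz)
  sp2 <- power_spectrum(tone_trace(33.3, 1024, 1000) -
                          mean(tone_trace(33.3, 1024, 1000)),
                        "hann", frame_rate_hz = 1000)
  est2 <- dominant_frequency(sp2, c(5, 100), 3)
  expect_lte(abs(est2$cbf_hz - 33.3), 1000 / 1024)

  spz <- power_spectrum(rep(0, 64), "rect", frame_rate_hz = 1000)
  estz <- dominant_frequency(spz, c(5, 100), 3)
  expect_false(estz$passed_qc)
  expect_true(is.na(estz$cbf_hz))
  expect_error(dominant_frequency(sp, c(600, 700)), "band")
})

test_that("dominant_frequency is invariant to positive rescaling of the spectrum", {
  set.seed(8)
  x <- tone_trace(23, 512, 1000) + stats::rnorm(512, sd = 0.3)
  sp <- power_spectrum(x - mean(x), "hann", frame_rate_hz = 1000)
  e1 <- dominant_frequency(sp, c(5, 100), 3)
  sp$power <- sp$power * 7.3e4
  e2 <- dominant_frequency(sp, c(5, 100), 3)
  expect_equal(e2$cbf_hz, e1$cbf_hz)
  expect_equal(e2$snr, e1$snr, tolerance = 1e-12)
})

test_that("analyze_video recovers the simulated beat frequency per ROI", {
  sim <- simulate_cilia_video(small_cilia_params(cbf_hz = 25))
  tab <- analyze_video(sim$stack, sim$mask, small_roi_config(),
                       video_id = "v1")
  ok <- tab[tab$passed_qc, ]
  expect_gte(nrow(ok), 4)
  expect_true(all(abs(ok$cbf_hz - 25) <= 1))  # within one 1-Hz bin
  # determinism: same stack and config give the identical table
  tab2 <- analyze_video(sim$stack, sim$mask, small_roi_config(),
                        video_id = "v1")
  expect_identical(tab, tab2)
})

test_that("a non-oscillating video yields no QC-passing ROIs", {
  p <- small_cilia_params(cbf_hz = 25, noise_sigma = 0.02)
  p$amplitude <- 0
  sim <- simulate_cilia_video(p)
  tab <- analyze_video(sim$stack, sim$mask, small_roi_config())
  expect_equal(sum(tab$passed_qc), 0)
  expect_equal(nrow(tab), length(unique(tab$roi_id)))  # failures reported
})
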