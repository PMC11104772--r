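test_that("cilia simulation is a pure function of its seed", {
  p <- small_cilia_params(seed = 13, frame_count = 50L)
  s1 <- simulate_cilia_video(p)
  s2 <- simulate_cilia_video(p)
  expect_identical(s1$stack$frames, s2$stack$frames)
  expect_identical(s1$mask$mask, s2$mask$mask)
  p2 <- p; p2$seed <- 14L
  expect_false(identical(simulate_cilia_video(p2)$stack$frames,
                         s1$stack$frames))
})

test_that("zero-amplitude videos contain only noise variance", {
  p <- small_cilia_params(noise_sigma = 0.05, frame_count = 400L)
  p$amplitude <- 0
  sim <- simulate_cilia_video(p)
  # temporal variance of band pixels: noise only, no oscillatory component
  vars <- apply(sim$stack$frames[, 20:40, 20:40], c(2, 3), var)
  expect_lt(mean(vars) / 0.05^2, 1.1)
  expect_gt(mean(vars) / 0.05^2, 0.9)
  expect_lt(max(vars) / 0.05^2, 1.5)
})

test_that("the mask is the stated band and the amplitude field respects it", {
  p <- cilia_sim_params(frame_count = 5L, shape = c(60L, 80L),
                        band = c(10L, 39L), seed = 2)
  sim <- simulate_cilia_video(p)
  expect_true(all(sim$mask$mask[11:40, ]))
  expect_false(any(sim$mask$mask[-(11:40), ]))
  expect_true(all(sim$truth$amplitude_map[-(11:40), ] == 0))
  expect_true(all(sim$truth$amplitude_map[11:40, ] > 0))
})

test_that("parameter validation guards Nyquist and clipping bounds", {
  expect_error(cilia_sim_params(cbf_hz = 600, frame_rate_hz = 1000),
               "Nyquist")
  expect_error(cilia_sim_params(amplitude = 0.5, baseline = 0.5,
                                noise_sigma = 0.1), "inside")
  expect_error(cilia_sim_params(band = c(50, 300)), "band")
})

test_that("jitter-free beads advance exactly speed*interval/pixel per frame", {
  p <- bead_sim_params(n_beads = 1, speed_um_s = 30, frame_count = 8,
                       jitter_sigma_px = 0, shape = c(40L, 120L), seed = 1)
  sim <- simulate_bead_movie(p)
  tr <- sim$truth
  expect_equal(diff(tr$col), rep(6, 7))  # 30 um/s * 0.2 s / 1 um/px
  expect_equal(diff(tr$row), rep(0, 7))
  # determinism
  sim2 <- simulate_bead_movie(p)
  expect_identical(sim$stack$frames, sim2$stack$frames)
})

test_that("beads leaving the frame are marked and no longer rendered", {
  p <- bead_sim_params(n_beads = 1, speed_um_s = 50, frame_count = 12,
                       jitter_sigma_px = 0, shape = c(40L, 60L),
                       noise_sigma = 0, seed = 1)
  sim <- simulate_bead_movie(p)
  out <- sim$truth[!sim$truth$in_frame, ]
  expect_gt(nrow(out), 0)
  last <- max(sim$truth$frame[!sim$truth$in_frame]) + 1L
  expect_lt(max(sim$stack$frames[last, , ]), 0.2)  # background only
})

test_that("an empty bead movie is pure background with no detections", {
  sim <- simulate_bead_movie(bead_sim_params(n_beads = 0, frame_count = 5,
                                             shape = c(40L, 60L), seed = 8))
  dets <- detect_beads_stack(sim$stack)
  expect_equal(nrow(dets), 0)
})

test_that("grouped CBF samples honour sd = 0, truncation and the seed", {
  g0 <- simulate_cbf_groups(5, 7, 28, 34, sd = 0, seed = 1)
  expect_equal(g0$a$values, rep(28, 5))
  expect_equal(g0$b$values, rep(34, 7))
  g1 <- simulate_cbf_groups(50, 50, 1, 1, sd = 2, seed = 2)
  expect_true(all(g1$a$values > 0))
  g2 <- simulate_cbf_groups(50, 50, 1, 1, sd = 2, seed = 2)
  expect_identical(g1$a$values, g2$a$values)
})
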