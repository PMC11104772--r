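test_that("a single Gaussian spot is detected within half a pixel", {
  fr <- spot_frame(c(120L, 140L), 50.0, 70.0, sigma = 2)
  d <- detect_beads(fr, sigma_px = 2, threshold_rel = 0.3)
  expect_equal(nrow(d), 1)
  expect_lt(abs(d$row - 50.0), 0.5)
  expect_lt(abs(d$col - 70.0), 0.5)
})

test_that("blank frames and bad input give no or failing detections", {
  expect_equal(nrow(detect_beads(matrix(0, 50, 50))), 0)
  expect_error(detect_beads(array(0, c(3, 4, 5))), "2-D")
})

test_that("well-separated spots are all recovered at their centers", {
  set.seed(17)
  centers <- cbind(row = seq(15, 105, by = 10),
                   col = sample(seq(20, 180, by = 16), 10))
  fr <- matrix(0, 120, 200)
  for (i in seq_len(nrow(centers)))
    fr <- fr + spot_frame(c(120L, 200L), centers[i, 1], centers[i, 2],
                          sigma = 2)
  d <- detect_beads(fr, sigma_px = 2, threshold_rel = 0.3)
  expect_equal(nrow(d), 10)
  # greedy matching oracle: each truth center has a detection within 0.5 px
  for (i in seq_len(nrow(centers))) {
    dist <- sqrt((d$row - centers[i, 1])^2 + (d$col - centers[i, 2])^2)
    expect_lt(min(dist), 0.5)
  }
})

test_that("detections are invariant to a global intensity rescaling", {
  fr <- spot_frame(c(80L, 80L), 30.2, 44.7, sigma = 2) +
    spot_frame(c(80L, 80L), 60.5, 20.1, sigma = 2)
  d1 <- detect_beads(fr)
  d2 <- detect_beads(fr * 0.137)
  expect_equal(d1[, c("row", "col")], d2[, c("row", "col")],
               tolerance = 1e-9)
})

test_that("linking follows a steadily moving bead and keeps identities apart", {
  det <- do.call(rbind, lapply(0:5, function(t)
    data.frame(frame = t, row = 10, col = 5 + 2 * t, intensity = 1)))
  tk <- link_tracks(det, max_disp_px = 5, min_len = 3)
  expect_equal(length(unique(tk$track_id)), 1)
  expect_equal(nrow(tk), 6)

  two <- do.call(rbind, lapply(0:7, function(t) rbind(
    data.frame(frame = t, row = 10, col = 5 + 2 * t, intensity = 1),
    data.frame(frame = t, row = 80, col = 5 + 3 * t, intensity = 1))))
  tk2 <- link_tracks(two, max_disp_px = 5, min_len = 3)
  expect_equal(length(unique(tk2$track_id)), 2)
  for (id in unique(tk2$track_id)) {
    rows <- tk2$row[tk2$track_id == id]
    expect_equal(length(unique(rows)), 1)  # no identity swap across tracks
  }
})

test_that("short tracks are discarded and every detection joins at most one track", {
  det <- data.frame(frame = 0:1, row = c(5, 5), col = c(5, 7),
                    intensity = 1)
  expect_equal(nrow(link_tracks(det, max_disp_px = 5, min_len = 3)), 0)
  expect_equal(nrow(link_tracks(det[0, ], max_disp_px = 5)), 0)

  set.seed(23)
  sim <- simulate_bead_movie(bead_sim_params(
    n_beads = 4, speed_um_s = c(10, 20, 30, 40), frame_count = 10,
    shape = c(150L, 160L), seed = 23))
  dets <- detect_beads_stack(sim$stack)
  tk <- link_tracks(dets, max_disp_px = 12, min_len = 3)
  # conservation: tracked + unassigned = total, no detection reused
  key <- paste(tk$frame, round(tk$row, 6), round(tk$col, 6))
  expect_equal(anyDuplicated(key), 0)
  expect_lte(nrow(tk), nrow(dets))
})

test_that("track_speed computes path and net speeds with unit conversion", {
  tk <- data.frame(frame = 0:2, row = c(0, 0, 0), col = c(0, 2, 4))
  expect_equal(track_speed(tk, pixel_size_um = 1, frame_interval_s = 0.2),
               10.0)
  still <- data.frame(frame = 0:3, row = rep(2, 4), col = rep(3, 4))
  expect_equal(track_speed(still, 1, 0.2), 0.0)
  # path vs net on an L-shaped track
  ell <- data.frame(frame = 0:2, row = c(0, 0, 3), col = c(0, 4, 4))
  expect_equal(track_speed(ell, 1, 1, "path"), 3.5)
  expect_equal(track_speed(ell, 1, 1, "net"), 2.5)
  expect_error(track_speed(ell[1, ], 1, 1), ">= 2 points")
})

test_that("commanded bead speed is recovered within 5% despite jitter", {
  sim <- simulate_bead_movie(bead_sim_params(
    n_beads = 1, speed_um_s = 35, frame_count = 15, shape = c(60L, 160L),
    jitter_sigma_px = 0.3, seed = 41))
  res <- track_beads(sim$stack, max_disp_px = 12)
  expect_equal(nrow(res$speeds), 1)
  expect_lt(abs(res$speeds$speed_um_s - 35) / 35, 0.05)
})
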