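#' Parameters for a synthetic ciliary-beating video
#'
#' Describes a metachronally beating ciliated field: every pixel inside a
#' horizontal ependymal band oscillates at one shared beat frequency, with a
#' linear spatial phase gradient (the metachronal wave) and a static smooth
#' random amplitude field (ciliary texture). Additive Gaussian noise models
#' camera noise. Defaults emulate a high-speed acquisition: 1000 frames at
#' 1000 frames/s.
#'
#' The invariant `baseline + amplitude + 3*noise_sigma <= 1` (and the
#' mirror-image bound at 0) keeps the clipping probability negligible so
#' spectra stay interpretable.
#'
#' @param frame_count number of frames (default 1000).
#' @param frame_rate_hz acquisition rate (default 1000).
#' @param shape c(rows, cols) frame shape (default c(200, 240), large
#'   enough to hold ~20 ROIs at 30 px separation inside the band).
#' @param cbf_hz true beat frequency, must be below Nyquist (default 28).
#' @param amplitude oscillation amplitude in intensity units (default 0.2).
#' @param baseline mean intensity (default 0.5).
#' @param noise_sigma additive Gaussian noise SD (default 0.05).
#' @param wave_vector c(k_row, k_col) spatial phase gradient in
#'   radians/pixel (default c(0.15, 0.15)).
#' @param band c(row_lo, row_hi) 0-based inclusive row extent of the
#'   ependymal band; defines the layer mask (default middle two thirds).
#' @param texture_scale spatial correlation length (px) of the amplitude
#'   field (default 8).
#' @param seed integer seed.
#' @return a validated list of class `CiliaSimParams`.
#' @export
cilia_sim_params <- function(frame_count = 1000L, frame_rate_hz = 1000,
                             shape = c(200L, 240L), cbf_hz = 28,
                             amplitude = 0.2, baseline = 0.5,
                             noise_sigma = 0.05,
                             wave_vector = c(0.15, 0.15),
                             band = NULL, texture_scale = 8, seed = 1L) {
  shape <- as.integer(shape)
  if (is.null(band)) band <- c(round(shape[1] / 6), round(shape[1] * 5 / 6))
  band <- as.integer(band)
  if (frame_count < 2L) stop_ciliaflow("frame_count must be >= 2")
  if (!(cbf_hz > 0 && cbf_hz < frame_rate_hz / 2))
    stop_ciliaflow("cbf_hz must lie in (0, Nyquist)")
  if (amplitude < 0 || noise_sigma < 0)
    stop_ciliaflow("amplitude and noise_sigma must be >= 0")
  if (baseline + amplitude + 3 * noise_sigma > 1 + 1e-9 ||
      baseline - amplitude - 3 * noise_sigma < -1e-9)
    stop_ciliaflow("baseline +/- (amplitude + 3*noise_sigma) must stay ",
                   "inside [0,1]")
  if (band[1] < 0 || band[2] >= shape[1] || band[1] > band[2])
    stop_ciliaflow("band must lie within the frame rows")
  structure(list(frame_count = as.integer(frame_count),
                 frame_rate_hz = frame_rate_hz, shape = shape,
                 cbf_hz = cbf_hz, amplitude = amplitude,
                 baseline = baseline, noise_sigma = noise_sigma,
                 wave_vector = as.numeric(wave_vector), band = band,
                 texture_scale = texture_scale, seed = as.integer(seed)),
            class = "CiliaSimParams")
}

# seeded smooth random field in [lo, hi], zero outside the band rows
smooth_amplitude_field <- function(shape, band, texture_scale, seed,
                                   lo = 0.5, hi = 1) {
  raw <- with_local_seed(seed, matrix(stats::rnorm(prod(shape)),
                                      shape[1], shape[2]))
  sm <- EBImage::gblur(raw, sigma = texture_scale)
  rng <- range(sm)
  A <- if (diff(rng) > 0) lo + (hi - lo) * (sm - rng[1]) / diff(rng)
  else matrix(lo, shape[1], shape[2])
  outside <- setdiff(seq_len(shape[1]) - 1L, band[1]:band[2])
  A[outside + 1L, ] <- 0
  A
}

#' Simulate a ciliary-beating video with known ground truth
#'
#' Renders I(r,c,t) = baseline + A(r,c) sin(2 pi f t / rate + k.(r,c)) +
#' noise, clipped to [0,1], where A is a seeded smooth amplitude field
#' supported on the ependymal band (zero outside) and k is the metachronal
#' wave vector. The layer mask is the band. A pure function of its
#' parameters: the same seed gives a bit-identical stack.
#'
#' @param params a [cilia_sim_params()] object.
#' @return list with `stack` (a `VideoStack`), `mask` (a `LayerMask`) and
#'   `truth` (cbf_hz, amplitude map, phase map, params).
#' @export
simulate_cilia_video <- function(params = cilia_sim_params()) {
  stopifnot(inherits(params, "CiliaSimParams"))
  p <- params
  A <- smooth_amplitude_field(p$shape, p$band, p$texture_scale,
                              stage_seed(p$seed, "texture")) * p$amplitude
  r <- seq_len(p$shape[1]) - 1L
  c_ <- seq_len(p$shape[2]) - 1L
  phase <- outer(r * p$wave_vector[1], c_ * p$wave_vector[2], "+")
  tt <- (seq_len(p$frame_count) - 1) / p$frame_rate_hz
  # A sin(wt + phi) = sin(wt) (A cos phi) + cos(wt) (A sin phi): two rank-1
  # outer products give the full time x pixel oscillation via BLAS.
  wt <- 2 * pi * p$cbf_hz * tt
  osc <- tcrossprod(sin(wt), as.numeric(A * cos(phase))) +
    tcrossprod(cos(wt), as.numeric(A * sin(phase)))
  if (p$noise_sigma > 0) {
    noise <- with_local_seed(stage_seed(p$seed, "noise"),
                             stats::rnorm(length(osc), sd = p$noise_sigma))
    osc <- osc + noise
  }
  frames <- p$baseline + osc
  frames[frames < 0] <- 0
  frames[frames > 1] <- 1
  dim(frames) <- c(p$frame_count, p$shape)
  mask <- matrix(FALSE, p$shape[1], p$shape[2])
  mask[(p$band[1]:p$band[2]) + 1L, ] <- TRUE
  list(stack = video_stack(frames, p$frame_rate_hz, pixel_size_um = 0.2,
                           origin_path = "simulate_cilia_video"),
       mask = layer_mask(mask),
       truth = list(cbf_hz = p$cbf_hz, amplitude_map = A,
                    phase_map = phase, params = p))
}

#' Parameters for a synthetic bead-flow movie
#'
#' Point-like fluorescent microbeads advected at constant commanded speed
#' along per-bead directions, with per-frame Gaussian positional jitter,
#' rendered as Gaussian spots on a noisy background. Defaults emulate the
#' bead-flow time-lapse: one frame every 200 ms (5 frames/s).
#'
#' @param frame_count frames (default 25).
#' @param frame_interval_s seconds between frames (default 0.2).
#' @param shape c(rows, cols) (default c(120, 320)).
#' @param pixel_size_um micrometres per pixel (default 1).
#' @param n_beads bead count (default 5).
#' @param speed_um_s commanded speed(s), scalar or one per bead (default 30).
#' @param direction c(d_row, d_col) unit vector, or an n_beads x 2 matrix
#'   (default along +col, the nominal flow direction).
#' @param jitter_sigma_px per-axis positional jitter SD (default 0.3).
#' @param spot_sigma_px rendered spot Gaussian SD (default 2; a ~2 um bead
#'   imaged over a few pixels).
#' @param peak spot peak intensity above background (default 0.7).
#' @param background background level (default 0.05).
#' @param noise_sigma additive noise SD (default 0.01).
#' @param start optional n_beads x 2 matrix of 0-based (row, col) start
#'   positions; default spreads beads over rows near the left edge.
#' @param seed integer seed.
#' @return a validated list of class `BeadSimParams`.
#' @export
bead_sim_params <- function(frame_count = 25L, frame_interval_s = 0.2,
                            shape = c(120L, 320L), pixel_size_um = 1,
                            n_beads = 5L, speed_um_s = 30,
                            direction = c(0, 1), jitter_sigma_px = 0.3,
                            spot_sigma_px = 2, peak = 0.7,
                            background = 0.05, noise_sigma = 0.01,
                            start = NULL, seed = 1L) {
  shape <- as.integer(shape)
  n_beads <- as.integer(n_beads)
  if (frame_count < 2L) stop_ciliaflow("frame_count must be >= 2")
  if (n_beads < 0L) stop_ciliaflow("n_beads must be >= 0")
  speed_um_s <- rep_len(as.numeric(speed_um_s), max(n_beads, 1L))
  if (any(speed_um_s < 0)) stop_ciliaflow("speeds must be >= 0")
  if (is.null(dim(direction)))
    direction <- matrix(direction, nrow = max(n_beads, 1L), ncol = 2,
                        byrow = TRUE)
  nrm <- sqrt(rowSums(direction^2))
  if (any(nrm == 0)) stop_ciliaflow("direction vectors must be nonzero")
  direction <- direction / nrm
  if (is.null(start) && n_beads > 0L) {
    margin <- ceiling(4 * spot_sigma_px)
    rows <- seq(margin, shape[1] - 1 - margin, length.out = n_beads)
    start <- cbind(rows, rep(margin, n_beads))
  }
  if (n_beads > 0L &&
      (any(start[, 1] < 0) || any(start[, 1] > shape[1] - 1) ||
       any(start[, 2] < 0) || any(start[, 2] > shape[2] - 1)))
    stop_ciliaflow("start positions must lie inside the frame")
  structure(list(frame_count = as.integer(frame_count),
                 frame_interval_s = frame_interval_s, shape = shape,
                 pixel_size_um = pixel_size_um, n_beads = n_beads,
                 speed_um_s = speed_um_s, direction = direction,
                 jitter_sigma_px = jitter_sigma_px,
                 spot_sigma_px = spot_sigma_px, peak = peak,
                 background = background, noise_sigma = noise_sigma,
                 start = start, seed = as.integer(seed)),
            class = "BeadSimParams")
}

render_spot <- function(frame, r0, c0, sigma, peak) {
  nr <- nrow(frame); nc <- ncol(frame)
  h <- ceiling(4 * sigma)
  rs <- max(1L, floor(r0) + 1L - h):min(nr, floor(r0) + 1L + h)
  cs <- max(1L, floor(c0) + 1L - h):min(nc, floor(c0) + 1L + h)
  if (length(rs) == 0L || length(cs) == 0L) return(frame)
  g <- peak * exp(-(outer((rs - 1 - r0)^2, (cs - 1 - c0)^2, "+")) /
                    (2 * sigma^2))
  frame[rs, cs] <- frame[rs, cs] + g
  frame
}

#' Simulate a bead-flow movie with known ground truth
#'
#' Each bead's center advances `speed * interval / pixel_size` pixels per
#' frame along its direction, plus independent N(0, jitter^2) per-axis
#' displacement; beads leaving the frame stop being rendered and the truth
#' table marks the exit. Same seed, same movie, bit for bit.
#'
#' @param params a [bead_sim_params()] object.
#' @return list with `stack` (a `VideoStack`; frame_rate_hz =
#'   1/frame_interval_s) and `truth` (data.frame bead_id, frame, row, col,
#'   speed_um_s, in_frame).
#' @export
simulate_bead_movie <- function(params = bead_sim_params()) {
  stopifnot(inherits(params, "BeadSimParams"))
  p <- params
  step_px <- p$speed_um_s * p$frame_interval_s / p$pixel_size_um
  pos <- p$start
  truth <- list()
  centers <- vector("list", p$frame_count)
  jit <- if (p$n_beads > 0L)
    with_local_seed(stage_seed(p$seed, "jitter"),
                    array(stats::rnorm(p$frame_count * p$n_beads * 2,
                                       sd = p$jitter_sigma_px),
                          dim = c(p$frame_count, p$n_beads, 2)))
  for (t in seq_len(p$frame_count)) {
    if (p$n_beads > 0L) {
      drift <- (t - 1) * step_px * p$direction
      cur <- p$start + drift + jit[t, , , drop = TRUE]
      if (p$n_beads == 1L) cur <- matrix(cur, nrow = 1)
      inside <- cur[, 1] >= 0 & cur[, 1] <= p$shape[1] - 1 &
        cur[, 2] >= 0 & cur[, 2] <= p$shape[2] - 1
      centers[[t]] <- cbind(cur, inside)
      truth[[t]] <- data.frame(bead_id = seq_len(p$n_beads), frame = t - 1L,
                               row = cur[, 1], col = cur[, 2],
                               speed_um_s = p$speed_um_s,
                               in_frame = inside)
    }
  }
  noise <- if (p$noise_sigma > 0)
    with_local_seed(stage_seed(p$seed, "camera"),
                    stats::rnorm(p$frame_count * prod(p$shape),
                                 sd = p$noise_sigma))
  else numeric(p$frame_count * prod(p$shape))
  dim(noise) <- c(p$frame_count, p$shape)
  frames <- array(p$background, dim = c(p$frame_count, p$shape)) + noise
  for (t in seq_len(p$frame_count)) {
    if (p$n_beads == 0L) next
    fr <- frames[t, , ]
    cc <- centers[[t]]
    for (b in seq_len(p$n_beads)) {
      if (cc[b, 3] == 1)
        fr <- render_spot(fr, cc[b, 1], cc[b, 2], p$spot_sigma_px, p$peak)
    }
    frames[t, , ] <- fr
  }
  frames[frames < 0] <- 0
  frames[frames > 1] <- 1
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(bead_id = integer(0), frame = integer(0), row = numeric(0),
               col = numeric(0), speed_um_s = numeric(0),
               in_frame = logical(0))
  list(stack = video_stack(frames, 1 / p$frame_interval_s,
                           pixel_size_um = p$pixel_size_um,
                           origin_path = "simulate_bead_movie"),
       truth = truth_df[order(truth_df$bead_id, truth_df$frame), ])
}

#' Simulate grouped CBF samples
#'
#' Seeded normal draws truncated at 0 (by rejection), one group sample per
#' cohort — a fixture generator for exercising the permutation test at
#' controlled effect sizes.
#'
#' @param n_a,n_b group sizes.
#' @param mean_a,mean_b group means (Hz).
#' @param sd shared SD (Hz), >= 0.
#' @param seed integer seed.
#' @return list of two `GroupSample` objects, `a` and `b`.
#' @export
simulate_cbf_groups <- function(n_a, n_b, mean_a, mean_b, sd, seed = 1L) {
  stopifnot(sd >= 0, n_a >= 1, n_b >= 1)
  draw <- function(n, mu) {
    if (sd == 0) return(rep(mu, n))
    out <- numeric(0)
    while (length(out) < n) {
      x <- stats::rnorm(n, mu, sd)
      out <- c(out, x[x > 0])
    }
    out[seq_len(n)]
  }
  with_local_seed(seed, {
    a <- draw(n_a, mean_a)
    b <- draw(n_b, mean_b)
  })
  list(a = group_sample("a", a, "Hz"), b = group_sample("b", b, "Hz"))
}

#' Named simulation scenarios
#'
#' Two cohort presets used throughout the examples and tests: "wt_like"
#' (beat frequency 28 Hz) and "ko_like" (34 Hz). The preset frequencies are
#' arbitrary fixtures chosen inside the murine ependymal range to give a
#' clear 6 Hz contrast; they are not measurements.
#'
#' @param name "wt_like" or "ko_like".
#' @param ... overrides passed on to [cilia_sim_params()].
#' @return a `CiliaSimParams`.
#' @export
cilia_scenario <- function(name = c("wt_like", "ko_like"), ...) {
  name <- match.arg(name)
  cbf <- c(wt_like = 28, ko_like = 34)[[name]]
  cilia_sim_params(cbf_hz = cbf, ...)
}

#' Simulate and analyze a cohort of ciliary videos
#'
#' Convenience wrapper: generates `n_videos` independent videos from a
#' scenario (per-video seeds derived from `seed`) and row-binds their
#' [analyze_video()] tables.
#'
#' @param n_videos videos in the cohort.
#' @param params a `CiliaSimParams` template (its seed field is replaced
#'   per video).
#' @param config an [analysis_config()].
#' @param seed cohort seed.
#' @param video_prefix prefix for video_id.
#' @return data.frame of per-ROI CBF estimates across the cohort.
#' @export
simulate_cbf_cohort <- function(n_videos, params, config = analysis_config(),
                                seed = 1L, video_prefix = "vid") {
  tables <- lapply(seq_len(n_videos), function(v) {
    pv <- params
    pv$seed <- stage_seed(seed, paste0(video_prefix, v))
    cfg <- config
    cfg$seed <- stage_seed(seed, paste0(video_prefix, v, ":roi"))
    sim <- simulate_cilia_video(pv)
    analyze_video(sim$stack, sim$mask, cfg,
                  video_id = sprintf("%s%02d", video_prefix, v))
  })
  do.call(rbind, tables)
}
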