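#' Detect fluorescent beads in one frame
#'
#' Smooths the frame with a Gaussian of scale `sigma_px` (matched to the
#' bead image, ~2 um FluoSpheres rendered over a few pixels), finds local
#' maxima above a relative threshold on the smoothed frame, and refines
#' each to a sub-pixel centroid by intensity-weighted mean over a
#' (2*ceil(sigma_px)+1)^2 neighbourhood. Because the threshold is relative,
#' a global intensity rescaling of the frame leaves detections unchanged.
#'
#' @param frame 2-D numeric intensity matrix.
#' @param sigma_px Gaussian smoothing scale in pixels (default 2).
#' @param threshold_rel detection threshold: fraction of the smoothed
#'   frame's dynamic range (max minus median) a peak must rise above the
#'   median, in (0, 1) (default 0.3).
#' @param noise_floor robust noise floor: a peak must also clear the frame
#'   median by this many robust SDs (mad) of the smoothed frame
#'   (default 8), so background-only frames give no detections.
#' @return data.frame with columns row, col (0-based sub-pixel centroids)
#'   and intensity (smoothed peak brightness); zero rows when nothing is
#'   detected.
#' @export
detect_beads <- function(frame, sigma_px = 2, threshold_rel = 0.3,
                         noise_floor = 8) {
  if (!is.matrix(frame) || !is.numeric(frame))
    stop_ciliaflow("frame must be a 2-D numeric matrix")
  stopifnot(threshold_rel > 0, threshold_rel < 1, sigma_px > 0)
  empty <- data.frame(row = numeric(0), col = numeric(0),
                      intensity = numeric(0))
  sm <- EBImage::gblur(frame, sigma = sigma_px)
  mx <- max(sm)
  if (mx <= 0) return(empty)
  # Relative threshold above the background level, with a robust noise
  # floor: a peak must clear the frame median by threshold_rel of the
  # frame's dynamic range AND by noise_floor robust SDs, so pure-background
  # frames (whose maxima are just smoothed noise) yield no detections.
  med <- stats::median(sm)
  thr <- med + max(threshold_rel * (mx - med),
                   noise_floor * stats::mad(sm))
  if (thr <= med) return(empty)
  nr <- nrow(sm); nc <- ncol(sm)
  if (nr < 3L || nc < 3L) return(empty)

  # strict local maxima over the 8-neighbourhood (interior pixels only)
  core <- sm[2:(nr - 1), 2:(nc - 1)]
  is_max <- core >= thr &
    core > sm[1:(nr - 2), 2:(nc - 1)] & core > sm[3:nr, 2:(nc - 1)] &
    core > sm[2:(nr - 1), 1:(nc - 2)] & core > sm[2:(nr - 1), 3:nc] &
    core > sm[1:(nr - 2), 1:(nc - 2)] & core > sm[1:(nr - 2), 3:nc] &
    core > sm[3:nr, 1:(nc - 2)] & core > sm[3:nr, 3:nc]
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  pr <- idx[, 1] + 1L  # back to full-frame 1-based indices
  pc <- idx[, 2] + 1L

  h <- as.integer(ceiling(sigma_px))
  out <- lapply(seq_along(pr), function(i) {
    r0 <- max(1L, pr[i] - h); r1 <- min(nr, pr[i] + h)
    c0 <- max(1L, pc[i] - h); c1 <- min(nc, pc[i] + h)
    w <- sm[r0:r1, c0:c1]
    tot <- sum(w)
    rr <- sum(w * ((r0:r1) - 1L)) / tot
    cc <- sum(t(w) * ((c0:c1) - 1L)) / tot
    c(rr, cc, sm[pr[i], pc[i]])
  })
  out <- do.call(rbind, out)
  data.frame(row = out[, 1], col = out[, 2], intensity = out[, 3])
}

#' Detect beads in every frame of a stack
#'
#' @param stack a `VideoStack`.
#' @inheritParams detect_beads
#' @return data.frame with columns frame (0-based), row, col, intensity.
#' @export
detect_beads_stack <- function(stack, sigma_px = 2, threshold_rel = 0.3,
                               noise_floor = 8) {
  stopifnot(inherits(stack, "VideoStack"))
  nT <- dim(stack$frames)[1]
  per <- lapply(seq_len(nT), function(t) {
    d <- detect_beads(stack$frames[t, , ], sigma_px, threshold_rel,
                      noise_floor)
    if (nrow(d)) cbind(frame = t - 1L, d)
    else data.frame(frame = integer(0), row = numeric(0), col = numeric(0),
                    intensity = numeric(0))
  })
  do.call(rbind, per)
}

# mutual-nearest-neighbour pairs between two point sets within max_disp;
# ambiguity broken by smaller displacement, then lower index
mutual_nn_pairs <- function(a, b, max_disp) {
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(matrix(integer(0), ncol = 2))
  d <- outer(a$row, b$row, "-")^2 + outer(a$col, b$col, "-")^2
  d[d > max_disp^2] <- Inf
  nn_ab <- apply(d, 1, which.min)   # ties: lowest index
  nn_ba <- apply(d, 2, which.min)
  i <- which(nn_ba[nn_ab] == seq_len(nrow(a)) &
               is.finite(d[cbind(seq_len(nrow(a)), nn_ab)]))
  if (length(i) == 0L) return(matrix(integer(0), ncol = 2))
  ord <- order(d[cbind(i, nn_ab[i])], i)
  cbind(i[ord], nn_ab[i][ord])
}

#' Link per-frame bead detections into tracks
#'
#' Greedy mutual-nearest-neighbour linking between consecutive frames: a
#' detection in frame t+1 extends a track ending in frame t when each is the
#' other's nearest neighbour and the displacement is at most `max_disp_px`.
#' Unmatched detections start new tracks; tracks are gapless (a track not
#' extended at frame t+1 is closed) and each detection belongs to at most
#' one track. Tracks shorter than `min_len` points are discarded.
#'
#' @param detections data.frame from [detect_beads_stack()] (columns frame,
#'   row, col; frame 0-based and sorted).
#' @param max_disp_px maximum per-frame displacement in pixels.
#' @param min_len minimum surviving track length in points (default 3).
#' @return data.frame with columns track_id, frame, row, col; zero rows for
#'   empty input.
#' @export
link_tracks <- function(detections, max_disp_px, min_len = 3L) {
  stopifnot(max_disp_px > 0, min_len >= 2)
  empty <- data.frame(track_id = integer(0), frame = integer(0),
                      row = numeric(0), col = numeric(0))
  if (is.null(detections) || nrow(detections) == 0L) return(empty)
  frames <- sort(unique(detections$frame))
  by_frame <- split(detections, detections$frame)

  next_id <- 1L
  open <- list()     # track_id -> list(pts = data.frame, last_frame)
  closed <- list()
  start_tracks <- function(dets, fr) {
    for (j in seq_len(nrow(dets))) {
      open[[as.character(next_id)]] <<- list(
        pts = data.frame(track_id = next_id, frame = fr,
                         row = dets$row[j], col = dets$col[j]),
        last_frame = fr)
      next_id <<- next_id + 1L
    }
  }
  start_tracks(by_frame[[as.character(frames[1])]], frames[1])

  for (fi in seq_along(frames)[-1]) {
    fr <- frames[fi]
    dets <- by_frame[[as.character(fr)]]
    # only tracks whose last point is the immediately preceding frame
    ids <- names(open)[vapply(open, function(tk) tk$last_frame == fr - 1L,
                              logical(1))]
    ends <- if (length(ids)) {
      data.frame(row = vapply(open[ids], function(tk)
                   tk$pts$row[nrow(tk$pts)], numeric(1)),
                 col = vapply(open[ids], function(tk)
                   tk$pts$col[nrow(tk$pts)], numeric(1)))
    } else data.frame(row = numeric(0), col = numeric(0))
    pairs <- mutual_nn_pairs(ends, dets, max_disp_px)
    used_det <- rep(FALSE, nrow(dets))
    for (k in seq_len(nrow(pairs))) {
      id <- ids[pairs[k, 1]]
      j <- pairs[k, 2]
      used_det[j] <- TRUE
      tk <- open[[id]]
      tk$pts <- rbind(tk$pts,
                      data.frame(track_id = as.integer(id), frame = fr,
                                 row = dets$row[j], col = dets$col[j]))
      tk$last_frame <- fr
      open[[id]] <- tk
    }
    # close tracks that were not extended
    stale <- names(open)[vapply(open, function(tk) tk$last_frame < fr,
                                logical(1))]
    closed <- c(closed, open[stale])
    open[stale] <- NULL
    if (any(!used_det)) start_tracks(dets[!used_det, , drop = FALSE], fr)
  }
  closed <- c(closed, open)
  keep <- Filter(function(tk) nrow(tk$pts) >= min_len, closed)
  if (length(keep) == 0L) return(empty)
  out <- do.call(rbind, lapply(keep, `[[`, "pts"))
  out <- out[order(out$track_id, out$frame), ]
  rownames(out) <- NULL
  out
}

#' Speed of one bead track
#'
#' Path speed (default): the mean over consecutive point pairs of the
#' Euclidean displacement in pixels, converted by `pixel_size_um /
#' frame_interval_s`. `speed_mode = "net"` instead uses the end-to-end
#' displacement divided by the elapsed time.
#'
#' @param track data.frame with columns frame, row, col (one track, frames
#'   strictly increasing).
#' @param pixel_size_um micrometres per pixel.
#' @param frame_interval_s seconds between consecutive frames (0.2 s for a
#'   5 fps bead movie).
#' @param speed_mode "path" (default) or "net".
#' @return speed in micrometres per second (scalar >= 0).
#' @export
track_speed <- function(track, pixel_size_um, frame_interval_s,
                        speed_mode = c("path", "net")) {
  speed_mode <- match.arg(speed_mode)
  stopifnot(pixel_size_um > 0, frame_interval_s > 0)
  n <- nrow(track)
  if (is.null(n) || n < 2L) stop_ciliaflow("track needs >= 2 points")
  if (any(diff(track$frame) <= 0))
    stop_ciliaflow("track frames must be strictly increasing")
  if (speed_mode == "path") {
    step <- sqrt(diff(track$row)^2 + diff(track$col)^2)
    mean(step) * pixel_size_um / frame_interval_s
  } else {
    disp <- sqrt((track$row[n] - track$row[1])^2 +
                   (track$col[n] - track$col[1])^2)
    dt <- (track$frame[n] - track$frame[1]) * frame_interval_s
    disp * pixel_size_um / dt
  }
}

#' End-to-end bead-flow quantification of a movie
#'
#' Runs detection on every frame, links detections into tracks, and
#' computes per-track speeds in micrometres per second. Optionally attaches
#' a region label to each track from an integer-valued label mask, by where
#' the track's midpoint falls.
#'
#' @param stack a `VideoStack` (its `pixel_size_um` and `frame_rate_hz`
#'   supply the scale factors; the frame interval is `1/frame_rate_hz`).
#' @param sigma_px,threshold_rel,noise_floor see [detect_beads()].
#' @param max_disp_px,min_len see [link_tracks()].
#' @param speed_mode see [track_speed()].
#' @param region_mask optional integer matrix of region labels (0 = none).
#' @return list with data.frames `detections`, `tracks` and `speeds`
#'   (track_id, n_points, speed_um_s, region_label).
#' @export
track_beads <- function(stack, sigma_px = 2, threshold_rel = 0.3,
                        max_disp_px = 15, min_len = 3L,
                        speed_mode = c("path", "net"), region_mask = NULL,
                        noise_floor = 8) {
  speed_mode <- match.arg(speed_mode)
  stopifnot(inherits(stack, "VideoStack"))
  if (is.na(stack$pixel_size_um))
    stop_ciliaflow("stack has no pixel size; speeds need pixel_size_um")
  dets <- detect_beads_stack(stack, sigma_px, threshold_rel, noise_floor)
  tracks <- link_tracks(dets, max_disp_px, min_len)
  interval <- 1 / stack$frame_rate_hz
  ids <- unique(tracks$track_id)
  speeds <- data.frame(track_id = integer(0), n_points = integer(0),
                       speed_um_s = numeric(0),
                       region_label = integer(0))
  if (length(ids)) {
    speeds <- do.call(rbind, lapply(ids, function(id) {
      tk <- tracks[tracks$track_id == id, ]
      mid <- tk[ceiling(nrow(tk) / 2), ]
      lab <- if (is.null(region_mask)) NA_integer_ else
        as.integer(region_mask[round(mid$row) + 1L, round(mid$col) + 1L])
      data.frame(track_id = id, n_points = nrow(tk),
                 speed_um_s = track_speed(tk, stack$pixel_size_um, interval,
                                          speed_mode),
                 region_label = lab)
    }))
  }
  list(detections = dets, tracks = tracks, speeds = speeds)
}
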