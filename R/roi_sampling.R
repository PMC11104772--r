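#' Construct an ROI specification
#'
#' An ROI is a square odd-sized window (default 11 x 11 px) identified by its
#' center pixel. Coordinates are 0-based (row, col); a window of odd size s
#' spans center +/- (s-1)/2 inclusive.
#'
#' @param center_row,center_col 0-based center pixel indices.
#' @param size odd window edge length in pixels (>= 3), default 11.
#' @return an object of class `RoiSpec`.
#' @export
roi_spec <- function(center_row, center_col, size = 11L) {
  size <- as.integer(size)
  if (size < 3L || size %% 2L == 0L)
    stop_ciliaflow("ROI size must be odd and >= 3")
  structure(list(center_row = as.integer(center_row),
                 center_col = as.integer(center_col),
                 size = size),
            class = "RoiSpec")
}

roi_half <- function(roi) (roi$size - 1L) %/% 2L

roi_in_bounds <- function(roi, shape) {
  h <- roi_half(roi)
  roi$center_row - h >= 0L && roi$center_col - h >= 0L &&
    roi$center_row + h <= shape[1] - 1L && roi$center_col + h <= shape[2] - 1L
}

# All s x s sliding-window sums of the mask via its padded integral image;
# W[i, j] = sum over mask[i:(i+s-1), j:(j+s-1)] (1-based top-left corner).
window_sums <- function(m, s) {
  nr <- nrow(m); nc <- ncol(m)
  S <- rbind(0, cbind(0, t(apply(apply(m * 1, 2, cumsum), 1, cumsum))))
  ri <- 1:(nr - s + 1L); ci <- 1:(nc - s + 1L)
  S[ri + s, ci + s, drop = FALSE] - S[ri, ci + s, drop = FALSE] -
    S[ri + s, ci, drop = FALSE] + S[ri, ci, drop = FALSE]
}

#' Sample non-overlapping ROIs confined to a layer mask
#'
#' Places 16-20 (by default) square ROIs whose full footprints lie inside the
#' mask and inside the frame, with pairwise center-to-center Euclidean
#' distances of at least `min_sep` pixels (default 30). Placement is seeded
#' rejection sampling over mask-valid centers: candidates are drawn
#' uniformly from the valid-center set and accepted greedily when far
#' enough from all accepted centers, until `n_max` are placed or no
#' acceptable candidate remains (random sequential adsorption to jamming).
#' The result is deterministic for a fixed seed.
#'
#' If the pool jams below `n_min`, the ROIs found are returned with
#' attribute `under_sampled = TRUE` and a warning; zero feasible placements
#' is an error.
#'
#' @param mask a `LayerMask` (or logical matrix).
#' @param n_min,n_max target ROI count range (defaults 16, 20).
#' @param size odd ROI edge length in pixels (default 11).
#' @param min_sep minimum pairwise center separation in pixels (default 30).
#' @param seed integer seed.
#' @param separation_mode "center" (Euclidean center-to-center distance,
#'   default) or "edge" (distance between closest footprint edges,
#'   `center distance - (size - 1)`).
#' @return list of `RoiSpec`, possibly with attribute `under_sampled`.
#' @export
sample_rois <- function(mask, n_min = 16L, n_max = 20L, size = 11L,
                        min_sep = 30, seed = 1L,
                        separation_mode = c("center", "edge")) {
  separation_mode <- match.arg(separation_mode)
  if (inherits(mask, "LayerMask")) mask <- mask$mask
  stopifnot(is.matrix(mask), n_min <= n_max, n_min >= 1L)
  size <- as.integer(size)
  if (size < 3L || size %% 2L == 0L)
    stop_ciliaflow("ROI size must be odd and >= 3")
  if (!any(mask)) stop_ciliaflow("empty mask")
  h <- (size - 1L) %/% 2L
  nr <- nrow(mask); nc <- ncol(mask)
  if (nr < size || nc < size) stop_ciliaflow("no feasible placement")

  ok <- which(window_sums(mask, size) == size * size, arr.ind = TRUE)
  if (nrow(ok) == 0L) stop_ciliaflow("no feasible placement")
  cand_r <- ok[, 1] - 1L + h  # corner (1-based) -> center (0-based)
  cand_c <- ok[, 2] - 1L + h

  # effective center separation implied by the chosen mode
  sep <- if (separation_mode == "center") min_sep else min_sep + (size - 1L)
  # Greedy seeded acceptance. Rejected draws never change the accepted set,
  # so drawing uniformly from the still-acceptable pool and pruning after
  # each acceptance is distributionally equivalent to rejection sampling
  # with an unbounded attempt budget; the loop ends when the pool is jammed.
  acc_r <- integer(0); acc_c <- integer(0)
  with_local_seed(seed, {
    while (length(acc_r) < n_max && length(cand_r) > 0L) {
      i <- if (length(cand_r) == 1L) 1L else sample.int(length(cand_r), 1L)
      r <- cand_r[i]; c <- cand_c[i]
      acc_r <- c(acc_r, r); acc_c <- c(acc_c, c)
      keep <- (cand_r - r)^2 + (cand_c - c)^2 >= sep^2
      cand_r <- cand_r[keep]; cand_c <- cand_c[keep]
    }
  })
  if (length(acc_r) == 0L) stop_ciliaflow("no feasible placement")
  rois <- mapply(roi_spec, acc_r, acc_c, MoreArgs = list(size = size),
                 SIMPLIFY = FALSE)
  if (length(rois) < n_min) {
    warning(sprintf("under-sampled: placed %d ROIs, wanted >= %d",
                    length(rois), n_min))
    attr(rois, "under_sampled") <- TRUE
  }
  rois
}

#' Extract the per-frame mean-brightness trace of an ROI
#'
#' The per-ROI signal whose temporal modulation carries the ciliary beat:
#' `values[t]` is the arithmetic mean of the size^2 pixel intensities of
#' frame t over the ROI footprint.
#'
#' @param stack a `VideoStack`.
#' @param roi a `RoiSpec`.
#' @return an object of class `RoiTrace` with fields `roi`, `values`,
#'   `frame_rate_hz`.
#' @export
extract_trace <- function(stack, roi) {
  stopifnot(inherits(stack, "VideoStack"), inherits(roi, "RoiSpec"))
  shp <- dim(stack$frames)[2:3]
  if (!roi_in_bounds(roi, shp))
    stop_ciliaflow("ROI footprint out of frame bounds")
  h <- roi_half(roi)
  rows <- (roi$center_row - h):(roi$center_row + h) + 1L
  cols <- (roi$center_col - h):(roi$center_col + h) + 1L
  block <- stack$frames[, rows, cols, drop = FALSE]
  values <- rowMeans(block, dims = 1L)
  structure(list(roi = roi, values = as.numeric(values),
                 frame_rate_hz = stack$frame_rate_hz),
            class = "RoiTrace")
}

#' Write / read ROI sets as CSV
#'
#' Columns: roi_id, center_row, center_col, size (0-based coordinates).
#' Importing a user CSV lets manual ROI placements reproduce the original
#' hand-confined workflow.
#'
#' @param rois list of `RoiSpec`.
#' @param path CSV path.
#' @return `path` invisibly (write) or a list of `RoiSpec` (read).
#' @export
write_rois_csv <- function(rois, path) {
  df <- data.frame(
    roi_id = seq_along(rois),
    center_row = vapply(rois, `[[`, integer(1), "center_row"),
    center_col = vapply(rois, `[[`, integer(1), "center_col"),
    size = vapply(rois, `[[`, integer(1), "size"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rois_csv
#' @export
read_rois_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("center_row", "center_col", "size")
  if (!all(need %in% names(df)))
    stop_ciliaflow("ROI CSV must have columns center_row, center_col, size")
  lapply(seq_len(nrow(df)), function(i)
    roi_spec(df$center_row[i], df$center_col[i], df$size[i]))
}
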