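default_config <- function() {
  list(
    band_hz = c(5, 100),
    snr_min = 20,
    window = "hann",
    detrend = "linear",
    roi = list(n_min = 16L, n_max = 20L, size = 11L, min_sep = 30,
               separation_mode = "center"),
    detection = list(sigma_px = 2, threshold_rel = 0.3, noise_floor = 8),
    linking = list(max_disp_px = 15, min_len = 3L, speed_mode = "path"),
    permutation = list(statistic = "mean_diff", n_iterations = 10000L,
                       alternative = "two_sided",
                       exhaustive_limit = 200000),
    seed = 1L,
    output_dir = "."
  )
}

#' Build and validate an analysis configuration
#'
#' The configuration gathers every tunable knob of the pipeline: the CBF
#' search band and QC threshold, taper and detrend choices, the ROI sampler
#' block (n_min, n_max, size, min_sep, separation_mode), bead detection and
#' linking blocks, the permutation-test block, the run seed and the output
#' directory. Values not supplied take package defaults; unknown keys are
#' errors (fail-fast), so a typo in a config file cannot silently fall back
#' to a default.
#'
#' @param x a (possibly partial) named list of settings, or an existing
#'   validated config to pass through.
#' @return a validated config list of class `AnalysisConfig`.
#' @export
analysis_config <- function(x = list()) {
  if (inherits(x, "AnalysisConfig")) return(x)
  stopifnot(is.list(x))
  cfg <- default_config()
  merge_block <- function(base, upd, path) {
    unknown <- setdiff(names(upd), names(base))
    if (length(unknown))
      stop_ciliaflow("unknown config key(s): ",
                     paste0(path, unknown, collapse = ", "))
    for (k in names(upd)) {
      if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
        base[[k]] <- merge_block(base[[k]], as.list(upd[[k]]),
                                 paste0(path, k, "."))
      } else {
        base[[k]] <- upd[[k]]
      }
    }
    base
  }
  cfg <- merge_block(cfg, x, "")

  with(cfg, {
    if (!is.numeric(band_hz) || length(band_hz) != 2L ||
        band_hz[1] < 0 || band_hz[2] <= band_hz[1])
      stop_ciliaflow("band_hz must be c(low, high) with 0 <= low < high")
    if (!is_scalar_num(snr_min, lo = 0)) stop_ciliaflow("snr_min must be > 0")
    if (!window %in% c("hann", "rect"))
      stop_ciliaflow("window must be 'hann' or 'rect'")
    if (!detrend %in% c("linear", "mean"))
      stop_ciliaflow("detrend must be 'linear' or 'mean'")
    if (roi$n_min > roi$n_max || roi$n_min < 1)
      stop_ciliaflow("roi: need 1 <= n_min <= n_max")
    if (roi$size %% 2 == 0 || roi$size < 3)
      stop_ciliaflow("roi: size must be odd and >= 3")
    if (!roi$separation_mode %in% c("center", "edge"))
      stop_ciliaflow("roi: separation_mode must be 'center' or 'edge'")
    if (!is_scalar_num(detection$sigma_px, lo = 0) ||
        detection$threshold_rel <= 0 || detection$threshold_rel >= 1 ||
        detection$noise_floor < 0)
      stop_ciliaflow("detection: need sigma_px > 0, 0 < threshold_rel < 1, ",
                     "noise_floor >= 0")
    if (!is_scalar_num(linking$max_disp_px, lo = 0) || linking$min_len < 2)
      stop_ciliaflow("linking: need max_disp_px > 0 and min_len >= 2")
    if (!linking$speed_mode %in% c("path", "net"))
      stop_ciliaflow("linking: speed_mode must be 'path' or 'net'")
    if (!permutation$statistic %in% c("mean_diff", "median_diff"))
      stop_ciliaflow("permutation: unknown statistic")
    if (permutation$n_iterations < 1)
      stop_ciliaflow("permutation: n_iterations must be >= 1")
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
      stop_ciliaflow("seed must be a single integer")
  })
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("AnalysisConfig", "list")
  cfg
}

#' Read an analysis configuration from YAML or JSON
#'
#' The file may set any subset of the keys of [analysis_config()]; unknown
#' keys are errors.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a validated `AnalysisConfig`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop_ciliaflow("config file not found: ", path)
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(x)) x <- list()
  analysis_config(x)
}
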