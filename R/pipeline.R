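config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  unname(tools::md5sum(tmp))
}

file_checksums <- function(paths) {
  paths <- paths[!vapply(paths, is.null, logical(1))]
  paths <- unlist(paths)
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

write_manifest <- function(out_dir, stage, config, inputs) {
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("ciliaflow")),
    config = unclass(config),
    config_hash = config_hash(config),
    seed = config$seed,
    inputs = file_checksums(inputs))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

ensure_dir <- function(d) {
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}

#' Run the CBF pipeline end to end on one video
#'
#' Reads a stack and its ependymal-layer mask, runs [analyze_video()], and
#' writes `cbf_table.csv`, optional per-ROI spectra (`spectra.csv`, long
#' format) and `run_manifest.json` (full config, config hash, seed, input
#' checksums — enough to reproduce the run bit for bit) into `output_dir`.
#' Rerunning with identical inputs and config yields byte-identical CSVs.
#'
#' @param stack_path TIFF stack path.
#' @param mask_path single-page mask TIFF path.
#' @param config an `AnalysisConfig`, or a YAML/JSON config path.
#' @param output_dir destination directory (default from config).
#' @param frame_rate_hz optional frame-rate override for the stack.
#' @param write_spectra also write per-ROI power spectra (default FALSE).
#' @return the output directory, invisibly.
#' @export
run_cbf <- function(stack_path, mask_path, config = analysis_config(),
                    output_dir = NULL, frame_rate_hz = NULL,
                    write_spectra = FALSE) {
  if (is.character(config)) config <- read_analysis_config(config)
  config <- analysis_config(config)
  if (!file.exists(stack_path))
    stop_ciliaflow("missing input stack: ", stack_path)
  if (!file.exists(mask_path))
    stop_ciliaflow("missing input mask: ", mask_path)
  out <- ensure_dir(if (is.null(output_dir)) config$output_dir else
    output_dir)
  stack <- read_stack(stack_path, frame_rate_hz = frame_rate_hz)
  mask <- read_mask(mask_path, dim(stack$frames)[2:3])
  tab <- analyze_video(stack, mask, config,
                       video_id = basename(stack_path))
  utils::write.csv(tab, file.path(out, "cbf_table.csv"), row.names = FALSE)
  if (write_spectra) {
    rois <- lapply(seq_len(nrow(tab)), function(i)
      roi_spec(tab$center_row[i], tab$center_col[i], config$roi$size))
    sp <- do.call(rbind, lapply(seq_along(rois), function(i) {
      tr <- detrend_trace(extract_trace(stack, rois[[i]]), config$detrend)
      s <- power_spectrum(tr, config$window)
      data.frame(roi_id = i, freq_hz = s$freqs_hz, power = s$power)
    }))
    utils::write.csv(sp, file.path(out, "spectra.csv"), row.names = FALSE)
  }
  write_manifest(out, "cbf", config,
                 list(stack = stack_path, mask = mask_path))
  invisible(out)
}

#' Run the bead-flow pipeline end to end on one movie
#'
#' Reads a bead time-lapse stack, detects and links beads, computes
#' per-track speeds, and writes `detections.csv`, `tracks.csv`,
#' `speeds.csv` and `run_manifest.json` into `output_dir`. Empty movies
#' yield header-only CSVs.
#'
#' @param stack_path TIFF stack path (sidecar or overrides must supply
#'   frame rate and pixel size).
#' @param config an `AnalysisConfig` or config path.
#' @param region_mask_path optional integer-valued TIFF of region labels.
#' @param output_dir destination directory.
#' @param frame_rate_hz,pixel_size_um optional metadata overrides.
#' @return the output directory, invisibly.
#' @export
run_beads <- function(stack_path, config = analysis_config(),
                      region_mask_path = NULL, output_dir = NULL,
                      frame_rate_hz = NULL, pixel_size_um = NULL) {
  if (is.character(config)) config <- read_analysis_config(config)
  config <- analysis_config(config)
  if (!file.exists(stack_path))
    stop_ciliaflow("missing input stack: ", stack_path)
  out <- ensure_dir(if (is.null(output_dir)) config$output_dir else
    output_dir)
  stack <- read_stack(stack_path, frame_rate_hz = frame_rate_hz,
                      pixel_size_um = pixel_size_um)
  region_mask <- NULL
  if (!is.null(region_mask_path)) {
    if (!file.exists(region_mask_path))
      stop_ciliaflow("missing region mask: ", region_mask_path)
    pg <- read_tiff_pages(region_mask_path)[[1]]
    region_mask <- round(pg * 255)  # labels stored as 8-bit levels
  }
  res <- track_beads(stack,
                     sigma_px = config$detection$sigma_px,
                     threshold_rel = config$detection$threshold_rel,
                     noise_floor = config$detection$noise_floor,
                     max_disp_px = config$linking$max_disp_px,
                     min_len = config$linking$min_len,
                     speed_mode = config$linking$speed_mode,
                     region_mask = region_mask)
  utils::write.csv(res$detections, file.path(out, "detections.csv"),
                   row.names = FALSE)
  utils::write.csv(res$tracks, file.path(out, "tracks.csv"),
                   row.names = FALSE)
  utils::write.csv(res$speeds, file.path(out, "speeds.csv"),
                   row.names = FALSE)
  write_manifest(out, "beads", config,
                 list(stack = stack_path, region_mask = region_mask_path))
  invisible(out)
}

#' Run a permutation comparison of two measurement tables
#'
#' Reads two CSV tables — either [analyze_video()] CBF tables (column
#' `cbf_hz`, QC-filtered) or bead `speeds.csv` tables (column
#' `speed_um_s`) — runs the permutation test from the config, and writes
#' `permtest.json` plus a one-line human-readable log.
#'
#' @param table_a_path,table_b_path CSV paths.
#' @param config an `AnalysisConfig` or config path.
#' @param output_dir destination directory.
#' @param labels character(2) group labels.
#' @return the `PermutationResult`, invisibly.
#' @export
run_permtest <- function(table_a_path, table_b_path,
                         config = analysis_config(), output_dir = NULL,
                         labels = c("A", "B")) {
  if (is.character(config)) config <- read_analysis_config(config)
  config <- analysis_config(config)
  for (p in c(table_a_path, table_b_path))
    if (!file.exists(p)) stop_ciliaflow("missing input table: ", p)
  out <- ensure_dir(if (is.null(output_dir)) config$output_dir else
    output_dir)
  pull <- function(path, lab) {
    df <- utils::read.csv(path)
    vals <- if ("cbf_hz" %in% names(df)) {
      if ("passed_qc" %in% names(df)) df <- df[df$passed_qc, , drop = FALSE]
      df$cbf_hz
    } else if ("speed_um_s" %in% names(df)) {
      df$speed_um_s
    } else stop_ciliaflow("table ", path,
                          " has neither cbf_hz nor speed_um_s")
    group_sample(lab, vals[is.finite(vals)])
  }
  res <- permutation_test(
    pull(table_a_path, labels[1]), pull(table_b_path, labels[2]),
    statistic = config$permutation$statistic,
    n_iterations = config$permutation$n_iterations,
    seed = stage_seed(config$seed, "permutation"),
    alternative = config$permutation$alternative,
    exhaustive_limit = config$permutation$exhaustive_limit)
  jsonlite::write_json(
    list(statistic_name = res$statistic_name, observed = res$observed,
         p_value = res$p_value, n_iterations = res$n_iterations,
         mode = res$mode, seed = res$seed,
         null_quantiles = res$null_quantiles),
    file.path(out, "permtest.json"), auto_unbox = TRUE, digits = NA)
  writeLines(utils::capture.output(print(res)),
             file.path(out, "permtest.log"))
  write_manifest(out, "permtest", config,
                 list(table_a = table_a_path, table_b = table_b_path))
  invisible(res)
}

#' Write a simulation scenario to disk
#'
#' Materializes a named ciliary scenario (or a bead movie) as the TIFF
#' stack, mask TIFF, JSON sidecar and truth CSV that the file-based
#' pipeline entry points consume.
#'
#' @param scenario "wt_like", "ko_like" or "beads".
#' @param output_dir destination directory.
#' @param seed integer seed.
#' @param ... overrides for [cilia_sim_params()] / [bead_sim_params()].
#' @return the output directory, invisibly.
#' @export
run_simulate <- function(scenario = c("wt_like", "ko_like", "beads"),
                         output_dir, seed = 1L, ...) {
  scenario <- match.arg(scenario)
  out <- ensure_dir(output_dir)
  if (scenario == "beads") {
    sim <- simulate_bead_movie(bead_sim_params(seed = seed, ...))
    write_stack(sim$stack, file.path(out, "beads.tif"))
    utils::write.csv(sim$truth, file.path(out, "truth.csv"),
                     row.names = FALSE)
  } else {
    sim <- simulate_cilia_video(cilia_scenario(scenario, seed = seed, ...))
    write_stack(sim$stack, file.path(out, "cilia.tif"))
    write_mask(sim$mask, file.path(out, "mask.tif"))
    utils::write.csv(data.frame(cbf_hz = sim$truth$cbf_hz),
                     file.path(out, "truth.csv"), row.names = FALSE)
  }
  invisible(out)
}
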