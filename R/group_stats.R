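#' Construct a group sample
#'
#' A labelled vector of per-ROI beat frequencies (Hz) or per-track bead
#' speeds (um/s) for one experimental group.
#'
#' @param label group label, e.g. "WT" or "KO".
#' @param values finite numeric measurements (at least one).
#' @param unit measurement unit, e.g. "Hz".
#' @return an object of class `GroupSample`.
#' @export
group_sample <- function(label, values, unit = "") {
  values <- as.numeric(values)
  if (length(values) < 1L) stop_ciliaflow("group '", label, "' is empty")
  if (!all(is.finite(values)))
    stop_ciliaflow("group '", label, "' has non-finite values")
  structure(list(label = as.character(label), values = values,
                 unit = as.character(unit)),
            class = "GroupSample")
}

group_stat_fun <- function(statistic) {
  switch(statistic,
         mean_diff = mean,
         median_diff = stats::median,
         stop_ciliaflow("unknown statistic '", statistic, "'"))
}

#' Two-group permutation test
#'
#' Tests a difference in group means (or medians) by randomly reassigning
#' the pooled values to groups of the original sizes. The observed
#' statistic is `statistic(a) - statistic(b)`. In Monte-Carlo mode the
#' p-value uses add-one smoothing, `p = (1 + k) / (1 + n_iterations)` with
#' k the number of null draws at least as extreme as the observed value
#' (two-sided: by absolute value), so p is never exactly 0. When the number
#' of distinct reassignments `choose(n, n_a)` is at most `exhaustive_limit`,
#' all of them are enumerated instead and the exact rational p = k/m is
#' returned with no smoothing. Deterministic for a fixed seed.
#'
#' @param a,b `GroupSample` objects (or bare numeric vectors).
#' @param statistic "mean_diff" (default) or "median_diff".
#' @param n_iterations Monte-Carlo iterations (default 10000).
#' @param seed integer seed for the Monte-Carlo reassignments.
#' @param alternative "two_sided" (default), "greater" or "less".
#' @param exhaustive_limit switch to full enumeration when the number of
#'   distinct reassignments does not exceed this (default 200000).
#' @return an object of class `PermutationResult`: statistic_name, observed,
#'   p_value, n_iterations, mode ("monte_carlo" or "exhaustive"), seed, and
#'   null_quantiles (2.5/50/97.5% of the null distribution).
#' @export
permutation_test <- function(a, b, statistic = c("mean_diff", "median_diff"),
                             n_iterations = 10000L, seed = 1L,
                             alternative = c("two_sided", "greater", "less"),
                             exhaustive_limit = 200000) {
  statistic <- match.arg(statistic)
  alternative <- match.arg(alternative)
  if (!inherits(a, "GroupSample")) a <- group_sample("a", a)
  if (!inherits(b, "GroupSample")) b <- group_sample("b", b)
  stopifnot(n_iterations >= 1)
  f <- group_stat_fun(statistic)
  observed <- f(a$values) - f(b$values)
  pooled <- c(a$values, b$values)
  na <- length(a$values); n <- length(pooled)

  exceed <- function(null) switch(
    alternative,
    two_sided = abs(null) >= abs(observed) - 1e-12,
    greater   = null >= observed - 1e-12,
    less      = null <= observed + 1e-12)

  n_comb <- choose(n, na)
  if (n_comb <= exhaustive_limit) {
    mode <- "exhaustive"
    idx <- utils::combn(n, na)
    if (statistic == "mean_diff") {
      tot <- sum(pooled)
      sa <- colSums(matrix(pooled[idx], nrow = na))
      null <- sa / na - (tot - sa) / (n - na)
    } else {
      null <- apply(idx, 2, function(i) f(pooled[i]) - f(pooled[-i]))
    }
    k <- sum(exceed(null))
    p <- k / n_comb
    n_used <- n_comb
    seed_used <- NA_integer_
  } else {
    mode <- "monte_carlo"
    null <- numeric(n_iterations)
    with_local_seed(seed, {
      if (statistic == "mean_diff") {
        tot <- sum(pooled)
        for (it in seq_len(n_iterations)) {
          sa <- sum(pooled[sample.int(n, na)])
          null[it] <- sa / na - (tot - sa) / (n - na)
        }
      } else {
        for (it in seq_len(n_iterations)) {
          i <- sample.int(n, na)
          null[it] <- f(pooled[i]) - f(pooled[-i])
        }
      }
    })
    p <- (1 + sum(exceed(null))) / (1 + n_iterations)
    n_used <- as.integer(n_iterations)
    seed_used <- as.integer(seed)
  }
  structure(list(statistic_name = statistic,
                 observed = observed,
                 p_value = p,
                 n_iterations = n_used,
                 mode = mode,
                 seed = seed_used,
                 null_quantiles = stats::quantile(
                   null, c(0.025, 0.5, 0.975), names = FALSE),
                 labels = c(a$label, b$label)),
            class = "PermutationResult")
}

#' @export
print.PermutationResult <- function(x, ...) {
  cat(sprintf(
    "Permutation test (%s, %s): observed = %.6g, p = %.4g (%d %s)\n",
    x$statistic_name, paste(x$labels, collapse = " vs "),
    x$observed, x$p_value, x$n_iterations,
    if (x$mode == "exhaustive") "arrangements" else "iterations"))
  invisible(x)
}

#' Compare two per-video CBF tables
#'
#' Builds group samples from the QC-passing `cbf_hz` rows of two
#' [analyze_video()] tables, runs [permutation_test()], and reports the
#' summary at the grain experimentalists quote: n ROIs from n videos per
#' group, with group means +/- SEM.
#'
#' The default exchange unit is the individual ROI, matching the "n = X
#' ROIs" reporting grain; `exchange_unit = "video"` instead permutes whole
#' videos between groups, which respects within-video correlation at the
#' cost of a much coarser null (Monte-Carlo only).
#'
#' @param table_a,table_b data.frames from [analyze_video()] (possibly
#'   row-bound over videos).
#' @param labels character(2) group labels.
#' @param statistic,n_iterations,seed,alternative passed to
#'   [permutation_test()].
#' @param exchange_unit "roi" (default) or "video".
#' @return list with `test` (a `PermutationResult`) and `summary`
#'   (data.frame: group, n_rois, n_videos, mean_cbf_hz, sem_cbf_hz).
#' @export
compare_cbf_tables <- function(table_a, table_b, labels = c("A", "B"),
                               statistic = "mean_diff",
                               n_iterations = 10000L, seed = 1L,
                               alternative = "two_sided",
                               exchange_unit = c("roi", "video")) {
  exchange_unit <- match.arg(exchange_unit)
  take <- function(tb, lab) {
    ok <- tb[tb$passed_qc & is.finite(tb$cbf_hz), , drop = FALSE]
    if (nrow(ok) == 0L)
      stop_ciliaflow("group '", lab, "' has no QC-passing ROIs")
    ok
  }
  qa <- take(table_a, labels[1]); qb <- take(table_b, labels[2])
  if (exchange_unit == "roi") {
    ga <- group_sample(labels[1], qa$cbf_hz, "Hz")
    gb <- group_sample(labels[2], qb$cbf_hz, "Hz")
    test <- permutation_test(ga, gb, statistic = statistic,
                             n_iterations = n_iterations, seed = seed,
                             alternative = alternative)
  } else {
    test <- block_permutation_test(qa$cbf_hz, qa$video_id,
                                   qb$cbf_hz, qb$video_id,
                                   statistic = statistic,
                                   n_iterations = n_iterations, seed = seed,
                                   alternative = alternative,
                                   labels = labels)
  }
  summ <- function(q, lab) data.frame(
    group = lab,
    n_rois = nrow(q),
    n_videos = length(unique(q$video_id)),
    mean_cbf_hz = mean(q$cbf_hz),
    sem_cbf_hz = stats::sd(q$cbf_hz) / sqrt(nrow(q)))
  list(test = test, summary = rbind(summ(qa, labels[1]), summ(qb, labels[2])))
}

#' Block-level permutation test
#'
#' Permutes whole blocks (e.g. videos) between two groups while the
#' statistic is still computed on the pooled individual measurements. Used
#' by [compare_cbf_tables()] when `exchange_unit = "video"`; Monte-Carlo
#' only.
#'
#' @param values_a,values_b numeric measurements.
#' @param blocks_a,blocks_b block identifier per measurement.
#' @param statistic,n_iterations,seed,alternative as [permutation_test()].
#' @param labels character(2) group labels.
#' @return a `PermutationResult` with mode "monte_carlo".
#' @export
block_permutation_test <- function(values_a, blocks_a, values_b, blocks_b,
                                   statistic = "mean_diff",
                                   n_iterations = 10000L, seed = 1L,
                                   alternative = "two_sided",
                                   labels = c("A", "B")) {
  f <- group_stat_fun(statistic)
  observed <- f(values_a) - f(values_b)
  blocks <- c(paste0("a:", blocks_a), paste0("b:", blocks_b))
  pooled <- c(values_a, values_b)
  ublocks <- unique(blocks)
  ka <- length(unique(blocks_a))
  by_block <- split(pooled, factor(blocks, levels = ublocks))
  null <- numeric(n_iterations)
  with_local_seed(seed, {
    for (it in seq_len(n_iterations)) {
      pick <- sample.int(length(ublocks), ka)
      va <- unlist(by_block[pick], use.names = FALSE)
      vb <- unlist(by_block[-pick], use.names = FALSE)
      null[it] <- f(va) - f(vb)
    }
  })
  exceed <- switch(alternative,
                   two_sided = abs(null) >= abs(observed) - 1e-12,
                   greater   = null >= observed - 1e-12,
                   less      = null <= observed + 1e-12)
  structure(list(statistic_name = paste0(statistic, " (block)"),
                 observed = observed,
                 p_value = (1 + sum(exceed)) / (1 + n_iterations),
                 n_iterations = as.integer(n_iterations),
                 mode = "monte_carlo",
                 seed = as.integer(seed),
                 null_quantiles = stats::quantile(
                   null, c(0.025, 0.5, 0.975), names = FALSE),
                 labels = labels),
            class = "PermutationResult")
}
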