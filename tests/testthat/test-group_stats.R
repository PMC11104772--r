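test_that("identical multisets give observed 0 and p = 1", {
  res <- permutation_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$observed, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$mode, "exhaustive")
})

test_that("the exhaustive p for [0,0,0] vs [1,1,1] is exactly 2/20", {
  res <- permutation_test(c(0, 0, 0), c(1, 1, 1))
  expect_equal(res$mode, "exhaustive")
  expect_equal(res$n_iterations, 20)
  expect_equal(res$observed, -1)
  expect_identical(res$p_value, 0.1)
})

test_that("Monte-Carlo p agrees with the exact p within 3 binomial SDs", {
  a <- c(0, 0, 0); b <- c(1, 1, 1)
  exact <- permutation_test(a, b)$p_value
  mc <- permutation_test(a, b, n_iterations = 10000, seed = 77,
                         exhaustive_limit = 1)
  expect_equal(mc$mode, "monte_carlo")
  tol <- 3 * sqrt(exact * (1 - exact) / 10000)
  expect_lt(abs(mc$p_value - exact), tol + 2 / 10001)  # +smoothing slack
})

test_that("p is shift-invariant and two-sided p is label-symmetric", {
  set.seed(12)
  a <- rnorm(8, 10); b <- rnorm(6, 11)
  r1 <- permutation_test(a, b, n_iterations = 2000, seed = 5)
  r2 <- permutation_test(a + 137.2, b + 137.2, n_iterations = 2000,
                         seed = 5)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$observed, r2$observed, tolerance = 1e-9)
  r3 <- permutation_test(b, a, n_iterations = 2000, seed = 5)
  expect_equal(r3$observed, -r1$observed, tolerance = 1e-12)
  expect_equal(r3$p_value, r1$p_value)
})

test_that("median statistic and one-sided alternatives behave sensibly", {
  a <- c(5, 6, 7, 8); b <- c(1, 2, 3, 4)
  rg <- permutation_test(a, b, alternative = "greater")
  rl <- permutation_test(a, b, alternative = "less")
  expect_lt(rg$p_value, 0.05)
  expect_gt(rl$p_value, 0.9)
  rm <- permutation_test(a, b, statistic = "median_diff")
  expect_equal(rm$observed, 4)
  expect_error(permutation_test(numeric(0), b), "empty")
})

test_that("compare_cbf_tables summarizes cohorts at the ROI/video grain", {
  mk <- function(vals, vids, qc = TRUE) data.frame(
    video_id = vids, roi_id = seq_along(vals), cbf_hz = vals,
    passed_qc = qc)
  ta <- mk(c(28, 28.5, 27.5, 28.2), c("v1", "v1", "v2", "v2"))
  tb <- mk(c(34, 33.8, 34.1, 34.3), c("v3", "v3", "v4", "v4"))
  out <- compare_cbf_tables(ta, tb, labels = c("WT", "KO"),
                            n_iterations = 2000, seed = 3)
  expect_equal(out$summary$n_rois, c(4, 4))
  expect_equal(out$summary$n_videos, c(2, 2))
  expect_equal(out$test$observed,
               mean(ta$cbf_hz) - mean(tb$cbf_hz), tolerance = 1e-12)
  expect_lt(out$test$p_value, 0.05)
  # all-QC-failed group is an error
  tb_bad <- mk(c(34, 34), c("v3", "v3"), qc = FALSE)
  expect_error(compare_cbf_tables(ta, tb_bad), "no QC-passing")
})

test_that("video-level exchange gives a valid, coarser permutation null", {
  set.seed(9)
  ta <- data.frame(video_id = rep(paste0("a", 1:4), each = 5),
                   roi_id = 1:20, cbf_hz = rnorm(20, 28, 1),
                   passed_qc = TRUE)
  tb <- data.frame(video_id = rep(paste0("b", 1:4), each = 5),
                   roi_id = 1:20, cbf_hz = rnorm(20, 29, 1),
                   passed_qc = TRUE)
  out <- compare_cbf_tables(ta, tb, n_iterations = 2000, seed = 4,
                            exchange_unit = "video")
  expect_s3_class(out$test, "PermutationResult")
  expect_gte(out$test$p_value, 1 / 2001)
  expect_lte(out$test$p_value, 1)
})
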