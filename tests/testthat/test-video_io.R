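test_that("full-scale 16-bit frames normalize to intensity 1.0", {
  p <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(replicate(3, matrix(1, 8, 8), simplify = FALSE), p,
                  bits.per.sample = 16L)
  st <- read_stack(p, frame_rate_hz = 1000)
  expect_equal(dim(st$frames), c(3L, 8L, 8L))
  expect_true(all(st$frames == 1.0))
  expect_equal(st$frame_rate_hz, 1000)
})

test_that("write_stack / read_stack round trip preserves data and metadata", {
  set.seed(42)
  frames <- array(runif(5 * 12 * 9), dim = c(5, 12, 9))
  st <- video_stack(frames, frame_rate_hz = 987.5, pixel_size_um = 0.31)
  p <- withr::local_tempfile(fileext = ".tif")
  write_stack(st, p)
  back <- read_stack(p)
  expect_equal(dim(back$frames), dim(st$frames))
  expect_equal(back$frame_rate_hz, 987.5)
  expect_equal(back$pixel_size_um, 0.31)
  expect_lte(max(abs(back$frames - st$frames)), 1 / 65535)
  # normalization is monotone: intensity ordering survives the round trip
  o1 <- order(st$frames[1, , ])
  expect_true(all(diff(back$frames[1, , ][o1]) >= -1e-12))
  # sidecar carries the metadata verbatim
  sc <- jsonlite::read_json(paste0(p, ".json"))
  expect_equal(sc$frame_rate_hz, 987.5)
})

test_that("directory input requires consistent shapes, lexicographic order", {
  d <- withr::local_tempdir()
  tiff::writeTIFF(matrix(0.2, 6, 6), file.path(d, "b_frame2.tif"),
                  bits.per.sample = 16L)
  tiff::writeTIFF(matrix(0.1, 6, 6), file.path(d, "a_frame1.tif"),
                  bits.per.sample = 16L)
  st <- read_stack(d, frame_rate_hz = 5)
  expect_equal(st$frames[1, 1, 1], 0.1, tolerance = 1e-4)
  expect_equal(st$frames[2, 1, 1], 0.2, tolerance = 1e-4)
  tiff::writeTIFF(matrix(0.3, 4, 4), file.path(d, "c_frame3.tif"),
                  bits.per.sample = 16L)
  expect_error(read_stack(d, frame_rate_hz = 5), "inconsistent frame shape")
})

test_that("missing frame rate and degenerate stacks are fatal", {
  p <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(replicate(2, matrix(0.5, 4, 4), simplify = FALSE), p,
                  bits.per.sample = 16L)
  expect_error(read_stack(p), "frame rate")
  p1 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(0.5, 4, 4), p1, bits.per.sample = 16L)
  expect_error(read_stack(p1, frame_rate_hz = 5), "single-frame")
  expect_error(video_stack(array(0.5, c(1, 4, 4)), 5), "at least 2")
  expect_error(video_stack(array(2, c(3, 4, 4)), 5), "\\[0,1\\]")
  expect_error(video_stack(array(0.5, c(3, 4, 4)), -1), "frame_rate_hz")
})

test_that("read_mask validates shape and preserves the inside-pixel count", {
  m <- matrix(0, 16, 16)
  set.seed(7)
  on_px <- sample(256, 40)
  m[on_px] <- 1
  p <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(m, p, bits.per.sample = 8L)
  lm <- read_mask(p, c(16L, 16L))
  expect_s3_class(lm, "LayerMask")
  expect_equal(sum(lm$mask), 40)
  expect_error(read_mask(p, c(8L, 8L)), "does not match")
  p0 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(0, 16, 16), p0, bits.per.sample = 8L)
  expect_warning(read_mask(p0, c(16L, 16L)), "no nonzero")
  pall <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(1, 16, 16), pall, bits.per.sample = 8L)
  expect_true(all(read_mask(pall, c(16L, 16L))$mask))
})
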