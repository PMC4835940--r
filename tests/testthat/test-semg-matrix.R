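test_that("matrix formation fills column-major and pads the last column", {
  m <- segment_to_matrix(make_record(1:8), 4)
  expect_equal(dim(m$values), c(4L, 2L))
  expect_equal(m$values[, 1], 1:4)
  expect_equal(m$values[, 2], 5:8)
  expect_equal(m$original_sample_count, 8L)

  m2 <- segment_to_matrix(make_record(1:6), 4)
  expect_equal(dim(m2$values), c(4L, 2L))
  expect_equal(m2$values[, 2], c(5L, 6L, 0L, 0L))
  expect_equal(m2$original_sample_count, 6L)
  # padding never alters any original sample value
  expect_equal(as.vector(m2$values)[1:6], 1:6)

  expect_error(semg_record(integer(0), 2000), "empty signal")
  expect_error(segment_to_matrix(make_record(1:5), 0), "segment_length")
})

test_that("matrix formation and its inverse compose to the identity", {
  meta <- list(sampling_rate_hz = 2000, bit_depth = 12L, offset = 0L)
  set.seed(42)
  for (i in 1:20) {
    n <- sample(1:200, 1)
    K <- sample(1:(n + 3), 1)
    r <- rand_record(n, seed = i)
    m <- segment_to_matrix(r, K)
    back <- matrix_to_record(m, r)
    expect_identical(back$samples, r$samples)
    expect_identical(back$sampling_rate_hz, r$sampling_rate_hz)
  }
  # full-capacity matrix decodes without truncation
  m <- segment_to_matrix(make_record(1:12), 3)
  expect_equal(m$n_segments * m$segment_length, 12L)
  expect_identical(matrix_to_record(m, meta)$samples, 1:12)
  # corrupted bookkeeping is rejected
  m$original_sample_count <- 13L
  expect_error(matrix_to_record(m, meta), "exceeds")
})

test_that("square segment length is the ceiling square root", {
  expect_identical(square_segment_length(16), 4L)
  expect_identical(square_segment_length(17), 5L)
  expect_error(square_segment_length(0), ">= 1")
  set.seed(1)
  for (n in c(1:64, sample.int(10000, 60))) {
    K <- square_segment_length(n)
    L <- ceiling(n / K)
    expect_true(K * L >= n)
    expect_true(K * (L - 1) < n)
    expect_true(L %in% c(K - 1L, K) || n <= 2)
  }
})

test_that("raw and text record files round-trip, including the offset", {
  r <- rand_record(257, seed = 3, amp = 2000L)
  fr <- tempfile(fileext = ".raw")
  ft <- tempfile(fileext = ".txt")
  on.exit(unlink(c(fr, ft)))
  write_semg_record(r, fr)
  write_semg_record(r, ft)
  expect_identical(read_semg_record(fr, 2000)$samples, r$samples)
  expect_identical(read_semg_record(ft, 2000)$samples, r$samples)

  # an unsigned 12-bit acquisition is zero-centered through the offset
  u <- make_record(sample.int(4096, 100) - 1L - 2048L, 2000, offset = 2048L)
  write_semg_record(u, fr)
  back <- read_semg_record(fr, 2000, offset = 2048L)
  expect_identical(back$samples, u$samples)
  raw16 <- readBin(fr, "integer", 100, size = 2, endian = "little")
  expect_true(all(raw16 >= 0 & raw16 <= 4095))
})

test_that("PGM export writes a valid 16-bit big-endian P5 image", {
  m <- segment_to_matrix(make_record(c(-2048L, 0L, 2047L, 5L)), 2)
  f <- tempfile(fileext = ".pgm")
  on.exit(unlink(f))
  export_pgm(m, f, offset = 2048L)
  con <- file(f, "rb")
  hdr <- character(3)
  for (i in 1:3) hdr[i] <- readLines(con, 1)
  expect_identical(hdr, c("P5", "2 2", "65535"))
  px <- readBin(con, "integer", 4, size = 2, signed = FALSE, endian = "big")
  close(con)
  # row-major pixel order with the offset re-applied
  expect_equal(px, as.vector(t(m$values)) + 2048L)
  expect_error(export_pgm(m, f, offset = 0L), "outside")
})
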