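test_that("arithmetic coding is exactly lossless", {
  expect_identical(arith_decode(arith_encode(integer(0), 5), 0, 5),
                   integer(0))
  set.seed(41)
  s <- sample(0:4, 10000, replace = TRUE)
  b <- arith_encode(s, 5)
  expect_identical(arith_decode(b, length(s), 5), s)
  # binary alphabet too
  s2 <- sample(0:1, 5000, replace = TRUE)
  expect_identical(arith_decode(arith_encode(s2, 2), 5000, 2), s2)
})

test_that("code lengths approach the source entropy", {
  set.seed(42)
  s <- sample(0:4, 10000, replace = TRUE)
  bits <- length(arith_encode(s, 5)) * 8
  H <- log2(5)
  expect_lte(bits / length(s), 1.02 * (H + 1))
  expect_gte(bits / length(s), 0.98 * H)
  # a skewed source (p = 0.9 on one symbol) codes below 1 bit/symbol
  sk <- sample(0:4, 10000, replace = TRUE, prob = c(0.9, rep(0.025, 4)))
  expect_lt(length(arith_encode(sk, 5)) * 8 / length(sk), 1)
  expect_identical(arith_decode(arith_encode(sk, 5), length(sk), 5), sk)
})

test_that("the container round-trips byte-exactly and validates its magic", {
  f <- tempfile(fileext = ".mmp2d")
  on.exit(unlink(f))
  payload <- as.raw(sample(0:255, 300, replace = TRUE))
  header <- list(n_samples = 600L, offset = 2048L, bit_depth = 12L,
                 sampling_rate_hz = 2000, x_max = 1433L,
                 segment_length = 25L, n_segments = 24L,
                 preprocess = "pds", lambda = 12.5, cap = 50000L,
                 additive_symmetric = FALSE,
                 permutation = sample(24L))
  write_container(f, header, payload)
  back <- read_container(f)
  expect_identical(back$payload, payload)
  expect_identical(back$header$permutation, header$permutation)
  for (k in setdiff(names(header), "permutation"))
    expect_equal(back$header[[k]], header[[k]], info = k)

  # unknown magic
  bad <- tempfile()
  writeBin(as.raw(1:40), bad)
  expect_error(read_container(bad), "not an .mmp2d container")
  # truncation
  bytes <- readBin(f, "raw", file.size(f))
  writeBin(bytes[1:20], bad)
  expect_error(read_container(bad), "truncated")
  unlink(bad)
})

test_that("the compression factor consumes the container size in bits", {
  r <- rand_record(256, seed = 51, amp = 800L)
  f <- tempfile(fileext = ".mmp2d")
  on.exit(unlink(f))
  info <- semg_compress(r, f, lambda = 20)
  expect_identical(info$bits, file.size(f) * 8)
  ev <- semg_evaluate(r, f)
  expect_equal(ev$cf_percent, cf(12 * 256, file.size(f) * 8))
})
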