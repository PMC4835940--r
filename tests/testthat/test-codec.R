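test_that("lambda = 0 reconstructs any matrix exactly", {
  m <- rand_matrix(32, 32, seed = 21, amp = 700L)
  e <- mmp_encode_matrix(m, 0)
  expect_identical(e$recon, m)
  d <- mmp_decode_matrix(e$payload, dim(m), e$x_max, 0)
  expect_identical(d$recon, m)
})

test_that("decoder reproduces the encoder trajectory at every lambda", {
  m <- rand_matrix(32, 32, seed = 22, amp = 400L)
  for (lam in c(0, 8, 64)) {
    e <- mmp_encode_matrix(m, lam)
    d <- mmp_decode_matrix(e$payload, dim(m), e$x_max, lam)
    expect_identical(d$recon, e$recon)
    expect_identical(d$state_hash, e$state_hash)   # dictionary + models
    expect_identical(d$dict_sizes, e$dict_sizes)
    expect_equal(d$symbols, e$symbols)
    expect_equal(d$trees, e$trees)
  }
})

test_that("a zero matrix codes as one leaf per block, reconstructed as zeros", {
  m <- matrix(0L, 16, 16)
  for (lam in c(0, 12)) {
    e <- mmp_encode_matrix(m, lam)
    expect_identical(e$recon, m)
    expect_identical(e$trees[[1]]$kind, "leaf")
  }
})

test_that("a homogeneous block at an initial level stays unsegmented at high lambda", {
  m <- matrix(19L, 16, 16)   # 19 is an initial dictionary level for X_max = 19
  e <- mmp_encode_matrix(m, 1000)
  expect_identical(e$trees[[1]]$kind, "leaf")
  expect_identical(e$recon, m)
})

test_that("optional codec features keep the two sides synchronized", {
  m <- rand_matrix(16, 16, seed = 23, amp = 60L)
  for (opts in list(mmp_options(additive_symmetric = TRUE),
                    mmp_options(search = "thorough"),
                    mmp_options(cap = 300L))) {
    e <- mmp_encode_matrix(m, 8, opts)
    d <- mmp_decode_matrix(e$payload, dim(m), e$x_max, 8, opts)
    expect_identical(d$recon, e$recon)
    expect_identical(d$state_hash, e$state_hash)
  }
  expect_true(all(mmp_encode_matrix(m, 8, mmp_options(cap = 300L))$dict_sizes
                  <= 300L))
  expect_error(mmp_options(norm_equalization = TRUE), "stub")
})

test_that("rate falls and distortion rises with lambda (one inversion allowed)", {
  m <- rand_matrix(32, 32, seed = 24, amp = 500L)
  lams <- c(0, 2, 8, 32, 128)
  bits <- numeric(length(lams)); dist <- numeric(length(lams))
  for (i in seq_along(lams)) {
    e <- mmp_encode_matrix(m, lams[i])
    bits[i] <- e$bits
    dist[i] <- sum((m - e$recon)^2)
  }
  expect_identical(dist[1], 0)
  expect_lte(sum(diff(bits) > 0), 1)    # rate non-increasing
  expect_lte(sum(diff(dist) < 0), 1)    # distortion non-decreasing
})

test_that("padding of partial edge blocks is invisible after decoding", {
  r <- rand_record(300, seed = 25, amp = 900L)   # 18 x 17 matrix, padded
  mat <- segment_to_matrix(r, 18L)
  e <- mmp_encode_matrix(mat$values, 0)
  expect_identical(e$recon, mat$values)
  d <- mmp_decode_matrix(e$payload, dim(mat$values), e$x_max, 0)
  mat2 <- mat; mat2$values <- d$recon
  expect_identical(matrix_to_record(mat2, r)$samples, r$samples)
})
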