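test_that("percentage difference matches its defining ratio", {
  expect_equal(percentage_difference(c(2, -3, 1), c(2, -3, 1)), 0)
  expect_equal(percentage_difference(c(1, 1), c(3, 3)), 4)
  expect_equal(percentage_difference(c(3, 4), c(0, 0)), 1)
  expect_error(percentage_difference(c(0, 0), c(1, 2)), "zero-energy")
  expect_error(percentage_difference(1:3, 1:4), "equal length")
})

test_that("PDS seeds at minimum variance and chains by similarity", {
  # columns A=[1,1], B=[3,3], C=[2,2]: variances all zero, tie -> A;
  # PD(A,C)=1 beats PD(A,B)=4, so the order is A, C, B
  m <- segment_to_matrix(make_record(c(1, 1, 3, 3, 2, 2)), 2)
  ps <- pds_sort(m)
  expect_equal(ps$ordering, c(1L, 3L, 2L))
  expect_equal(ps$matrix$values, cbind(c(1L, 1L), c(2L, 2L), c(3L, 3L)))

  # all-identical columns: every tie resolves to the lowest index
  mi <- segment_to_matrix(make_record(rep(c(5L, -5L), 4)), 2)
  expect_equal(pds_sort(mi)$ordering, 1:4)

  # a zero-energy column must not crash the greedy scan
  mz <- segment_to_matrix(make_record(c(0L, 0L, 4L, 4L, 1L, 1L)), 2)
  expect_equal(length(pds_sort(mz)$ordering), 3L)
})

test_that("PDS output is a column permutation and restores exactly", {
  for (i in 1:10) {
    m <- segment_to_matrix(rand_record(60, seed = 100 + i), 6)
    ps <- pds_sort(m)
    # multiset of columns preserved
    expect_equal(sort(as.vector(ps$matrix$values)), sort(as.vector(m$values)))
    expect_setequal(ps$ordering, 1:10)
    expect_identical(pds_restore(ps$matrix, ps$ordering)$values, m$values)
  }
  m <- segment_to_matrix(make_record(1:9), 3)
  expect_identical(pds_restore(m, 1:3)$values, m$values)
  expect_error(pds_restore(m, c(1L, 1L, 2L)), "not a permutation")
})

test_that("SbS picks the segment length with the most similar neighbors", {
  # periodic signal: every multiple of the period scores a zero mean PD,
  # and the tie resolves to the smallest candidate, 32
  per <- round(1000 * sin(2 * pi * (0:31) / 32))
  r <- make_record(rep(per, 128))
  expect_identical(sbs_select_length(r), 32L)

  # constant nonzero signal: all means are zero, smallest N wins
  expect_identical(sbs_select_length(make_record(rep(7L, 4096))), 32L)

  expect_error(sbs_select_length(make_record(1:63)), "too short")
})

test_that("SbS equals a brute-force re-computation on noise", {
  sbs_oracle <- function(x) {
    best_n <- NA; best <- Inf
    for (n in 2:64) {
      N <- 16 * n
      k <- length(x) %/% N
      if (k < 2) next
      tot <- 0
      for (i in seq_len(k - 1)) {
        a <- x[((i - 1) * N + 1):(i * N)]
        b <- x[(i * N + 1):((i + 1) * N)]
        tot <- tot + sum((a - b)^2) / sum(a^2)
      }
      sc <- tot / (k - 1)
      if (sc < best) { best <- sc; best_n <- N }
    }
    best_n
  }
  for (i in 1:5) {
    r <- rand_record(sample(2000:6000, 1), seed = 200 + i)
    N <- sbs_select_length(r)
    expect_identical(N, as.integer(sbs_oracle(r$samples)))
    expect_true(N %% 16 == 0 && N >= 32 && N <= 1024)
    # the chosen length's mean adjacent PD is minimal among all candidates
    means <- vapply(2:64, function(n) {
      NN <- 16 * n
      k <- length(r$samples) %/% NN
      if (k < 2) return(Inf)
      segs <- matrix(r$samples[1:(k * NN)], nrow = NN)
      mean(vapply(seq_len(k - 1), function(j)
        sum((segs[, j] - segs[, j + 1])^2) / sum(segs[, j]^2), numeric(1)))
    }, numeric(1))
    expect_equal(min(means), means[match(N / 16, 2:64)])
  }
})
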