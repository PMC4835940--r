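test_that("mode availability follows the scale gating", {
  expect_identical(allowed_modes(2), integer(0))
  expect_length(allowed_modes(25), 35)       # planar + MFV + 33 angular
  expect_length(allowed_modes(5), 34)        # planar excluded
  for (s in 1:25) {
    am <- allowed_modes(s)
    expect_true(length(am) %in% c(0L, 34L, 35L))
    expect_identical(length(am) == 35L, s %in% c(4L, 9L, 16L, 25L))
    if (s >= 4) {
      expect_true(all(2:34 %in% am))          # 33 angular modes
      expect_true(1 %in% am)                  # MFV
    }
  }
  expect_error(allowed_modes(0), "scale")
  expect_error(allowed_modes(26), "scale")
})

test_that("reference vectors copy, substitute and default correctly", {
  # nothing coded yet: all references default to zero
  rec <- matrix(NA_integer_, 20, 20)
  rf <- build_reference_vectors(rec, c(1, 1), c(4, 4))
  expect_identical(rf$vertical, rep(0L, 9))
  expect_identical(rf$horizontal, rep(0L, 9))

  # fully coded interior: vectors copy the reconstruction verbatim
  full <- outer(1:20, 1:20, function(r, c) 100L * r + c)
  rf <- build_reference_vectors(full, c(5, 5), c(4, 4))
  expect_identical(rf$vertical, c(full[4, 4], full[5:12, 4]))
  expect_identical(rf$horizontal, c(full[4, 4], full[4, 5:12]))

  # unavailable upper-right and lower-left spans propagate the last
  # available sample outward (explicit substitution oracle)
  part <- full
  part[5:20, 5:20] <- NA         # current block and everything after
  part[9:20, ] <- NA             # lower-left rows not yet coded
  part[1:4, 9:20] <- NA          # upper-right columns not yet coded
  rf <- build_reference_vectors(part, c(5, 5), c(4, 4))
  expect_identical(rf$horizontal,
                   c(full[4, 4], full[4, 5:8], rep(full[4, 8], 4L)))
  expect_identical(rf$vertical,
                   c(full[4, 4], full[5:8, 4], rep(full[8, 4], 4L)))
})

test_that("every interpolating mode propagates constant references", {
  for (dims in list(c(16L, 16L), c(4L, 4L))) {
    n <- 2L * max(dims) + 1L
    refs <- list(vertical = rep(7L, n), horizontal = rep(7L, n))
    for (m in allowed_modes(scale_index(dims[1], dims[2]))) {
      p <- predict_block(refs, m, dims)
      expect_identical(p, matrix(7L, dims[1], dims[2]))
    }
  }
})

test_that("pure vertical and horizontal modes copy their reference line", {
  n <- 33L
  refs <- list(vertical = c(0L, 101:132), horizontal = c(0L, 1:32))
  v <- predict_block(refs, 26, c(16, 16))   # zero-displacement vertical
  expect_identical(v, matrix(1:16, 16, 16, byrow = TRUE))
  h <- predict_block(refs, 10, c(16, 16))   # zero-displacement horizontal
  expect_identical(h, matrix(101:116, 16, 16, byrow = FALSE))
})

test_that("planar equals a brute-force two-interpolation average", {
  set.seed(5)
  L <- as.integer(sample(-50:50, 9))  # vertical: corner + 8 left samples
  A <- as.integer(sample(-50:50, 9))  # horizontal: corner + 8 above samples
  p <- predict_block(list(vertical = L, horizontal = A), 0, c(4, 4))
  oracle <- matrix(0L, 4, 4)
  for (y in 0:3) for (x in 0:3) {
    ph <- ((3 - x) * L[y + 2] + (x + 1) * A[6]) / 4   # -> top-right sample
    pv <- ((3 - y) * A[x + 2] + (y + 1) * L[6]) / 4   # -> bottom-left sample
    v <- (ph + pv) / 2
    oracle[y + 1, x + 1] <- as.integer(if (v >= 0) floor(v + 0.5) else ceiling(v - 0.5))
  }
  expect_identical(p, oracle)
})

test_that("MFV takes the modal reference value, smallest on ties", {
  refs <- list(vertical = c(3L, rep(5L, 8)), horizontal = c(3L, rep(2L, 8)))
  # 5 occurs 8 times, 2 occurs 8 times, 3 twice (corner in both vectors):
  # tie between 2 and 5 resolves to 2
  expect_identical(predict_block(refs, 1, c(4, 4)), matrix(2L, 4, 4))
  refs2 <- list(vertical = rep(9L, 9), horizontal = c(9L, rep(1L, 8)))
  expect_identical(predict_block(refs2, 1, c(4, 4)), matrix(9L, 4, 4))
})

test_that("residual subtracts elementwise and checks dimensions", {
  x <- matrix(5L, 2, 2); p <- matrix(2L, 2, 2)
  expect_identical(residual(x, p), matrix(3L, 2, 2))
  expect_identical(residual(x, x), matrix(0L, 2, 2))
  expect_error(residual(x, matrix(0L, 2, 3)), "dimensions differ")
})

test_that("disallowed modes are rejected", {
  refs <- list(vertical = rep(0L, 9), horizontal = rep(0L, 9))
  expect_error(predict_block(refs, 0, c(2, 4)), "not allowed")  # planar off-scale
  expect_error(predict_block(refs, 5, c(1, 2)), "not allowed")  # scale 3: no modes
})
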