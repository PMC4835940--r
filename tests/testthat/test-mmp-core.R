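test_that("the scale formula maps the 25 block geometries bijectively", {
  expect_identical(scale_index(16, 16), 25L)
  expect_identical(scale_index(1, 1), 1L)
  expect_identical(scale_index(16, 8), 23L)
  dims <- expand.grid(M = c(1, 2, 4, 8, 16), N = c(1, 2, 4, 8, 16))
  scales <- mapply(scale_index, dims$M, dims$N)
  expect_setequal(scales, 1:25)
  for (s in 1:25) {
    d <- scale_dims(s)
    expect_identical(scale_index(d[1], d[2]), s)
  }
  expect_error(scale_index(3, 4), "powers of two")
  expect_error(scale_index(32, 16), "powers of two")
})

test_that("initial dictionary levels follow the magnitude-banded step", {
  d <- init_dictionary(255)
  expect_length(d$scales[[1]]$patterns, 511)            # all ints in [-255, 255]
  lv <- d$levels
  expect_identical(lv[1], -255L)                        # largest value times -1
  expect_true(all(lv >= -255 & lv <= 255))
  # every consecutive pair advances by the step of the previous level
  expect_identical(diff(lv), dict_level_step(lv[-length(lv)]))
  # the level after -5 is -4 (step 1 for magnitudes up to 10)
  i <- match(-5L, lv)
  expect_identical(lv[i + 1], -4L)
  # band edges of the step rule
  expect_identical(dict_level_step(c(-5, 10, 11, 22, 23, 30, 86, 87, 200)),
                   c(1L, 1L, 4L, 4L, 8L, 8L, 8L, 13L, 13L))
  expect_identical(dict_level_step(30) + 30L, 38L)      # the level after 30
})

test_that("the redundancy threshold is piecewise constant in lambda", {
  expect_identical(redundancy_threshold(0), 20)
  expect_identical(redundancy_threshold(4), 20)
  expect_identical(redundancy_threshold(4.01), 40)
  expect_identical(redundancy_threshold(22), 40)
  expect_identical(redundancy_threshold(30), 60)
  expect_identical(redundancy_threshold(50), 60)
  expect_identical(redundancy_threshold(51), 80)
  expect_error(redundancy_threshold(-1), "nonnegative")
})

test_that("best_match minimizes J = D + lambda R with deterministic ties", {
  set.seed(11)
  entries <- lapply(1:50, function(i) matrix(sample(-30:30, 4), 2, 2))
  # a verbatim entry at lambda = 0 is matched with zero cost
  bm <- best_match(entries[[17]], entries, lambda = 0)
  expect_identical(bm$index, 17L)
  expect_identical(bm$cost, 0)
  # equal-cost duplicates resolve to the lower index
  dup <- c(entries[1], entries[1])
  expect_identical(best_match(entries[[1]], dup, 0)$index, 1L)
  # exhaustive-search oracle with rates and nonzero lambda
  rates <- runif(50, 0, 16)
  for (i in 1:50) {
    blk <- matrix(sample(-30:30, 4), 2, 2)
    for (lam in c(0, 7.3)) {
      costs <- vapply(seq_along(entries), function(e)
        sum((blk - entries[[e]])^2) + lam * rates[e], numeric(1))
      bm <- best_match(blk, entries, lam, rates)
      expect_identical(bm$index, which.min(costs))
      expect_equal(bm$cost, min(costs))
    }
  }
  expect_error(best_match(matrix(0, 2, 2), list(), 0), "empty")
})

test_that("the separable scale transform behaves as specified", {
  p <- matrix(sample(-9:9, 32, replace = TRUE), 4, 8)
  expect_identical(scale_transform(p, c(4, 8)), p)             # identity
  for (s in 1:25) {                                            # constants
    d <- scale_dims(s)
    expect_identical(scale_transform(matrix(6L, 2, 2), d),
                     matrix(6L, d[1], d[2]))
  }
  v <- matrix(c(2L, 4L), 2, 1)
  expect_identical(scale_transform(scale_transform(v, c(2, 2)), c(2, 1)), v)
})

test_that("dictionary updates respect redundancy, partitions and the cap", {
  d0 <- init_dictionary(20, lambda = 0)     # d = 20
  sizes0 <- vapply(d0$scales, function(s) length(s$patterns), integer(1))
  # a pattern identical to an existing entry is inserted nowhere
  d1 <- update_dictionary(d0, matrix(0L, 2, 2), origin_scale = 4L)
  expect_identical(vapply(d1$scales, function(s) length(s$patterns),
                          integer(1)), sizes0)
  # a pattern far from every entry enters every scale above 1
  # (scale 1 already holds every representable value); quadrant structure
  # keeps its row- and column-contractions away from homogeneous levels
  far <- rbind(cbind(matrix(-20L, 2, 2), matrix(20L, 2, 2)),
               matrix(-20L, 2, 4))
  d2 <- update_dictionary(d0, far, origin_scale = 9L)
  sizes2 <- vapply(d2$scales, function(s) length(s$patterns), integer(1))
  expect_identical(sizes2[1], sizes0[1])
  expect_identical(sizes2[-1], sizes0[-1] + 1L)
  expect_identical(d2$scales[[25]]$origin[sizes2[25]], 9L)
  # additive symmetric inserts the negated pattern too
  da <- init_dictionary(20, lambda = 0, additive_symmetric = TRUE)
  da2 <- update_dictionary(da, far, origin_scale = 9L)
  expect_identical(length(da2$scales[[25]]$patterns), sizes0[25] + 2L)
  # a full scale accepts nothing
  dc <- init_dictionary(20, lambda = 0, cap = sizes0[2])
  dc2 <- update_dictionary(dc, far, origin_scale = 9L)
  expect_identical(length(dc2$scales[[2]]$patterns), sizes0[2])
})
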