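test_that("the canonical predicted-segmentation tree serializes to its symbol string", {
  # vertical prediction split at the root; left half predicted with M1 and
  # coded as one leaf; right half predicted with M2, residue horizontally
  # segmented, lower part segmented again: "3 0 M1 i0 2 M2 0 i1 2 0 i2 0 i3"
  M1 <- 1L; M2 <- 14L
  tree <- list(
    kind = "pred_vsplit", scale = 25L, mode = NULL,
    children = list(
      list(kind = "leaf", scale = 23L, mode = M1, partition = 0L, index = 10L),
      list(kind = "hsplit", scale = 23L, mode = M2,
           children = list(
             list(kind = "leaf", scale = 16L, mode = NULL,
                  partition = 0L, index = 11L),
             list(kind = "hsplit", scale = 16L, mode = NULL,
                  children = list(
                    list(kind = "leaf", scale = 15L, mode = NULL,
                         partition = 0L, index = 12L),
                    list(kind = "leaf", scale = 15L, mode = NULL,
                         partition = 0L, index = 13L)))))))
  s <- serialize_tree(tree)
  expect_identical(s$type, c("flag", "flag", "mode", "index", "flag", "mode",
                             "flag", "index", "flag", "flag", "index",
                             "flag", "index"))
  expect_identical(s$value, c(3L, 0L, M1, 10L, 2L, M2, 0L, 11L, 2L, 0L, 12L,
                              0L, 13L))
  expect_equal(deserialize_tree(s, 25L), tree)
})

test_that("minimal trees serialize per the traversal rules", {
  leaf <- list(kind = "leaf", scale = 25L, mode = NULL,
               partition = 0L, index = 5L)
  s <- serialize_tree(leaf)
  expect_identical(s$type, c("flag", "index"))     # "0 i"
  expect_identical(s$value, c(0L, 5L))

  vs <- list(kind = "vsplit", scale = 25L, mode = NULL,
             children = list(
               list(kind = "leaf", scale = 23L, mode = NULL,
                    partition = 0L, index = 1L),
               list(kind = "leaf", scale = 23L, mode = NULL,
                    partition = 0L, index = 2L)))
  s2 <- serialize_tree(vs)
  expect_identical(s2$value, c(1L, 0L, 1L, 0L, 2L))  # "1 0 i0 0 i1"
  expect_identical(s2$type[1], "flag")
  expect_equal(deserialize_tree(s2, 25L), vs)
})

test_that("serialization round-trips on random valid trees", {
  set.seed(77)
  for (i in 1:150) {
    t1 <- rand_tree(25L, with_modes = TRUE)
    expect_equal(deserialize_tree(serialize_tree(t1), 25L), t1)
  }
  for (i in 1:50) {
    t2 <- rand_tree(25L, with_modes = FALSE)
    expect_equal(deserialize_tree(serialize_tree(t2), 25L), t2)
  }
  # smaller root scales round-trip too
  for (i in 1:30) {
    t3 <- rand_tree(16L)
    expect_equal(deserialize_tree(serialize_tree(t3), 16L), t3)
  }
})

test_that("invalid symbol streams are rejected with clear errors", {
  sym <- function(...) {
    rows <- list(...)
    data.frame(type = vapply(rows, `[[`, "", 1),
               value = vapply(rows, function(r) as.integer(r[[2]]), 0L),
               partition = NA_integer_)
  }
  # prediction split below scale 9 is illegal
  bad <- sym(list("flag", 3))
  expect_error(deserialize_tree(bad, 8L), "not allowed at scale")
  # truncated stream
  expect_error(deserialize_tree(sym(list("flag", 1)), 25L),
               "unexpected end")
  # trailing garbage after a complete tree
  over <- sym(list("flag", 0), list("index", 1), list("flag", 0))
  expect_error(deserialize_tree(over, 25L), "trailing")
  # splitting a unit dimension
  expect_error(deserialize_tree(sym(list("flag", 1), list("index", 1)), 17L),
               "unit dimension")
})

test_that("codec trees serialize to exactly the emitted symbol streams", {
  m <- rand_matrix(32, 32, seed = 31, amp = 200L)
  e <- mmp_encode_matrix(m, 12)
  for (b in seq_along(e$trees)) {
    expect_identical(serialize_tree(e$trees[[b]]),
                     as_symbol_frame(e$symbols[[b]]))
    expect_equal(deserialize_tree(as_symbol_frame(e$symbols[[b]]), 25L),
                 e$trees[[b]])
  }
})
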