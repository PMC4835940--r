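# Shared fixtures, built in code.

make_record <- function(samples, fs = 2000, bit_depth = 12L, offset = 0L) {
  semg_record(as.integer(samples), fs, bit_depth, offset)
}

rand_record <- function(n, seed, amp = 1000L, fs = 2000) {
  set.seed(seed)
  make_record(sample.int(2L * amp + 1L, n, replace = TRUE) - amp - 1L, fs)
}

rand_matrix <- function(K, L, seed, amp = 500L) {
  set.seed(seed)
  matrix(sample.int(2L * amp + 1L, K * L, replace = TRUE) - amp - 1L, K, L)
}

# random valid segmentation tree, for serialization round trips
rand_tree <- function(scale = 25L, predicted = FALSE, p_split = 0.45,
                      with_modes = TRUE) {
  d <- scale_dims(scale)
  M <- d[1]; N <- d[2]
  opts <- "leaf"
  if (N >= 2) opts <- c(opts, "vsplit")
  if (M >= 2) opts <- c(opts, "hsplit")
  if (!predicted && scale >= 9) {
    if (N >= 2) opts <- c(opts, "pred_vsplit")
    if (M >= 2) opts <- c(opts, "pred_hsplit")
  }
  w <- ifelse(opts == "leaf", 1 - p_split, p_split / (length(opts) - 1))
  kind <- sample(opts, 1, prob = if (length(opts) > 1) w else NULL)
  if (kind %in% c("pred_vsplit", "pred_hsplit")) {
    cs <- if (kind == "pred_vsplit") scale_index(M, N / 2)
          else scale_index(M / 2, N)
    return(list(kind = kind, scale = scale, mode = NULL,
                children = list(
                  rand_tree(cs, FALSE, p_split * 0.8, with_modes),
                  rand_tree(cs, FALSE, p_split * 0.8, with_modes))))
  }
  mode <- NULL
  if (!predicted && with_modes && scale >= 4)
    mode <- sample(c(allowed_modes(scale), 35L), 1)
  if (kind == "leaf")
    return(list(kind = "leaf", scale = scale, mode = mode,
                partition = sample(0:25, 1), index = sample(1:200, 1)))
  cs <- if (kind == "vsplit") scale_index(M, N / 2) else scale_index(M / 2, N)
  list(kind = kind, scale = scale, mode = mode,
       children = list(rand_tree(cs, TRUE, p_split * 0.8, with_modes),
                       rand_tree(cs, TRUE, p_split * 0.8, with_modes)))
}
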