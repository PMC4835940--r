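#' Percentage difference between two segments
#'
#' The similarity measure driving both PDS and SbS:
#' `PD(x, m) = sum((x - m)^2) / sum(x^2)`,
#' where `x` is the reference segment and `m` the segment under analysis.
#' Despite the name it is a dimensionless ratio; no factor of 100 is
#' applied (the ordering of segments is unaffected either way).
#'
#' @param x reference segment (nonzero energy).
#' @param m segment under analysis, same length as `x`.
#' @return nonnegative number.
#' @examples
#' percentage_difference(c(1, 1), c(3, 3)) # (4 + 4) / 2 = 4
#' @export
percentage_difference <- function(x, m) {
  if (length(x) != length(m)) stop("segments must have equal length")
  if (length(x) < 1) stop("segments must be nonempty")
  ex <- sum(as.numeric(x)^2)
  if (ex == 0) stop("zero-energy reference segment")
  sum((as.numeric(x) - as.numeric(m))^2) / ex
}

# internal: PD with the zero-energy fallback used by the greedy scans --
# when the reference has no energy the unnormalized squared difference
# (the numerator) is used, which keeps the ordering defined.
pd_safe <- function(x, m) {
  ex <- sum(as.numeric(x)^2)
  d <- sum((as.numeric(x) - as.numeric(m))^2)
  if (ex == 0) d else d / ex
}

#' Percentage difference sorting (PDS) of matrix columns
#'
#' Greedy column reordering that increases intersegment correlation before
#' two-dimensional coding: the first output column is the segment with the
#' smallest variance; each subsequent column is the not-yet-placed segment
#' with the smallest percentage difference relative to the last placed
#' one.  The resulting permutation must travel in the container header so
#' the decoder can restore the original order.
#'
#' @param matrix an `semg_matrix` (see [segment_to_matrix()]).
#' @return list with elements `matrix` (the reordered `semg_matrix`) and
#'   `ordering`, an integer permutation such that output column `j` came
#'   from original column `ordering[j]`.
#' @seealso [pds_restore()]
#' @export
pds_sort <- function(matrix) {
  stopifnot(inherits(matrix, "semg_matrix"))
  v <- matrix$values
  L <- ncol(v)
  vars <- apply(v, 2, function(col) mean((col - mean(col))^2))
  ordering <- integer(L)
  placed <- logical(L)
  cur <- which.min(vars)          # ties: lowest original index
  ordering[1] <- cur; placed[cur] <- TRUE
  if (L > 1) {
    for (j in 2:L) {
      ref <- v[, cur]
      cand <- which(!placed)
      pd <- vapply(cand, function(k) pd_safe(ref, v[, k]), numeric(1))
      cur <- cand[which.min(pd)]  # ties: lowest original index
      ordering[j] <- cur; placed[cur] <- TRUE
    }
  }
  out <- matrix
  out$values <- v[, ordering, drop = FALSE]
  list(matrix = out, ordering = ordering)
}

#' Restore the original column order after PDS
#'
#' @param matrix the reordered `semg_matrix`.
#' @param ordering the permutation returned by [pds_sort()].
#' @return the `semg_matrix` with columns back in signal order.
#' @export
pds_restore <- function(matrix, ordering) {
  stopifnot(inherits(matrix, "semg_matrix"))
  L <- ncol(matrix$values)
  ordering <- as.integer(ordering)
  if (length(ordering) != L || !setequal(ordering, seq_len(L)))
    stop("ordering is not a permutation of the column indices")
  out <- matrix
  out$values[, ordering] <- matrix$values
  out
}

#' Segmentation by similarity (SbS): adaptive segment length
#'
#' Searches the candidate segment lengths `N = 16 n`, `n = 2, ..., 64`,
#' for the one whose consecutive segments are most alike: for each `N` the
#' record is split into full segments of `N` samples (a trailing partial
#' segment is excluded from scoring) and the mean percentage difference
#' over adjacent segment pairs is computed; the `N` with the smallest mean
#' wins, ties going to the smallest `N`.  Because the segment length is
#' chosen adaptively, no reordering side information is needed — matrix
#' formation and preprocessing collapse into one step.
#'
#' @param record an [semg_record()] with at least 64 samples.
#' @return the chosen segment length (a multiple of 16 in `[32, 1024]`).
#' @export
sbs_select_length <- function(record) {
  stopifnot(inherits(record, "semg_record"))
  x <- record$samples
  if (length(x) < 64) stop("signal too short for SbS")
  cand <- 16L * (2:64)
  cand <- cand[length(x) %/% cand >= 2]
  if (length(cand) == 0) stop("signal too short for SbS")
  score <- vapply(cand, function(N) {
    k <- length(x) %/% N
    segs <- matrix(x[seq_len(k * N)], nrow = N)
    mean(vapply(seq_len(k - 1), function(i)
      pd_safe(segs[, i], segs[, i + 1]), numeric(1)))
  }, numeric(1))
  cand[which.min(score)]   # ties: smallest N
}
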