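#' Segment length for a square SEMG matrix
#'
#' Returns the number of rows `K = ceiling(sqrt(n))` such that filling the
#' matrix column by column yields `L` columns with `L` in `{K - 1, K}` —
#' as square as zero padding allows.
#'
#' @param n_samples number of samples in the record.
#' @return integer segment length.
#' @examples
#' square_segment_length(16) # 4
#' square_segment_length(17) # 5
#' @export
square_segment_length <- function(n_samples) {
  if (!is.numeric(n_samples) || n_samples < 1) stop("n_samples must be >= 1")
  as.integer(ceiling(sqrt(n_samples)))
}

#' Rearrange a 1-D SEMG record as a 2-D matrix
#'
#' Splits the record into consecutive segments of `segment_length` samples
#' and inserts each segment into one matrix column (column-major fill).
#' The trailing shortfall of the last column is padded with `pad_value`;
#' the original sample count is recorded so the inverse is exact.
#'
#' @param record an [semg_record()].
#' @param segment_length number of rows `K`; defaults to the square layout
#'   of [square_segment_length()].
#' @param pad_value value used to fill the incomplete last column
#'   (default 0, the mean of zero-centered signals).
#' @return An object of class `semg_matrix` with elements `values`
#'   (`K x L` integer matrix), `segment_length`, `n_segments`,
#'   `original_sample_count` and `pad_value`.
#' @seealso [matrix_to_record()] for the exact inverse.
#' @export
segment_to_matrix <- function(record,
                              segment_length = square_segment_length(
                                length(record$samples)),
                              pad_value = 0L) {
  stopifnot(inherits(record, "semg_record"))
  x <- record$samples
  if (length(x) < 1) stop("empty signal")
  K <- as.integer(segment_length)
  if (K < 1) stop("segment_length must be >= 1")
  L <- as.integer(ceiling(length(x) / K))
  v <- rep(as.integer(pad_value), K * L)
  v[seq_along(x)] <- x
  structure(
    list(values = matrix(v, nrow = K, ncol = L),
         segment_length = K, n_segments = L,
         original_sample_count = length(x),
         pad_value = as.integer(pad_value)),
    class = "semg_matrix")
}

#' @export
print.semg_matrix <- function(x, ...) {
  cat(sprintf("<semg_matrix: %d x %d, %d original samples, pad %d>\n",
              x$segment_length, x$n_segments, x$original_sample_count,
              x$pad_value))
  invisible(x)
}

#' Invert the matrix formation
#'
#' Concatenates the matrix columns and truncates to the original sample
#' count, restoring the one-dimensional record exactly (provided any
#' column permutation has been undone first, see [pds_restore()]).
#'
#' @param matrix an `semg_matrix`.
#' @param meta an [semg_record()] or a list supplying `sampling_rate_hz`,
#'   `bit_depth` and `offset` for the rebuilt record.
#' @return an [semg_record()].
#' @export
matrix_to_record <- function(matrix, meta) {
  stopifnot(inherits(matrix, "semg_matrix"))
  n <- matrix$original_sample_count
  if (n > matrix$segment_length * matrix$n_segments)
    stop("original_sample_count exceeds matrix capacity")
  x <- as.vector(matrix$values)[seq_len(n)]
  semg_record(x, meta$sampling_rate_hz, meta$bit_depth %||% 12L,
              meta$offset %||% 0L)
}

#' Export an SEMG matrix as a 16-bit PGM image
#'
#' Writes the (optionally preprocessed) matrix as a binary `P5` portable
#' graymap with `maxval` 65535, re-applying the amplitude offset so the
#' pixel values are nonnegative.  This is an interoperability hook for
#' benchmarking external image codecs on the same matrices; invoking those
#' codecs is out of scope.
#'
#' @param matrix an `semg_matrix` (or plain integer matrix).
#' @param path output file.
#' @param offset value added to every sample before writing (2048 recovers
#'   the unsigned 12-bit acquisition range of zero-centered data).
#' @return `path`, invisibly.
#' @export
export_pgm <- function(matrix, path, offset = 2048L) {
  v <- if (inherits(matrix, "semg_matrix")) matrix$values else matrix
  stopifnot(is.matrix(v))
  px <- v + as.integer(offset)
  if (any(px < 0) || any(px > 65535))
    stop("pixel values outside [0, 65535] after applying the offset")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n65535\n", ncol(v), nrow(v)), con,
            eos = NULL)
  # P5 stores the image row by row; samples are 16-bit big-endian.
  # writeBin() has no unsigned 16-bit type, so map [32768, 65535] onto
  # the negative two's-complement range.
  seq16 <- as.vector(t(px))
  seq16[seq16 > 32767] <- seq16[seq16 > 32767] - 65536L
  writeBin(as.integer(seq16), con, size = 2, endian = "big")
  invisible(path)
}
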