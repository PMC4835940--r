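#' SEMG record objects
#'
#' An `semg_record` holds a one-dimensional SEMG signal as zero-centered
#' integer samples together with its acquisition metadata.  Acquisition
#' systems typically deliver unsigned 12-bit samples in `[0, 4095]`; the
#' `offset` (2048 for such data) is subtracted at load so that the stored
#' samples are signed and zero-centered, which is what the prediction
#' residues and the symmetric dictionary range `[-X, X]` of the codec
#' assume.  The offset travels in the compressed-container header and is
#' re-applied on export.
#'
#' @param samples integer vector of zero-centered sample values.
#' @param sampling_rate_hz positive sampling rate in Hz (2000 for the
#'   isometric protocol, 2048 for the dynamic one).
#' @param bit_depth acquisition resolution in bits (default 12).
#' @param offset integer that was subtracted from the raw samples at load.
#' @return An object of class `semg_record`.
#' @examples
#' r <- semg_record(c(-3L, 5L, 2L, -1L), 2000)
#' length(r$samples)
#' @export
semg_record <- function(samples, sampling_rate_hz, bit_depth = 12L,
                        offset = 0L) {
  if (length(samples) < 1) stop("empty signal")
  if (!is.numeric(samples) || any(!is.finite(samples)))
    stop("samples must be finite numbers")
  samples <- as.integer(round(samples))
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0)
    stop("sampling_rate_hz must be positive")
  bit_depth <- as.integer(bit_depth)
  if (bit_depth < 1) stop("bit_depth must be a positive integer")
  raw <- samples + as.integer(offset)
  if (any(raw < -(2^(bit_depth - 1))) || any(raw > 2^bit_depth - 1))
    stop("samples not representable at the stated bit depth")
  structure(
    list(samples = samples, sampling_rate_hz = as.numeric(sampling_rate_hz),
         bit_depth = bit_depth, offset = as.integer(offset)),
    class = "semg_record")
}

#' @export
print.semg_record <- function(x, ...) {
  cat(sprintf(
    "<semg_record: %d samples, %g Hz, %d bit, offset %d, range [%d, %d]>\n",
    length(x$samples), x$sampling_rate_hz, x$bit_depth, x$offset,
    min(x$samples), max(x$samples)))
  invisible(x)
}

#' Read / write raw SEMG signal files
#'
#' Two plain dialects are supported: `"raw"`, little-endian signed 16-bit
#' integers, and `"txt"`, one integer sample per line.  `"auto"` picks the
#' dialect from the file extension (`.txt` means text, anything else raw).
#' Sampling rate and bit depth are always supplied by the caller; they are
#' not guessed from the file.
#'
#' @param path file to read or write.
#' @param sampling_rate_hz,bit_depth,offset metadata for the record; the
#'   `offset` is subtracted from the stored values at load (and re-added
#'   when writing).
#' @param format `"auto"`, `"raw"` or `"txt"`.
#' @return `read_semg_record()` returns an [semg_record()];
#'   `write_semg_record()` returns `path` invisibly.
#' @export
read_semg_record <- function(path, sampling_rate_hz, bit_depth = 12L,
                             offset = 0L, format = c("auto", "raw", "txt")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.txt$", path, ignore.case = TRUE)) "txt" else "raw"
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "txt") {
    v <- scan(path, what = integer(), quiet = TRUE)
  } else {
    n <- file.size(path) / 2
    v <- readBin(path, "integer", n = n, size = 2, signed = TRUE,
                 endian = "little")
  }
  if (length(v) < 1) stop("empty signal")
  semg_record(v - offset, sampling_rate_hz, bit_depth, offset)
}

#' @rdname read_semg_record
#' @param record an [semg_record()].
#' @export
write_semg_record <- function(record, path, format = c("auto", "raw", "txt")) {
  stopifnot(inherits(record, "semg_record"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.txt$", path, ignore.case = TRUE)) "txt" else "raw"
  v <- record$samples + record$offset
  if (format == "txt") {
    writeLines(as.character(v), path)
  } else {
    writeBin(as.integer(v), path, size = 2, endian = "little")
  }
  invisible(path)
}
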