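#' Codec configuration
#'
#' @param cap per-scale dictionary entry limit.
#' @param additive_symmetric also insert the negated pattern on every
#'   dictionary update (off by default).
#' @param search encoder-side mode search: `"fast"` ranks the allowed
#'   prediction modes by the sum of absolute differences of their
#'   prediction against the block and fully evaluates only the
#'   `n_full_modes` best (plus coding without prediction); `"thorough"`
#'   evaluates every allowed mode at every eligible node.  The choice only
#'   affects how hard the encoder searches — the bitstream format and the
#'   decoder are identical.
#' @param n_full_modes number of preselected modes fully evaluated per
#'   node under `"fast"` search.
#' @param norm_equalization configuration stub; must be `FALSE`.
#' @return list of options for [mmp_encode_matrix()] and friends.
#' @export
mmp_options <- function(cap = 50000L, additive_symmetric = FALSE,
                        search = c("fast", "thorough"), n_full_modes = 2L,
                        norm_equalization = FALSE) {
  search <- match.arg(search)
  if (isTRUE(norm_equalization))
    stop("norm equalization is a configuration stub and not implemented")
  list(cap = as.integer(cap),
       additive_symmetric = isTRUE(additive_symmetric),
       thorough = identical(search, "thorough"),
       n_full_modes = as.integer(n_full_modes))
}

pad16 <- function(n) as.integer(16L * ceiling(n / 16L))

#' Encode / decode an SEMG matrix with the modified 2-D MMP codec
#'
#' `mmp_encode_matrix()` pads the matrix with zeros to multiples of 16 in
#' both dimensions, processes the 16x16 blocks in raster order — for each
#' block it optimizes the segmentation/prediction tree under
#' `J = D + lambda * R`, emits the symbol string through the adaptive
#' arithmetic coder, reconstructs, and updates the multiscale dictionary —
#' and returns the coded payload together with the encoder-side
#' reconstruction and the per-block codec state.  `mmp_decode_matrix()`
#' reproduces the identical reconstruction and dictionary trajectory from
#' the payload alone (plus the header quantities `dims`, `x_max`,
#' `lambda`).
#'
#' At `lambda = 0` the reconstruction is exact for any input: rate is
#' free, and the scale-1 dictionary holds every representable value.
#'
#' @param values integer matrix (zero-centered samples).
#' @param lambda nonnegative Lagrangian multiplier; larger values trade
#'   distortion for rate.
#' @param options see [mmp_options()].
#' @return `mmp_encode_matrix()`: an object of class `mmp_encoded` with
#'   `payload` (raw vector), `bits`, `recon` (unpadded), `x_max`,
#'   `dims`, `trees`, `symbols`, `dict_sizes` and `state_hash` (one per
#'   block).  `mmp_decode_matrix()`: the same minus the payload.
#' @export
mmp_encode_matrix <- function(values, lambda, options = mmp_options()) {
  stopifnot(is.matrix(values))
  storage.mode(values) <- "integer"
  if (lambda < 0) stop("lambda must be nonnegative")
  K <- nrow(values); L <- ncol(values)
  H <- pad16(K); W <- pad16(L)
  padded <- matrix(0L, H, W)
  padded[seq_len(K), seq_len(L)] <- values
  out <- cpp_mmp_encode(padded, as.numeric(lambda), options)
  structure(
    list(payload = out$payload, bits = out$bits,
         recon = out$recon[seq_len(K), seq_len(L), drop = FALSE],
         x_max = out$x_max, dims = c(K, L), lambda = as.numeric(lambda),
         trees = out$trees, symbols = out$symbols,
         dict_sizes = out$dict_sizes, state_hash = out$state_hash),
    class = "mmp_encoded")
}

#' @rdname mmp_encode_matrix
#' @param payload raw vector produced by the encoder.
#' @param dims `c(K, L)` true (unpadded) matrix dimensions.
#' @param x_max amplitude bound from the container header.
#' @export
mmp_decode_matrix <- function(payload, dims, x_max, lambda,
                              options = mmp_options()) {
  K <- as.integer(dims[1]); L <- as.integer(dims[2])
  out <- cpp_mmp_decode(payload, pad16(K), pad16(L), as.integer(x_max),
                        as.numeric(lambda), options)
  structure(
    list(recon = out$recon[seq_len(K), seq_len(L), drop = FALSE],
         x_max = as.integer(x_max), dims = c(K, L),
         lambda = as.numeric(lambda),
         trees = out$trees, symbols = out$symbols,
         dict_sizes = out$dict_sizes, state_hash = out$state_hash),
    class = "mmp_decoded")
}

#' Compress an SEMG record to an .mmp2d container
#'
#' Runs the full three-stage architecture: matrix formation (one segment
#' per column), preprocessing (none, PDS column sorting, or SbS adaptive
#' segment length — with SbS the first two stages collapse into one), and
#' the modified 2-D MMP image coder.  All side information the decoder
#' needs (sample count, amplitude offset and bound, segment length,
#' preprocessing id, the arithmetically coded PDS permutation, lambda)
#' goes into the container header.
#'
#' @param record an [semg_record()].
#' @param file output path (conventionally `.mmp2d`).
#' @param lambda rate-distortion multiplier; 0 is lossless.
#' @param preprocess `"none"`, `"pds"` or `"sbs"`.
#' @param segment_length matrix rows `K`; `NULL` means the square layout
#'   (ignored under `"sbs"`, which chooses its own).
#' @param options see [mmp_options()].
#' @return Invisibly, a list with the coded size in `bits`, `cf_percent`,
#'   `prd_percent` (from the encoder-side reconstruction), `x_max`,
#'   `segment_length` and `preprocess`.
#' @seealso [semg_decompress()], [rd_sweep()]
#' @export
semg_compress <- function(record, file, lambda = 10,
                          preprocess = c("none", "pds", "sbs"),
                          segment_length = NULL,
                          options = mmp_options()) {
  stopifnot(inherits(record, "semg_record"))
  preprocess <- match.arg(preprocess)
  n <- length(record$samples)
  K <- if (preprocess == "sbs") sbs_select_length(record)
       else as.integer(segment_length %||% square_segment_length(n))
  mat <- segment_to_matrix(record, K)
  perm <- NULL
  if (preprocess == "pds") {
    ps <- pds_sort(mat)
    mat <- ps$matrix
    perm <- ps$ordering
  }
  enc <- mmp_encode_matrix(mat$values, lambda, options)
  header <- list(
    n_samples = n, offset = record$offset, bit_depth = record$bit_depth,
    sampling_rate_hz = record$sampling_rate_hz,
    x_max = enc$x_max, segment_length = K, n_segments = mat$n_segments,
    preprocess = preprocess, lambda = as.numeric(lambda),
    cap = options$cap, additive_symmetric = options$additive_symmetric,
    permutation = perm)
  write_container(file, header, enc$payload)
  bits <- file.size(file) * 8
  # encoder-side distortion: restore the pipeline on the local recon
  rmat <- mat; rmat$values <- enc$recon
  if (preprocess == "pds") rmat <- pds_restore(rmat, perm)
  rrec <- matrix_to_record(rmat, record)
  invisible(list(
    file = file, bits = bits,
    cf_percent = cf(12 * n, bits),
    prd_percent = prd(record$samples, rrec$samples),
    x_max = enc$x_max, segment_length = K, n_segments = mat$n_segments,
    preprocess = preprocess, lambda = as.numeric(lambda),
    dict_sizes = enc$dict_sizes))
}

#' Decompress an .mmp2d container
#'
#' The stages of [semg_compress()] performed in reverse order, configured
#' entirely from the container header.
#'
#' @param file path to a `.mmp2d` file.
#' @return the reconstructed [semg_record()].
#' @export
semg_decompress <- function(file) {
  ct <- read_container(file)
  h <- ct$header
  opts <- mmp_options(cap = h$cap, additive_symmetric = h$additive_symmetric)
  dec <- mmp_decode_matrix(ct$payload,
                           c(h$segment_length, h$n_segments),
                           h$x_max, h$lambda, opts)
  mat <- structure(
    list(values = dec$recon, segment_length = h$segment_length,
         n_segments = h$n_segments, original_sample_count = h$n_samples,
         pad_value = 0L),
    class = "semg_matrix")
  if (h$preprocess == "pds") mat <- pds_restore(mat, h$permutation)
  matrix_to_record(mat, list(sampling_rate_hz = h$sampling_rate_hz,
                             bit_depth = h$bit_depth, offset = h$offset))
}

#' Evaluate a compressed file against its original record
#'
#' @param record the original [semg_record()].
#' @param file a `.mmp2d` container produced from it.
#' @return list with `prd_percent`, `cf_percent` and `bits`.
#' @export
semg_evaluate <- function(record, file) {
  stopifnot(inherits(record, "semg_record"))
  dec <- semg_decompress(file)
  if (length(dec$samples) != length(record$samples))
    stop("sample counts differ; not the matching original?")
  bits <- file.size(file) * 8
  list(prd_percent = prd(record$samples, dec$samples),
       cf_percent = cf(12 * length(record$samples), bits),
       bits = bits)
}
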