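#' Serialize a segmentation tree to its symbol string
#'
#' Converts an optimal tree to the flag/mode/index symbol string, top-down
#' and depth-first: at a vertical or horizontal segmentation the left or
#' upper subtree is emitted first.  Five flags identify the node kinds —
#' 0 a leaf (followed by a dictionary index), 1/2 a vertical/horizontal
#' residue segmentation, 3/4 a vertical/horizontal segmentation of the
#' hierarchical prediction layer.  Where a node starts a predicted region
#' its prediction-mode symbol follows the node's flag.
#'
#' Trees are nested lists as returned in `$trees` by
#' [mmp_encode_matrix()]: every node has `kind` (`"leaf"`, `"vsplit"`,
#' `"hsplit"`, `"pred_vsplit"`, `"pred_hsplit"`) and `scale`; region roots
#' carry `mode` (0–34, or 35 for "no prediction"); leaves carry
#' `partition` (origin scale of the entry) and `index` (1-based position
#' within the partition); split nodes carry two `children`.
#'
#' @param tree a segmentation-tree node.
#' @return a data frame with columns `type` (`"flag"`, `"mode"`,
#'   `"index"`), `value`, and `partition` (`NA` except for index rows).
#' @seealso [deserialize_tree()]
#' @export
serialize_tree <- function(tree) {
  rows <- list()
  emit <- function(type, value, partition = NA_integer_) {
    rows[[length(rows) + 1L]] <<- list(type = type,
                                       value = as.integer(value),
                                       partition = as.integer(partition))
  }
  walk <- function(node, predicted) {
    if (is.null(node$kind)) stop("malformed tree node: missing kind")
    kind <- node$kind
    if (kind %in% c("pred_vsplit", "pred_hsplit")) {
      if (predicted)
        stop("prediction split inside a predicted region")
      if (node$scale < 9)
        stop("prediction split not allowed at scale ", node$scale)
      emit("flag", if (kind == "pred_vsplit") 3L else 4L)
      walk(node$children[[1]], FALSE)
      walk(node$children[[2]], FALSE)
      return(invisible())
    }
    flag <- switch(kind, leaf = 0L, vsplit = 1L, hsplit = 2L,
                   stop("malformed tree node: kind ", kind))
    emit("flag", flag)
    if (!predicted) {
      # a region root may carry a prediction mode (the codec always emits
      # one, using 35 for "no prediction"); a bare plain-MMP tree may not
      if (!is.null(node$mode)) emit("mode", node$mode)
    } else if (!is.null(node$mode)) {
      stop("mode attached to an interior residue node")
    }
    if (kind == "leaf") {
      emit("index", node$index, node$partition)
    } else {
      walk(node$children[[1]], TRUE)
      walk(node$children[[2]], TRUE)
    }
  }
  walk(tree, FALSE)
  data.frame(type = vapply(rows, `[[`, "", "type"),
             value = vapply(rows, `[[`, 0L, "value"),
             partition = vapply(rows, `[[`, 0L, "partition"),
             stringsAsFactors = FALSE)
}

#' Parse a symbol string back into a segmentation tree
#'
#' Exact inverse of [serialize_tree()]: `deserialize_tree(serialize_tree(t),
#' root_scale)` reproduces `t`.  The parser tracks the scale of every node
#' from the split geometry (a vertical segmentation halves the width, a
#' horizontal one the height) and rejects streams violating the grammar —
#' a truncated stream, a prediction split below scale 9, or a split along
#' a unit dimension.
#'
#' @param symbols a data frame as produced by [serialize_tree()].
#' @param root_scale scale of the tree's root block (25 for a full 16x16
#'   input block).
#' @return the segmentation tree.
#' @export
deserialize_tree <- function(symbols, root_scale = 25L) {
  pos <- 0L
  nxt <- function(type) {
    pos <<- pos + 1L
    if (pos > nrow(symbols)) stop("unexpected end of symbols")
    if (symbols$type[pos] != type)
      stop("expected a ", type, " symbol at position ", pos)
    symbols[pos, ]
  }
  parse <- function(scale, predicted) {
    d <- scale_dims(scale); M <- d[1]; N <- d[2]
    f <- nxt("flag")$value
    if (f %in% c(3L, 4L)) {
      if (predicted) stop("prediction split inside a predicted region")
      if (scale < 9) stop("prediction split not allowed at scale ", scale)
      if (f == 3L && N < 2) stop("vertical split along a unit dimension")
      if (f == 4L && M < 2) stop("horizontal split along a unit dimension")
      cs <- if (f == 3L) scale_index(M, N / 2) else scale_index(M / 2, N)
      return(list(kind = if (f == 3L) "pred_vsplit" else "pred_hsplit",
                  scale = scale, mode = NULL,
                  children = list(parse(cs, FALSE), parse(cs, FALSE))))
    }
    mode <- NULL
    if (!predicted && pos < nrow(symbols) && symbols$type[pos + 1L] == "mode")
      mode <- nxt("mode")$value
    if (f == 0L) {
      ix <- nxt("index")
      return(list(kind = "leaf", scale = scale, mode = mode,
                  partition = ix$partition, index = ix$value))
    }
    if (f == 1L && N < 2) stop("vertical split along a unit dimension")
    if (f == 2L && M < 2) stop("horizontal split along a unit dimension")
    cs <- if (f == 1L) scale_index(M, N / 2) else scale_index(M / 2, N)
    list(kind = if (f == 1L) "vsplit" else "hsplit", scale = scale,
         mode = mode,
         children = list(parse(cs, TRUE), parse(cs, TRUE)))
  }
  out <- parse(as.integer(root_scale), FALSE)
  if (pos != nrow(symbols)) stop("trailing symbols after a complete tree")
  out
}

#' Convert a codec symbol matrix to a symbol data frame
#'
#' [mmp_encode_matrix()] and [mmp_decode_matrix()] report each block's
#' symbol string as an integer matrix; this helper converts it to the
#' data-frame form used by [serialize_tree()].
#'
#' @param m integer matrix with columns `type` (0 flag, 1 mode, 2 index),
#'   `value` and `partition`.
#' @return symbol data frame.
#' @export
as_symbol_frame <- function(m) {
  data.frame(type = c("flag", "mode", "index")[m[, "type"] + 1L],
             value = as.integer(m[, "value"]),
             partition = ifelse(m[, "type"] == 2L,
                                as.integer(m[, "partition"]), NA_integer_),
             stringsAsFactors = FALSE)
}

#' Adaptive arithmetic coding of a symbol sequence
#'
#' A 32-bit integer arithmetic coder with a single adaptive frequency
#' table: all symbols start with count 1, counts increment by 1 per
#' occurrence, and the table is rescaled when the total reaches 2^14.
#' The layer is exactly lossless: `arith_decode(arith_encode(s, k),
#' length(s), k)` reproduces `s` for every sequence.  The same coder (with
#' many context-specific tables) carries the codec's flag, mode and index
#' symbols, and codes the PDS permutation in the container header.
#'
#' @param symbols integer vector of symbols in `0:(alphabet_size - 1)`.
#' @param alphabet_size number of distinct symbols.
#' @return `arith_encode()`: a raw vector. `arith_decode()`: the integer
#'   symbol vector.
#' @export
arith_encode <- function(symbols, alphabet_size) {
  cpp_arith_encode(as.integer(symbols), as.integer(alphabet_size))
}

#' @rdname arith_encode
#' @param bytes raw vector produced by `arith_encode()`.
#' @param n number of symbols to decode.
#' @export
arith_decode <- function(bytes, n, alphabet_size) {
  cpp_arith_decode(bytes, as.integer(n), as.integer(alphabet_size))
}

CONTAINER_MAGIC <- charToRaw("MMP2DSEMG")
PREPROC_IDS <- c(none = 0L, pds = 1L, sbs = 2L)

#' Read and write the .mmp2d container format
#'
#' Byte layout: the magic `"MMP2DSEMG"`, a version byte, the preprocessing
#' id, an option byte, seven little-endian int32 header fields (sample
#' count, amplitude offset, bit depth, X_max, segment length, segment
#' count, dictionary cap), two doubles (lambda, sampling rate), the
#' arithmetically coded PDS permutation (byte-aligned, length-prefixed;
#' empty unless PDS was used), and the length-prefixed arithmetic-coded
#' payload.  The header alone configures the decoder.
#'
#' @param file path.
#' @param header named list as assembled by [semg_compress()].
#' @param payload raw vector from the encoder.
#' @return `write_container()` returns `file` invisibly; `read_container()`
#'   returns `list(header = ..., payload = ...)`.
#' @export
write_container <- function(file, header, payload) {
  tmp <- paste0(file, ".tmp")
  con <- file(tmp, "wb")
  ok <- FALSE
  on.exit({
    close(con)
    if (!ok) unlink(tmp)
  })
  writeBin(CONTAINER_MAGIC, con)
  writeBin(as.raw(1L), con)
  writeBin(as.raw(PREPROC_IDS[[header$preprocess]]), con)
  writeBin(as.raw(as.integer(isTRUE(header$additive_symmetric))), con)
  writeBin(as.integer(c(header$n_samples, header$offset, header$bit_depth,
                        header$x_max, header$segment_length,
                        header$n_segments, header$cap)),
           con, size = 4, endian = "little")
  writeBin(as.numeric(c(header$lambda, header$sampling_rate_hz)),
           con, size = 8, endian = "little")
  pb <- raw(0)
  if (!is.null(header$permutation))
    pb <- arith_encode(header$permutation - 1L, header$n_segments)
  writeBin(length(pb), con, size = 4, endian = "little")
  if (length(pb)) writeBin(pb, con)
  writeBin(length(payload), con, size = 4, endian = "little")
  writeBin(payload, con)
  close(con)
  on.exit()
  file.rename(tmp, file)
  invisible(file)
}

#' @rdname write_container
#' @export
read_container <- function(file) {
  if (!file.exists(file)) stop("no such file: ", file)
  con <- file(file, "rb")
  on.exit(close(con))
  need <- function(x, n, what) {
    if (length(x) != n) stop("truncated container (", what, ")")
    x
  }
  magic <- need(readBin(con, "raw", length(CONTAINER_MAGIC)),
                length(CONTAINER_MAGIC), "magic")
  if (!identical(magic, CONTAINER_MAGIC)) stop("not an .mmp2d container")
  version <- as.integer(need(readBin(con, "raw", 1), 1, "version"))
  if (version != 1L) stop("unsupported container version ", version)
  pre <- as.integer(need(readBin(con, "raw", 1), 1, "preprocess id"))
  if (!pre %in% PREPROC_IDS) stop("unknown preprocessing id ", pre)
  addsym <- as.integer(need(readBin(con, "raw", 1), 1, "options")) == 1L
  ints <- need(readBin(con, "integer", 7, size = 4, endian = "little"),
               7, "header")
  dbls <- need(readBin(con, "numeric", 2, size = 8, endian = "little"),
               2, "header")
  npb <- need(readBin(con, "integer", 1, size = 4, endian = "little"),
              1, "permutation length")
  perm <- NULL
  if (npb > 0) {
    pb <- need(readBin(con, "raw", npb), npb, "permutation")
    perm <- arith_decode(pb, ints[6], ints[6]) + 1L
  }
  npay <- need(readBin(con, "integer", 1, size = 4, endian = "little"),
               1, "payload length")
  payload <- need(readBin(con, "raw", npay), npay, "payload")
  list(header = list(
         n_samples = ints[1], offset = ints[2], bit_depth = ints[3],
         x_max = ints[4], segment_length = ints[5], n_segments = ints[6],
         cap = ints[7], lambda = dbls[1], sampling_rate_hz = dbls[2],
         preprocess = names(PREPROC_IDS)[match(pre, PREPROC_IDS)],
         additive_symmetric = addsym, permutation = perm),
       payload = payload)
}
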