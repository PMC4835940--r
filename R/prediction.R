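#' Prediction modes available at a dictionary scale
#'
#' Mode ids follow the HEVC numbering: 0 = planar, 1 = most frequent value
#' (MFV, which replaces the DC mode in the MMP lineage), 2..34 = the 33
#' angular modes.  No prediction mode is used at scales 3 and below, where
#' the blocks are too small for directions to differ; the planar mode is
#' restricted to the square scales 4, 9, 16 and 25, since elsewhere its
#' output is close to MFV.
#'
#' @param scale dictionary scale, an integer in `[1, 25]`.
#' @return integer vector of mode ids (possibly empty).
#' @examples
#' length(allowed_modes(25)) # 35
#' allowed_modes(2)          # integer(0)
#' @export
allowed_modes <- function(scale) {
  scale <- as.integer(scale)
  if (length(scale) != 1 || is.na(scale) || scale < 1 || scale > 25)
    stop("scale must be an integer in [1, 25]")
  if (scale <= 3) return(integer(0))
  planar <- if (scale %in% c(4L, 9L, 16L, 25L)) 0L else integer(0)
  c(planar, 1L, 2:34)
}

#' Build the intra-prediction reference vectors
#'
#' Assembles the two reference vectors used by every prediction mode at
#' every scale from previously reconstructed samples around the block:
#' the *vertical* vector (top-left corner, then the left and lower-left
#' boundary moving down) serves angular modes 2–17, and the *horizontal*
#' vector (corner, then the above and upper-right boundary moving right)
#' serves modes 18–34.  Each vector holds `2 * max(M, N) + 1` samples.
#' Unavailable positions are substituted HEVC-style: the first available
#' sample (scanning from the lower-left end upward and then rightward) is
#' propagated backward, and every later gap copies its predecessor; if
#' nothing has been coded yet all references default to 0.
#'
#' @param reconstruction numeric matrix of the partially reconstructed
#'   image; positions not yet coded must be `NA`.
#' @param origin `c(row, col)` of the block's top-left sample (1-based).
#' @param dims `c(M, N)` block dimensions.
#' @return list with integer vectors `vertical` and `horizontal`.
#' @export
build_reference_vectors <- function(reconstruction, origin, dims) {
  stopifnot(is.matrix(reconstruction), length(origin) == 2, length(dims) == 2)
  mask <- !is.na(reconstruction)
  rec <- reconstruction
  rec[!mask] <- 0L
  storage.mode(rec) <- "integer"
  cpp_build_refs(rec, mask, as.integer(origin[1]), as.integer(origin[2]),
                 as.integer(dims[1]), as.integer(dims[2]))
}

#' Predict a block from its reference vectors
#'
#' Angular modes project the reference samples along the mode's HEVC
#' displacement with 1/32-sample linear interpolation; the planar mode
#' averages a horizontal and a vertical linear interpolation; MFV
#' replicates the modal value of the concatenated reference vectors (ties
#' broken towards the smallest value).  Interpolated values are rounded
#' half-away-from-zero.  The function is pure — the output depends only on
#' the references, the mode and the dimensions — which is what makes the
#' decoder reproducible.
#'
#' @param refs list with `vertical` and `horizontal` reference vectors
#'   (see [build_reference_vectors()]).
#' @param mode prediction mode id; must belong to
#'   `allowed_modes(scale_index(M, N))`.
#' @param dims `c(M, N)`.
#' @return `M x N` integer matrix.
#' @export
predict_block <- function(refs, mode, dims) {
  M <- as.integer(dims[1]); N <- as.integer(dims[2])
  s <- scale_index(M, N)
  if (!(mode %in% allowed_modes(s)))
    stop("prediction mode ", mode, " is not allowed at scale ", s)
  cpp_predict_block(as.integer(refs$vertical), as.integer(refs$horizontal),
                    as.integer(mode), M, N)
}

#' Prediction residue
#'
#' Elementwise difference `X - P` between a block and its prediction.  The
#' residue may be negative; the symmetric dictionary range covers it.  On
#' both codec sides the reconstruction contract is exact:
#' `P + coded residue approximation == reconstructed block`.
#'
#' @param block,prediction integer matrices with identical dimensions.
#' @return integer matrix of the same shape.
#' @export
residual <- function(block, prediction) {
  if (!identical(dim(block), dim(prediction)))
    stop("block and prediction dimensions differ")
  block - prediction
}
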