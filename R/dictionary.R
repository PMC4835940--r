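#' Scale index of a block dimension pair
#'
#' Maps block dimensions `M x N` (powers of two up to 16) onto the scale
#' index `1..25` used to address the subdictionaries.  The map is a
#' bijection between the 25 valid dimension pairs and `{1, ..., 25}`:
#' `scale(1, 1) = 1` is the lowest level and `scale(16, 16) = 25` the
#' highest (the input block size of the codec).
#'
#' @param M,N block height and width, each in `{1, 2, 4, 8, 16}`.
#' @return integer scale in `[1, 25]`.
#' @examples
#' scale_index(16, 16) # 25
#' scale_index(16, 8)  # 23
#' @export
scale_index <- function(M, N) cpp_scale_index(as.integer(M), as.integer(N))

#' @rdname scale_index
#' @param scale a scale index in `[1, 25]`.
#' @return `scale_dims()` returns the `c(M, N)` pair of a scale.
#' @export
scale_dims <- function(scale) {
  scale <- as.integer(scale)
  if (length(scale) != 1 || is.na(scale) || scale < 1 || scale > 25)
    stop("scale must be an integer in [1, 25]")
  for (M in c(1L, 2L, 4L, 8L, 16L))
    for (N in c(1L, 2L, 4L, 8L, 16L))
      if (cpp_scale_index(M, N) == scale) return(c(M, N))
}

#' Redundancy-control threshold d(lambda)
#'
#' Minimum distance (mean squared difference per sample) a candidate
#' pattern must keep from every same-scale dictionary entry to be
#' inserted.  The map is piecewise constant in the Lagrangian multiplier:
#' large lambda (low rates) admits only well-separated patterns, small
#' lambda admits finer variations for accurate matching.
#'
#' @param lambda nonnegative Lagrangian multiplier.
#' @return the threshold: 20, 40, 60 or 80.
#' @examples
#' redundancy_threshold(30) # 60
#' @export
redundancy_threshold <- function(lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0)
    stop("lambda must be a nonnegative number")
  if (lambda <= 4) 20 else if (lambda <= 22) 40 else if (lambda <= 50) 60 else 80
}

#' Level step of the initial dictionary
#'
#' Distance between consecutive homogeneous levels of the initial
#' dictionary as a function of the current level's magnitude: the step is
#' 1 while `|value| <= 10`, 4 up to 22, 8 up to 86 and 13 beyond, so the
#' level grid is densest where residue samples concentrate.
#'
#' @param value level value(s).
#' @return integer step(s) in `{1, 4, 8, 13}`.
#' @examples
#' dict_level_step(-5) # 1
#' dict_level_step(50) # 8
#' @export
dict_level_step <- function(value) {
  c(1L, 4L, 8L, 13L)[findInterval(abs(value), c(0, 11, 23, 87))]
}

#' Initial multiscale dictionary
#'
#' Builds the 25 subdictionaries before any adaptation.  Scale 1 holds
#' every integer in `[-X_max, X_max]`.  Every other scale holds
#' homogeneous blocks whose levels start at `-X_max` and advance by a
#' magnitude-banded step `p`: 1 while `|value| <= 10`, 4 up to 22, 8 up to
#' 86 and 13 beyond — the range near zero is the densest because residue
#' samples cluster there.  All initial entries live in origin partition 0.
#'
#' @param X_max positive amplitude bound (the largest absolute image
#'   value; it travels in the container header).
#' @param lambda Lagrangian multiplier, used only to fix the redundancy
#'   threshold `d` carried by the dictionary (see
#'   [redundancy_threshold()]).
#' @param cap maximum number of entries per scale.
#' @param additive_symmetric if `TRUE`, [update_dictionary()] also inserts
#'   the negated pattern.
#' @return an object of class `mmp_dictionary`.
#' @export
init_dictionary <- function(X_max, lambda = 0, cap = 50000L,
                            additive_symmetric = FALSE) {
  X_max <- as.integer(X_max)
  if (X_max < 1) stop("X_max must be >= 1")
  levels <- cpp_dict_levels(X_max)
  scales <- vector("list", 25)
  for (s in 1:25) {
    d <- scale_dims(s)
    pats <- if (s == 1) {
      lapply(seq.int(-X_max, X_max), function(v) matrix(v, 1, 1))
    } else {
      lapply(levels, function(v) matrix(as.integer(v), d[1], d[2]))
    }
    scales[[s]] <- list(patterns = pats,
                        origin = rep(0L, length(pats)))
  }
  structure(
    list(x_max = X_max, levels = as.integer(levels),
         d = redundancy_threshold(lambda), cap = as.integer(cap),
         additive_symmetric = isTRUE(additive_symmetric), scales = scales),
    class = "mmp_dictionary")
}

#' @export
print.mmp_dictionary <- function(x, ...) {
  cat(sprintf(
    "<mmp_dictionary: X_max %d, %d levels/scale, d = %g, cap %d>\n",
    x$x_max, length(x$levels), x$d, x$cap))
  invisible(x)
}

#' Separable scale transformation of a dictionary pattern
#'
#' Resamples a pattern to another of the 25 block geometries, rows first
#' and then columns: contraction averages adjacent samples, expansion
#' interpolates linearly between repeated samples; the result is rounded
#' half-away-from-zero.  Constant blocks map to constant blocks at every
#' target geometry.
#'
#' @param pattern integer matrix with dimensions in `{1, 2, 4, 8, 16}`.
#' @param dims target `c(M, N)`.
#' @return resampled integer matrix.
#' @export
scale_transform <- function(pattern, dims) {
  cpp_scale_transform(pattern, as.integer(dims[1]), as.integer(dims[2]))
}

#' Insert a concatenation pattern into the dictionary
#'
#' When a coded block is segmented, the concatenation of its two
#' children's reconstructions becomes a candidate pattern: it is
#' scale-transformed to all 25 geometries and appended to each scale's
#' partition for `origin_scale`, but only where its mean squared
#' difference per sample to *every* existing entry at that scale exceeds
#' the redundancy threshold `d` — near-duplicates contribute little to
#' coding and only dilute the index alphabet.  A full scale (at `cap`)
#' accepts no insertion.
#'
#' @param dict an [init_dictionary()] object.
#' @param new_pattern integer matrix (the children concatenation).
#' @param origin_scale scale of the segmented block that gave rise to the
#'   pattern; determines the probability-context partition.
#' @return the updated `mmp_dictionary`.
#' @export
update_dictionary <- function(dict, new_pattern, origin_scale) {
  stopifnot(inherits(dict, "mmp_dictionary"))
  origin_scale <- as.integer(origin_scale)
  cands <- list(new_pattern)
  if (dict$additive_symmetric) cands <- c(cands, list(-new_pattern))
  for (s in 1:25) {
    d <- scale_dims(s)
    for (cand in cands) {
      if (length(dict$scales[[s]]$patterns) >= dict$cap) next
      pt <- cpp_scale_transform(cand, d[1], d[2])
      dist <- vapply(dict$scales[[s]]$patterns,
                     function(q) mean((as.numeric(q) - as.numeric(pt))^2),
                     numeric(1))
      if (all(dist > dict$d)) {
        k <- length(dict$scales[[s]]$patterns) + 1L
        dict$scales[[s]]$patterns[[k]] <- pt
        dict$scales[[s]]$origin[k] <- origin_scale
      }
    }
  }
  dict
}

#' Best dictionary match under the Lagrangian cost
#'
#' Scans the candidate entries for the one minimizing
#' `J = D + lambda * R`, where `D` is the sum of squared differences
#' between the block and the entry and `R` the current model's code length
#' for the entry's index, in bits.  Ties keep the earliest entry in scan
#' order (lowest partition, then lowest index).
#'
#' @param block integer matrix to approximate.
#' @param entries list of candidate patterns with the block's dimensions
#'   (e.g. `dict$scales[[s]]$patterns`).
#' @param lambda Lagrangian multiplier.
#' @param rates optional numeric vector of per-entry code lengths in bits;
#'   omitted means rate 0 for every entry.
#' @return list with `index` (1-based position in `entries`) and the cost
#'   `J`.
#' @export
best_match <- function(block, entries, lambda = 0, rates = NULL) {
  if (length(entries) == 0) stop("empty dictionary scale")
  if (!is.null(rates) && length(rates) != length(entries))
    stop("rates must match entries")
  cpp_best_match(block, entries, as.numeric(lambda),
                 as.numeric(rates %||% numeric(0)))
}
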