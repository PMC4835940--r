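#' Percent root-mean-square difference (PRD)
#'
#' `PRD = 100 * sqrt(sum((x - xhat)^2) / sum(x^2))`, computed on the
#' quantized integer samples as acquired, without mean removal.  In the
#' full pipeline it is evaluated on the restored one-dimensional signal,
#' after any preprocessing has been undone.  The measure is scale
#' consistent: `prd(c * x, c * xhat) == prd(x, xhat)` for `c != 0`.
#'
#' @param x original sample vector (nonzero energy).
#' @param xhat reconstructed sample vector of the same length.
#' @return PRD in percent.
#' @examples
#' prd(c(3, 4), c(3, 0)) # 80
#' @export
prd <- function(x, xhat) {
  if (length(x) != length(xhat)) stop("signals must have equal length")
  ex <- sum(as.numeric(x)^2)
  if (ex == 0) stop("zero-energy original signal")
  100 * sqrt(sum((as.numeric(x) - as.numeric(xhat))^2) / ex)
}

#' Compression factor (CF)
#'
#' `CF = 100 * (B_o - B_c) / B_o`, where `B_o` is the bit count of the
#' original signal (`12 n` for 12-bit SEMG records of `n` samples) and
#' `B_c` the size of the compressed container in bits, byte padding
#' included.  A negative CF means expansion, which can legitimately
#' happen at `lambda = 0` (lossless coding).
#'
#' @param b_original bits in the original representation (> 0).
#' @param b_compressed bits in the compressed representation.
#' @return CF in percent.
#' @examples
#' cf(1200, 300) # 75
#' @export
cf <- function(b_original, b_compressed) {
  if (!is.numeric(b_original) || b_original <= 0)
    stop("b_original must be positive")
  100 * (b_original - b_compressed) / b_original
}

#' Rate-distortion sweep over a lambda grid
#'
#' Runs the full pipeline (preprocess, encode, container, decode, restore,
#' PRD/CF) once per lambda and collects one rate-distortion point per
#' value.  The bitrate is a consequence of lambda, so the default grid
#' `{0, 2, 4, 8, 16, 32, 64, 128}` spans the whole range of the
#' redundancy-control map.
#'
#' @param record an [semg_record()].
#' @param lambdas numeric grid of Lagrangian multipliers.
#' @param preprocess,segment_length,options passed to [semg_compress()].
#' @param csv optional path; when given the table is also written as CSV.
#' @return data frame with columns `lambda`, `bits`, `cf_percent`,
#'   `prd_percent`, sorted by increasing CF.
#' @export
rd_sweep <- function(record, lambdas = c(0, 2, 4, 8, 16, 32, 64, 128),
                     preprocess = "none", segment_length = NULL,
                     options = mmp_options(), csv = NULL) {
  if (length(lambdas) < 1) stop("empty lambda grid")
  f <- tempfile(fileext = ".mmp2d")
  on.exit(unlink(f))
  rows <- lapply(lambdas, function(lam) {
    semg_compress(record, f, lambda = lam, preprocess = preprocess,
                  segment_length = segment_length, options = options)
    ev <- semg_evaluate(record, f)
    data.frame(lambda = lam, bits = ev$bits,
               cf_percent = ev$cf_percent, prd_percent = ev$prd_percent)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$cf_percent), ]
  rownames(out) <- NULL
  if (!is.null(csv)) write.csv(out, csv, row.names = FALSE)
  out
}

#' Find the lambda achieving a target compression factor
#'
#' Bisection on the (empirically nondecreasing) CF-versus-lambda curve.
#' Dictionary adaptation makes the curve only approximately monotone, so
#' the result is the best bracket endpoint after `max_iter` halvings.
#'
#' @inheritParams rd_sweep
#' @param target_cf desired CF in percent.
#' @param lower,upper initial lambda bracket.
#' @param max_iter bisection steps.
#' @return list with `lambda` and the achieved `cf_percent` and
#'   `prd_percent`.
#' @export
lambda_for_cf <- function(record, target_cf, lower = 0, upper = 512,
                          max_iter = 10, preprocess = "none",
                          segment_length = NULL, options = mmp_options()) {
  f <- tempfile(fileext = ".mmp2d")
  on.exit(unlink(f))
  eval_at <- function(lam) {
    semg_compress(record, f, lambda = lam, preprocess = preprocess,
                  segment_length = segment_length, options = options)
    semg_evaluate(record, f)
  }
  best <- NULL
  for (i in seq_len(max_iter)) {
    mid <- (lower + upper) / 2
    ev <- eval_at(mid)
    if (is.null(best) ||
        abs(ev$cf_percent - target_cf) < abs(best$cf_percent - target_cf))
      best <- c(list(lambda = mid), ev)
    if (ev$cf_percent < target_cf) lower <- mid else upper <- mid
  }
  best
}

#' Plot a rate-distortion sweep
#'
#' @param sweep data frame from [rd_sweep()].
#' @param ... passed to [plot()].
#' @return the input, invisibly.
#' @export
plot_rd <- function(sweep, ...) {
  graphics::plot(sweep$cf_percent, sweep$prd_percent, type = "b", pch = 16,
                 xlab = "CF (%)", ylab = "PRD (%)", ...)
  invisible(sweep)
}
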