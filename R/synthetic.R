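#' Synthetic isometric SEMG record
#'
#' Emulates the statistics of constant-force surface EMG: i.i.d. noise
#' with a Gaussian amplitude distribution (typical of forceful isometric
#' contractions, e.g. 60% MVC) or a Laplacian one (light force),
#' band-pass filtered to the 10–500 Hz band of surface EMG with a
#' 4th-order zero-phase Butterworth filter, scaled to occupy about 70% of
#' the signed 12-bit range — wide enough to exercise every band of the
#' dictionary level step — and quantized to integers.  Deterministic for
#' a given seed.
#'
#' The generator reproduces amplitude distribution, bandwidth and dynamic
#' range only; it has no motor-unit structure, electrode artifacts or
#' slow nonstationarities, so results on it bound codec correctness, not
#' clinical performance.
#'
#' @param duration_s record duration in seconds.
#' @param sampling_rate_hz sampling rate (2000 Hz for the isometric
#'   protocol).
#' @param amplitude_family `"gaussian"` or `"laplacian"`.
#' @param band band-pass edges in Hz.
#' @param peak_fraction fraction of the 12-bit signed range occupied by
#'   the largest sample.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return an [semg_record()].
#' @export
gen_isometric <- function(duration_s = 1, sampling_rate_hz = 2000,
                          amplitude_family = c("gaussian", "laplacian"),
                          band = c(10, 500), peak_fraction = 0.7,
                          seed = NULL) {
  amplitude_family <- match.arg(amplitude_family)
  spec_check(duration_s, sampling_rate_hz, band)
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * sampling_rate_hz)
  x <- gen_carrier(n, amplitude_family)
  quantize_semg(bandpass(x, sampling_rate_hz, band), peak_fraction,
                sampling_rate_hz)
}

#' Synthetic dynamic SEMG record
#'
#' Emulates movement-modulated surface EMG (e.g. isokinetic knee-joint
#' exercise): an isometric-style noise carrier is multiplied by a
#' periodic raised-cosine burst envelope — one burst per contraction
#' cycle, with mild seed-controlled jitter in burst amplitude (±10%) and
#' period (±5%) — then band-pass filtered and quantized as in
#' [gen_isometric()], at the 2048 Hz rate of the dynamic protocol.  With
#' `bursts_per_min = 0` the envelope degenerates to its resting floor and
#' the record is near-silence.
#'
#' @inheritParams gen_isometric
#' @param bursts_per_min contraction cycles per minute.
#' @param envelope_floor resting activity level between bursts, as a
#'   fraction of the burst peak.
#' @return an [semg_record()]; the modulation envelope is attached as
#'   attribute `"envelope"`.
#' @export
gen_dynamic <- function(duration_s = 1, sampling_rate_hz = 2048,
                        bursts_per_min = 30,
                        amplitude_family = c("gaussian", "laplacian"),
                        band = c(10, 500), peak_fraction = 0.7,
                        envelope_floor = 0.05, seed = NULL) {
  amplitude_family <- match.arg(amplitude_family)
  spec_check(duration_s, sampling_rate_hz, band)
  if (bursts_per_min < 0) stop("bursts_per_min must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * sampling_rate_hz)
  x <- gen_carrier(n, amplitude_family)
  env <- rep(envelope_floor, n)
  if (bursts_per_min > 0) {
    period <- 60 / bursts_per_min
    t0 <- 0
    while (t0 < duration_s) {
      len <- period * (1 + runif(1, -0.05, 0.05))
      amp <- 1 + runif(1, -0.1, 0.1)
      i0 <- floor(t0 * sampling_rate_hz) + 1
      i1 <- min(n, floor((t0 + len) * sampling_rate_hz))
      if (i1 >= i0) {
        phase <- seq(0, 1, length.out = i1 - i0 + 1)
        env[i0:i1] <- envelope_floor +
          amp * (1 - envelope_floor) * (0.5 - 0.5 * cos(2 * pi * phase))
      }
      t0 <- t0 + len
    }
  }
  # normalize against the unmodulated carrier so the burst peaks sit at
  # peak_fraction of full scale and the resting floor stays near silence
  xf <- bandpass(x * env, sampling_rate_hz, band)
  ref <- max(abs(bandpass(x, sampling_rate_hz, band)), 1e-12)
  out <- quantize_semg(xf / ref, peak_fraction, sampling_rate_hz,
                       normalize = FALSE)
  attr(out, "envelope") <- env
  out
}

spec_check <- function(duration_s, fs, band) {
  if (duration_s <= 0) stop("duration must be positive")
  if (fs <= 0) stop("sampling rate must be positive")
  if (band[1] <= 0 || band[2] <= band[1] || band[2] >= fs / 2)
    stop("band must lie inside (0, Nyquist)")
}

gen_carrier <- function(n, family) {
  if (family == "gaussian") {
    rnorm(n)
  } else { # Laplacian via inverse CDF
    u <- runif(n) - 0.5
    -sign(u) * log(1 - 2 * abs(u))
  }
}

bandpass <- function(x, fs, band) {
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}

quantize_semg <- function(x, peak_fraction, fs, normalize = TRUE) {
  if (normalize) x <- x / max(abs(x), 1e-12)
  x <- x * peak_fraction * 2047
  v <- as.integer(round(x))
  v[v > 2047L] <- 2047L
  v[v < -2048L] <- -2048L
  semg_record(v, fs, 12L, 0L)
}
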