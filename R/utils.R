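#' @keywords internal
#' @useDynLib murmil, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Shared small numerics used across modules. Division floor used by every
# ratio feature/signal.
EPS_RATIO <- 1e-8

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Hilbert envelope of a real signal
#'
#' Magnitude of the analytic signal, computed with the FFT construction
#' (positive frequencies doubled, negative zeroed).
#'
#' @param x numeric vector.
#' @return nonnegative numeric vector of the same length.
#' @export
hilbert_envelope <- function(x) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  if (n == 1L) return(abs(x))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

#' Band-limited Hilbert envelope
#'
#' Band-pass filters the input (zero-phase Butterworth, order 4) and returns
#' the Hilbert envelope of the result. This is the primitive behind the
#' LF/MF/HF/SF/UF envelope transformations.
#'
#' @param x numeric vector.
#' @param rate sampling rate in Hz.
#' @param band numeric length-2, (low, high) corner frequencies in Hz.
#' @return nonnegative numeric vector, same length as `x`.
#' @export
band_envelope <- function(x, rate, band) {
  stopifnot(length(band) == 2, band[1] > 0, band[1] < band[2])
  if (band[2] >= rate / 2)
    stop("band upper edge must be below the Nyquist frequency")
  if (length(x) == 0L) return(numeric(0))
  hilbert_envelope(butter_filtfilt(x, rate, band, order = 4))
}

# Zero-phase Butterworth band-pass. `order` is the final band-pass order
# (must be even); signal::butter doubles the prototype order for "pass".
# Odd-reflection padding at both ends suppresses the start-up transients of
# the forward-backward pass (low corner frequencies decay slowly).
butter_filtfilt <- function(x, rate, band, order = 10) {
  stopifnot(order %% 2 == 0)
  bf <- signal::butter(order / 2, band / (rate / 2), type = "pass")
  x <- x - mean(x)   # remove DC up front; a band-pass keeps none of it
  n <- length(x)
  pad <- min(n - 1L, as.integer(round(3 * rate / band[1])))
  if (pad > 0L) {
    head_ref <- 2 * x[1] - x[(pad + 1L):2L]
    tail_ref <- 2 * x[n] - x[(n - 1L):(n - pad)]
    xp <- c(head_ref, x, tail_ref)
  } else xp <- x
  y <- signal::filtfilt(bf, xp)
  y[(pad + 1L):(pad + n)]
}

# Moving-average smoother with odd window, reflected edges.
smooth_ma <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w %% 2 == 0) w <- w + 1L
  if (w == 1L || length(x) < 2L) return(x)
  half <- (w - 1L) / 2L
  xp <- c(rev(x[seq_len(min(half, length(x)))]),
          x,
          rev(x[seq.int(length(x) - min(half, length(x)) + 1L, length(x))]))
  # pad further if the signal is shorter than half
  while (length(xp) < length(x) + 2 * half) xp <- c(xp[1], xp, xp[length(xp)])
  cs <- cumsum(c(0, xp))
  (cs[(1 + w):(length(x) + w)] - cs[seq_len(length(x))]) / w
}

# Contiguous runs of TRUE in a logical vector: matrix with columns start, end
# (1-based inclusive). Zero-row matrix when none.
true_runs <- function(mask) {
  if (!length(mask) || !any(mask)) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}
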