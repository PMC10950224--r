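# Signal conditioning: resampling, quality assessment, band-pass filtering,
# best-segment selection and the minimum-cycle rule, plus the extra
# conditioning used before explainable feature extraction (despiking, edge
# clipping, envelope-threshold clipping).

#' Preprocessing configuration
#'
#' @param target_rate working sampling rate, Hz.
#' @param band band-pass corner frequencies, Hz.
#' @param filter_order Butterworth band-pass order (even).
#' @param g_th envelope-clipping gain: samples with Hilbert envelope below
#'   `mean + g_th * sd` are kept.
#' @param min_cycles minimum usable heart cycles; recordings below are
#'   discarded.
#' @param quality_window quality-criteria window length, seconds.
#' @param sat_bin_frac amplitude-range fraction defining the extreme
#'   top/bottom histogram bins.
#' @param sat_threshold fraction of samples in the extreme bins above which a
#'   window counts as saturated.
#' @param noise_bands list of two (low, high) bands, Hz: a window is noisy
#'   when the first band's envelope energy exceeds the second's.
#' @param despike_window despiking window length, seconds.
#' @param target_length fixed segment length in samples used for training.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(target_rate = 2000, band = c(10, 800),
                              filter_order = 10, g_th = 2.7, min_cycles = 3,
                              quality_window = 1, sat_bin_frac = 0.02,
                              sat_threshold = 0.30,
                              noise_bands = list(c(100, 250), c(15, 90)),
                              despike_window = 0.5, target_length = 2^14) {
  stopifnot(target_rate > 0, band[1] > 0, band[2] > band[1],
            band[2] < target_rate / 2, g_th > 0, min_cycles >= 0,
            quality_window > 0, filter_order %% 2 == 0)
  structure(list(target_rate = target_rate, band = band,
                 filter_order = filter_order, g_th = g_th,
                 min_cycles = min_cycles, quality_window = quality_window,
                 sat_bin_frac = sat_bin_frac, sat_threshold = sat_threshold,
                 noise_bands = noise_bands, despike_window = despike_window,
                 target_length = target_length),
            class = "preprocess_config")
}

#' Resample by linear interpolation
#'
#' @param samples numeric vector.
#' @param rate_in,rate_out sampling rates in Hz.
#' @return numeric vector of length `round(length(samples) * rate_out / rate_in)`.
#' @export
resample_linear <- function(samples, rate_in, rate_out) {
  stopifnot(rate_in > 0, rate_out > 0)
  n <- length(samples)
  if (n == 0L) stop("cannot resample an empty signal")
  if (rate_in == rate_out) return(samples)
  m <- round(n * rate_out / rate_in)
  if (n == 1L) return(rep(samples, m))
  t_out <- (seq_len(m) - 1) / rate_out
  t_in <- (seq_len(n) - 1) / rate_in
  stats::approx(t_in, samples, xout = pmin(t_out, t_in[n]), rule = 2)$y
}

#' Assess signal quality
#'
#' Two per-window criteria on non-overlapping windows: a window is
#' *saturated* when the extreme top/bottom amplitude-histogram bins jointly
#' hold more than `sat_threshold` of its samples, and *noisy* when the
#' Hilbert-envelope energy of the 100-250 Hz band exceeds that of the
#' 15-90 Hz band. The usable mask marks samples whose window raises neither
#' flag.
#'
#' @param samples signal at `rate` Hz.
#' @param rate sampling rate, Hz.
#' @param config a [preprocess_config()].
#' @return a `quality_report`: list with per-window `saturated` and `noisy`
#'   flags, sample-level `usable` mask and `window_samples`.
#' @export
assess_quality <- function(samples, rate, config = preprocess_config()) {
  n <- length(samples)
  stopifnot(n > 0)
  w <- max(1L, round(config$quality_window * rate))
  n_win <- max(1L, ceiling(n / w))
  hi_env <- hilbert_envelope(
    if (config$noise_bands[[1]][2] < rate / 2)
      butter_filtfilt(samples, rate, config$noise_bands[[1]], order = 4)
    else samples)
  lo_env <- hilbert_envelope(
    butter_filtfilt(samples, rate, config$noise_bands[[2]], order = 4))
  saturated <- logical(n_win); noisy <- logical(n_win)
  for (k in seq_len(n_win)) {
    idx <- (((k - 1) * w) + 1):min(k * w, n)
    win <- samples[idx]
    rng <- range(win)
    if (diff(rng) > 1e-12) {
      lo_thr <- rng[1] + config$sat_bin_frac * diff(rng)
      hi_thr <- rng[2] - config$sat_bin_frac * diff(rng)
      saturated[k] <- mean(win <= lo_thr | win >= hi_thr) > config$sat_threshold
    }
    noisy[k] <- sum(hi_env[idx]^2) > sum(lo_env[idx]^2)
  }
  usable <- rep(!(saturated | noisy), each = w, length.out = n)
  structure(list(saturated = saturated, noisy = noisy, usable = usable,
                 window_samples = w, n = n),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("Quality report: %d windows (%d saturated, %d noisy), %.0f%% usable\n",
              length(x$saturated), sum(x$saturated), sum(x$noisy),
              100 * mean(x$usable)))
  invisible(x)
}

#' Serialize a quality report to JSON
#' @param report a `quality_report`.
#' @param path optional output file.
#' @return JSON string (invisibly if written to `path`).
#' @export
quality_report_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Band-pass filter a PCG
#'
#' Zero-phase (forward-backward) Butterworth band-pass at the configured
#' order and corners; removes DC.
#'
#' @inheritParams assess_quality
#' @return filtered signal, same length.
#' @export
pcg_bandpass <- function(samples, rate, config = preprocess_config()) {
  if (config$band[2] >= rate / 2) stop("band edge at or above Nyquist")
  butter_filtfilt(samples, rate, config$band, order = config$filter_order)
}

#' Select the highest-quality contiguous segment
#'
#' @param samples signal.
#' @param quality a `quality_report` for the same signal.
#' @param target_length window length in samples.
#' @return integer `c(start, end)`, a 0-based half-open sample interval of
#'   length `target_length` maximizing the fraction of usable samples
#'   (leftmost on ties). Falls back to the signal prefix (with a warning)
#'   when nothing is usable.
#' @export
best_segment <- function(samples, quality, target_length) {
  n <- length(samples)
  L <- min(as.integer(target_length), n)
  stopifnot(L >= 1)
  u <- as.numeric(quality$usable[seq_len(n)])
  cs <- cumsum(c(0, u))
  scores <- cs[(L + 1):(n + 1)] - cs[1:(n - L + 1)]
  if (max(scores) == 0 && any(!quality$usable))
    warning("no usable samples; falling back to signal prefix")
  s <- which.max(scores) - 1L   # leftmost maximum, 0-based
  c(start = s, end = s + L)
}

#' Count heart cycles fully inside the usable mask
#'
#' @param segmentation a [phase_segmentation()].
#' @param quality a `quality_report` covering the same samples.
#' @return integer count of complete S1->diastole cycles whose full extent is
#'   usable.
#' @export
count_usable_cycles <- function(segmentation, quality) {
  cyc <- cycles(segmentation)
  if (!length(cyc)) return(0L)
  ok <- vapply(cyc, function(cy) {
    a <- min(cy$start) + 1L; b <- max(cy$end)
    b <= quality$n && all(quality$usable[a:b])
  }, logical(1))
  sum(ok)
}

#' Discard recordings with too few usable cycles
#'
#' @inheritParams count_usable_cycles
#' @param config a [preprocess_config()]; `min_cycles` is the cutoff.
#' @return the usable cycle count, invisibly, or an error when below the
#'   minimum.
#' @export
reject_recording <- function(segmentation, quality, config = preprocess_config()) {
  k <- count_usable_cycles(segmentation, quality)
  if (k < config$min_cycles)
    stop(sprintf("recording discarded: %d usable heart cycles (minimum %d)",
                 k, config$min_cycles))
  invisible(k)
}

#' Remove friction spikes
#'
#' Window-based despiking: the signal is cut into windows; while any
#' window's maximum absolute amplitude exceeds 3x the median of window
#' maxima (at most 100 iterations), the spike is located at the maximum
#' slope of the absolute signal inside the worst window, expanded outwards
#' to where the amplitude settles below the window median, and replaced by
#' linear interpolation.
#'
#' @param samples signal.
#' @param rate sampling rate, Hz.
#' @param window despiking window length, seconds.
#' @return despiked signal, same length.
#' @export
despike <- function(samples, rate, window = 0.5) {
  n <- length(samples)
  w <- max(8L, round(window * rate))
  if (n < 2L * w) return(samples)
  x <- samples
  for (iter in seq_len(100)) {
    n_win <- floor(n / w)
    idx_mat <- matrix(seq_len(n_win * w), nrow = w)
    maxes <- apply(matrix(abs(x[seq_len(n_win * w)]), nrow = w), 2, max)
    med <- stats::median(maxes)
    if (med == 0 || !any(maxes > 3 * med)) break
    k <- which.max(maxes)
    win_idx <- idx_mat[, k]
    ax <- abs(x[win_idx])
    # steepest edge of |x| marks the spike; take the higher side of the edge
    slope_idx <- which.max(abs(diff(ax)))
    spike_rel <- if (ax[slope_idx] >= ax[slope_idx + 1L]) slope_idx
                 else slope_idx + 1L
    med_w <- stats::median(ax)
    lo <- spike_rel
    while (lo > 1L && ax[lo] > med_w) lo <- lo - 1L
    hi <- spike_rel
    while (hi < w && ax[hi] > med_w) hi <- hi + 1L
    # interpolate across the spike from the samples just outside it
    a <- win_idx[lo]; b <- win_idx[hi]
    left <- if (a > 1L) x[a - 1L] else 0
    right <- if (b < n) x[b + 1L] else 0
    x[a:b] <- seq(left, right, length.out = b - a + 2L)[-1][seq_len(b - a + 1L)]
  }
  x
}

#' Clip noisy recording edges
#'
#' Removes `c(d) = clamp(3 (d - 5) / 25, 0, 3)` seconds from each end of a
#' recording of duration `d` seconds: nothing at 5 s, 3 s per end at 30 s,
#' linear in between.
#'
#' @param samples signal.
#' @param rate sampling rate, Hz.
#' @return clipped signal (contiguous sub-interval); returned uncut with a
#'   warning when clipping would leave less than 1 s.
#' @export
clip_edges <- function(samples, rate) {
  d <- length(samples) / rate
  stopifnot(d >= 1)
  cut_s <- clamp(3 * (d - 5) / 25, 0, 3)
  k <- round(cut_s * rate)
  if (length(samples) - 2 * k < rate) {
    warning("edge clipping would leave < 1 s; returning signal uncut")
    return(samples)
  }
  if (k == 0) return(samples)
  samples[(k + 1):(length(samples) - k)]
}

#' Clip a recording by its Hilbert-envelope threshold
#'
#' Keeps the longest contiguous run of samples whose smoothed (0.5 s
#' moving average, so individual heart sounds do not register as
#' disturbances) Hilbert envelope satisfies
#' `env < mean(env) + g_th * sd(env)`. A zero-variance envelope
#' keeps the whole signal. The run's leading/trailing stretch up to the
#' first envelope dip below the run mean is additionally trimmed when it
#' exceeds 5 s (boundary-adjacent content sits close to the threshold).
#'
#' @param samples signal.
#' @param rate sampling rate, Hz.
#' @param g_th threshold gain (default 2.7).
#' @return contiguous sub-interval of `samples`; the full signal (with a
#'   warning) when no sample satisfies the criterion.
#' @export
clip_by_envelope <- function(samples, rate, g_th = 2.7) {
  stopifnot(length(samples) > 0)
  env <- smooth_ma(hilbert_envelope(samples), round(0.5 * rate))
  s <- stats::sd(env)
  if (!is.finite(s) || s == 0) return(samples)
  keep <- env < mean(env) + g_th * s
  if (!any(keep)) {
    warning("no sample satisfies the envelope criterion; returning full signal")
    return(samples)
  }
  runs <- true_runs(keep)
  lens <- runs[, 2] - runs[, 1] + 1L
  r <- runs[which.max(lens), ]
  a <- r[1]; b <- r[2]
  run_env <- env[a:b]
  cap <- round(5 * rate)
  m <- mean(run_env)
  settle_lead <- which(run_env < m)[1]
  if (!is.na(settle_lead) && settle_lead > cap) a <- a + settle_lead - 1L
  settle_tail <- which(rev(run_env) < m)[1]
  if (!is.na(settle_tail) && settle_tail > cap) b <- b - settle_tail + 1L
  samples[a:b]
}

#' Full preprocessing chain for one recording
#'
#' Resample to the target rate, assess quality, band-pass filter, pick the
#' best fixed-length segment, and count usable cycles (when a segmentation
#' is supplied).
#'
#' @param samples raw signal.
#' @param rate its sampling rate, Hz.
#' @param segmentation optional [phase_segmentation()] at the *target* rate.
#' @param config a [preprocess_config()].
#' @return list with `samples` (filtered, target rate), `rate`, `quality`,
#'   `segment` (0-based best segment bounds), `usable_cycles` (NA without
#'   segmentation) and `accepted`.
#' @export
preprocess_recording <- function(samples, rate, segmentation = NULL,
                                 config = preprocess_config()) {
  x <- resample_linear(samples, rate, config$target_rate)
  quality <- assess_quality(x, config$target_rate, config)
  x <- pcg_bandpass(x, config$target_rate, config)
  seg_bounds <- best_segment(x, quality, config$target_length)
  usable_cycles <- NA_integer_
  accepted <- TRUE
  if (!is.null(segmentation)) {
    usable_cycles <- count_usable_cycles(segmentation, quality)
    accepted <- usable_cycles >= config$min_cycles
  }
  list(samples = x, rate = config$target_rate, quality = quality,
       segment = seg_bounds, usable_cycles = usable_cycles,
       accepted = accepted)
}
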