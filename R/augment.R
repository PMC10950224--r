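# Stochastic waveform augmentations used during network training: scaling,
# Gaussian noise, drop, cutout, shift, resampling, random resampling (smooth
# time-warp), sine-wave addition and low-frequency band-pass filtering.
# Registry order is alphabetical and fixed for reproducibility.

AUGMENTATION_NAMES <- c("bandpass", "cutout", "drop", "gaussian",
                        "random_resample", "resample", "scaling", "shift",
                        "sine")

#' Augmentation policy
#'
#' Per-augmentation application probability plus parameter ranges. Default
#' probability is 0.3 per augmentation with at most `max_augments` applied in
#' one call (a configuration choice, not a dataset-derived ground truth).
#'
#' @param prob named numeric of per-augmentation probabilities (missing names
#'   filled with `default_prob`).
#' @param default_prob probability for unspecified augmentations.
#' @param max_augments cap on the number of augmentations per call.
#' @param scaling_range multiplicative factor range.
#' @param gaussian_sigma_range additive noise sigma range.
#' @param drop_rate_range fraction of samples zeroed.
#' @param cutout_range zeroed-interval length range, seconds.
#' @param shift_range time-shift range, seconds (either direction).
#' @param resample_factor_range linear time-scaling factor range.
#' @param warp_strength random-resampling warp strength (fractional rate
#'   deviation).
#' @param sine_amp_range,sine_freq_range added-sinusoid amplitude and
#'   frequency (Hz) ranges.
#' @param bandpass_corners band-pass corner frequencies, Hz.
#' @return an `augmentation_policy` list.
#' @export
augmentation_policy <- function(prob = NULL, default_prob = 0.3,
                                max_augments = 3,
                                scaling_range = c(0.5, 1.5),
                                gaussian_sigma_range = c(0.005, 0.05),
                                drop_rate_range = c(0.0, 0.05),
                                cutout_range = c(0.05, 0.5),
                                shift_range = c(-0.5, 0.5),
                                resample_factor_range = c(0.8, 1.25),
                                warp_strength = 0.15,
                                sine_amp_range = c(0.005, 0.05),
                                sine_freq_range = c(0.5, 100),
                                bandpass_corners = c(0.2, 45)) {
  p <- stats::setNames(rep(default_prob, length(AUGMENTATION_NAMES)),
                       AUGMENTATION_NAMES)
  if (!is.null(prob)) {
    bad <- setdiff(names(prob), AUGMENTATION_NAMES)
    if (length(bad)) stop("unknown augmentation(s): ", paste(bad, collapse = ", "))
    p[names(prob)] <- prob
  }
  stopifnot(all(p >= 0 & p <= 1), max_augments >= 0)
  structure(list(prob = p, max_augments = max_augments,
                 scaling_range = scaling_range,
                 gaussian_sigma_range = gaussian_sigma_range,
                 drop_rate_range = drop_rate_range,
                 cutout_range = cutout_range, shift_range = shift_range,
                 resample_factor_range = resample_factor_range,
                 warp_strength = warp_strength,
                 sine_amp_range = sine_amp_range,
                 sine_freq_range = sine_freq_range,
                 bandpass_corners = bandpass_corners),
            class = "augmentation_policy")
}

#' Apply a single named augmentation
#'
#' All augmentations preserve length except `resample`, which linearly
#' time-scales the signal (simulated heart-rate change).
#'
#' @param samples signal.
#' @param rate sampling rate, Hz.
#' @param name one of `r paste(AUGMENTATION_NAMES, collapse = ", ")`.
#' @param params named list of parameters (see [augmentation_policy()] for
#'   the corresponding ranges): `factor` (scaling, resample), `sigma`
#'   (gaussian), `rate_frac` (drop), `length_s` + optional `start` (cutout),
#'   `shift_s` (shift), `warp` (random_resample), `amp` + `freq` + optional
#'   `phase` (sine), `corners` (bandpass).
#' @return augmented signal.
#' @export
apply_augmentation <- function(samples, rate, name, params = list()) {
  name <- match.arg(name, AUGMENTATION_NAMES)
  n <- length(samples)
  switch(name,
    scaling = samples * params$factor,
    gaussian = samples + stats::rnorm(n, 0, params$sigma),
    drop = {
      k <- round(params$rate_frac * n)
      if (k > 0) samples[sample.int(n, min(k, n))] <- 0
      samples
    },
    cutout = {
      L <- min(n, max(1L, round(params$length_s * rate)))
      s <- if (!is.null(params$start)) params$start
           else sample.int(n - L + 1L, 1)
      samples[s:(s + L - 1L)] <- 0
      samples
    },
    shift = {
      k <- round(params$shift_s * rate)
      if (k == 0) samples
      else if (k > 0) c(numeric(min(k, n)), samples)[seq_len(n)]
      else c(samples[-seq_len(min(-k, n))], numeric(min(-k, n)))
    },
    resample = resample_linear(samples, rate, rate * params$factor),
    random_resample = {
      # smooth random time-warp: integrate a slowly varying rate modulation
      n_knots <- 6L
      mod <- stats::rnorm(n_knots, 0, params$warp)
      warp <- stats::spline(seq(0, 1, length.out = n_knots), mod, n = n)$y
      dt <- 1 + warp - mean(warp)
      pos <- cumsum(pmax(dt, 0.2))
      pos <- 1 + (pos - pos[1]) / (pos[n] - pos[1]) * (n - 1)
      stats::approx(seq_len(n), samples, xout = pos, rule = 2)$y
    },
    sine = {
      ph <- if (!is.null(params$phase)) params$phase else stats::runif(1, 0, 2 * pi)
      samples + params$amp * sin(2 * pi * params$freq * seq_len(n) / rate + ph)
    },
    bandpass = {
      co <- params$corners
      butter_filtfilt(samples, rate, co, order = 4)
    })
}

#' Randomly compose augmentations under a policy
#'
#' Each augmentation is independently selected with its policy probability
#' (registry order, capped at `max_augments`, strongest-probability first on
#' overflow) and applied with parameters drawn from the policy ranges.
#' Deterministic under a fixed RNG state.
#'
#' @param samples signal.
#' @param rate sampling rate, Hz.
#' @param policy an [augmentation_policy()].
#' @return augmented signal.
#' @export
compose_augmentations <- function(samples, rate, policy = augmentation_policy()) {
  stopifnot(inherits(policy, "augmentation_policy"))
  sel <- stats::runif(length(AUGMENTATION_NAMES)) < policy$prob
  names(sel) <- AUGMENTATION_NAMES
  if (sum(sel) > policy$max_augments) {
    keep <- names(sort(policy$prob[sel], decreasing = TRUE))[seq_len(policy$max_augments)]
    sel[] <- FALSE; sel[keep] <- TRUE
  }
  x <- samples
  ru <- function(r) stats::runif(1, r[1], r[2])
  for (nm in AUGMENTATION_NAMES[sel]) {
    params <- switch(nm,
      scaling = list(factor = ru(policy$scaling_range)),
      gaussian = list(sigma = ru(policy$gaussian_sigma_range)),
      drop = list(rate_frac = ru(policy$drop_rate_range)),
      cutout = list(length_s = ru(policy$cutout_range)),
      shift = list(shift_s = ru(policy$shift_range)),
      resample = list(factor = ru(policy$resample_factor_range)),
      random_resample = list(warp = policy$warp_strength),
      sine = list(amp = ru(policy$sine_amp_range),
                  freq = ru(policy$sine_freq_range)),
      bandpass = list(corners = policy$bandpass_corners))
    x <- apply_augmentation(x, rate, nm, params)
  }
  x
}
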