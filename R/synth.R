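# Synthetic phonocardiogram generator. Produces recordings with exact
# ground-truth phase segmentation and murmur intervals so that every
# downstream stage (preprocessing, MIL localization, feature extraction,
# patient-level classification) is testable without clinical data. The
# waveshape is a statistical emulation, not a physiological model: S1/S2 are
# decaying band-limited chirps, murmurs are band-limited noise bursts
# amplitude-modulated by one of the four classic murmur shapes.

MURMUR_SHAPES <- c("diamond", "plateau", "crescendo", "decrescendo")
AUSCULTATION_LOCATIONS <- c("AV", "PV", "TV", "MV", "other")

#' Murmur shape template
#'
#' Unit-height amplitude templates on \[0, 1\]: `crescendo` = t,
#' `decrescendo` = 1 - t, `diamond` = 1 - |2t - 1|, `plateau` = 1 inside
#' \[0.1, 0.9\] with linear ramps outside. Shared between the generator and
#' the shape features (single source of truth).
#'
#' @param shape one of `r paste(MURMUR_SHAPES, collapse = ", ")`.
#' @param n number of samples.
#' @return numeric vector of length `n` in \[0, 1\].
#' @export
murmur_shape_template <- function(shape, n) {
  shape <- match.arg(shape, MURMUR_SHAPES)
  t <- if (n == 1) 0.5 else seq(0, 1, length.out = n)
  switch(shape,
    crescendo = t,
    decrescendo = 1 - t,
    diamond = 1 - abs(2 * t - 1),
    plateau = pmin(1, pmin(t / 0.1, (1 - t) / 0.1)))
}

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Simulation configuration for one synthetic PCG
#'
#' @param sampling_rate Hz (default 2000, the working rate of the pipeline).
#' @param duration seconds.
#' @param heart_rate beats per minute, in \[40, 220\].
#' @param hr_jitter fractional cycle-to-cycle heart-rate jitter.
#' @param murmur_present logical.
#' @param murmur_phase "systolic", "diastolic" or "both".
#' @param murmur_shape one of diamond, plateau, crescendo, decrescendo.
#' @param murmur_band (low, high) Hz of the murmur noise band.
#' @param murmur_snr murmur peak level in dB relative to the S1 peak.
#' @param noise_level background white-noise amplitude relative to S1 peak.
#' @param spike_rate friction-spike events per second.
#' @param saturation_prob probability that the recording is clipped.
#' @param seed integer RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(sampling_rate = 2000, duration = 10, heart_rate = 100,
                       hr_jitter = 0.05, murmur_present = FALSE,
                       murmur_phase = "systolic", murmur_shape = "diamond",
                       murmur_band = c(200, 450), murmur_snr = 6,
                       noise_level = 0.02, spike_rate = 0,
                       saturation_prob = 0, seed = 1L) {
  cfg <- list(sampling_rate = sampling_rate, duration = duration,
              heart_rate = heart_rate, hr_jitter = hr_jitter,
              murmur_present = isTRUE(murmur_present),
              murmur_phase = match.arg(murmur_phase, c("systolic", "diastolic", "both")),
              murmur_shape = match.arg(murmur_shape, MURMUR_SHAPES),
              murmur_band = murmur_band, murmur_snr = murmur_snr,
              noise_level = noise_level, spike_rate = spike_rate,
              saturation_prob = saturation_prob, seed = as.integer(seed))
  stopifnot(cfg$sampling_rate > 0, cfg$duration > 0,
            cfg$heart_rate >= 40, cfg$heart_rate <= 220,
            cfg$hr_jitter >= 0, length(cfg$murmur_band) == 2,
            cfg$murmur_band[1] > 0,
            cfg$murmur_band[1] < cfg$murmur_band[2],
            cfg$murmur_band[2] < cfg$sampling_rate / 2,
            cfg$noise_level >= 0, cfg$spike_rate >= 0,
            cfg$saturation_prob >= 0, cfg$saturation_prob <= 1)
  class(cfg) <- "sim_config"
  cfg
}

# Decaying chirp used for S1/S2 transients: frequency glides f_hi -> f_lo,
# amplitude has a fast attack and exponential decay, tapered to zero at both
# ends so the ground-truth interval exactly covers the support.
heart_sound_wave <- function(n, rate, f_hi, f_lo, decay = 18) {
  t <- seq_len(n) / rate
  d <- n / rate
  f <- f_hi + (f_lo - f_hi) * (t / d)
  phase <- 2 * pi * cumsum(f) / rate
  env <- (1 - exp(-t / (0.12 * d))) * exp(-decay * t / d)
  taper <- pmin(1, pmin(seq_len(n), rev(seq_len(n))) / (0.08 * n + 1))
  w <- sin(phase) * env * taper
  w / max(abs(w))
}

#' Generate one synthetic PCG recording
#'
#' @param config a [sim_config()].
#' @param location auscultation location tag (AV/PV/TV/MV/other).
#' @param demographics optional [demographic_record()]; generated if `NULL`.
#' @return a `pcg_recording`: list with `samples` (in \[-1, 1\]), `rate`,
#'   `segmentation` ([phase_segmentation()]), `murmur_intervals`
#'   (data.frame start/end/phase, 0-based half-open samples), `location`,
#'   `demographics`, `murmur_label`, `outcome_label` and the `config`.
#' @export
synth_recording <- function(config, location = "AV", demographics = NULL) {
  stopifnot(inherits(config, "sim_config"))
  location <- match.arg(location, AUSCULTATION_LOCATIONS)
  rate <- config$sampling_rate
  min_dur <- 3 * 60 / config$heart_rate
  if (config$duration < min_dur)
    stop(sprintf("duration %.2f s too short for 3 cycles at %g bpm",
                 config$duration, config$heart_rate))
  with_seed(config$seed, {
    n <- round(config$duration * rate)
    x <- numeric(n)
    seg_start <- integer(0); seg_end <- integer(0); seg_lab <- character(0)
    mur <- list()
    s1_amp <- 1
    t0 <- 0.02 * 60 / config$heart_rate  # small lead-in
    repeat {
      cyc <- (60 / config$heart_rate) *
        (1 + config$hr_jitter * clamp(stats::rnorm(1), -2, 2))
      d_s1 <- stats::runif(1, 0.09, 0.11)
      d_s2 <- stats::runif(1, 0.07, 0.09)
      rem <- cyc - d_s1 - d_s2
      if (rem <= 0.08) break
      d_sys <- min(0.35, 0.44 * rem)
      d_dia <- rem - d_sys
      bounds <- t0 + cumsum(c(0, d_s1, d_sys, d_s2, d_dia))
      if (bounds[5] > config$duration - 0.01) break
      sb <- round(bounds * rate)
      sb <- cummax(sb)
      if (sb[5] > n) break
      labs <- c("S1", "systole", "S2", "diastole")
      for (k in 1:4) {
        if (sb[k + 1] > sb[k]) {
          seg_start <- c(seg_start, sb[k]); seg_end <- c(seg_end, sb[k + 1])
          seg_lab <- c(seg_lab, labs[k])
        }
      }
      # transients
      n1 <- sb[2] - sb[1]
      x[(sb[1] + 1):sb[2]] <- x[(sb[1] + 1):sb[2]] +
        s1_amp * heart_sound_wave(n1, rate, 90, 30)
      n2 <- sb[4] - sb[3]
      x[(sb[3] + 1):sb[4]] <- x[(sb[3] + 1):sb[4]] +
        0.8 * s1_amp * heart_sound_wave(n2, rate, 95, 38, decay = 22)
      # murmur(s)
      if (config$murmur_present) {
        phases <- switch(config$murmur_phase,
                         systolic = "systolic", diastolic = "diastolic",
                         both = c("systolic", "diastolic"))
        for (ph in phases) {
          iv <- if (ph == "systolic") c(sb[2], sb[3]) else c(sb[4], sb[5])
          m <- iv[2] - iv[1]
          if (m > 8) {
            noise <- butter_filtfilt(stats::rnorm(m + 2 * 64), rate,
                                     config$murmur_band, order = 4)
            noise <- noise[(64 + 1):(64 + m)]
            shape <- murmur_shape_template(config$murmur_shape, m)
            burst <- noise * shape
            peak_env <- max(abs(burst))
            target <- s1_amp * 10^(config$murmur_snr / 20)
            x[(iv[1] + 1):iv[2]] <- x[(iv[1] + 1):iv[2]] +
              burst / peak_env * target
            mur[[length(mur) + 1L]] <-
              data.frame(start = iv[1], end = iv[2], phase = ph)
          }
        }
      }
      t0 <- bounds[5]
    }
    if (sum(seg_lab == "S1") < 3)
      stop("duration too short for 3 cycles")
    # trim the cycle-free tail so every part of the recording carries sounds
    n <- max(seg_end)
    # ambient background: low-frequency-weighted (rumble/handling) with a
    # small broadband component
    rumble <- smooth_ma(stats::rnorm(n), 13L)
    rumble <- rumble / stats::sd(rumble)
    x <- x[seq_len(n)] +
      config$noise_level * (0.85 * rumble + 0.15 * stats::rnorm(n))
    # friction spikes
    n_spk <- stats::rpois(1, config$spike_rate * config$duration)
    if (n_spk > 0) {
      for (p in sample.int(n - 20, n_spk)) {
        w <- round(0.004 * rate)
        amp <- stats::runif(1, 2, 4) * sample(c(-1, 1), 1)
        x[p:(p + w)] <- x[p:(p + w)] + amp * exp(-seq(0, 6, length.out = w + 1))
      }
    }
    x <- x / max(abs(x))
    if (stats::runif(1) < config$saturation_prob)
      x <- clamp(x / 0.6, -0.95, 0.95)  # drive into the rails
    if (is.null(demographics)) demographics <- random_demographics()
    rec <- list(
      samples = x, rate = rate,
      segmentation = phase_segmentation(seg_start, seg_end, seg_lab,
                                        n_samples = n),
      murmur_intervals = if (length(mur)) do.call(rbind, mur)
                         else data.frame(start = integer(0), end = integer(0),
                                         phase = character(0)),
      location = location, demographics = demographics,
      murmur_label = if (config$murmur_present) "Present" else "Absent",
      outcome_label = NA_character_,
      config = config)
    class(rec) <- "pcg_recording"
    rec
  })
}

#' @export
print.pcg_recording <- function(x, ...) {
  cat(sprintf(
    "Synthetic PCG: %.1f s @ %d Hz, %s, murmur %s (%d intervals), %d cycles\n",
    length(x$samples) / x$rate, x$rate, x$location, x$murmur_label,
    nrow(x$murmur_intervals), length(cycles(x$segmentation))))
  invisible(x)
}

#' Demographic record
#'
#' @param age age in months (NA allowed).
#' @param sex "female" or "male" (NA allowed).
#' @param weight kg (NA allowed).
#' @param height cm (NA allowed).
#' @return a `demographic_record` list.
#' @export
demographic_record <- function(age = NA_real_, sex = NA_character_,
                               weight = NA_real_, height = NA_real_) {
  if (!is.na(sex)) sex <- match.arg(sex, c("female", "male"))
  stopifnot(is.na(age) || age >= 0, is.na(weight) || weight >= 0,
            is.na(height) || height >= 0)
  structure(list(age = age, sex = sex, weight = weight, height = height),
            class = "demographic_record")
}

# Pediatric-flavoured random demographics: age 1-15 years, simple linear
# growth curves with noise.
random_demographics <- function() {
  age <- round(stats::runif(1, 12, 180))
  yr <- age / 12
  demographic_record(
    age = age,
    sex = sample(c("female", "male"), 1),
    weight = round(2.4 * yr + 8 + stats::rnorm(1, 0, 2), 1),
    height = round(6.2 * yr + 76 + stats::rnorm(1, 0, 4), 1))
}

#' Generate a synthetic patient cohort
#'
#' Each patient receives 1-4 auscultation-location recordings with shared
#' demographics, a patient murmur label (Present / Unknown / Absent) and a
#' clinical outcome label (Normal / Abnormal). "Unknown" patients carry a
#' low-SNR murmur buried in heavy noise. For murmur-present patients, the
#' murmur is audible in a random non-empty subset of the recorded locations;
#' each recording carries its own recording-level label.
#'
#' @param n_patients number of patients (>= 1).
#' @param config_distribution list of ranges: `duration` (s), `heart_rate`
#'   (bpm), `snr` (dB), `noise` (relative), `unknown_snr`, `unknown_noise`,
#'   plus scalars `prevalence` (murmur probability, default 0.5),
#'   `unknown_prob` (probability a murmur patient is labeled Unknown, default
#'   0.1), `murmur_phase_probs` (named systolic/diastolic/both), and
#'   `outcome_probs` (P(Abnormal) given Present/Unknown/Absent).
#' @param seed integer RNG seed.
#' @return list of patients; each has `id`, `demographics`, `murmur_label`,
#'   `outcome_label` and `recordings`.
#' @export
synth_cohort <- function(n_patients, config_distribution = list(), seed = 1L) {
  stopifnot(n_patients >= 1)
  cd <- utils::modifyList(list(
    duration = c(8, 12), heart_rate = c(70, 140), snr = c(3, 10),
    noise = c(0.01, 0.05), unknown_snr = c(-2, 1), unknown_noise = c(0.1, 0.2),
    prevalence = 0.5, unknown_prob = 0.1,
    murmur_phase_probs = c(systolic = 0.9, diastolic = 0.05, both = 0.05),
    outcome_probs = c(Present = 0.84, Unknown = 0.63, Absent = 0.38)),
    config_distribution)
  for (r in c("duration", "heart_rate", "snr", "noise", "unknown_snr",
              "unknown_noise")) {
    if (length(cd[[r]]) != 2 || cd[[r]][1] > cd[[r]][2])
      stop("degenerate range for ", r)
  }
  stopifnot(cd$prevalence >= 0, cd$prevalence <= 1,
            cd$unknown_prob >= 0, cd$unknown_prob <= 1)
  with_seed(seed, {
    lapply(seq_len(n_patients), function(i) {
      demo <- random_demographics()
      has_murmur <- stats::runif(1) < cd$prevalence
      label <- if (!has_murmur) "Absent"
               else if (stats::runif(1) < cd$unknown_prob) "Unknown"
               else "Present"
      n_loc <- sample(1:4, 1, prob = c(0.1, 0.2, 0.2, 0.5))
      locs <- sample(c("AV", "PV", "TV", "MV"), n_loc)
      hearable <- rep(FALSE, n_loc)
      if (has_murmur) {
        hearable <- stats::runif(n_loc) < 0.75
        if (!any(hearable)) hearable[sample.int(n_loc, 1)] <- TRUE
      }
      phase <- sample(names(cd$murmur_phase_probs), 1,
                      prob = cd$murmur_phase_probs)
      shape <- sample(MURMUR_SHAPES, 1)
      unknown <- identical(label, "Unknown")
      recs <- lapply(seq_len(n_loc), function(j) {
        cfg <- sim_config(
          duration = stats::runif(1, cd$duration[1], cd$duration[2]),
          heart_rate = stats::runif(1, cd$heart_rate[1], cd$heart_rate[2]),
          murmur_present = hearable[j],
          murmur_phase = phase, murmur_shape = shape,
          murmur_snr = if (unknown) stats::runif(1, cd$unknown_snr[1], cd$unknown_snr[2])
                       else stats::runif(1, cd$snr[1], cd$snr[2]),
          noise_level = if (unknown) stats::runif(1, cd$unknown_noise[1], cd$unknown_noise[2])
                        else stats::runif(1, cd$noise[1], cd$noise[2]),
          seed = sample.int(.Machine$integer.max, 1))
        rec <- synth_recording(cfg, location = locs[j], demographics = demo)
        if (unknown && hearable[j]) rec$murmur_label <- "Unknown"
        rec
      })
      outcome <- if (stats::runif(1) < cd$outcome_probs[[label]]) "Abnormal"
                 else "Normal"
      for (j in seq_along(recs)) recs[[j]]$outcome_label <- outcome
      list(id = sprintf("SYN%04d", i), demographics = demo,
           murmur_label = label, outcome_label = outcome, recordings = recs)
    })
  })
}

#' Write a cohort in CirCor-style layout
#'
#' Per recording: `<patient>_<LOC>.wav` (16-bit PCM) and `<patient>_<LOC>.tsv`
#' (start s, end s, state code); per patient `<patient>.txt` with
#' demographics and labels.
#'
#' @param cohort output of [synth_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_circor_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in cohort) {
    for (rec in p$recordings) {
      base <- file.path(dir, paste0(p$id, "_", rec$location))
      write_wav(rec$samples, rec$rate, paste0(base, ".wav"))
      write_segmentation_tsv(rec$segmentation, rec$rate, paste0(base, ".tsv"))
    }
    d <- p$demographics
    lines <- c(
      paste0("#Patient: ", p$id),
      paste0("#Locations: ", paste(vapply(p$recordings, `[[`, "", "location"),
                                   collapse = "+")),
      paste0("#Age (months): ", d$age),
      paste0("#Sex: ", d$sex),
      paste0("#Weight (kg): ", d$weight),
      paste0("#Height (cm): ", d$height),
      paste0("#Murmur: ", p$murmur_label),
      paste0("#Outcome: ", p$outcome_label))
    writeLines(lines, file.path(dir, paste0(p$id, ".txt")))
  }
  invisible(dir)
}
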