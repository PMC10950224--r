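test_that("generator rejects invalid configurations and short durations", {
  expect_error(sim_config(murmur_band = c(500, 200)))
  expect_error(sim_config(heart_rate = 20))
  expect_error(sim_config(murmur_band = c(200, 1200)))
  expect_error(synth_recording(sim_config(duration = 1, heart_rate = 60)),
               "3 cycles")
})

test_that("murmur-free recordings have no murmur intervals and label Absent", {
  rec <- fix_clean_rec()
  expect_identical(rec$murmur_label, "Absent")
  expect_identical(nrow(rec$murmur_intervals), 0L)
})

test_that("identical seed gives bit-identical samples; different seeds differ", {
  cfg <- sim_config(duration = 8, murmur_present = TRUE, seed = 42)
  r1 <- synth_recording(cfg)
  r2 <- synth_recording(cfg)
  expect_identical(r1$samples, r2$samples)
  cfg2 <- sim_config(duration = 8, murmur_present = TRUE, seed = 43)
  expect_false(identical(synth_recording(cfg2)$samples, r1$samples))
})

test_that("murmur intervals lie inside ground-truth phases of matching type", {
  for (phase in c("systolic", "diastolic", "both")) {
    rec <- synth_recording(sim_config(duration = 8, murmur_present = TRUE,
                                      murmur_phase = phase, seed = 5))
    seg <- rec$segmentation
    expect_gt(nrow(rec$murmur_intervals), 0)
    for (i in seq_len(nrow(rec$murmur_intervals))) {
      mi <- rec$murmur_intervals[i, ]
      lab <- if (mi$phase == "systolic") "systole" else "diastole"
      ph <- seg[seg$label == lab, ]
      expect_true(any(ph$start <= mi$start & ph$end >= mi$end))
    }
  }
})

test_that("cycle count tracks duration x heart rate", {
  for (hr in c(60, 100, 140)) {
    rec <- synth_recording(sim_config(duration = 12, heart_rate = hr,
                                      hr_jitter = 0.02, seed = 3))
    expected <- floor(12 * hr / 60)
    expect_lte(abs(length(cycles(rec$segmentation)) - expected), 1)
  }
})

test_that("a +6 dB systolic murmur raises the murmur-band envelope in systole", {
  # independent oracle: band-pass + rectified mean per ground-truth interval
  rec <- synth_recording(sim_config(duration = 10, murmur_present = TRUE,
                                    murmur_snr = 6, murmur_band = c(200, 450),
                                    seed = 21))
  bf <- signal::butter(2, c(200, 450) / 1000, type = "pass")
  filt <- abs(signal::filtfilt(bf, rec$samples))
  seg <- rec$segmentation
  mean_over <- function(lab) {
    idx <- unlist(lapply(which(seg$label == lab),
                         function(i) (seg$start[i] + 1):seg$end[i]))
    mean(filt[idx])
  }
  expect_gt(mean_over("systole"), mean_over("diastole"))
})

test_that("samples stay in [-1, 1] and are normalized to peak 1", {
  rec <- fix_murmur_rec()
  expect_lte(max(abs(rec$samples)), 1)
  expect_equal(max(abs(rec$samples)), 1, tolerance = 1e-12)
})

test_that("saturation defect clips the waveform at the 0.95 rails", {
  rec <- synth_recording(sim_config(duration = 8, saturation_prob = 1,
                                    seed = 2))
  expect_lte(max(abs(rec$samples)), 0.95)
  expect_gt(mean(abs(rec$samples) > 0.949), 0.001)
})

test_that("cohorts are reproducible and labels consistent", {
  co1 <- synth_cohort(8, seed = 3)
  co2 <- synth_cohort(8, seed = 3)
  expect_identical(lapply(co1, function(p) p$recordings[[1]]$samples),
                   lapply(co2, function(p) p$recordings[[1]]$samples))
  co3 <- synth_cohort(10, list(prevalence = 0), seed = 4)
  expect_true(all(vapply(co3, `[[`, "", "murmur_label") == "Absent"))
  for (p in co1) {
    expect_gte(length(p$recordings), 1)
    expect_lte(length(p$recordings), 4)
    locs <- vapply(p$recordings, `[[`, "", "location")
    expect_false(anyDuplicated(locs) > 0)
    if (p$murmur_label == "Absent")
      expect_true(all(vapply(p$recordings, `[[`, "", "murmur_label") ==
                        "Absent"))
    else
      expect_true(any(vapply(p$recordings, `[[`, "", "murmur_label") !=
                        "Absent"))
  }
})

test_that("requested prevalence is met within binomial bounds", {
  co <- synth_cohort(100, list(prevalence = 0.5, unknown_prob = 0), seed = 9)
  n_mur <- sum(vapply(co, `[[`, "", "murmur_label") == "Present")
  # 99% binomial bounds for n = 100, p = 0.5
  expect_gte(n_mur, qbinom(0.005, 100, 0.5))
  expect_lte(n_mur, qbinom(0.995, 100, 0.5))
})

test_that("degenerate config ranges are rejected", {
  expect_error(synth_cohort(5, list(heart_rate = c(140, 70))), "degenerate")
  expect_error(synth_cohort(0), ">= 1")
})

test_that("CirCor-style writer produces readable WAV + TSV + metadata", {
  dir <- withr::local_tempdir()
  co <- synth_cohort(2, seed = 6)
  write_circor_cohort(co, dir)
  p <- co[[1]]
  rec <- p$recordings[[1]]
  base <- file.path(dir, paste0(p$id, "_", rec$location))
  w <- read_wav(paste0(base, ".wav"))
  expect_equal(w$rate, rec$rate)
  expect_lt(max(abs(w$samples - rec$samples)), 1e-4)  # 16-bit quantization
  seg <- read_segmentation_tsv(paste0(base, ".tsv"), rec$rate)
  expect_equal(seg$label, rec$segmentation$label)
  expect_true(file.exists(file.path(dir, paste0(p$id, ".txt"))))
  txt <- readLines(file.path(dir, paste0(p$id, ".txt")))
  expect_true(any(grepl(p$murmur_label, txt)))
})
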