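test_that("linear resampling matches closed forms", {
  x <- sin(2 * pi * 5 * seq(0, 1, length.out = 4000))
  expect_identical(resample_linear(x, 4000, 4000), x)
  expect_equal(resample_linear(rep(3.7, 1000), 1000, 300), rep(3.7, 300))
  # ramp 0..1 over 1 s at 4000 Hz -> values equal the line at output times
  ramp <- seq(0, 1, length.out = 4000)   # value = t * 4000/3999 per sample
  out <- resample_linear(ramp, 4000, 2000)
  expect_length(out, 2000)
  t_out <- (seq_len(2000) - 1) / 2000
  expect_equal(out, pmin(t_out, 3999 / 4000) * 4000 / 3999, tolerance = 1e-12)
  expect_error(resample_linear(numeric(0), 100, 50), "empty")
})

test_that("quality criteria flag saturation and high-band noise correctly", {
  rate <- 2000
  t <- seq_len(4 * rate) / rate
  # pure 50 Hz tone: low band dominates -> noise flag false everywhere
  tone <- 0.5 * sin(2 * pi * 50 * t)
  q <- assess_quality(tone, rate)
  expect_false(any(q$noisy))
  # oracle: direct two-band envelope energy comparison on the whole signal
  e_hi <- sum(hilbert_envelope(murmil:::butter_filtfilt(tone, rate, c(100, 250),
                                               order = 4))^2)
  e_lo <- sum(hilbert_envelope(murmil:::butter_filtfilt(tone, rate, c(15, 90),
                                               order = 4))^2)
  expect_lt(e_hi, e_lo)
  # clipped square wave: histogram extremes over-represented
  sq <- sign(sin(2 * pi * 30 * t))
  q2 <- assess_quality(sq, rate)
  expect_true(all(q2$saturated))
  # direct histogram-count oracle on one window
  win <- sq[seq_len(rate)]
  rng <- range(win)
  frac <- mean(win <= rng[1] + 0.02 * diff(rng) |
                 win >= rng[2] - 0.02 * diff(rng))
  expect_gt(frac, 0.30)
  # all-zero signal: nothing flagged by convention
  q3 <- assess_quality(numeric(rate * 2), rate)
  expect_false(any(q3$saturated))
  expect_false(any(q3$noisy))
  expect_true(all(q3$usable))
})

test_that("quality flags on a clean synthetic recording are all usable", {
  rec <- fix_clean_rec()
  q <- assess_quality(rec$samples, rec$rate)
  expect_true(all(q$usable))
})

test_that("band-pass rejects DC, preserves 100 Hz, attenuates 5 Hz", {
  rate <- 2000
  t <- seq_len(4 * rate) / rate
  out_dc <- pcg_bandpass(rep(0.8, length(t)), rate)
  expect_lt(max(abs(out_dc)), 1e-6 * 0.8)
  tone100 <- sin(2 * pi * 100 * t)
  r100 <- sqrt(mean(pcg_bandpass(tone100, rate)^2)) / sqrt(mean(tone100^2))
  expect_gt(r100, 0.95); expect_lt(r100, 1.05)
  tone5 <- sin(2 * pi * 5 * t)
  r5 <- sqrt(mean(pcg_bandpass(tone5, rate)^2)) / sqrt(mean(tone5^2))
  expect_lt(r5, 10^(-20 / 20))
  expect_error(pcg_bandpass(tone5, 1200), "Nyquist")
})

test_that("best segment maximizes usable fraction, leftmost on ties", {
  n <- 6000
  q <- structure(list(usable = rep(TRUE, n), n = n), class = "quality_report")
  expect_equal(unname(best_segment(numeric(n), q, 2000)), c(0, 2000))
  # usable only in the second half -> window inside second half
  q$usable <- rep(c(FALSE, TRUE), each = n / 2)
  got <- best_segment(numeric(n), q, 2000)
  # oracle: exhaustive scan
  scores <- vapply(0:(n - 2000), function(s)
    sum(q$usable[(s + 1):(s + 2000)]), numeric(1))
  expect_equal(unname(got[1]), which.max(scores) - 1)
  expect_gte(got[1], n / 2)
  q$usable <- rep(FALSE, n)
  expect_warning(got <- best_segment(numeric(n), q, 2000), "prefix")
  expect_equal(unname(got), c(0, 2000))
})

test_that("usable-cycle counting and the three-cycle rule", {
  rec <- fix_clean_rec()
  q <- assess_quality(rec$samples, rec$rate)
  n_cyc <- length(cycles(rec$segmentation))
  expect_equal(count_usable_cycles(rec$segmentation, q), n_cyc)
  expect_invisible(reject_recording(rec$segmentation, q))
  # two cycles -> discarded
  seg2 <- phase_segmentation(
    c(0, 200, 700, 900, 1400, 1600, 2100, 2300),
    c(200, 700, 900, 1400, 1600, 2100, 2300, 2800),
    rep(c("S1", "systole", "S2", "diastole"), 2))
  q2 <- structure(list(usable = rep(TRUE, 3000), n = 3000),
                  class = "quality_report")
  expect_equal(count_usable_cycles(seg2, q2), 2L)
  expect_error(reject_recording(seg2, q2), "discarded")
  # 5 cycles with the middle 3 masked unusable -> 2 usable, rejected
  mk <- function(k0) phase_segmentation(
    k0 + c(0, 200, 700, 900), k0 + c(200, 700, 900, 1400),
    c("S1", "systole", "S2", "diastole"))
  segs <- do.call(rbind, lapply(0:4 * 1400, mk))
  seg5 <- phase_segmentation(segs$start, segs$end, segs$label)
  usable <- rep(TRUE, 7000); usable[1401:5600] <- FALSE
  q5 <- structure(list(usable = usable, n = 7000), class = "quality_report")
  # oracle: manual interval intersection -> cycles 1 and 5 survive
  expect_equal(count_usable_cycles(seg5, q5), 2L)
  expect_error(reject_recording(seg5, q5), "discarded")
})

test_that("despiking removes isolated spikes and leaves clean signals alone", {
  rate <- 2000
  t <- seq_len(6 * rate) / rate
  x <- 0.4 * sin(2 * pi * 40 * t)
  expect_lt(max(abs(despike(x, rate) - x)), 1e-9)
  x_spiked <- x
  x_spiked[6001:6004] <- 8  # x20 amplitude spike
  out <- despike(x_spiked, rate)
  expect_lt(max(abs(out)), 2 * max(abs(x)))
  expect_identical(despike(numeric(4000), rate), numeric(4000))
})

test_that("edge clipping follows the duration-linear rule", {
  rate <- 2000
  expect_length(clip_edges(numeric(5 * rate), rate), 5 * rate)        # 0 s cut
  expect_length(clip_edges(numeric(30 * rate), rate), 24 * rate)      # 3 s/end
  # midpoint of the linear rule: 17.5 s -> 1.5 s per end
  expect_length(clip_edges(numeric(17.5 * rate), rate), 14.5 * rate)
  expect_length(clip_edges(numeric(60 * rate), rate), 54 * rate)      # clamp 3 s
  # below 5 s nothing is cut
  expect_length(clip_edges(numeric(3 * rate), rate), 3 * rate)
})

test_that("envelope clipping keeps the longest quiet run", {
  rate <- 2000
  # constant-envelope signal: sd = 0 -> whole signal kept
  x <- sin(2 * pi * 60 * seq_len(4 * rate) / rate)
  expect_length(clip_by_envelope(x, rate), length(x))
  # one huge burst in the middle -> output equals the longer flank
  set.seed(1)
  y <- 0.05 * stats::rnorm(10 * rate)
  y[(4 * rate):(5 * rate)] <- y[(4 * rate):(5 * rate)] +
    2 * sin(2 * pi * 90 * seq(0, 1, length.out = rate + 1))
  kept <- clip_by_envelope(y, rate, 2.7)
  expect_lt(length(kept), length(y))
  # oracle: direct threshold + run-length scan on the same envelope rule
  env <- murmil:::smooth_ma(hilbert_envelope(y), rate / 2)
  keep <- env < mean(env) + 2.7 * sd(env)
  r <- rle(keep)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  runs <- cbind(starts[r$values], ends[r$values])
  best <- runs[which.max(runs[, 2] - runs[, 1]), ]
  expect_equal(kept, y[best[1]:best[2]])
  # g_th -> infinity keeps everything
  expect_length(clip_by_envelope(y, rate, 1e9), length(y))
})

test_that("the preprocessing chain is deterministic and idempotent", {
  rec <- fix_clean_rec()
  p1 <- preprocess_recording(rec$samples, rec$rate, rec$segmentation)
  p2 <- preprocess_recording(rec$samples, rec$rate, rec$segmentation)
  expect_identical(p1$samples, p2$samples)
  expect_true(p1$accepted)
  # clipping operations return contiguous unmodified sub-intervals
  x <- rec$samples
  ce <- clip_edges(x, rec$rate)
  expect_true(any(vapply(seq_len(length(x) - length(ce) + 1), function(s)
    identical(x[s:(s + length(ce) - 1)], ce), logical(1))))
})
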