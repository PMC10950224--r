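test_that("the transformation registry has 18 stable entries", {
  reg <- transformation_registry()
  expect_equal(nrow(reg), 18)
  expect_equal(reg$name, paste0("t", 1:18))
})

test_that("band envelopes track amplitude in-band and vanish out-of-band", {
  rate <- 2000
  t <- seq_len(4 * rate) / rate
  tone <- 0.7 * sin(2 * pi * 160 * t)
  env <- band_envelope(tone, rate, c(100, 250))
  core <- env[2000:6000]   # away from filter edges
  expect_lt(max(abs(core - 0.7)) / 0.7, 0.05)
  env_out <- band_envelope(tone, rate, c(400, 800))
  expect_lt(mean(env_out[2000:6000]), 0.02)
  expect_identical(band_envelope(numeric(0), rate, c(100, 250)), numeric(0))
  expect_equal(band_envelope(numeric(1000), rate, c(100, 250)),
               numeric(1000), tolerance = 1e-12)
  expect_error(band_envelope(tone, rate, c(400, 1200)), "Nyquist")
})

test_that("transformations: count, white-noise centroid, tone band ratios", {
  rate <- 2000
  set.seed(21)
  tr <- compute_transformations(stats::rnorm(4 * rate), rate)
  expect_length(tr, 18)
  expect_true(all(vapply(tr, length, integer(1)) == 4 * rate))
  # flat-spectrum oracle: spectral centroid of white noise ~ rate / 4
  expect_lt(abs(mean(tr$t3) - rate / 4) / (rate / 4), 0.20)
  # 50 Hz tone: HF/LF ratio signal ~ 0 (HF envelope empty, LF carries it)
  tone <- sin(2 * pi * 50 * seq_len(4 * rate) / rate)
  tr2 <- compute_transformations(tone, rate)
  expect_lt(mean(tr2$t12[2000:6000]), 0.05)
  # direct envelope-division oracle
  direct <- band_envelope(tone, rate, c(100, 250)) /
    pmax(band_envelope(tone, rate, c(15, 90)), 1e-8)
  expect_equal(tr2$t12, direct, tolerance = 1e-12)
})

test_that("region statistics honor the segmentation", {
  seg <- phase_segmentation(c(0, 200, 800, 960), c(200, 800, 960, 2000),
                            c("S1", "systole", "S2", "diastole"))
  x <- rep(5, 2000)
  st <- region_stats(x, seg)
  expect_length(st, 18)
  expect_true(all(st[grep("^a", names(st))] == 5))
  expect_true(all(st[grep("^m", names(st))] == 5))
  expect_true(all(st[grep("^s", names(st))] == 0))
  # indicator on systole: mean over systole 1, over diastole 0
  ind <- numeric(2000); ind[201:800] <- 1
  st2 <- region_stats(ind, seg)
  expect_equal(unname(st2["aSys"]), 1)
  expect_equal(unname(st2["aDias"]), 0)
  # single cycle: per-cycle average equals the cycle's own value
  expect_equal(unname(st2["aRR"]), mean(ind))
  expect_error(region_stats(x, phase_segmentation()), "cycle")
})

test_that("stat ratios: flat signal gives unit mean-ratios and zero s/a", {
  seg <- phase_segmentation(c(0, 200, 800, 960), c(200, 800, 960, 2000),
                            c("S1", "systole", "S2", "diastole"))
  st <- region_stats(rep(2.5, 2000), seg)
  r <- stat_ratios(st)
  expect_length(r, 15)
  expect_true(all(r[grep("^r_a", names(r))] == 1))
  expect_true(all(r[grep("^r_s", names(r))] == 0))
  # mean(sys) = 2 mean(dias) -> r_aSys_aDias = 2
  x <- numeric(2000); x[201:800] <- 2; x[961:2000] <- 1
  r2 <- stat_ratios(region_stats(x, seg))
  expect_equal(unname(r2["r_aSys_aDias"]), 2)
})

test_that("duration features: averages, ratios, count", {
  mk <- function(k0) data.frame(start = k0 + c(0, 200, 800, 960),
                                end = k0 + c(200, 800, 960, 2000),
                                label = c("S1", "systole", "S2", "diastole"))
  d <- do.call(rbind, lapply(0:2 * 2000, mk))
  seg <- phase_segmentation(d$start, d$end, d$label)
  dur <- duration_features(seg, 2000)
  expect_length(dur, 15)
  expect_equal(unname(dur["dur_aS1"]), 0.1)
  expect_equal(unname(dur["dur_aSys"]), 0.3)
  expect_equal(unname(dur["dur_aRR"]), 1.0)
  # S2 = 0.08 s, systole = 0.3 s -> ratio oracle by direct division
  expect_equal(unname(dur["dur_r_S2_Sys"]), 0.08 / 0.3)
})

test_that("shape features: self-correlation, symmetry, opposite ramps", {
  seg <- phase_segmentation(c(0, 200, 800, 960), c(200, 800, 960, 2000),
                            c("S1", "systole", "S2", "diastole"))
  n_sys <- 600
  env <- numeric(2000)
  env[201:800] <- seq(0, 1, length.out = n_sys)        # crescendo in systole
  sf <- shape_features(env, seg, 2000)
  expect_length(sf, 8)
  expect_equal(unname(sf["shape_crescendo_sys"]), 1, tolerance = 1e-6)
  # crescendo vs decrescendo templates: closed-form correlation of two
  # opposite mean-centered ramps is exactly -1
  expect_equal(unname(sf["shape_decrescendo_sys"]), -1, tolerance = 1e-6)
  # diamond template is symmetric under time reversal
  env_d <- numeric(2000)
  env_d[201:800] <- murmur_shape_template("diamond", n_sys)
  f_fwd <- shape_features(env_d, seg, 2000)
  env_r <- env_d; env_r[201:800] <- rev(env_d[201:800])
  f_rev <- shape_features(env_r, seg, 2000)
  expect_equal(f_fwd["shape_diamond_sys"], f_rev["shape_diamond_sys"],
               tolerance = 1e-9)
  expect_true(all(abs(sf[!is.na(sf)]) <= 1 + 1e-9))
})

test_that("demographic features handle missing values with NA sentinels", {
  d <- demographic_record(age = 24, sex = "female", weight = 20, height = 100)
  f <- demographic_features(d)
  expect_length(f, 5)
  expect_equal(unname(f["weight_height"]), 0.2)
  expect_equal(unname(f["sex"]), 0)
  d2 <- demographic_record(age = 24, sex = "male", weight = 20)
  f2 <- demographic_features(d2)
  expect_true(is.na(f2["height"]))
  expect_true(is.na(f2["weight_height"]))
  expect_equal(unname(f2["sex"]), 1)
})

test_that("extraction yields exactly 622 deterministic named features", {
  rec <- fix_murmur_rec()
  x <- pcg_bandpass(rec$samples, rec$rate)
  fv <- extract_features(x, rec$rate, rec$demographics,
                         segmentation = rec$segmentation)
  expect_length(fv, 622)
  expect_identical(names(fv), feature_names())
  # block structure: 5 + 15 + 594 + 8
  expect_length(grep("^t\\d+_", names(fv)), 594)
  expect_length(grep("^dur_", names(fv)), 15)
  expect_length(grep("^shape_", names(fv)), 8)
  fv2 <- extract_features(x, rec$rate, rec$demographics,
                          segmentation = rec$segmentation)
  expect_identical(fv, fv2)
})

test_that("ratio features are invariant to global amplitude scaling", {
  rec <- fix_murmur_rec()
  x <- pcg_bandpass(rec$samples, rec$rate)
  f1 <- extract_features(x, rec$rate, rec$demographics,
                         segmentation = rec$segmentation)
  f10 <- extract_features(10 * x, rec$rate, rec$demographics,
                          segmentation = rec$segmentation)
  ratio_cols <- grep("_r_", names(f1), value = TRUE)
  expect_equal(f1[ratio_cols], f10[ratio_cols], tolerance = 1e-6)
})

test_that("systolic murmurs raise the HF systole/diastole envelope ratio", {
  # sign consistency with the positive correlation of this feature
  vals <- vapply(c(31, 32, 33), function(s) {
    rec <- synth_recording(sim_config(duration = 10, murmur_present = TRUE,
                                      murmur_snr = 6, seed = s))
    twin <- synth_recording(sim_config(duration = 10, murmur_present = FALSE,
                                       seed = s))
    f_m <- extract_features(pcg_bandpass(rec$samples, 2000), 2000,
                            rec$demographics, segmentation = rec$segmentation)
    f_c <- extract_features(pcg_bandpass(twin$samples, 2000), 2000,
                            twin$demographics,
                            segmentation = twin$segmentation)
    f_m[["t9_r_aSys_aDias"]] - f_c[["t9_r_aSys_aDias"]]
  }, numeric(1))
  expect_true(all(vals > 0))
})

test_that("importance selection returns top-k plus age and weight", {
  set.seed(41)
  n <- 120
  X <- matrix(stats::rnorm(n * 622), n, 622,
              dimnames = list(NULL, feature_names()))
  y <- rep(0:1, each = n / 2)
  # plant one informative column (equal to the label plus small noise)
  X[, "t9_r_aSys_aDias"] <- y + stats::rnorm(n, 0, 0.4)
  # 30 further informative columns so the top-20 all carry positive gain
  info <- grep("^t1[0-7]_a", feature_names(), value = TRUE)[1:30]
  for (k in seq_along(info))
    X[, info[k]] <- y + stats::rnorm(n, 0, 0.6 + 0.05 * k)
  X[, "t1_a"] <- 3.14  # constant feature
  sel <- rank_and_select(X, y, k = 20, seed = 2)
  expect_length(sel$selected, 22)
  expect_identical(sel$ranking$feature[1], "t9_r_aSys_aDias")
  expect_equal(sel$ranking$importance[sel$ranking$feature == "t1_a"], 0)
  expect_true(all(c("age", "weight") %in% sel$selected))
  # deterministic under the seed
  sel2 <- rank_and_select(X, y, k = 20, seed = 2)
  expect_identical(sel$ranking, sel2$ranking)
  expect_error(rank_and_select(X, rep(1, n)), "classes")
})
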