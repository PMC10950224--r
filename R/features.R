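# Explainable handcrafted features: 18 signal transformations, region
# statistics over the heart phases, their ratios, duration features, murmur
# shape-template correlations and demographics — 622 features in total,
# reduced to 22 by gradient-boosted feature importance.
#
# Layout: 5 demographic + 15 duration + (3 + 15 + 15) x 18 = 594
# time-frequency + 8 shape = 622.

FEATURE_BANDS <- list(LF = c(15, 90), MF = c(55, 150), HF = c(100, 250),
                      SF = c(200, 450), UF = c(400, 800))

REGION_ORDER <- c("S1", "S2", "Sys", "Dias", "RR")

#' The 18-entry signal transformation registry
#'
#' t1 = rectified amplitude, t2 = full-band Hilbert envelope, t3 = spectral
#' centroid, t4 = spectral bandwidth, t5 = zero-crossing rate, t6 = windowed
#' signal energy (13 ms), t7..t11 = LF/MF/HF/SF/UF band envelopes
#' (15-90 / 55-150 / 100-250 / 200-450 / 400-800 Hz), t12..t18 = envelope
#' ratio signals HF/LF, HF/MF, MF/LF, SF/MF, SF/LF, UF/LF, (HF+MF)/LF.
#'
#' @return data.frame with `name` and `description` (18 rows).
#' @export
transformation_registry <- function() {
  data.frame(
    name = paste0("t", 1:18),
    description = c(
      "rectified amplitude", "Hilbert envelope",
      "spectral centroid (13 ms frames)", "spectral bandwidth (13 ms frames)",
      "zero-crossing rate (13 ms frames)", "windowed energy (13 ms frames)",
      "LF envelope (15-90 Hz)", "MF envelope (55-150 Hz)",
      "HF envelope (100-250 Hz)", "SF envelope (200-450 Hz)",
      "UF envelope (400-800 Hz)",
      "HF/LF envelope ratio", "HF/MF envelope ratio", "MF/LF envelope ratio",
      "SF/MF envelope ratio", "SF/LF envelope ratio", "UF/LF envelope ratio",
      "(HF+MF)/LF envelope ratio"),
    stringsAsFactors = FALSE)
}

# framewise short-time features, interpolated back to signal length
frame_feature <- function(x, rate, frame_s = 0.013,
                          kind = c("centroid", "bandwidth", "zcr", "energy")) {
  kind <- match.arg(kind)
  n <- length(x)
  w <- max(4L, round(frame_s * rate))
  hop <- max(1L, w %/% 2L)
  starts <- seq(1L, max(1L, n - w + 1L), by = hop)
  freqs <- (0:(w %/% 2L)) * rate / w
  vals <- vapply(starts, function(s) {
    fr <- x[s:min(s + w - 1L, n)]
    if (kind == "energy") return(mean(fr^2))
    if (kind == "zcr") {
      if (length(fr) < 2L) return(0)
      return(sum(abs(diff(sign(fr))) > 0) / (length(fr) / rate))
    }
    mag <- Mod(stats::fft(fr))[seq_along(freqs)][seq_len(min(length(freqs),
                                                             length(fr)))]
    tot <- sum(mag)
    if (tot < EPS_RATIO) return(0)
    ctr <- sum(freqs[seq_along(mag)] * mag) / tot
    if (kind == "centroid") ctr
    else sqrt(sum((freqs[seq_along(mag)] - ctr)^2 * mag) / tot)
  }, numeric(1))
  centers <- pmin(starts + (w - 1L) / 2, n)
  if (length(vals) == 1L) return(rep(vals, n))
  stats::approx(centers, vals, xout = seq_len(n), rule = 2)$y
}

#' Compute the 18 signal transformations
#'
#' @param samples preprocessed signal (>= 1 s).
#' @param rate sampling rate, Hz.
#' @return named list of 18 numeric vectors, each the length of `samples`,
#'   in registry order ([transformation_registry()]).
#' @export
compute_transformations <- function(samples, rate) {
  stopifnot(length(samples) >= rate)
  env <- lapply(FEATURE_BANDS, function(b)
    band_envelope(samples, rate, c(b[1], min(b[2], rate / 2 - 1))))
  rat <- function(a, b) a / pmax(b, EPS_RATIO)
  out <- list(
    t1 = abs(samples),
    t2 = hilbert_envelope(samples),
    t3 = frame_feature(samples, rate, kind = "centroid"),
    t4 = frame_feature(samples, rate, kind = "bandwidth"),
    t5 = frame_feature(samples, rate, kind = "zcr"),
    t6 = frame_feature(samples, rate, kind = "energy"),
    t7 = env$LF, t8 = env$MF, t9 = env$HF, t10 = env$SF, t11 = env$UF,
    t12 = rat(env$HF, env$LF), t13 = rat(env$HF, env$MF),
    t14 = rat(env$MF, env$LF), t15 = rat(env$SF, env$MF),
    t16 = rat(env$SF, env$LF), t17 = rat(env$UF, env$LF),
    t18 = rat(env$HF + env$MF, env$LF))
  out
}

# per-cycle region index lists for S1/S2/Sys/Dias/RR
region_indices <- function(segmentation) {
  cyc <- cycles(segmentation)
  if (!length(cyc)) stop("no complete heart cycle in segmentation")
  lab_map <- c(S1 = "S1", systole = "Sys", S2 = "S2", diastole = "Dias")
  per_cycle <- lapply(cyc, function(cy) {
    idx <- stats::setNames(vector("list", 5), REGION_ORDER)
    for (r in seq_len(nrow(cy)))
      idx[[lab_map[[cy$label[r]]]]] <- (cy$start[r] + 1L):cy$end[r]
    idx$RR <- (min(cy$start) + 1L):max(cy$end)
    idx
  })
  per_cycle
}

#' Region statistics of a transformed signal
#'
#' Mean, standard deviation and maximum over the whole signal and over each
#' of S1, S2, systole, diastole and the full heart cycle (RR). Phase
#' statistics are computed per cycle occurrence and averaged across cycles.
#'
#' @param tsignal numeric vector (one transformation of the signal).
#' @param segmentation a [phase_segmentation()] with >= 1 complete cycle.
#' @return named numeric vector of 18 values: `a`, `s`, `m` (whole signal)
#'   then `aS1`, `sS1`, `mS1`, ..., `aRR`, `sRR`, `mRR`.
#' @export
region_stats <- function(tsignal, segmentation) {
  per_cycle <- region_indices(segmentation)
  out <- c(a = mean(tsignal), s = stats::sd(tsignal), m = max(tsignal))
  for (reg in REGION_ORDER) {
    st <- vapply(per_cycle, function(pc) {
      v <- tsignal[pc[[reg]]]
      c(mean(v), stats::sd(v), max(v))
    }, numeric(3))
    st[is.na(st)] <- 0  # sd of a length-1 region
    out[paste0(c("a", "s", "m"), reg)] <- rowMeans(st)
  }
  out
}

#' Ratios of region statistics
#'
#' The fixed 15-ratio list per transformation: 6 mean ratios of phase pairs
#' (S1/S2, S1/Sys, S1/Dias, S2/Sys, S2/Dias, Sys/Dias), 4 mean ratios of
#' phase to full cycle (S1/RR, S2/RR, Sys/RR, Dias/RR) and 5 std-to-mean
#' ratios (one per region, RR included).
#'
#' @param stats18 output of [region_stats()].
#' @return named numeric vector of 15 ratio values.
#' @export
stat_ratios <- function(stats18) {
  rt <- function(num, den) stats18[[num]] / max(stats18[[den]], EPS_RATIO)
  pairs <- list(c("S1", "S2"), c("S1", "Sys"), c("S1", "Dias"),
                c("S2", "Sys"), c("S2", "Dias"), c("Sys", "Dias"))
  out <- numeric(0)
  for (p in pairs)
    out[paste0("r_a", p[1], "_a", p[2])] <- rt(paste0("a", p[1]),
                                               paste0("a", p[2]))
  for (r in c("S1", "S2", "Sys", "Dias"))
    out[paste0("r_a", r, "_aRR")] <- rt(paste0("a", r), "aRR")
  for (r in REGION_ORDER)
    out[paste0("r_s", r, "_a", r)] <- rt(paste0("s", r), paste0("a", r))
  out
}

#' Heart-phase duration features
#'
#' Average durations (seconds) of S1, S2, systole, diastole and the full
#' cycle, plus all 10 pairwise duration ratios in fixed orientation
#' (earlier region in `S1, S2, Sys, Dias, RR` order divided by the later).
#'
#' @param segmentation a [phase_segmentation()] with >= 1 complete cycle.
#' @param rate sampling rate, Hz.
#' @return named numeric vector of 15 values (`dur_aS1` ... `dur_r_Dias_RR`).
#' @export
duration_features <- function(segmentation, rate) {
  per_cycle <- region_indices(segmentation)
  durs <- vapply(REGION_ORDER, function(reg)
    mean(vapply(per_cycle, function(pc) length(pc[[reg]]) / rate,
                numeric(1))), numeric(1))
  out <- stats::setNames(durs, paste0("dur_a", REGION_ORDER))
  for (i in 1:4) for (j in (i + 1):5) {
    out[paste0("dur_r_", REGION_ORDER[i], "_", REGION_ORDER[j])] <-
      durs[i] / max(durs[j], EPS_RATIO)
  }
  out
}

#' Murmur shape features
#'
#' For each phase (systole, diastole) and each murmur shape template
#' (diamond, plateau, crescendo, decrescendo): the normalized cross-
#' correlation between the cycle-averaged phase envelope (each occurrence
#' resampled to the phase's average duration) and the template, both
#' mean-centered. Values lie in \[-1, 1\].
#'
#' @param envelope full-band Hilbert envelope of the signal.
#' @param segmentation a [phase_segmentation()] with >= 1 complete cycle.
#' @param rate sampling rate, Hz.
#' @return named numeric vector of 8 values (`shape_diamond_sys`, ...,
#'   `shape_decrescendo_dias`); `NA` when a phase is absent.
#' @export
shape_features <- function(envelope, segmentation, rate) {
  per_cycle <- region_indices(segmentation)
  out <- numeric(0)
  for (ph in c("Sys", "Dias")) {
    lens <- vapply(per_cycle, function(pc) length(pc[[ph]]), integer(1))
    nm <- paste0("shape_", MURMUR_SHAPES, "_", tolower(ph))
    if (!any(lens > 3)) { out[nm] <- NA_real_; next }
    target <- max(4L, round(mean(lens[lens > 3])))
    curves <- vapply(per_cycle[lens > 3], function(pc) {
      v <- envelope[pc[[ph]]]
      stats::approx(seq_along(v), v, xout = seq(1, length(v),
                                                length.out = target))$y
    }, numeric(target))
    avg <- rowMeans(curves)
    a <- avg - mean(avg)
    for (k in seq_along(MURMUR_SHAPES)) {
      tmpl <- murmur_shape_template(MURMUR_SHAPES[k], target)
      b <- tmpl - mean(tmpl)
      denom <- sqrt(sum(a^2) * sum(b^2))
      out[nm[k]] <- if (denom < EPS_RATIO) 0 else sum(a * b) / denom
    }
  }
  out
}

#' Demographic features
#'
#' @param record a [demographic_record()].
#' @return named numeric vector: `age` (months), `sex` (0 = female,
#'   1 = male), `weight` (kg), `height` (cm), `weight_height` (kg/cm);
#'   missing inputs propagate as `NA`, never as silent zeros.
#' @export
demographic_features <- function(record) {
  sex_num <- if (is.na(record$sex)) NA_real_
             else as.numeric(record$sex == "male")
  c(age = as.numeric(record$age), sex = sex_num,
    weight = as.numeric(record$weight), height = as.numeric(record$height),
    weight_height = as.numeric(record$weight) /
      ifelse(is.na(record$height) || record$height <= 0, NA_real_,
             record$height))
}

#' Canonical names of the 622 features, in extraction order
#' @return character vector of length 622.
#' @export
feature_names <- function() {
  stat_nm <- c("a", "s", "m",
               unlist(lapply(REGION_ORDER, function(r) paste0(c("a", "s", "m"), r))))
  pairs <- list(c("S1", "S2"), c("S1", "Sys"), c("S1", "Dias"),
                c("S2", "Sys"), c("S2", "Dias"), c("Sys", "Dias"))
  ratio_nm <- c(vapply(pairs, function(p) paste0("r_a", p[1], "_a", p[2]), ""),
                paste0("r_a", c("S1", "S2", "Sys", "Dias"), "_aRR"),
                paste0("r_s", REGION_ORDER, "_a", REGION_ORDER))
  dur_pairs <- character(0)
  for (i in 1:4) for (j in (i + 1):5)
    dur_pairs <- c(dur_pairs,
                   paste0("dur_r_", REGION_ORDER[i], "_", REGION_ORDER[j]))
  c(c("age", "sex", "weight", "height", "weight_height"),
    c(paste0("dur_a", REGION_ORDER), dur_pairs),
    unlist(lapply(paste0("t", 1:18), function(t)
      paste0(t, "_", c(stat_nm, ratio_nm)))),
    paste0("shape_", rep(MURMUR_SHAPES, 2), "_",
           rep(c("sys", "dias"), each = 4)))
}

#' Extract the full 622-feature vector from one recording
#'
#' The feature-specific conditioning chain is applied first: despiking,
#' duration-dependent edge clipping, and envelope-threshold clipping
#' (Eq.-style `mean + g_th * sd` rule); a supplied reference segmentation is
#' cropped and re-indexed to the clipped window, otherwise the signal is
#' segmented with [segment_phases()].
#'
#' @param samples preprocessed signal at `rate` (band-passed, target rate).
#' @param rate sampling rate, Hz.
#' @param demographics a [demographic_record()].
#' @param segmentation optional reference [phase_segmentation()] aligned
#'   with `samples`.
#' @param g_th envelope clipping gain.
#' @return named numeric vector of exactly 622 features.
#' @export
extract_features <- function(samples, rate, demographics = demographic_record(),
                             segmentation = NULL, g_th = 2.7) {
  x0 <- despike(samples, rate)
  x1 <- clip_edges(x0, rate)
  off1 <- (length(x0) - length(x1)) %/% 2L
  x2 <- clip_by_envelope(x1, rate, g_th)
  # locate x2 inside x1 (clip_by_envelope returns a contiguous run)
  off2 <- find_subsequence_offset(x1, x2)
  offset <- off1 + off2
  seg <- if (is.null(segmentation)) segment_phases(x2, rate)
         else crop_segmentation(segmentation, offset, offset + length(x2))
  if (!length(cycles(seg)))
    stop("recording unusable: no complete heart cycle after clipping")
  trans <- compute_transformations(x2, rate)
  tf <- unlist(lapply(names(trans), function(tn) {
    st <- region_stats(trans[[tn]], seg)
    v <- c(st, stat_ratios(st))
    stats::setNames(v, paste0(tn, "_", names(v)))
  }))
  out <- c(demographic_features(demographics),
           duration_features(seg, rate),
           tf,
           shape_features(trans$t2, seg, rate))
  stopifnot(length(out) == 622L)
  out
}

find_subsequence_offset <- function(x, sub) {
  if (length(sub) == length(x)) return(0L)
  cand <- which(x == sub[1])
  for (s in cand) {
    if (s + length(sub) - 1L <= length(x) &&
        isTRUE(all.equal(x[s:(s + length(sub) - 1L)], sub)))
      return(s - 1L)
  }
  0L
}

# crop a segmentation to [start, end) (0-based sample window) and re-index
crop_segmentation <- function(seg, start, end) {
  s <- pmax(seg$start, start) - start
  e <- pmin(seg$end, end) - start
  keep <- e > s & seg$end > start & seg$start < end
  # partially cut intervals at the window edge become unlabeled to avoid
  # breaking the cyclic order with truncated phases
  lab <- seg$label
  cut_part <- (seg$start < start | seg$end > end) & keep
  lab[cut_part] <- "unlabeled"
  drop_dupes <- keep
  phase_segmentation(s[drop_dupes], e[drop_dupes], lab[drop_dupes],
                     n_samples = end - start)
}

#' Rank features by gradient-boosted importance and select the top set
#'
#' Fits a gradient-boosted tree ensemble (xgboost) on the binary murmur
#' task, ranks all features by gain importance, and selects the `k` most
#' important plus `age` and `weight` (kept for the outcome task regardless
#' of their murmur importance). Features the ensemble never splits on all
#' carry zero gain; those ties are broken by the absolute point-biserial
#' correlation with the label (importance metrics and correlation analysis
#' together), so the selection stays informative even when a single strong
#' feature saturates the trees.
#'
#' @param feature_table numeric matrix or data.frame, rows = recordings,
#'   columns = features (named).
#' @param labels binary murmur labels (1 = present), length `nrow`.
#' @param k number of top features to keep (default 20).
#' @param always_keep features appended to the selection regardless of rank.
#' @param nrounds,max_depth,eta xgboost hyperparameters.
#' @param seed RNG seed (xgboost made single-threaded and deterministic).
#' @return a `feature_selection`: list with `ranking` (data.frame feature /
#'   importance / rank) and `selected` (character vector).
#' @export
rank_and_select <- function(feature_table, labels, k = 20,
                            always_keep = c("age", "weight"),
                            nrounds = 60, max_depth = 3, eta = 0.2,
                            seed = 1L) {
  X <- as.matrix(feature_table)
  stopifnot(nrow(X) == length(labels))
  y <- as.numeric(labels)
  if (length(unique(y)) < 2) stop("need both classes for feature selection")
  with_seed(seed, {
    bst <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = max_depth,
                    eta = eta, nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
      nrounds = nrounds)
    imp <- xgboost::xgb.importance(model = bst)
  })
  importance <- stats::setNames(rep(0, ncol(X)), colnames(X))
  importance[imp$Feature] <- imp$Gain
  abs_cor <- suppressWarnings(abs(apply(X, 2, stats::cor, y = y,
                                        use = "complete.obs")))
  abs_cor[!is.finite(abs_cor)] <- 0
  ord <- order(importance, abs_cor, decreasing = TRUE)
  ranking <- data.frame(feature = colnames(X)[ord],
                        importance = unname(importance[ord]),
                        abs_correlation = unname(abs_cor[ord]),
                        rank = seq_len(ncol(X)), stringsAsFactors = FALSE)
  selected <- union(ranking$feature[seq_len(min(k, nrow(ranking)))],
                    intersect(always_keep, colnames(X)))
  structure(list(ranking = ranking, selected = selected, k = k),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf("Feature selection: %d features selected (top %d + kept)\n",
              length(x$selected), x$k))
  print(utils::head(x$ranking, 10))
  invisible(x)
}
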