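# End-to-end orchestration: patient-level stratified cross-validation
# utilities, the murmurness explanation runner, and the two-stage pipeline
# (handcrafted features + selection -> PANN -> patient-level multitask
# classifier).

#' Stratified patient-level folds
#'
#' @param labels per-patient stratification labels.
#' @param k number of folds.
#' @param seed RNG seed (fixed seed gives identical folds).
#' @return integer fold assignment (1..k) per patient; within each label
#'   class, patients are spread round-robin over shuffled folds.
#' @export
patient_folds <- function(labels, k = 10, seed = 1L) {
  stopifnot(k >= 2, length(labels) >= k)
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      fold[idx] <- rep_len(sample(k), length(idx))
    }
    fold
  })
}

#' Patient-level cross-validation
#'
#' Splits patients into stratified folds (no patient appears in two folds)
#' and calls `fit_predict(train_idx, test_idx)` per fold, which must return
#' a named numeric vector of metrics. If a fold's training portion misses a
#' class, the split is resampled with a warning (fresh seed offset).
#'
#' @param labels per-patient stratification labels (murmur label).
#' @param fit_predict function(train_idx, test_idx) -> named numeric.
#' @param k folds (default 10).
#' @param seed RNG seed.
#' @param max_resample resampling attempts for degenerate splits.
#' @return a `murmur_cv` list: `per_fold` (data.frame, one row per fold)
#'   and `aggregate` (mean and sd per metric).
#' @export
cross_validate <- function(labels, fit_predict, k = 10, seed = 1L,
                           max_resample = 10) {
  for (attempt in seq_len(max_resample)) {
    fold <- patient_folds(labels, k, seed + attempt - 1L)
    ok <- all(vapply(seq_len(k), function(f)
      length(unique(labels[fold != f])) == length(unique(labels)),
      logical(1)))
    if (ok) break
    warning("class absent from a fold's training portion; resampling split")
  }
  rows <- lapply(seq_len(k), function(f) {
    m <- fit_predict(which(fold != f), which(fold == f))
    as.data.frame(as.list(m))
  })
  per_fold <- do.call(rbind, rows)
  per_fold$fold <- seq_len(k)
  agg <- data.frame(
    metric = setdiff(names(per_fold), "fold"),
    mean = vapply(setdiff(names(per_fold), "fold"),
                  function(m) mean(per_fold[[m]]), numeric(1)),
    sd = vapply(setdiff(names(per_fold), "fold"),
                function(m) stats::sd(per_fold[[m]]), numeric(1)),
    row.names = NULL)
  structure(list(per_fold = per_fold, aggregate = agg, folds = fold),
            class = "murmur_cv")
}

#' @export
print.murmur_cv <- function(x, ...) {
  cat(sprintf("Patient-level cross-validation (%d folds)\n",
              nrow(x$per_fold)))
  print(x$aggregate)
  invisible(x)
}

#' Explain one recording with a trained MIL U-Net
#'
#' Produces the murmurness trace, the postprocessed murmur segments, and
#' (when a segmentation is available) the per-phase precision report.
#'
#' @param model a trained `mil_unet`.
#' @param samples recording (preprocessed; `wav` alternative below).
#' @param rate sampling rate, Hz.
#' @param segmentation optional [phase_segmentation()]; when `NULL`,
#'   precision entries are omitted.
#' @param wav,tsv optional file paths read with [read_wav()] /
#'   [read_segmentation_tsv()] instead of `samples` / `segmentation`.
#' @param threshold,merge_ms postprocessing parameters.
#' @param input_gain gain applied before the network (the training-time
#'   global gain).
#' @return list with `trace`, `segments`, and per-phase `precision`
#'   (systolic/diastolic) plus `pseudo` when a segmentation is present.
#' @export
run_explain <- function(model, samples = NULL, rate = 2000,
                        segmentation = NULL, wav = NULL, tsv = NULL,
                        threshold = 0.6, merge_ms = 60, input_gain = 4) {
  if (!is.null(wav)) {
    w <- read_wav(wav)
    samples <- resample_linear(w$samples, w$rate, rate)
    samples <- pcg_bandpass(samples, rate)
  }
  stopifnot(!is.null(samples))
  if (!is.null(tsv)) segmentation <- read_segmentation_tsv(tsv, rate)
  trace <- murmurness(model, input_gain * samples)
  segments <- postprocess_trace(trace, rate, threshold, merge_ms)
  out <- list(trace = trace, segments = segments)
  if (!is.null(segmentation)) {
    out$precision <- list(
      systolic = phase_precision(segments, segmentation, "systolic"),
      diastolic = phase_precision(segments, segmentation, "diastolic"))
    out$pseudo <- pseudo_precision(segments, segmentation)
  }
  out
}

#' Plot a murmurness explanation
#'
#' @param x output of [run_explain()].
#' @param samples the recording (for the waveform panel).
#' @param rate sampling rate, Hz.
#' @param ... passed to [graphics::plot()].
#' @export
plot_explanation <- function(x, samples, rate = 2000, ...) {
  old <- graphics::par(mfrow = c(2, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(old))
  t <- seq_along(samples) / rate
  graphics::plot(t, samples, type = "l", col = "steelblue",
                 ylab = "amplitude", xlab = "", ...)
  if (nrow(x$segments)) {
    for (i in seq_len(nrow(x$segments)))
      graphics::rect(x$segments$start[i] / rate, min(samples),
                     x$segments$end[i] / rate, max(samples),
                     col = grDevices::adjustcolor("red", 0.25), border = NA)
  }
  graphics::plot(t, x$trace, type = "l", ylim = c(0, 1),
                 ylab = "murmurness", xlab = "time (s)")
  graphics::abline(h = 0.6, lty = 2)
  invisible(x)
}

# recording-level 3-class label per the stage-1 rule: Unknown patients give
# Unknown recordings; otherwise Present where hearable, else Absent
recording_labels <- function(patient) {
  vapply(patient$recordings, function(r) {
    if (identical(patient$murmur_label, "Unknown")) "Unknown"
    else r$murmur_label
  }, character(1))
}

#' Run the full two-stage murmur pipeline on a cohort
#'
#' Preprocesses every recording (band-pass at the working rate), extracts
#' the 622 handcrafted features (reference segmentations), selects 22 by
#' gradient-boosted importance on recording-level binary murmur labels
#' (Unknown recordings excluded from selection), trains the PANN on 3-class
#' recording labels, assembles patient-level feature vectors, and trains
#' the stage-2 multitask classifier.
#'
#' @param cohort output of [synth_cohort()] (training patients).
#' @param pann_cfg a [pann_config()].
#' @param stage2_cfg a [stage2_config()].
#' @param k_features number of top features to select.
#' @param seed RNG seed for every stage.
#' @param verbose print stage progress.
#' @return a `murmur_pipeline` list with `selection`, `pann`, `stage2`,
#'   and the training-cohort feature matrix.
#' @export
murmur_pipeline <- function(cohort, pann_cfg = pann_config(),
                            stage2_cfg = stage2_config(), k_features = 20,
                            seed = 1L, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  say("extracting features from %d patients", length(cohort))
  rec_rows <- pipeline_recording_table(cohort)
  say("selecting features (%d recordings)", nrow(rec_rows$features))
  keep <- rec_rows$labels3 != "Unknown"
  sel <- rank_and_select(rec_rows$features[keep, , drop = FALSE],
                         as.numeric(rec_rows$labels3[keep] == "Present"),
                         k = k_features, seed = seed)
  say("training PANN")
  pann <- train_pann(rec_rows$signals, rec_rows$labels3, rec_rows$locations,
                     config = pann_cfg, seed = seed, verbose = verbose)
  say("assembling patient features")
  X <- patient_feature_matrix(cohort, rec_rows, sel, pann)
  say("training stage 2")
  s2 <- train_stage2(X,
                     vapply(cohort, `[[`, "", "murmur_label"),
                     vapply(cohort, `[[`, "", "outcome_label"),
                     config = stage2_cfg, seed = seed, verbose = verbose)
  structure(list(selection = sel, pann = pann, stage2 = s2,
                 features = X, seed = seed),
            class = "murmur_pipeline")
}

# per-recording preprocessing + feature extraction for a cohort
pipeline_recording_table <- function(cohort) {
  signals <- list(); locations <- character(0); labels3 <- character(0)
  patient_of <- integer(0); feats <- list()
  for (pi in seq_along(cohort)) {
    p <- cohort[[pi]]
    labs <- recording_labels(p)
    for (ri in seq_along(p$recordings)) {
      rec <- p$recordings[[ri]]
      x <- pcg_bandpass(rec$samples, rec$rate)
      fv <- tryCatch(
        extract_features(x, rec$rate, rec$demographics,
                         segmentation = rec$segmentation),
        error = function(e) rep(NA_real_, 622))
      if (all(is.na(fv))) names(fv) <- feature_names()
      signals[[length(signals) + 1L]] <- x
      locations <- c(locations, rec$location)
      labels3 <- c(labels3, labs[ri])
      patient_of <- c(patient_of, pi)
      feats[[length(feats) + 1L]] <- fv
    }
  }
  features <- do.call(rbind, feats)
  list(signals = signals, locations = locations, labels3 = labels3,
       patient_of = patient_of, features = features)
}

# assemble the stage-2 matrix for every patient in a cohort
patient_feature_matrix <- function(cohort, rec_rows, selection, pann) {
  rows <- lapply(seq_along(cohort), function(pi) {
    idx <- which(rec_rows$patient_of == pi)
    ro <- lapply(idx, function(i) {
      list(features = rec_rows$features[i, ],
           pann = pann_features(pann, rec_rows$signals[[i]],
                                rec_rows$locations[i]),
           location = rec_rows$locations[i])
    })
    assemble_patient_features(ro, selection, cohort[[pi]]$demographics)
  })
  do.call(rbind, rows)
}

#' Predict murmur and outcome for new patients with a trained pipeline
#'
#' @param object a `murmur_pipeline`.
#' @param cohort list of patients (same structure as [synth_cohort()]).
#' @param ... unused.
#' @return the [predict.stage2()] result for the cohort.
#' @export
predict.murmur_pipeline <- function(object, cohort, ...) {
  rec_rows <- pipeline_recording_table(cohort)
  X <- patient_feature_matrix(cohort, rec_rows, object$selection,
                              object$pann)
  predict(object$stage2, X)
}

#' @export
print.murmur_pipeline <- function(x, ...) {
  cat("Two-stage murmur pipeline:\n")
  cat(sprintf("  selection: %d features\n", length(x$selection$selected)))
  print(x$pann)
  print(x$stage2)
  invisible(x)
}
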