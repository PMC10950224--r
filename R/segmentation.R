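# Heart-phase segmentation: the PhaseSegmentation container, the CirCor-style
# TSV dialect, and a simplified envelope-based segmenter standing in for the
# HSMM segmentation algorithms used on real data. All downstream features
# depend only on the container contract, so reference segmentations (when a
# dataset provides them) are interchangeable with the algorithmic ones.

PHASE_LEVELS <- c("S1", "systole", "S2", "diastole", "unlabeled")
PHASE_CODES <- c(unlabeled = 0L, S1 = 1L, systole = 2L, S2 = 3L, diastole = 4L)

#' Construct a phase segmentation
#'
#' Intervals are 0-based, half-open sample ranges `[start, end)`, sorted and
#' non-overlapping; labeled intervals must follow the cyclic order
#' S1 -> systole -> S2 -> diastole (unlabeled gaps are allowed anywhere).
#'
#' @param start,end integer vectors of interval bounds (samples).
#' @param label character vector over S1/systole/S2/diastole/unlabeled.
#' @param n_samples optional total signal length for bound checking.
#' @return an object of class `phase_segmentation` (a data.frame).
#' @export
phase_segmentation <- function(start = integer(0), end = integer(0),
                               label = character(0), n_samples = NULL) {
  stopifnot(length(start) == length(end), length(end) == length(label))
  start <- as.integer(start); end <- as.integer(end)
  label <- as.character(label)
  if (!all(label %in% PHASE_LEVELS))
    stop("unknown phase label(s): ", paste(setdiff(label, PHASE_LEVELS), collapse = ", "))
  if (any(end <= start)) stop("intervals must satisfy end > start")
  if (length(start) > 1) {
    o <- order(start)
    start <- start[o]; end <- end[o]; label <- label[o]
    if (any(start[-1] < end[-length(end)]))
      stop("intervals overlap")
  }
  if (any(start < 0)) stop("negative interval start")
  if (!is.null(n_samples) && length(end) && max(end) > n_samples)
    stop("interval exceeds signal length")
  lab <- label[label != "unlabeled"]
  if (length(lab) > 1) {
    nxt <- c(S1 = "systole", systole = "S2", S2 = "diastole", diastole = "S1")
    ok <- nxt[lab[-length(lab)]] == lab[-1]
    if (!all(ok))
      stop("labeled intervals break the S1->systole->S2->diastole cycle at index ",
           which(!ok)[1])
  }
  out <- data.frame(start = start, end = end, label = label,
                    stringsAsFactors = FALSE)
  class(out) <- c("phase_segmentation", "data.frame")
  attr(out, "n_samples") <- n_samples
  out
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat(sprintf("Phase segmentation: %d intervals, %d complete cycles\n",
              nrow(x), length(cycles(x))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat("...\n")
  invisible(x)
}

#' Read a CirCor-style segmentation TSV
#'
#' Three tab-separated columns: start seconds, end seconds, state code
#' (0 = unlabeled, 1 = S1, 2 = systole, 3 = S2, 4 = diastole). Seconds are
#' converted to samples with floor for starts and ceiling for ends.
#'
#' @param path TSV file path.
#' @param rate sampling rate in Hz used for the seconds-to-samples conversion.
#' @return a [phase_segmentation()].
#' @export
read_segmentation_tsv <- function(path, rate) {
  stopifnot(rate > 0)
  if (file.size(path) == 0)
    return(phase_segmentation())
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("start_s", "end_s", "code"))
  if (!nrow(d)) return(phase_segmentation())
  if (!all(d$code %in% PHASE_CODES))
    stop("unknown state code at row ", which(!d$code %in% PHASE_CODES)[1])
  bad <- which(diff(d$start_s) < 0)
  if (length(bad))
    stop("rows out of order starting at row ", bad[1] + 1L)
  ov <- which(d$start_s[-1] < d$end_s[-nrow(d)] - 1e-12)
  if (length(ov))
    stop("overlapping rows starting at row ", ov[1] + 1L)
  start <- as.integer(floor(d$start_s * rate))
  end <- as.integer(ceiling(d$end_s * rate))
  # ceiling can push an end one sample onto the next floor-ed start
  end <- pmin(end, c(start[-1], max(end)))
  keep <- end > start
  lab <- names(PHASE_CODES)[match(d$code, PHASE_CODES)]
  phase_segmentation(start[keep], end[keep], lab[keep])
}

#' Write a segmentation as a CirCor-style TSV
#'
#' @param seg a [phase_segmentation()].
#' @param rate sampling rate in Hz.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segmentation_tsv <- function(seg, rate, path) {
  codes <- PHASE_CODES[seg$label]
  utils::write.table(
    data.frame(sprintf("%.6f", seg$start / rate),
               sprintf("%.6f", seg$end / rate),
               codes),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a segmentation as JSON
#'
#' @param seg a [phase_segmentation()].
#' @param rate optional sampling rate; when given, seconds are included.
#' @param path optional output file.
#' @return JSON string (invisibly when written to `path`).
#' @export
segmentation_json <- function(seg, rate = NULL, path = NULL) {
  d <- as.data.frame(seg)
  if (!is.null(rate)) {
    d$start_s <- d$start / rate
    d$end_s <- d$end / rate
  }
  js <- jsonlite::toJSON(d, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Complete heart cycles of a segmentation
#'
#' @param seg a [phase_segmentation()].
#' @return list of complete cycles; each element is a data.frame with the four
#'   rows S1, systole, S2, diastole (in order). Partial leading/trailing cycles
#'   are dropped.
#' @export
cycles <- function(seg) {
  lab <- seg$label
  idx <- which(lab != "unlabeled")
  if (!length(idx)) return(list())
  out <- list()
  i <- 1L
  while (i + 3L <= length(idx)) {
    four <- idx[i:(i + 3L)]
    if (identical(lab[four], c("S1", "systole", "S2", "diastole"))) {
      out[[length(out) + 1L]] <- as.data.frame(seg[four, , drop = FALSE])
      i <- i + 4L
    } else {
      i <- i + 1L
    }
  }
  out
}

#' Envelope-based heart-phase segmentation
#'
#' A simplified segmenter: S1/S2 candidates are peaks of the smoothed
#' (50 ms) Hilbert envelope of the 25-150 Hz band; alternation is resolved
#' with the systole-shorter-than-diastole rule, and phase intervals are
#' derived from envelope threshold crossings around each detected sound.
#' Reference segmentations should be preferred when a dataset provides them.
#'
#' @param samples preprocessed signal at `rate` Hz.
#' @param rate sampling rate in Hz.
#' @param min_cycles minimum number of complete cycles required (default 3).
#' @return a [phase_segmentation()].
#' @export
segment_phases <- function(samples, rate, min_cycles = 3) {
  stopifnot(length(samples) > rate)  # need at least a second
  env <- smooth_ma(band_envelope(samples, rate, c(25, 150)), round(0.05 * rate))
  n <- length(env)
  # heart-cycle length from the envelope autocorrelation (40-220 bpm)
  e0 <- env - mean(env)
  lag_max <- min(n - 2L, round(60 / 40 * rate))
  ac <- stats::acf(e0, lag.max = lag_max, plot = FALSE)$acf[, 1, 1]
  lag_min <- round(60 / 220 * rate)
  if (lag_max <= lag_min + 2)
    stop("signal too short for cycle estimation")
  ac_win <- ac[(lag_min + 1):(lag_max + 1)]
  if (max(ac_win) < 0.15)
    stop("no cardiac periodicity detected; recording unusable")
  cyc_len <- lag_min - 1L + which.max(ac_win)
  # one primary peak per candidate cycle: greedy strongest-first,
  # >= 0.7 cycle apart
  thr <- 0.3 * stats::quantile(env, 0.999)
  primaries_for <- function(Tc) {
    min_gap <- round(0.7 * Tc)
    sel <- logical(n)
    for (p in order(env, decreasing = TRUE)) {
      if (env[p] < thr) break
      if (!any(sel[max(1, p - min_gap):min(n, p + min_gap)])) sel[p] <- TRUE
    }
    which(sel)
  }
  # The autocorrelation can lock onto the S1-S2 spacing (half cycle, most
  # likely when systole+S1 ~ diastole+S2) or onto two cycles. With a halved
  # estimate the primaries alternate S1/S2 and their heights vary strongly,
  # whereas true one-per-cycle primaries are all S1 with uniform heights:
  # score the candidate periods by primary-height variability and take the
  # smallest period among near-ties (more cycles, never skipping beats).
  ac_peak_in <- function(lo, hi) {
    hi <- min(hi, lag_max)
    if (hi <= lo || lo < lag_min) return(NULL)
    lo - 1L + which.max(ac[(lo + 1):(hi + 1)])
  }
  cands <- unique(c(cyc_len,
                    ac_peak_in(round(1.7 * cyc_len), round(2.3 * cyc_len)),
                    ac_peak_in(round(0.4 * cyc_len), round(0.6 * cyc_len))))
  prims <- lapply(cands, primaries_for)
  cvs <- vapply(prims, function(p) {
    if (length(p) < 3) Inf else stats::sd(env[p]) / mean(env[p])
  }, numeric(1))
  ok <- which(cvs <= min(cvs) + 0.05)
  pick <- ok[which.min(cands[ok])]
  cyc_len <- cands[pick]
  prim <- prims[[pick]]
  if (length(prim) < 2)
    stop("fewer than ", min_cycles, " heart cycles detected; recording unusable")
  # the other sound of each cycle: envelope maximum between primaries
  guard <- round(0.1 * rate)
  sec <- integer(0)
  for (i in seq_len(length(prim) - 1L)) {
    a <- prim[i] + guard; b <- prim[i + 1L] - guard
    if (b > a) sec <- c(sec, a - 1L + which.max(env[a:b]))
  }
  pk <- sort(c(prim, sec))
  if (length(pk) < 2 * min_cycles + 1)
    stop("fewer than ", min_cycles, " heart cycles detected; recording unusable")
  # alternation: gaps alternate short (systole) / long (diastole); the peak
  # before a short gap is S1
  gaps <- diff(pk)
  odd <- gaps[seq(1, length(gaps), by = 2)]
  even <- if (length(gaps) > 1) gaps[seq(2, length(gaps), by = 2)] else Inf
  first_is_s1 <- mean(odd) < mean(even)
  kind <- if (first_is_s1) rep(c("S1", "S2"), length.out = length(pk))
          else rep(c("S2", "S1"), length.out = length(pk))
  # sound extents: envelope above 25% of local peak, bounded to +-90 ms
  bound <- round(0.09 * rate)
  ext <- t(vapply(pk, function(p) {
    lo <- max(1L, p - bound); hi <- min(n, p + bound)
    seg <- env[lo:hi]
    above <- seg >= 0.25 * env[p]
    # contiguous run containing the peak
    runs <- true_runs(above)
    pc <- p - lo + 1L
    row <- runs[runs[, 1] <= pc & runs[, 2] >= pc, , drop = FALSE]
    as.integer(c(lo + row[1, 1] - 1L, lo + row[1, 2] - 1L))
  }, integer(2)))
  # keep extents disjoint: clamp to midpoints between adjacent peaks
  if (length(pk) > 1) {
    mids <- floor((pk[-length(pk)] + pk[-1]) / 2)
    ext[, 1] <- pmax(ext[, 1], c(1L, mids + 1L))
    ext[, 2] <- pmin(ext[, 2], c(mids, n))
    # guarantee a nonempty systole/diastole gap between consecutive sounds
    for (i in seq_len(length(pk) - 1L)) {
      if (ext[i + 1L, 1] - ext[i, 2] < 2L)
        ext[i, 2] <- max(ext[i, 1], ext[i + 1L, 1] - 2L)
    }
  }
  starts <- integer(0); ends <- integer(0); labs <- character(0)
  for (i in seq_along(pk)) {
    s <- ext[i, 1] - 1L; e <- ext[i, 2]   # to 0-based half-open
    starts <- c(starts, s); ends <- c(ends, e)
    labs <- c(labs, kind[i])
    if (i < length(pk)) {
      gap_lab <- if (kind[i] == "S1") "systole" else "diastole"
      gs <- e; ge <- ext[i + 1, 1] - 1L
      if (ge > gs) {
        starts <- c(starts, gs); ends <- c(ends, ge)
        labs <- c(labs, gap_lab)
      }
    }
  }
  seg <- phase_segmentation(starts, ends, labs, n_samples = length(samples))
  if (length(cycles(seg)) < min_cycles)
    stop("fewer than ", min_cycles, " complete cycles segmented; recording unusable")
  seg
}
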