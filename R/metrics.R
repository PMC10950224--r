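# Clinical challenge metrics: class-weighted murmur accuracy, the
# per-patient outcome cost with pluggable cost components, and standard
# binary/multiclass metrics (AUROC, AUPRC, F1, accuracy).

#' Murmur confusion matrix
#'
#' 3x3 counts `m[X, Y]` = number of patients predicted X with true label Y,
#' over (Present, Unknown, Absent).
#'
#' @param predicted,truth character vectors over Present/Unknown/Absent.
#' @return a `murmur_confusion` matrix (rows = predicted, cols = truth).
#' @export
murmur_confusion <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  m <- table(factor(predicted, levels = MURMUR_CLASSES),
             factor(truth, levels = MURMUR_CLASSES))
  m <- unclass(m)
  dimnames(m) <- list(predicted = MURMUR_CLASSES, truth = MURMUR_CLASSES)
  class(m) <- c("murmur_confusion", class(m))
  m
}

#' Class-weighted murmur accuracy
#'
#' `(5 m_PP + 3 m_UU + m_AA) / (5 n_P + 3 n_U + n_A)` where `m_XX` are the
#' correctly predicted counts and `n_X` the true-class totals: recall-style
#' accuracy weighting Present 5x and Unknown 3x relative to Absent.
#'
#' @param confusion a [murmur_confusion()] (or any 3x3 matrix ordered
#'   Present/Unknown/Absent, rows = predicted).
#' @param weights per-true-class weights (default `c(5, 3, 1)`).
#' @return scalar in \[0, 1\].
#' @export
weighted_accuracy <- function(confusion, weights = c(5, 3, 1)) {
  m <- unclass(confusion)
  stopifnot(is.matrix(m), nrow(m) == 3, ncol(m) == 3)
  if (sum(m) == 0) stop("empty confusion matrix")
  num <- sum(weights * diag(m))
  den <- sum(weights * colSums(m))
  if (den == 0) stop("no labeled examples in confusion matrix")
  num / den
}

#' Pluggable outcome cost components
#'
#' The four components of the screening cost: algorithmic processing,
#' expert review of algorithm-positive patients, treatment of true
#' positives, and missed diagnoses. The defaults are a simple linear cost
#' model (synthetic defaults for exercising the metric; the challenge's
#' published component definitions can be injected instead).
#'
#' @param c_algorithm function of `n_patients`.
#' @param c_expert function of (`n_screened`, `n_patients`).
#' @param c_treatment function of `n_tp`.
#' @param c_error function of `n_fn`.
#' @return a `cost_params` list of the four functions.
#' @export
cost_params <- function(
    c_algorithm = function(n_patients) 10 * n_patients,
    c_expert = function(n_screened, n_patients) 500 * n_screened,
    c_treatment = function(n_tp) 1000 * n_tp,
    c_error = function(n_fn) 10000 * n_fn) {
  structure(list(c_algorithm = c_algorithm, c_expert = c_expert,
                 c_treatment = c_treatment, c_error = c_error),
            class = "cost_params")
}

#' Outcome counts from binary decisions
#'
#' @param predicted,truth character vectors over Normal/Abnormal (Abnormal
#'   is the positive class).
#' @return an `outcome_counts` list with `n_tp`, `n_fp`, `n_fn`, `n_tn`,
#'   `n_patients`.
#' @export
outcome_counts <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth),
            all(predicted %in% c("Normal", "Abnormal")),
            all(truth %in% c("Normal", "Abnormal")))
  pos_p <- predicted == "Abnormal"; pos_t <- truth == "Abnormal"
  structure(list(n_tp = sum(pos_p & pos_t), n_fp = sum(pos_p & !pos_t),
                 n_fn = sum(!pos_p & pos_t), n_tn = sum(!pos_p & !pos_t),
                 n_patients = length(predicted)),
            class = "outcome_counts")
}

#' Mean outcome cost per patient
#'
#' `(c_algorithm(n_p) + c_expert(n_TP + n_FP, n_p) + c_treatment(n_TP) +
#' c_error(n_FN)) / n_p` with the supplied component functions.
#'
#' @param counts an [outcome_counts()] (or compatible list).
#' @param params a [cost_params()].
#' @return scalar mean cost per patient.
#' @export
outcome_cost <- function(counts, params = cost_params()) {
  n_p <- counts$n_patients
  stopifnot(n_p >= 1)
  (params$c_algorithm(n_p) +
     params$c_expert(counts$n_tp + counts$n_fp, n_p) +
     params$c_treatment(counts$n_tp) +
     params$c_error(counts$n_fn)) / n_p
}

#' Area under the ROC curve
#'
#' Rank-statistic (Mann-Whitney) form with ties averaged.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels (1/TRUE = positive).
#' @return AUROC in \[0, 1\]; `NA` when one class is absent.
#' @export
auroc <- function(scores, labels) {
  y <- as.logical(labels)
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step interpolation: precision is integrated over recall increments at
#' each distinct threshold (descending scores).
#'
#' @inheritParams auroc
#' @return AUPRC in \[0, 1\]; `NA` when no positive is present.
#' @export
auprc <- function(scores, labels) {
  y <- as.logical(labels)
  n_pos <- sum(y)
  if (n_pos == 0) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; ss <- scores[o]
  tp <- cumsum(ys); fp <- cumsum(!ys)
  keep <- c(diff(ss) != 0, TRUE)   # threshold boundaries at distinct scores
  tp <- tp[keep]; fp <- fp[keep]
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  sum(prec * diff(c(0, rec)))
}

#' F1 score
#'
#' Binary F1 for two classes, macro-averaged F1 for more.
#'
#' @param predicted,truth label vectors (same level set).
#' @param positive positive class for the binary case (default: second
#'   sorted level).
#' @return F1 in \[0, 1\].
#' @export
f1_score <- function(predicted, truth, positive = NULL) {
  levs <- sort(unique(c(as.character(predicted), as.character(truth))))
  f1_one <- function(cls) {
    tp <- sum(predicted == cls & truth == cls)
    fp <- sum(predicted == cls & truth != cls)
    fn <- sum(predicted != cls & truth == cls)
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }
  if (length(levs) <= 2) {
    pos <- if (!is.null(positive)) positive else levs[length(levs)]
    f1_one(pos)
  } else {
    mean(vapply(levs, f1_one, numeric(1)))
  }
}

#' Standard classification metrics
#'
#' @param scores numeric scores for the positive class (binary) or a matrix
#'   of class probabilities (multiclass; AUROC/AUPRC computed one-vs-rest
#'   macro).
#' @param labels true labels: binary 0/1 for vector scores, class names
#'   matching `colnames(scores)` for a matrix.
#' @return list with `auroc`, `auprc`, `f1`, `accuracy`.
#' @export
standard_metrics <- function(scores, labels) {
  if (is.matrix(scores)) {
    cls <- colnames(scores)
    stopifnot(!is.null(cls), all(labels %in% cls))
    pred <- cls[apply(scores, 1, which.max)]
    aucs <- vapply(cls, function(c) auroc(scores[, c], labels == c), numeric(1))
    prcs <- vapply(cls, function(c) auprc(scores[, c], labels == c), numeric(1))
    list(auroc = mean(aucs, na.rm = TRUE), auprc = mean(prcs, na.rm = TRUE),
         f1 = f1_score(pred, labels), accuracy = mean(pred == labels))
  } else {
    y <- as.numeric(labels)
    pred <- as.numeric(scores >= 0.5)
    list(auroc = auroc(scores, y), auprc = auprc(scores, y),
         f1 = f1_score(pred, y, positive = "1"),
         accuracy = mean(pred == y))
  }
}
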