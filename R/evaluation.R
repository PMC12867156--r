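#' Youden-optimal classification threshold
#'
#' Candidate thresholds are the midpoints between consecutive distinct sorted
#' scores plus sentinels below the minimum and above the maximum; the
#' classification rule is `score > threshold` = positive. Among thresholds
#' maximizing Youden's J = TPR - FPR, the largest is returned (favoring
#' specificity).
#'
#' @inheritParams roc_auc
#' @return A `threshold_result` list: `threshold`, `youden_j`, `tpr`, `fpr`.
#' @export
youden_threshold <- function(scores, labels, pos_label = NULL) {
  if (!is.logical(labels)) {
    if (is.null(pos_label)) stop("supply pos_label for non-logical labels")
    labels <- labels == pos_label
  }
  if (sum(labels) == 0L || sum(!labels) == 0L)
    stop("need at least one sample of each class")
  su <- sort(unique(scores))
  cand <- c(su[1L] - 1, if (length(su) > 1L) (su[-length(su)] + su[-1L]) / 2,
            su[length(su)] + 1)
  tpr <- vapply(cand, function(t) mean(scores[labels] > t), numeric(1L))
  fpr <- vapply(cand, function(t) mean(scores[!labels] > t), numeric(1L))
  j <- tpr - fpr
  best <- which(j == max(j))
  best <- best[length(best)]  # largest threshold among ties
  structure(list(threshold = cand[best], youden_j = j[best],
                 tpr = tpr[best], fpr = fpr[best]),
            class = "threshold_result")
}

#' Leave-one-out cross-validated classification
#'
#' Each sample is held out in turn; the Youden-optimal threshold is fit on
#' the remaining samples and applied to the held-out score
#' (`score > threshold` = positive). Pooled held-out predictions give
#' precision, recall (sensitivity) and specificity; `mean_threshold` is the
#' arithmetic mean of the per-fold thresholds.
#'
#' @inheritParams roc_auc
#' @return A `loocv_result` list: `predictions` (logical), `precision`,
#'   `recall`, `specificity`, `mean_threshold`, `thresholds`.
#' @export
loo_cv <- function(scores, labels, pos_label = NULL) {
  if (!is.logical(labels)) {
    if (is.null(pos_label)) stop("supply pos_label for non-logical labels")
    labels <- labels == pos_label
  }
  n <- length(scores)
  stopifnot(n >= 3L, length(labels) == n)
  pred <- logical(n); thr <- numeric(n)
  for (i in seq_len(n)) {
    tr_lab <- labels[-i]
    if (sum(tr_lab) == 0L || sum(!tr_lab) == 0L)
      stop("fold ", i, ": training fold contains a single class")
    t_i <- youden_threshold(scores[-i], tr_lab)
    thr[i] <- t_i$threshold
    pred[i] <- scores[i] > t_i$threshold
  }
  tp <- sum(pred & labels); fp <- sum(pred & !labels)
  fn <- sum(!pred & labels); tn <- sum(!pred & !labels)
  structure(list(predictions = pred,
                 precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 recall = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 mean_threshold = mean(thr), thresholds = thr),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("<loocv_result> precision=%.3f recall=%.3f specificity=%.3f mean_threshold=%.3f\n",
              x$precision, x$recall, x$specificity, x$mean_threshold))
  invisible(x)
}

#' Consecutive-draw changes for longitudinal monitoring
#'
#' For every pair of consecutive plasma draws of a patient, computes the
#' percent change in the integrated score, `100 * (TIES1 - TIES0) / |TIES0|`,
#' and the absolute change in tumor fraction. Each pair carries the clinical
#' status of the interval (taken from the later draw). Pairs whose baseline
#' score is within `10 * eps` of 0 are excluded with a message (percent
#' change is undefined at a near-zero baseline).
#'
#' @param series data.frame with columns `patient_id`, `draw_date`, `ties`,
#'   `tumor_fraction`, `status` (one row per draw).
#' @param eps score floor used in [compute_ties()] (default `1e-6`).
#' @return data.table of draw pairs: patient_id, t0, t1, ties0, ties1,
#'   delta_ties (percent), delta_tf, status.
#' @export
consecutive_deltas <- function(series, eps = 1e-6) {
  need <- c("patient_id", "draw_date", "ties", "tumor_fraction", "status")
  miss <- setdiff(need, names(series))
  if (length(miss) > 0L)
    stop("series is missing column(s): ", paste(miss, collapse = ", "))
  dt <- as.data.table(series)[order(patient_id, draw_date)]
  pairs <- dt[, if (.N >= 2L) {
    i0 <- seq_len(.N - 1L); i1 <- i0 + 1L
    data.table(t0 = draw_date[i0], t1 = draw_date[i1],
               ties0 = ties[i0], ties1 = ties[i1],
               delta_tf = tumor_fraction[i1] - tumor_fraction[i0],
               status = status[i1])
  }, by = patient_id]
  if (nrow(pairs) == 0L) return(pairs)
  ok <- abs(pairs$ties0) >= 10 * eps
  if (any(!ok))
    message(sum(!ok), " draw pair(s) excluded: baseline score within 10*eps of 0")
  pairs <- pairs[ok]
  pairs[, delta_ties := 100 * (ties1 - ties0) / abs(ties0)]
  pairs[]
}

#' Two-group Wilcoxon rank-sum comparison
#'
#' Two-sided Wilcoxon rank-sum test: exact for small samples without ties,
#' normal approximation with tie and continuity correction otherwise.
#'
#' @param values_a,values_b nonempty numeric vectors.
#' @return List with `statistic` (rank-sum W) and `p_value`.
#' @export
group_compare <- function(values_a, values_b) {
  stopifnot(length(values_a) > 0L, length(values_b) > 0L)
  w <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                           alternative = "two.sided"))
  list(statistic = unname(w$statistic), p_value = w$p.value)
}
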