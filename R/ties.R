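#' Integrated epigenomic score from three component signals
#'
#' The integrated score is the logarithm of the summed, normalized signals at
#' the three cell-line-informed site sets (H3K4me3 up sites, H3K27ac up
#' sites, fusion-occupied TFBS), floored at `eps` before the log so that
#' all-background samples get a finite score.
#'
#' @param s_k4,s_k27,s_tfbs nonnegative component signals.
#' @param log_base base of the log transform (default `exp(1)`); any base is
#'   a strictly increasing transform, so AUC and threshold orderings do not
#'   depend on it.
#' @param eps floor applied to the sum before the log (default `1e-6`).
#' @return Scalar score, strictly increasing in each component above `eps`.
#' @export
compute_ties <- function(s_k4, s_k27, s_tfbs, log_base = exp(1), eps = 1e-6) {
  log(pmax(s_k4 + s_k27 + s_tfbs, eps), base = log_base)
}

#' Score one plasma sample against a signature bundle
#'
#' H3K4me3 fragments are quantified at the H3K4me3 up sites; H3K27ac
#' fragments at the H3K27ac up sites and (separately) at the deduplicated
#' fusion-occupied TFBS. Each mark's housekeeping reference is computed once
#' from that mark's fragments. The three normalized signals are summed and
#' log-transformed into the integrated score.
#'
#' @param sample list with elements `k4` and `k27` (each a `fragment_set` or
#'   `NULL`), and optionally `sample_id`.
#' @param bundle a [assemble_bundle()] result.
#' @param dhs housekeeping `site_set`.
#' @param allow_partial if `TRUE`, samples missing one assay are scored on
#'   the available components (missing components contribute 0, recorded as
#'   `NA` in the output) with a message; if `FALSE` (default) a missing assay
#'   is an error naming it.
#' @inheritParams dhs_reference
#' @inheritParams compute_ties
#' @return A one-row data.table: sample_id, s_k4, s_k27, s_tfbs, ties.
#' @export
score_sample <- function(sample, bundle, dhs, window = 3000, bin_width = 40,
                         shoulder_frac = 0.2, central_frac = 1/3,
                         log_base = exp(1), eps = 1e-6, allow_partial = FALSE) {
  stopifnot(inherits(bundle, "signature_bundle"))
  sid <- sample$sample_id %||% attr(sample$k4 %||% sample$k27, "sample_id")
  missing_marks <- c(if (is.null(sample$k4)) "H3K4me3",
                     if (is.null(sample$k27)) "H3K27ac")
  if (length(missing_marks) > 0L && !allow_partial)
    stop("sample ", sid, ": missing assay ", paste(missing_marks, collapse = ", "))
  if (length(missing_marks) > 0L)
    message("sample ", sid, ": scoring without ", paste(missing_marks, collapse = ", "))

  quant <- function(frags, sites_list) {
    ref <- dhs_reference(frags, dhs, window, bin_width, shoulder_frac, central_frac)
    pts <- midpoints(frags)
    vapply(sites_list, function(s) {
      p <- shoulder_normalize(aggregate_profile(s, pts, window, bin_width),
                              shoulder_frac, central_frac)
      p$central_signal / ref
    }, numeric(1L))
  }
  s_k4 <- if (is.null(sample$k4)) NA_real_ else
    quant(sample$k4, list(bundle$k4_up))
  k27_sig <- if (is.null(sample$k27)) c(NA_real_, NA_real_) else
    quant(sample$k27, list(bundle$k27_up, bundle$tfbs))
  comps <- c(s_k4, k27_sig)
  ties <- compute_ties(sum(comps[1], na.rm = TRUE),
                       sum(comps[2], na.rm = TRUE),
                       sum(comps[3], na.rm = TRUE),
                       log_base = log_base, eps = eps)
  data.table(sample_id = sid, s_k4 = comps[1], s_k27 = comps[2],
             s_tfbs = comps[3], ties = ties)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rank-based ROC curve and AUC
#'
#' The AUC is computed from ranks (equivalent to the Mann-Whitney U statistic
#' divided by `n_pos * n_neg`, ties counted 1/2); curve points are the
#' (FPR, TPR) pairs over all distinct score thresholds, including (0,0) and
#' (1,1).
#'
#' @param scores numeric scores (higher = more positive-like).
#' @param labels logical, or a vector coercible via `labels == pos_label`.
#' @param pos_label value of `labels` marking the positive class (ignored if
#'   `labels` is logical).
#' @return A `roc_result` list with `auc` and a data.table `points`.
#' @export
roc_auc <- function(scores, labels, pos_label = NULL) {
  if (!is.logical(labels)) {
    if (is.null(pos_label)) stop("supply pos_label for non-logical labels")
    labels <- labels == pos_label
  }
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) stop("need at least one sample of each class")
  r <- rank(scores)
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  keep <- c(diff(s) != 0, TRUE)  # last duplicate of each distinct score
  tpr <- cumsum(l)[keep] / n_pos
  fpr <- cumsum(!l)[keep] / n_neg
  pts <- data.table(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  structure(list(auc = auc, points = unique(pts)), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d curve points)\n",
              x$auc, nrow(x$points)))
  invisible(x)
}
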