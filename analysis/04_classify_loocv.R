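#!/usr/bin/env Rscript
# Stage 4: classification performance of the integrated score.
#
# ROC/AUC for tRCC vs ccRCC and tRCC vs healthy (integrated score and each
# component), the Youden-optimal cutoff, and leave-one-out cross-validation
# of the tRCC-vs-healthy classifier with pooled precision/recall/specificity.
# Writes results/04_classifier/.

suppressMessages(library(cfties))
suppressMessages(library(data.table))

out <- "results/04_classifier"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
scores <- fread("results/03_scores/ties_scores.tsv")
base <- scores[is.na(status) | status == ""]  # cross-sectional + baseline draws

contrast <- function(col, against) {
  sub <- base[label %in% c("tRCC", against)]
  roc_auc(sub[[col]], sub$label, pos_label = "tRCC")$auc
}
aucs <- data.table(
  signal = rep(c("ties", "s_k4", "s_k27", "s_tfbs"), 2),
  contrast = rep(c("tRCC_vs_ccRCC", "tRCC_vs_healthy"), each = 4),
  auc = c(vapply(c("ties", "s_k4", "s_k27", "s_tfbs"), contrast,
                 numeric(1), against = "ccRCC"),
          vapply(c("ties", "s_k4", "s_k27", "s_tfbs"), contrast,
                 numeric(1), against = "healthy")))
fwrite(aucs, file.path(out, "auc_table.tsv"), sep = "\t")
print(aucs)

tvh <- base[label %in% c("tRCC", "healthy")]
roc <- roc_auc(tvh$ties, tvh$label, pos_label = "tRCC")
fwrite(roc$points, file.path(out, "roc_ties_trcc_vs_healthy.tsv"), sep = "\t")

thr <- youden_threshold(tvh$ties, tvh$label, pos_label = "tRCC")
cv <- loo_cv(tvh$ties, tvh$label, pos_label = "tRCC")
metrics <- list(
  auc_ties_trcc_vs_healthy = roc$auc,
  youden_threshold = thr$threshold, youden_j = thr$youden_j,
  loocv_precision = cv$precision, loocv_recall = cv$recall,
  loocv_specificity = cv$specificity, loocv_mean_threshold = cv$mean_threshold)
jsonlite::write_json(metrics, file.path(out, "metrics.json"),
                     auto_unbox = TRUE, digits = NA)
message(sprintf("LOO-CV (n=%d): precision %.1f%%, recall %.1f%%, specificity %.1f%%, mean cutoff %.2f",
                nrow(tvh), 100 * cv$precision, 100 * cv$recall,
                100 * cv$specificity, cv$mean_threshold))
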