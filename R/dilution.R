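#' In silico dilution specification
#'
#' @param dilution_levels tumor read fractions, each in (0, 1). Default is
#'   the eleven levels 0.9, 0.8, ..., 0.1, 0.05, 0.01.
#' @param bin_width_tf expected-tumor-fraction bin width (default 0.004,
#'   i.e. 0.4%).
#' @param tf_min_bin,tf_max_bin edges of the open terminal bins: mixtures
#'   below `tf_min_bin` pool into the lowest bin ("<0.4%") and above
#'   `tf_max_bin` into the highest (">3.2%").
#' @param seed RNG seed for fragment subsampling.
#' @return A `dilution_spec` list.
#' @export
dilution_spec <- function(dilution_levels = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4,
                                              0.3, 0.2, 0.1, 0.05, 0.01),
                          bin_width_tf = 0.004, tf_min_bin = 0.004,
                          tf_max_bin = 0.032, seed = 1L) {
  stopifnot(all(dilution_levels > 0), all(dilution_levels < 1),
            bin_width_tf > 0, tf_min_bin <= tf_max_bin)
  structure(list(dilution_levels = dilution_levels,
                 bin_width_tf = bin_width_tf, tf_min_bin = tf_min_bin,
                 tf_max_bin = tf_max_bin, seed = as.integer(seed)),
            class = "dilution_spec")
}

#' Mix tumor and healthy fragments at a fixed tumor read fraction
#'
#' The read budget is `N = min(|tumor|, |healthy|)`; `round(N * dl)`
#' fragments are drawn without replacement from the tumor sample and
#' `round(N * (1 - dl))` from the healthy sample, so `dl` is the tumor
#' fraction of reads and the expected tumor fraction of the mixture is the
#' tumor sample's tumor fraction times `dl`. Deterministic given `seed`.
#'
#' @param tumor,healthy `fragment_set` objects of the same mark.
#' @param dl tumor read fraction in (0, 1).
#' @param tumor_tf tumor fraction of the tumor sample (defaults to its `tf`
#'   attribute).
#' @param seed RNG seed.
#' @return A `dilution_mixture` list: `fragments` (the mixed
#'   `fragment_set`), `dl`, `expected_tf`, `n_reads`, `n_tumor`, `n_healthy`.
#' @export
dilute_pair <- function(tumor, healthy, dl, tumor_tf = attr(tumor, "tf"),
                        seed = 1L) {
  stopifnot(dl > 0, dl < 1, nrow(tumor) > 0L, nrow(healthy) > 0L)
  if (is.null(tumor_tf)) stop("tumor sample has no tumor fraction")
  N <- min(nrow(tumor), nrow(healthy))
  n_t <- round(N * dl); n_h <- round(N * (1 - dl))
  stopifnot(n_t <= nrow(tumor), n_h <= nrow(healthy))
  set.seed(seed)
  it <- sample.int(nrow(tumor), n_t)
  ih <- sample.int(nrow(healthy), n_h)
  mix <- rbindlist(list(as.data.table(tumor)[it], as.data.table(healthy)[ih]))
  fs <- fragment_set(mix$chrom, mix$start, mix$end,
                     sample_id = paste0(attr(tumor, "sample_id"), "x",
                                        attr(healthy, "sample_id"), "_dl", dl),
                     mark = site_mark(tumor))
  structure(list(fragments = fs, dl = dl, expected_tf = tumor_tf * dl,
                 n_reads = n_t + n_h, n_tumor = n_t, n_healthy = n_h),
            class = "dilution_mixture")
}

tf_bin_index <- function(tf, spec) {
  pmin(pmax(floor(tf / spec$bin_width_tf), 0),
       round(spec$tf_max_bin / spec$bin_width_tf))
}

tf_bin_label <- function(idx, spec) {
  top <- round(spec$tf_max_bin / spec$bin_width_tf)
  ifelse(idx == 0, sprintf("<%.1f%%", 100 * spec$tf_min_bin),
    ifelse(idx >= top, sprintf(">%.1f%%", 100 * spec$tf_max_bin),
      sprintf("%.1f%%-%.1f%%", 100 * idx * spec$bin_width_tf,
              100 * (idx + 1) * spec$bin_width_tf)))
}

#' In silico dilution experiment and limit of detection
#'
#' Every tumor x healthy pair is mixed at every dilution level (both marks
#' diluted at the same tumor read fraction), each mixture is scored against
#' the signature bundle, mixtures are binned by expected tumor fraction
#' (0.4%-wide bins with open terminal bins), and each bin's pooled scores
#' are compared with the undiluted healthy samples' scores by two-sided
#' Wilcoxon rank-sum test. The limit of detection is the lowest-TF bin with
#' p < 0.05 such that every higher-TF bin is also significant.
#'
#' @param tumors list of tumor plasma samples (each a list with `sample_id`,
#'   `tf` > 0.03, `k4`, `k27`).
#' @param healthies list of healthy plasma samples (same structure, any tf).
#' @param spec a [dilution_spec()].
#' @param bundle a [assemble_bundle()] result.
#' @param dhs housekeeping `site_set`.
#' @param ... passed to [score_sample()] (window, normalization, log
#'   parameters).
#' @return A `lod_result` list: `mixtures` (data.table: tumor_id,
#'   healthy_id, dl, expected_tf, bin, ties), `per_bin` (bin, bin_label,
#'   tf_lo, n, p), `healthy_ties`, `lod_bin` (row of `per_bin` or `NULL`),
#'   `lod_label`.
#' @export
dilution_experiment <- function(tumors, healthies, spec, bundle, dhs, ...) {
  stopifnot(length(tumors) > 0L, length(healthies) > 0L)
  tfs <- vapply(tumors, `[[`, numeric(1L), "tf")
  if (any(tfs <= 0.03))
    stop("tumor samples must have tumor fraction > 0.03 (filter upstream)")

  healthy_ties <- vapply(healthies, function(h)
    score_sample(list(sample_id = h$sample_id, k4 = h$k4, k27 = h$k27),
                 bundle, dhs, ...)$ties, numeric(1L))

  rows <- vector("list", length(tumors) * length(healthies) *
                   length(spec$dilution_levels))
  k <- 0L
  for (ti in seq_along(tumors)) for (hi in seq_along(healthies))
    for (dl in spec$dilution_levels) {
      t <- tumors[[ti]]; h <- healthies[[hi]]
      sd1 <- derive_seed(spec$seed, paste(t$sample_id, h$sample_id, dl, "K4"))
      sd2 <- derive_seed(spec$seed, paste(t$sample_id, h$sample_id, dl, "K27"))
      mk4 <- dilute_pair(t$k4, h$k4, dl, tumor_tf = t$tf, seed = sd1)
      mk27 <- dilute_pair(t$k27, h$k27, dl, tumor_tf = t$tf, seed = sd2)
      sc <- score_sample(list(sample_id = mk4$fragments |> attr("sample_id"),
                              k4 = mk4$fragments, k27 = mk27$fragments),
                         bundle, dhs, ...)
      k <- k + 1L
      rows[[k]] <- data.table(tumor_id = t$sample_id, healthy_id = h$sample_id,
                              dl = dl, expected_tf = mk4$expected_tf,
                              ties = sc$ties)
    }
  mixtures <- rbindlist(rows)
  mixtures[, bin := tf_bin_index(expected_tf, spec)]

  per_bin <- mixtures[, .(n = .N,
                          p = group_compare(ties, healthy_ties)$p_value),
                      by = bin][order(bin)]
  per_bin[, `:=`(bin_label = tf_bin_label(bin, spec),
                 tf_lo = bin * spec$bin_width_tf)]

  sig <- per_bin$p < 0.05
  lod_idx <- NA_integer_
  for (i in seq_along(sig)) if (all(sig[i:length(sig)])) { lod_idx <- i; break }
  structure(list(mixtures = mixtures[], per_bin = per_bin[],
                 healthy_ties = healthy_ties,
                 lod_bin = if (!is.na(lod_idx)) per_bin[lod_idx] else NULL,
                 lod_label = if (!is.na(lod_idx)) per_bin$bin_label[lod_idx]
                             else NA_character_),
            class = "lod_result")
}

#' @export
print.lod_result <- function(x, ...) {
  cat(sprintf("<lod_result> %d mixtures, %d TF bins; LOD bin: %s\n",
              nrow(x$mixtures), nrow(x$per_bin), x$lod_label))
  print(x$per_bin)
  invisible(x)
}
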