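#' Per-peak count matrix for differential analysis
#'
#' Couples a consensus peak set with nonnegative integer read counts per
#' (peak, sample) and a two-level group factor (tRCC vs ccRCC cell lines).
#'
#' @param peaks a [site_set()]; one row per peak.
#' @param counts integer matrix, `nrow(peaks)` x `length(samples)`.
#' @param samples character vector of sample ids (column order of `counts`).
#' @param group per-sample labels, two levels (e.g. `"tRCC"`, `"ccRCC"`).
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(peaks, counts, samples, group) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == nrow(peaks),
            ncol(counts) == length(samples),
            length(group) == length(samples),
            all(counts >= 0))
  structure(list(peaks = peaks, counts = counts,
                 samples = as.character(samples), group = as.character(group)),
            class = "count_matrix")
}

#' Merge peak sets into a consensus set
#'
#' Overlapping peaks across samples are merged for each mark into maximal
#' disjoint intervals (union of covered ranges).
#'
#' @param peak_sets list of `site_set` objects sharing one mark.
#' @return A merged `site_set`.
#' @export
consensus_peaks <- function(peak_sets) {
  stopifnot(length(peak_sets) >= 1L)
  marks <- unique(vapply(peak_sets, site_mark, ""))
  marks <- marks[!is.na(marks)]
  if (length(marks) > 1L)
    stop("mixed marks in consensus_peaks: ", paste(marks, collapse = ", "))
  all <- rbindlist(lapply(peak_sets, as.data.table))
  pooled <- new_site_set(all, mark = if (length(marks)) marks else NA_character_,
                         label = "consensus")
  extend_and_merge(pooled, flank = 0)
}

#' Differential peak selection between groups
#'
#' Counts are normalized to counts-per-million with a 0.5 pseudocount; the
#' per-peak log2 fold change is the log2 ratio of group mean CPM (positive =
#' enriched in the first group, tRCC by convention). The per-peak two-sided
#' p-value is an empirical-Bayes moderated t-test on log2-CPM
#' (limma-trend): with a handful of cell lines per group, sharing the
#' mean-variance trend across peaks is what makes recovery at stringent FDR
#' feasible at all, and mirrors the information sharing of the count-GLM
#' tools used on such designs. P-values are adjusted by
#' Benjamini-Hochberg across all peaks of the matrix, and peaks passing
#' `q < q_max` with `log2fc > lfc_min` (up) or `< -lfc_min` (down) are
#' returned.
#'
#' @param m a [count_matrix()].
#' @param lfc_min minimum |log2FC| (1 for H3K27ac/MeDIP, 2 for H3K4me3).
#' @param q_max FDR q-value cutoff (default 0.01).
#' @param group_up group label treated as "up" (default `"tRCC"`).
#' @return List with data.tables `up` and `down` (chrom, start, end, log2fc,
#'   p, q) and the full per-peak `table`.
#' @export
differential_peaks <- function(m, lfc_min = 1, q_max = 0.01, group_up = "tRCC") {
  stopifnot(inherits(m, "count_matrix"))
  g <- m$group
  lv <- unique(g)
  stopifnot(length(lv) == 2L, group_up %in% lv)
  ia <- which(g == group_up); ib <- which(g != group_up)
  if (length(ia) < 2L || length(ib) < 2L) stop("need >= 2 samples per group")
  libsize <- colSums(m$counts)
  if (sum(libsize[ia]) == 0 || sum(libsize[ib]) == 0)
    stop("a group has zero total counts")
  cpm <- sweep(m$counts + 0.5, 2L, libsize, "/") * 1e6
  lcpm <- log2(cpm)
  log2fc <- log2(rowMeans(cpm[, ia, drop = FALSE])) -
            log2(rowMeans(cpm[, ib, drop = FALSE]))
  grp <- factor(ifelse(g == group_up, "up", "ref"), levels = c("ref", "up"))
  design <- stats::model.matrix(~grp)
  fit <- limma::eBayes(limma::lmFit(lcpm, design), trend = TRUE)
  p <- fit$p.value[, "grpup"]
  q <- stats::p.adjust(p, method = "BH")
  tab <- data.table(as.data.table(m$peaks)[, c("chrom", "start", "end"), with = FALSE],
                    log2fc = log2fc, p = p, q = q)
  list(up = tab[q < q_max & log2fc > lfc_min],
       down = tab[q < q_max & log2fc < -lfc_min],
       table = tab)
}

#' Fusion-occupied transcription factor binding sites
#'
#' Intersects a database of known binding sites with the merged union of
#' fusion-protein ChIP-seq peak sets from tumor cell lines; a known site is
#' kept when it shares at least 1 bp with any fusion peak, and its original
#' coordinates are retained.
#'
#' @param known_tfbs `site_set` of database binding sites (nonempty).
#' @param fusion_peak_sets list of `site_set` fusion ChIP-seq peak sets.
#' @return `site_set` of fusion-occupied sites (subset of `known_tfbs`).
#' @export
fusion_occupied_tfbs <- function(known_tfbs, fusion_peak_sets) {
  stopifnot(nrow(known_tfbs) > 0L)
  if (length(fusion_peak_sets) == 0L)
    return(new_site_set(known_tfbs[0L], mark = site_mark(known_tfbs),
                        label = "fusion-occupied"))
  pooled <- consensus_peaks(fusion_peak_sets)
  out <- overlap_intersect(known_tfbs, pooled)
  setattr(out, "label", "fusion-occupied")
  out
}

#' Assemble the deduplicated three-part signature bundle
#'
#' Removes from the raw fusion-occupied TFBS set every site sharing >= 1 bp
#' with an H3K27ac up site, so signal at shared sites is not counted twice
#' when the three component signals are summed into one score.
#'
#' @param k4_up H3K4me3 up `site_set`.
#' @param k27_up H3K27ac up `site_set`.
#' @param tfbs_raw raw fusion-occupied TFBS `site_set`.
#' @return A `signature_bundle` list with elements `k4_up`, `k27_up`, `tfbs`
#'   (deduplicated) and `n_shared` (count removed).
#' @export
assemble_bundle <- function(k4_up, k27_up, tfbs_raw) {
  tfbs <- subtract_overlapping(tfbs_raw, k27_up)
  structure(list(k4_up = k4_up, k27_up = k27_up, tfbs = tfbs,
                 n_shared = nrow(tfbs_raw) - nrow(tfbs)),
            class = "signature_bundle")
}

#' @export
print.signature_bundle <- function(x, ...) {
  cat(sprintf("<signature_bundle> k4_up=%d  k27_up=%d  tfbs=%d (%d shared sites removed)\n",
              nrow(x$k4_up), nrow(x$k27_up), nrow(x$tfbs), x$n_shared))
  invisible(x)
}
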