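# Independent brute-force oracles used to cross-check the package's
# interval, quantification and classifier machinery. These deliberately use
# nothing from the implementation path (plain loops over data.frames).

# members of `a` overlapping >= 1 bp with any member of `b` (half-open coords)
oracle_overlaps_any <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & b$end > a$start[i])
  }, logical(1L))
}

# union-of-ranges merge on the integer line (bp-by-bp coverage)
oracle_union_merge <- function(df) {
  out <- list()
  for (ch in sort(unique(df$chrom))) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    covered <- sort(unique(unlist(
      lapply(seq_len(nrow(sub)), function(i) seq(sub$start[i], sub$end[i] - 1)))))
    brk <- c(0, which(diff(covered) > 1), length(covered))
    for (k in seq_len(length(brk) - 1)) {
      run <- covered[(brk[k] + 1):brk[k + 1]]
      out[[length(out) + 1]] <- data.frame(chrom = ch, start = run[1],
                                           end = run[length(run)] + 1)
    }
  }
  do.call(rbind, out)
}

# per-bin midpoint counts by explicit per-site loop
oracle_profile <- function(sites, pts, window, bin_width) {
  nbins <- window %/% bin_width
  counts <- numeric(nbins)
  for (i in seq_len(nrow(sites))) {
    ctr <- (sites$start[i] + sites$end[i]) %/% 2
    s <- max(ctr - window %/% 2, 0)
    e <- ctr - window %/% 2 + window  # lower clip does not extend the end
    for (j in seq_len(nrow(pts))) {
      if (pts$chrom[j] == sites$chrom[i] && pts$start[j] >= s && pts$start[j] < e) {
        b <- (pts$start[j] - s) %/% bin_width
        counts[b + 1] <- counts[b + 1] + 1
      }
    }
  }
  counts
}

# AUC by all-pairs comparison, ties counted 1/2
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# maximum Youden J by exhaustive scan over a dense threshold grid
oracle_max_youden <- function(scores, labels) {
  cand <- sort(unique(c(scores, scores - 1e-9, scores + 1e-9,
                        min(scores) - 1, max(scores) + 1)))
  best <- -Inf
  for (t in cand) {
    j <- mean(scores[labels] > t) - mean(scores[!labels] > t)
    if (j > best) best <- j
  }
  best
}

random_sites <- function(n, chrom_len = 10000, max_w = 400, chroms = "chr1") {
  ch <- sample(chroms, n, replace = TRUE)
  s <- sample.int(chrom_len - max_w, n, replace = TRUE) - 1
  w <- sample.int(max_w, n, replace = TRUE)
  data.frame(chrom = ch, start = s, end = s + w)
}

as_site_set <- function(df, ...) site_set(df$chrom, df$start, df$end, ...)

# small deterministic plasma fixture shared by quantification tests
toy_cfg <- function(seed = 42, n_fragments_per_sample = 2e4, ...) {
  cohort_config(genome = data.frame(chrom = "chr1", length = 2e6),
                n_k4_sites = 15, n_k27_sites = 25, n_tfbs_sites = 25,
                n_dhs_sites = 40, n_ccrcc_sites = 20, n_background_peaks = 50,
                n_fragments_per_sample = n_fragments_per_sample,
                seed = seed, ...)
}
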