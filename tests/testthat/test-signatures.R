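test_that("consensus_peaks merges across sets and matches the union oracle", {
  a <- site_set("chr1", 0, 100, mark = "H3K27ac")
  b <- site_set("chr1", 50, 150, mark = "H3K27ac")
  cons <- consensus_peaks(list(a, b))
  expect_equal(as.numeric(c(cons$start, cons$end)), c(0, 150))
  # idempotent union of identical peaks
  expect_equal(nrow(consensus_peaks(list(a, a))), 1L)
  expect_error(consensus_peaks(list(a, site_set("chr1", 0, 10, mark = "H3K4me3"))),
               "mixed marks")

  set.seed(303)
  for (rep in 1:10) {
    sets <- lapply(1:5, function(i) as_site_set(random_sites(20), mark = "H3K27ac"))
    got <- as.data.frame(consensus_peaks(sets))
    want <- oracle_union_merge(do.call(rbind, lapply(sets, as.data.frame)))
    expect_equal(got[, c("chrom", "start", "end")], want, ignore_attr = TRUE)
  }
})

test_that("differential_peaks: null peaks give log2FC 0; label swap mirrors up/down", {
  peaks <- as_site_set(data.frame(chrom = "chr1", start = (0:19) * 1000,
                                  end = (0:19) * 1000 + 500))
  counts <- matrix(100L, nrow = 20, ncol = 8)
  m <- count_matrix(peaks, counts, paste0("s", 1:8),
                    rep(c("tRCC", "ccRCC"), each = 4))
  dp <- differential_peaks(m)
  expect_true(all(dp$table$log2fc == 0))
  expect_equal(nrow(dp$up) + nrow(dp$down), 0L)

  set.seed(7)
  counts2 <- matrix(rnbinom(20 * 8, mu = 100, size = 10), nrow = 20)
  m2 <- count_matrix(peaks, counts2, paste0("s", 1:8),
                     rep(c("tRCC", "ccRCC"), each = 4))
  fwd <- differential_peaks(m2, lfc_min = 0.1, q_max = 0.9)
  rev <- differential_peaks(
    count_matrix(peaks, counts2, paste0("s", 1:8),
                 rep(c("ccRCC", "tRCC"), each = 4)),
    lfc_min = 0.1, q_max = 0.9)
  expect_equal(fwd$table$log2fc, -rev$table$log2fc)
  expect_equal(fwd$table$p, rev$table$p)
  key <- function(x) paste(x$chrom, x$start, x$end)
  expect_setequal(key(fwd$up), key(rev$down))
  expect_setequal(key(fwd$down), key(rev$up))
})

test_that("differential_peaks errors on degenerate designs", {
  peaks <- as_site_set(data.frame(chrom = "chr1", start = 0, end = 100))
  m <- count_matrix(peaks, matrix(0L, 1, 4), paste0("s", 1:4),
                    rep(c("tRCC", "ccRCC"), each = 2))
  expect_error(differential_peaks(m), "zero total counts")
  m2 <- count_matrix(peaks, matrix(1L, 1, 3), paste0("s", 1:3),
                     c("tRCC", "ccRCC", "ccRCC"))
  expect_error(differential_peaks(m2), ">= 2 samples")
})

test_that("spiked negative-binomial peaks are recovered with high power and FDR control", {
  cfg <- toy_cfg()
  peaks <- as_site_set(data.frame(chrom = "chr1", start = (0:199) * 2000,
                                  end = (0:199) * 2000 + 500))
  recovered <- fp <- null_sel <- numeric(10)
  for (s in 1:10) {
    m <- simulate_cell_line_counts(cfg, peaks, true_up = 1:20, log2fc_true = 3,
                                   n_per_group = 4L, seed = 1000 + s)
    dp <- differential_peaks(m, lfc_min = 1, q_max = 0.01)
    sel <- which(dp$table$q < 0.01 & dp$table$log2fc > 1)
    recovered[s] <- length(intersect(sel, 1:20))
    fp[s] <- length(setdiff(sel, 1:20))
    m0 <- simulate_cell_line_counts(cfg, peaks, true_up = 1:20, log2fc_true = 0,
                                    n_per_group = 4L, seed = 2000 + s)
    dp0 <- differential_peaks(m0, lfc_min = 0, q_max = 1)
    null_sel[s] <- mean(dp0$table$q < 0.01)
  }
  expect_gte(mean(recovered), 18)      # >= 90% of spiked peaks on average
  expect_equal(mean(fp), 0)            # no false positives at q<0.01 & lfc>1
  expect_lte(mean(null_sel), 0.01)     # null calibration
})

test_that("fusion_occupied_tfbs keeps known-site coordinates and is monotone", {
  known <- site_set(rep("chr1", 3), c(100, 500, 900), c(200, 600, 1000),
                    mark = "TFBS")
  f1 <- site_set("chr1", 150, 520, mark = "TFBS")   # hits sites 1 and 2
  got <- fusion_occupied_tfbs(known, list(f1))
  expect_equal(nrow(got), 2L)
  expect_equal(as.numeric(got$start), c(100, 500))  # known coordinates kept
  expect_equal(nrow(fusion_occupied_tfbs(known, list())), 0L)

  f2 <- site_set("chr1", 950, 960, mark = "TFBS")
  grown <- fusion_occupied_tfbs(known, list(f1, f2))
  expect_equal(nrow(grown), 3L)
  expect_true(all(paste(got$start) %in% paste(grown$start)))

  set.seed(404)
  for (rep in 1:10) {
    kn <- as_site_set(random_sites(30), mark = "TFBS")
    fp <- lapply(1:3, function(i) as_site_set(random_sites(15), mark = "TFBS"))
    got <- fusion_occupied_tfbs(kn, fp)
    hit <- oracle_overlaps_any(as.data.frame(kn),
                               do.call(rbind, lapply(fp, as.data.frame)))
    expect_equal(nrow(got), sum(hit))
  }
})

test_that("assemble_bundle removes shared TFBS and is idempotent", {
  k27 <- site_set("chr1", c(1000, 3000, 5000, 7000), c(1500, 3500, 5500, 7500),
                  mark = "H3K27ac")
  tfbs <- site_set("chr1", seq(900, 9900, by = 1000), seq(950, 9950, by = 1000),
                   mark = "TFBS")
  k4 <- site_set("chr1", 20000, 20500, mark = "H3K4me3")
  b <- assemble_bundle(k4, k27, tfbs)
  n_ov <- nrow(overlap_intersect(tfbs, k27))
  expect_equal(nrow(b$tfbs), nrow(tfbs) - n_ov)
  expect_equal(b$n_shared, n_ov)
  expect_equal(nrow(overlap_intersect(b$tfbs, b$k27_up)), 0L)
  # idempotent
  b2 <- assemble_bundle(b$k4_up, b$k27_up, b$tfbs)
  expect_equal(as.data.frame(b2$tfbs), as.data.frame(b$tfbs))
  # disjoint inputs pass through
  b3 <- assemble_bundle(k4, k27, site_set("chr1", 30000, 30100, mark = "TFBS"))
  expect_equal(nrow(b3$tfbs), 1L)
})
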