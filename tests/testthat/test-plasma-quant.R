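test_that("midpoints collapse fragments to the floored center", {
  f <- fragment_set(c("chr1", "chr1"), c(100, 100), c(300, 101), "s1", "H3K27ac")
  pts <- midpoints(f)
  expect_equal(as.numeric(pts$start), c(100, 200))
  expect_equal(as.numeric(pts$end - pts$start), c(1, 1))

  set.seed(11)
  df <- random_sites(1000, chrom_len = 1e6, max_w = 500)
  fs <- fragment_set(df$chrom, df$start, df$end)
  mp <- midpoints(fs)
  setkey <- order(df$chrom, (df$start + df$end) %/% 2)
  expect_true(all(mp$start >= df$start[setkey] & mp$start < df$end[setkey]))
})

test_that("aggregate_profile bins match arithmetic and the per-site loop oracle", {
  sites <- site_set("chr1", 0, 3000, label = "toy")
  pts <- midpoints(fragment_set("chr1", 1400, 1601))  # midpoint at 1500
  p <- aggregate_profile(sites, pts, window = 3000, bin_width = 40)
  expect_equal(length(p$bin_counts), 75L)
  expect_equal(p$bin_counts[38], 1)          # floor(1500/40) = 37 (0-based)
  expect_equal(sum(p$bin_counts), 1)

  p0 <- aggregate_profile(sites, midpoints(fragment_set(character(), integer(), integer())))
  expect_true(all(p0$bin_counts == 0))
  expect_error(aggregate_profile(site_set(), pts), "empty site set")
  expect_error(aggregate_profile(sites, pts, window = 3000, bin_width = 37),
               "divisible")

  set.seed(22)
  for (rep in 1:10) {
    sdf <- random_sites(8, chrom_len = 50000, max_w = 900)
    fdf <- random_sites(300, chrom_len = 50000, max_w = 300)
    ss <- as_site_set(sdf)
    pp <- midpoints(fragment_set(fdf$chrom, fdf$start, fdf$end))
    got <- aggregate_profile(ss, pp, 3000, 40)$bin_counts
    want <- oracle_profile(as.data.frame(ss), as.data.frame(pp), 3000, 40)
    expect_equal(got, want)
    expect_equal(sum(got), sum(want))  # midpoint-incidence conservation
  }
})

test_that("shoulder normalization cancels additive flat background exactly", {
  mk <- function(counts) {
    structure(list(site_set_label = "toy", window = 3000, bin_width = 40,
                   bin_counts = counts, shoulder_level = NULL,
                   central_signal = NULL, normalized_signal = NULL),
              class = "aggregate_profile")
  }
  flat <- shoulder_normalize(mk(rep(7, 75)))
  expect_equal(flat$shoulder_level, 7)
  expect_equal(flat$central_signal, 0)

  spike <- rep(3, 75); spike[36:40] <- 3 + 11
  sp <- shoulder_normalize(mk(spike))
  expect_equal(sp$central_signal, 5 * 11)

  set.seed(33)
  for (rep in 1:20) {
    base <- rpois(75, 20)
    c0 <- shoulder_normalize(mk(base))$central_signal
    c1 <- shoulder_normalize(mk(base + 13))$central_signal
    expect_equal(c0, c1)
  }
})

test_that("shoulder geometry uses the outer 20% per side and middle third", {
  x <- rep(0, 75)
  x[c(1:15, 61:75)] <- 10       # shoulders only
  p <- shoulder_normalize(structure(list(site_set_label = "g", window = 3000,
    bin_width = 40, bin_counts = x, shoulder_level = NULL,
    central_signal = NULL, normalized_signal = NULL),
    class = "aggregate_profile"))
  expect_equal(p$shoulder_level, 10)
  x2 <- rep(0, 75); x2[26:50] <- 4   # central bins only
  p2 <- shoulder_normalize(structure(list(site_set_label = "g", window = 3000,
    bin_width = 40, bin_counts = x2, shoulder_level = NULL,
    central_signal = NULL, normalized_signal = NULL),
    class = "aggregate_profile"))
  expect_equal(p2$central_signal, 100)
  expect_error(shoulder_normalize(p2, shoulder_frac = 0.5, central_frac = 0.9),
               "overlap")
})

test_that("dhs_reference is positive, linear in depth, and flags empty samples", {
  cfg <- toy_cfg()
  sites <- make_sites(cfg)
  s <- simulate_plasma_sample(cfg, "healthy", 0, "H3K27ac", sites, seed = 5,
                              sample_id = "h1")
  ref <- dhs_reference(s, sites$dhs)
  expect_gt(ref, 0)
  doubled <- fragment_set(rep(s$chrom, 2), rep(s$start, 2), rep(s$end, 2),
                          "h1x2", "H3K27ac")
  expect_equal(dhs_reference(doubled, sites$dhs), 2 * ref)

  empty <- fragment_set(character(), integer(), integer(), "none", "H3K27ac")
  expect_error(dhs_reference(empty, sites$dhs), class = "cfties_unquantifiable")
})

test_that("site_signal is depth-invariant, zero without local signal, monotone in enrichment", {
  cfg <- toy_cfg()
  sites <- make_sites(cfg)
  s <- simulate_plasma_sample(cfg, "tRCC", 0.2, "H3K27ac", sites, seed = 6,
                              sample_id = "t1")
  sig <- site_signal(s, sites$k27_up, sites$dhs)
  dup <- fragment_set(rep(s$chrom, 2), rep(s$start, 2), rep(s$end, 2),
                      "t1x2", "H3K27ac")
  expect_identical(site_signal(dup, sites$k27_up, sites$dhs), sig)

  # fragments only at a far-away housekeeping site: zero signature signal
  toy_dhs <- site_set("chr1", 100000, 100500, mark = "DHS")
  toy_sig <- site_set("chr1", 500000, 500500, mark = "H3K27ac")
  pure <- fragment_set(rep("chr1", 500), rep(100150, 500), rep(100350, 500),
                       "pure", "H3K27ac")
  expect_equal(site_signal(pure, toy_sig, toy_dhs), 0)

  lam <- c(1, 5, 10, 20, 40)
  sigs <- vapply(seq_along(lam), function(i) {
    cfg_l <- toy_cfg(enrichment = lam[i])
    sl <- simulate_plasma_sample(cfg_l, "tRCC", 0.2, "H3K27ac", sites,
                                 seed = 100, sample_id = "t")
    site_signal(sl, sites$k27_up, sites$dhs)
  }, numeric(1L))
  expect_true(all(diff(sigs) > 0))
})

test_that("uniform background fragments barely move site_signal", {
  cfg <- toy_cfg()
  sites <- make_sites(cfg)
  s <- simulate_plasma_sample(cfg, "tRCC", 0.3, "H3K27ac", sites, seed = 9,
                              sample_id = "t1")
  base <- site_signal(s, sites$k27_up, sites$dhs)
  set.seed(77)
  n_add <- nrow(s) %/% 2
  pos <- floor(runif(n_add) * (2e6 - 200))
  aug <- fragment_set(c(s$chrom, rep("chr1", n_add)), c(s$start, pos),
                      c(s$end, pos + 167), "t1bg", "H3K27ac")
  shifted <- site_signal(aug, sites$k27_up, sites$dhs)
  expect_lt(abs(shifted - base) / base, 0.05)
})

test_that("fragment BED round-trips through write_bed/read_fragments", {
  f <- fragment_set(c("chr1", "chr2"), c(10, 20), c(180, 190), "s1", "H3K4me3")
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(f, path)
  back <- read_fragments(path, sample_id = "s1", mark = "H3K4me3")
  expect_equal(as.data.frame(back), as.data.frame(f), ignore_attr = TRUE)
})
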