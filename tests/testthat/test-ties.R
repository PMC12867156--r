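test_that("compute_ties is log of the floored sum and monotone in components", {
  expect_equal(compute_ties(1, 1, 1), log(3))
  expect_equal(compute_ties(0, 0, 0, eps = 1e-6), log(1e-6))
  expect_equal(compute_ties(1, 2, 3, log_base = 2), log2(6))

  set.seed(1)
  for (i in 1:50) {
    x <- runif(3, 0, 5)
    j <- sample(3, 1)
    bump <- x; bump[j] <- bump[j] + runif(1)
    expect_gte(compute_ties(bump[1], bump[2], bump[3]),
               compute_ties(x[1], x[2], x[3]))
  }
})

test_that("roc_auc matches the pair-counting oracle and handles ties", {
  expect_equal(roc_auc(1:4, c(FALSE, FALSE, TRUE, TRUE))$auc, 1)
  expect_equal(roc_auc(rep(2, 6), rep(c(TRUE, FALSE), 3))$auc, 0.5)
  expect_error(roc_auc(1:3, rep(TRUE, 3)), "each class")

  set.seed(12)
  for (rep in 1:10) {
    n <- 200
    scores <- sample(round(rnorm(n), 1))  # coarse grid forces ties
    labels <- runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, oracle_auc(scores, labels), tolerance = 1e-12)
    expect_equal(unlist(r$points[1]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(r$points[nrow(r$points)]), c(fpr = 1, tpr = 1))
    # invariance under strictly increasing transforms
    expect_equal(roc_auc(exp(scores), labels)$auc, r$auc)
    expect_equal(roc_auc(3 * scores - 7, labels)$auc, r$auc)
  }
})

test_that("roc_auc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  scores <- rnorm(60)
  labels <- runif(60) < 0.5
  got <- roc_auc(scores, labels)$auc
  want <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                         direction = "<")))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("score_sample orders tumor above healthy and errors on missing marks", {
  cfg <- toy_cfg()
  sites <- make_sites(cfg)
  bundle <- assemble_bundle(sites$k4_up, sites$k27_up, sites$tfbs_raw)
  mk <- function(label, tf, seed, id) list(
    sample_id = id,
    k4 = simulate_plasma_sample(cfg, label, tf, "H3K4me3", sites, seed, id),
    k27 = simulate_plasma_sample(cfg, label, tf, "H3K27ac", sites, seed + 1, id))
  tumor <- mk("tRCC", 0.2, 100, "t1")
  healthy <- mk("healthy", 0, 200, "h1")
  st <- score_sample(tumor, bundle, sites$dhs)
  sh <- score_sample(healthy, bundle, sites$dhs)
  expect_gt(st$ties, sh$ties)
  expect_true(all(c(st$s_k4, st$s_k27, st$s_tfbs) >= 0))
  # determinism
  expect_identical(score_sample(tumor, bundle, sites$dhs), st)

  expect_error(score_sample(list(sample_id = "t1", k4 = tumor$k4, k27 = NULL),
                            bundle, sites$dhs), "H3K27ac")
  expect_message(
    part <- score_sample(list(sample_id = "t1", k4 = tumor$k4, k27 = NULL),
                         bundle, sites$dhs, allow_partial = TRUE),
    "H3K27ac")
  expect_true(is.na(part$s_k27) && is.na(part$s_tfbs))
  expect_equal(part$ties, compute_ties(part$s_k4, 0, 0))
})

test_that("skipping TFBS deduplication inflates the TFBS component", {
  cfg <- toy_cfg(tfbs_k27_overlap_frac = 0.4)  # many shared, signal-bearing sites
  sites <- make_sites(cfg)
  bundle <- assemble_bundle(sites$k4_up, sites$k27_up, sites$tfbs_raw)
  raw_bundle <- structure(list(k4_up = sites$k4_up, k27_up = sites$k27_up,
                               tfbs = sites$tfbs_raw, n_shared = 0L),
                          class = "signature_bundle")
  tumor <- list(
    sample_id = "t1",
    k4 = simulate_plasma_sample(cfg, "tRCC", 0.3, "H3K4me3", sites, 300, "t1"),
    k27 = simulate_plasma_sample(cfg, "tRCC", 0.3, "H3K27ac", sites, 301, "t1"))
  dedup <- score_sample(tumor, bundle, sites$dhs)
  raw <- score_sample(tumor, raw_bundle, sites$dhs)
  expect_gt(raw$s_tfbs, dedup$s_tfbs)
})

test_that("synthetic cohorts separate with effect and stay null without", {
  cfg <- toy_cfg()
  sites <- make_sites(cfg)
  bundle <- assemble_bundle(sites$k4_up, sites$k27_up, sites$tfbs_raw)
  score_one <- function(label, tf, seed, id) {
    s <- list(sample_id = id,
              k4 = simulate_plasma_sample(cfg, label, tf, "H3K4me3", sites, seed, id),
              k27 = simulate_plasma_sample(cfg, label, tf, "H3K27ac", sites, seed + 5000, id))
    score_sample(s, bundle, sites$dhs)$ties
  }
  set.seed(21)
  eff <- vapply(1:8, function(i)
    score_one("tRCC", runif(1, 0.1, 0.3), i, paste0("t", i)), numeric(1L))
  nul <- vapply(1:8, function(i)
    score_one("healthy", 0, 100 + i, paste0("h", i)), numeric(1L))
  expect_equal(roc_auc(c(eff, nul), rep(c(TRUE, FALSE), each = 8))$auc, 1)

  nul2 <- vapply(1:8, function(i)
    score_one("tRCC", 0, 200 + i, paste0("n", i)), numeric(1L))  # tf = 0 null
  auc0 <- roc_auc(c(nul2, nul), rep(c(TRUE, FALSE), each = 8))$auc
  expect_gte(auc0, 0.2)
  expect_lte(auc0, 0.8)
})
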