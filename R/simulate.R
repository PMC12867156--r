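#' Synthetic cohort configuration
#'
#' Defaults define the study conditions every simulation-based test runs
#' under: one 10-Mb chromosome; signature site sets scaled down from the
#' cell-line-derived sets (with 13% of TFBS overlapping H3K27ac up sites, the
#' observed fraction of shared sites); mononucleosomal fragment lengths
#' (167 +/- 20 bp); sequencing depth 100,000 fragments per sample per mark;
#' site-localized enrichment lambda = 20 relative to uniform background for
#' tumor-derived fragments; a shared housekeeping rate at DHS sites; and
#' log-uniform tumor fractions 0.005-0.30 for cancer samples.
#'
#' @param genome data.frame with columns `chrom`, `length`.
#' @param n_k4_sites,n_k27_sites,n_tfbs_sites,n_dhs_sites,n_ccrcc_sites
#'   site-set sizes.
#' @param n_background_peaks consensus peaks with no group difference; they
#'   pad the differential-analysis peak universe the way non-differential
#'   peaks dominate a real consensus set.
#' @param tfbs_k27_overlap_frac fraction of TFBS placed overlapping H3K27ac
#'   up sites (exercises signature deduplication).
#' @param site_width_range uniform range of site widths in bp.
#' @param enrichment lambda: midpoint density at signature sites relative to
#'   background, for tumor-derived fragments.
#' @param dhs_enrichment housekeeping lambda at DHS sites, shared by all
#'   fragments of non-tumor origin.
#' @param n_fragments_per_sample sequencing depth per sample per mark.
#' @param tf_log_range log-uniform range of tumor fractions for tRCC and
#'   ccRCC samples.
#' @param fragment_length_mean,fragment_length_sd fragment length model
#'   (normal, floored at 60 bp).
#' @param nb_dispersion negative-binomial dispersion of cell-line counts.
#' @param seed master seed; all per-sample randomness derives from it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(genome = data.frame(chrom = "chr1", length = 1e7),
                          n_k4_sites = 60, n_k27_sites = 100,
                          n_tfbs_sites = 100, n_dhs_sites = 200,
                          n_ccrcc_sites = 80, n_background_peaks = 600,
                          tfbs_k27_overlap_frac = 0.13,
                          site_width_range = c(200, 1000),
                          enrichment = 20, dhs_enrichment = 20,
                          n_fragments_per_sample = 1e5,
                          tf_log_range = c(0.005, 0.30),
                          fragment_length_mean = 167,
                          fragment_length_sd = 20,
                          nb_dispersion = 0.1,
                          seed = 1L) {
  cfg <- list(genome = genome, n_k4_sites = n_k4_sites,
              n_k27_sites = n_k27_sites, n_tfbs_sites = n_tfbs_sites,
              n_dhs_sites = n_dhs_sites, n_ccrcc_sites = n_ccrcc_sites,
              n_background_peaks = n_background_peaks,
              tfbs_k27_overlap_frac = tfbs_k27_overlap_frac,
              site_width_range = site_width_range,
              enrichment = enrichment, dhs_enrichment = dhs_enrichment,
              n_fragments_per_sample = n_fragments_per_sample,
              tf_log_range = tf_log_range,
              fragment_length_mean = fragment_length_mean,
              fragment_length_sd = fragment_length_sd,
              nb_dispersion = nb_dispersion, seed = as.integer(seed))
  stopifnot(all(unlist(cfg[grep("^n_", names(cfg))]) > 0),
            tfbs_k27_overlap_frac >= 0, tfbs_k27_overlap_frac <= 1)
  structure(cfg, class = "cohort_config")
}

## deterministic substream seed below 2^31, derived from master seed + key
derive_seed <- function(master, key) {
  h <- as.numeric(master) %% 2147483629
  for (k in utf8ToInt(as.character(key))) h <- (h * 131 + k) %% 2147483629
  as.integer(h + 1)
}

place_disjoint <- function(n, widths, genome, occ, margin = 5000,
                           max_tries = 200L) {
  starts <- numeric(n); ends <- numeric(n); chroms <- character(n)
  oc <- occ$chrom; os <- occ$start; oe <- occ$end
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      ci <- sample.int(nrow(genome), 1L, prob = genome$length)
      lo <- margin; hi <- genome$length[ci] - margin - widths[i]
      if (hi <= lo) next
      s <- lo + floor(stats::runif(1) * (hi - lo))
      e <- s + widths[i]
      cl <- genome$chrom[ci]
      if (!any(oc == cl & os < e & oe > s)) {
        ok <- TRUE; break
      }
    }
    if (!ok) stop("site placement failed; use a larger genome or fewer sites")
    chroms[i] <- cl; starts[i] <- s; ends[i] <- e
    oc <- c(oc, cl); os <- c(os, s); oe <- c(oe, e)
  }
  list(sites = data.frame(chrom = chroms, start = starts, end = ends),
       occ = data.frame(chrom = oc, start = os, end = oe))
}

#' Generate the synthetic signature, housekeeping and comparator site sets
#'
#' Places the five site sets uniformly at random (widths uniform in
#' `site_width_range`) with no overlaps between sets, except that a
#' configured fraction of TFBS is constructed to overlap H3K27ac up sites
#' (so bundle deduplication is exercised). DHS sites are disjoint from all
#' signature sets. Deterministic given `cfg$seed`.
#'
#' @param cfg a [cohort_config()].
#' @return List of `site_set`: `k4_up`, `k27_up`, `tfbs_raw`, `dhs`,
#'   `ccrcc_up`, `background`.
#' @export
make_sites <- function(cfg) {
  set.seed(derive_seed(cfg$seed, "sites"))
  g <- cfg$genome
  wr <- cfg$site_width_range
  rw <- function(n) round(stats::runif(n, wr[1], wr[2]))
  occ <- data.frame(chrom = character(), start = numeric(), end = numeric())

  pk4 <- place_disjoint(cfg$n_k4_sites, rw(cfg$n_k4_sites), g, occ); occ <- pk4$occ
  pk27 <- place_disjoint(cfg$n_k27_sites, rw(cfg$n_k27_sites), g, occ); occ <- pk27$occ
  pcc <- place_disjoint(cfg$n_ccrcc_sites, rw(cfg$n_ccrcc_sites), g, occ); occ <- pcc$occ
  pdhs <- place_disjoint(cfg$n_dhs_sites, rw(cfg$n_dhs_sites), g, occ); occ <- pdhs$occ
  pbg <- place_disjoint(cfg$n_background_peaks, rw(cfg$n_background_peaks),
                        g, occ); occ <- pbg$occ

  n_ov <- round(cfg$tfbs_k27_overlap_frac * cfg$n_tfbs_sites)
  k27 <- pk27$sites
  ov_rows <- if (n_ov > 0) sample.int(nrow(k27), n_ov) else integer()
  ov_list <- vector("list", n_ov)
  for (j in seq_len(n_ov)) {
    anchor <- k27[ov_rows[j], ]
    occ_other <- occ[!(occ$chrom == anchor$chrom & occ$start == anchor$start &
                         occ$end == anchor$end), ]
    placed <- FALSE
    for (try in 1:500) {
      w <- rw(1L)
      ## any start in [anchor_start - w + 1, anchor_end - 1] shares >= 1 bp
      s <- anchor$start - w + 1 +
        floor(stats::runif(1) * (anchor$end - anchor$start + w - 1))
      e <- s + w
      if (s >= 0 &&
          !any(occ_other$chrom == anchor$chrom & occ_other$start < e &
                 occ_other$end > s)) { placed <- TRUE; break }
    }
    if (!placed) stop("site placement failed; use a larger genome or fewer sites")
    ov_list[[j]] <- data.frame(chrom = anchor$chrom, start = s, end = e)
    occ <- rbind(occ, ov_list[[j]])
  }
  n_free <- cfg$n_tfbs_sites - n_ov
  pfree <- place_disjoint(n_free, rw(n_free), g, occ)
  tfbs <- rbind(do.call(rbind, ov_list), pfree$sites)

  mk <- function(df, mark, label)
    site_set(df$chrom, df$start, df$end, mark = mark, label = label)
  list(k4_up = mk(pk4$sites, "H3K4me3", "tRCC-up"),
       k27_up = mk(pk27$sites, "H3K27ac", "tRCC-up"),
       tfbs_raw = mk(tfbs, "TFBS", "fusion-occupied"),
       dhs = mk(pdhs$sites, "DHS", "housekeeping"),
       ccrcc_up = mk(pcc$sites, "H3K27ac", "ccRCC-up"),
       background = mk(pbg$sites, NA_character_, "background"))
}

#' Simulate a cell-line count matrix with known differential peaks
#'
#' Baseline per-peak means are log-normal; counts are negative-binomial with
#' dispersion `cfg$nb_dispersion`; the tRCC group mean is multiplied by
#' `2^log2fc_true` at the `true_up` peaks.
#'
#' @param cfg a [cohort_config()].
#' @param consensus consensus peak `site_set` (rows of the matrix).
#' @param true_up integer indices of truly tRCC-enriched peaks.
#' @param log2fc_true true log2 fold change at `true_up`.
#' @param n_per_group samples per group; a length-2 vector gives (tRCC,
#'   ccRCC) counts (the cell-line panel design is 4 tRCC vs 6 ccRCC lines).
#' @param seed substream seed (default derived from `cfg$seed`).
#' @return A [count_matrix()].
#' @export
simulate_cell_line_counts <- function(cfg, consensus, true_up, log2fc_true,
                                      n_per_group = 4L,
                                      seed = derive_seed(cfg$seed, "counts")) {
  stopifnot(all(true_up >= 1), all(true_up <= nrow(consensus)))
  n_per_group <- rep_len(as.integer(n_per_group), 2L)
  set.seed(seed)
  np <- nrow(consensus)
  base_mu <- stats::rlnorm(np, meanlog = log(100), sdlog = 1)
  mu_t <- base_mu
  mu_t[true_up] <- mu_t[true_up] * 2^log2fc_true
  size <- 1 / cfg$nb_dispersion
  counts <- cbind(
    matrix(stats::rnbinom(np * n_per_group[1], mu = rep(mu_t, n_per_group[1]),
                          size = size), nrow = np),
    matrix(stats::rnbinom(np * n_per_group[2], mu = rep(base_mu, n_per_group[2]),
                          size = size), nrow = np))
  samples <- c(sprintf("tRCC_cl%02d", seq_len(n_per_group[1])),
               sprintf("ccRCC_cl%02d", seq_len(n_per_group[2])))
  count_matrix(consensus, counts, samples,
               rep(c("tRCC", "ccRCC"), n_per_group))
}

#' Simulate one plasma cf-ChIP sample
#'
#' Each of `cfg$n_fragments_per_sample` fragments is tumor-derived with
#' probability `tf`. Tumor-derived fragment midpoints localize to the
#' label's signature sites for the given mark with probability
#' `lambda*W / (lambda*W + (G - W))` (lambda = `cfg$enrichment`, W = total
#' signature width, G = genome size), otherwise uniform background.
#' Non-tumor fragments localize to DHS sites at the shared housekeeping rate
#' (`cfg$dhs_enrichment`), otherwise uniform background. Fragment lengths
#' are normal (`cfg$fragment_length_mean` +/- `sd`, floored at 60 bp).
#' Deterministic given `seed`.
#'
#' @param cfg a [cohort_config()].
#' @param label one of `"tRCC"`, `"ccRCC"`, `"healthy"`.
#' @param tf tumor fraction in \[0, 1\].
#' @param mark `"H3K4me3"` or `"H3K27ac"`.
#' @param sites output of [make_sites()].
#' @param seed substream seed.
#' @param sample_id sample identifier.
#' @return A `fragment_set` with attributes `tf` and `label`.
#' @export
simulate_plasma_sample <- function(cfg, label, tf, mark, sites, seed,
                                   sample_id = paste0(label, "_", seed)) {
  stopifnot(tf >= 0, tf <= 1, mark %in% c("H3K4me3", "H3K27ac"))
  force(sites)  # evaluate before seeding: the promise may itself use the RNG
  set.seed(seed)
  g <- cfg$genome
  G <- sum(g$length)
  sig <- switch(label,
    tRCC = if (mark == "H3K4me3") as.data.table(sites$k4_up) else
      rbindlist(list(as.data.table(sites$k27_up), as.data.table(sites$tfbs_raw))),
    ccRCC = as.data.table(sites$ccrcc_up),
    healthy = NULL)
  dhs <- as.data.table(sites$dhs)

  n <- cfg$n_fragments_per_sample
  is_tumor <- stats::runif(n) < tf

  loc_prob <- function(lam, W) lam * W / (lam * W + (G - W))
  draw_uniform <- function(k) {
    ci <- sample.int(nrow(g), k, replace = TRUE, prob = g$length)
    list(chrom = g$chrom[ci], pos = floor(stats::runif(k) * g$length[ci]))
  }

  mid <- numeric(n); chrom <- character(n)
  ## tumor-derived fragments: signature sites vs background
  it <- which(is_tumor)
  if (length(it) > 0L) {
    p_sig <- if (is.null(sig)) 0 else
      loc_prob(cfg$enrichment, sum(sig$end - sig$start))
    at_sig <- stats::runif(length(it)) < p_sig
    if (any(at_sig)) {
      w <- sig$end - sig$start
      idx <- sample.int(nrow(sig), sum(at_sig), replace = TRUE, prob = w)
      mid[it[at_sig]] <- sig$start[idx] + floor(stats::runif(sum(at_sig)) * w[idx])
      chrom[it[at_sig]] <- sig$chrom[idx]
    }
    bg <- it[!at_sig]
    if (length(bg) > 0L) {
      u <- draw_uniform(length(bg))
      mid[bg] <- u$pos; chrom[bg] <- u$chrom
    }
  }
  ## non-tumor fragments: housekeeping DHS vs background
  ih <- which(!is_tumor)
  if (length(ih) > 0L) {
    p_dhs <- loc_prob(cfg$dhs_enrichment, sum(dhs$end - dhs$start))
    at_dhs <- stats::runif(length(ih)) < p_dhs
    if (any(at_dhs)) {
      w <- dhs$end - dhs$start
      idx <- sample.int(nrow(dhs), sum(at_dhs), replace = TRUE, prob = w)
      mid[ih[at_dhs]] <- dhs$start[idx] + floor(stats::runif(sum(at_dhs)) * w[idx])
      chrom[ih[at_dhs]] <- dhs$chrom[idx]
    }
    bg <- ih[!at_dhs]
    if (length(bg) > 0L) {
      u <- draw_uniform(length(bg))
      mid[bg] <- u$pos; chrom[bg] <- u$chrom
    }
  }

  len <- pmax(round(stats::rnorm(n, cfg$fragment_length_mean,
                                 cfg$fragment_length_sd)), 60)
  start <- pmax(mid - len %/% 2, 0)
  chrom_len <- stats::setNames(g$length, g$chrom)[chrom]
  end <- pmin(start + len, chrom_len)
  start <- pmin(start, end - 1)
  fs <- fragment_set(chrom, start, end, sample_id = sample_id, mark = mark)
  setattr(fs, "tf", tf)
  setattr(fs, "label", label)
  fs
}

#' Simulate a full plasma cohort (optionally longitudinal)
#'
#' Draws per-sample tumor fractions (log-uniform over `cfg$tf_log_range` for
#' tRCC and ccRCC, 0 for healthy), simulates both marks per sample, and
#' returns a sample sheet plus in-memory fragment sets. Longitudinal patients
#' get ordered draws whose tumor fraction rises across intervals labeled
#' `progression` and falls across `response` (roughly stable under `stable`).
#' When `out_dir` is given, fragment BEDs and the sample sheet are written as
#' plain text.
#'
#' @param cfg a [cohort_config()].
#' @param n_trcc,n_ccrcc,n_healthy cross-sectional sample counts.
#' @param longitudinal optional list of patients, each a list with
#'   `patient_id`, `tf0` (baseline tumor fraction) and `statuses` (vector of
#'   interval statuses among `"progression"`, `"stable"`, `"response"`;
#'   k statuses produce k+1 draws).
#' @param sites optional precomputed [make_sites()] output.
#' @param out_dir optional output directory for BED/TSV artifacts.
#' @return List with `sites`, `samples` (named list; each element has
#'   `sample_id`, `label`, `tf`, `patient_id`, `draw_date`, `status`, `k4`,
#'   `k27`) and `sheet` (data.table).
#' @export
simulate_cohort <- function(cfg, n_trcc, n_ccrcc, n_healthy,
                            longitudinal = NULL, sites = NULL, out_dir = NULL) {
  stopifnot(n_trcc >= 0, n_ccrcc >= 0, n_healthy >= 0)
  if (is.null(sites)) sites <- make_sites(cfg)
  draw_tf <- function(key) {
    set.seed(derive_seed(cfg$seed, paste0("tf_", key)))
    exp(stats::runif(1, log(cfg$tf_log_range[1]), log(cfg$tf_log_range[2])))
  }
  spec <- list()
  add <- function(spec, sample_id, label, tf, patient_id, draw_date, status) {
    spec[[sample_id]] <- list(sample_id = sample_id, label = label, tf = tf,
                              patient_id = patient_id, draw_date = draw_date,
                              status = status)
    spec
  }
  for (i in seq_len(n_trcc))
    spec <- add(spec, sprintf("tRCC_%02d", i), "tRCC",
                draw_tf(sprintf("tRCC_%02d", i)), sprintf("TRCCP%02d", i),
                as.Date("2024-01-01"), NA_character_)
  for (i in seq_len(n_ccrcc))
    spec <- add(spec, sprintf("ccRCC_%02d", i), "ccRCC",
                draw_tf(sprintf("ccRCC_%02d", i)), sprintf("CCRCCP%02d", i),
                as.Date("2024-01-01"), NA_character_)
  for (i in seq_len(n_healthy))
    spec <- add(spec, sprintf("healthy_%02d", i), "healthy", 0,
                sprintf("HP%02d", i), as.Date("2024-01-01"), NA_character_)

  for (pt in longitudinal) {
    tf <- pt$tf0
    set.seed(derive_seed(cfg$seed, paste0("traj_", pt$patient_id)))
    mult <- vapply(pt$statuses, function(s) switch(s,
      progression = stats::runif(1, 2, 3),
      response = stats::runif(1, 0.2, 0.4),
      stable = stats::runif(1, 0.85, 1.15),
      stop("unknown status: ", s)), numeric(1L))
    tfs <- pmin(tf * cumprod(c(1, mult)), 0.5)
    for (d in seq_along(tfs)) {
      sid <- sprintf("%s_d%02d", pt$patient_id, d)
      spec <- add(spec, sid, "tRCC", tfs[d], pt$patient_id,
                  as.Date("2024-01-01") + 30 * (d - 1),
                  if (d == 1L) NA_character_ else pt$statuses[d - 1L])
    }
  }

  samples <- lapply(spec, function(s) {
    s$k4 <- simulate_plasma_sample(cfg, s$label, s$tf, "H3K4me3", sites,
                                   derive_seed(cfg$seed, paste0(s$sample_id, "_K4")),
                                   sample_id = s$sample_id)
    s$k27 <- simulate_plasma_sample(cfg, s$label, s$tf, "H3K27ac", sites,
                                    derive_seed(cfg$seed, paste0(s$sample_id, "_K27")),
                                    sample_id = s$sample_id)
    s
  })
  sheet <- rbindlist(lapply(samples, function(s)
    data.table(sample_id = s$sample_id, patient_id = s$patient_id,
               label = s$label, tumor_fraction = s$tf,
               draw_date = as.character(s$draw_date), status = s$status)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("k4_up", "k27_up", "tfbs_raw", "dhs", "ccrcc_up", "background"))
      write_bed(sites[[nm]], file.path(out_dir, paste0(nm, ".bed")))
    for (s in samples) {
      write_bed(s$k4, file.path(out_dir, paste0(s$sample_id, "_H3K4me3.bed")))
      write_bed(s$k27, file.path(out_dir, paste0(s$sample_id, "_H3K27ac.bed")))
    }
    fwrite(sheet, file.path(out_dir, "sample_sheet.tsv"), sep = "\t")
  }
  list(sites = sites, samples = samples, sheet = sheet)
}
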