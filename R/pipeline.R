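#' Score every sample of a cohort
#'
#' @param cohort a [simulate_cohort()] result (or any list with `samples`).
#' @param bundle a [assemble_bundle()] result.
#' @param dhs housekeeping `site_set`.
#' @param ... passed to [score_sample()].
#' @return data.table: sample_id, s_k4, s_k27, s_tfbs, ties, label,
#'   tumor_fraction, patient_id, draw_date, status.
#' @export
score_cohort <- function(cohort, bundle, dhs, ...) {
  rows <- lapply(cohort$samples, function(s) {
    sc <- score_sample(list(sample_id = s$sample_id, k4 = s$k4, k27 = s$k27),
                       bundle, dhs, ...)
    sc[, `:=`(label = s$label, tumor_fraction = s$tf,
              patient_id = s$patient_id, draw_date = as.character(s$draw_date),
              status = s$status)]
    sc
  })
  rbindlist(rows)
}

validate_sample_sheet <- function(sheet) {
  need <- c("sample_id", "patient_id", "label", "tumor_fraction",
            "draw_date", "status")
  miss <- setdiff(need, names(sheet))
  if (length(miss) > 0L)
    stop("sample sheet is missing column(s): ", paste(miss, collapse = ", "))
  invisible(sheet)
}

#' Run the full synthetic end-to-end pipeline
#'
#' Orchestrates, in dependency order: synthetic site and cohort generation,
#' cell-line differential signature recovery, signature bundle assembly,
#' per-sample scoring, ROC/AUC contrasts, leave-one-out cross-validation
#' (tRCC vs healthy), the in silico dilution limit-of-detection experiment,
#' and the longitudinal monitoring contrast. All stage outputs are written as
#' plain-text TSV/BED under `out_dir` together with a manifest (config echo,
#' output file hashes, per-stage row counts). Identical config and seed give
#' identical outputs.
#'
#' @param cfg a [cohort_config()]; its `seed` drives every stage.
#' @param n_trcc,n_ccrcc,n_healthy cohort sizes.
#' @param longitudinal optional longitudinal patient list (see
#'   [simulate_cohort()]).
#' @param dilution optional [dilution_spec()]; `NULL` skips the dilution
#'   stage.
#' @param n_dilution_tumors,n_dilution_healthy dilution arm sizes; tumor
#'   samples are re-drawn with tumor fraction > 3% per the inclusion rule.
#' @param out_dir output directory (`NULL` = no files written).
#' @return List with `scores`, `roc` (list of contrasts), `loocv`,
#'   `dilution`, `monitoring`, `signatures`, `manifest`.
#' @export
run_pipeline <- function(cfg, n_trcc = 15, n_ccrcc = 12, n_healthy = 9,
                         longitudinal = NULL, dilution = dilution_spec(),
                         n_dilution_tumors = 10, n_dilution_healthy = 9,
                         out_dir = NULL) {
  stages <- list()
  sites <- make_sites(cfg)

  ## signature derivation from simulated cell-line counts: consensus peaks
  ## over the synthetic k4/k27 "truth" plus the comparator and background
  ## peak universe (non-differential peaks dominate, as in a real consensus)
  derive_sig <- function(true_sites, mark, lfc_min, key) {
    consensus <- consensus_peaks(list(
      new_site_set(rbindlist(list(as.data.table(true_sites),
                                  as.data.table(sites$ccrcc_up),
                                  as.data.table(sites$background))),
                   mark = mark, label = "consensus")))
    true_idx <- which(!is.na(overlap_match(consensus, true_sites)))
    m <- simulate_cell_line_counts(cfg, consensus, true_idx, log2fc_true = 3,
                                   n_per_group = c(4L, 6L),
                                   seed = derive_seed(cfg$seed, key))
    dp <- differential_peaks(m, lfc_min = lfc_min, q_max = 0.01)
    new_site_set(dp$up[, c("chrom", "start", "end")], mark = mark,
                 label = "tRCC-up")
  }
  k4_up <- derive_sig(sites$k4_up, "H3K4me3", 2, "k4_counts")
  k27_up <- derive_sig(sites$k27_up, "H3K27ac", 1, "k27_counts")
  bundle <- assemble_bundle(k4_up, k27_up, sites$tfbs_raw)
  stages$signatures <- list(k4_up = nrow(k4_up), k27_up = nrow(k27_up),
                            tfbs = nrow(bundle$tfbs),
                            tfbs_shared_removed = bundle$n_shared)

  cohort <- simulate_cohort(cfg, n_trcc, n_ccrcc, n_healthy,
                            longitudinal = longitudinal, sites = sites,
                            out_dir = if (!is.null(out_dir))
                              file.path(out_dir, "cohort"))
  validate_sample_sheet(cohort$sheet)
  scores <- score_cohort(cohort, bundle, sites$dhs)
  stages$scores <- nrow(scores)

  base <- scores[is.na(status)]  # cross-sectional draws only
  roc <- list(
    trcc_vs_healthy = roc_auc(base[label %in% c("tRCC", "healthy")]$ties,
                              base[label %in% c("tRCC", "healthy")]$label,
                              pos_label = "tRCC"),
    trcc_vs_ccrcc = roc_auc(base[label %in% c("tRCC", "ccRCC")]$ties,
                            base[label %in% c("tRCC", "ccRCC")]$label,
                            pos_label = "tRCC"))
  tvh <- base[label %in% c("tRCC", "healthy")]
  loocv <- loo_cv(tvh$ties, tvh$label, pos_label = "tRCC")
  stages$loocv <- list(n = nrow(tvh))

  dil <- NULL
  if (!is.null(dilution)) {
    dil_cfg <- cfg
    dil_cfg$tf_log_range <- c(max(0.031, cfg$tf_log_range[1]),
                              max(0.1, cfg$tf_log_range[2]))
    dil_cfg$seed <- derive_seed(cfg$seed, "dilution_arm")
    dil_cohort <- simulate_cohort(dil_cfg, n_dilution_tumors, 0,
                                  n_dilution_healthy, sites = sites)
    tumors <- Filter(function(s) s$label == "tRCC", dil_cohort$samples)
    healthies <- Filter(function(s) s$label == "healthy", dil_cohort$samples)
    dil <- dilution_experiment(tumors, healthies, dilution, bundle, sites$dhs)
    stages$dilution <- list(n_mixtures = nrow(dil$mixtures),
                            lod = dil$lod_label)
  }

  monitoring <- NULL
  if (!is.null(longitudinal)) {
    series <- scores[!is.na(patient_id) & patient_id %in%
                       vapply(longitudinal, `[[`, "", "patient_id")]
    deltas <- consecutive_deltas(series[, .(patient_id, draw_date, ties,
                                            tumor_fraction, status)])
    prog <- deltas[status == "progression"]$delta_ties
    other <- deltas[status %in% c("stable", "response")]$delta_ties
    cmp <- if (length(prog) > 0L && length(other) > 0L)
      group_compare(prog, other) else NULL
    monitoring <- list(deltas = deltas, progression_vs_rest = cmp)
    stages$monitoring <- list(n_pairs = nrow(deltas))
  }

  manifest <- list(config = unclass(cfg), stages = stages,
                   r_version = as.character(getRversion()))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fwrite(scores, file.path(out_dir, "ties_scores.tsv"), sep = "\t")
    for (nm in names(roc))
      fwrite(roc[[nm]]$points, file.path(out_dir, paste0("roc_", nm, ".tsv")),
             sep = "\t")
    if (!is.null(dil)) {
      fwrite(dil$mixtures, file.path(out_dir, "dilution_mixtures.tsv"), sep = "\t")
      fwrite(dil$per_bin, file.path(out_dir, "dilution_bins.tsv"), sep = "\t")
    }
    if (!is.null(monitoring) && nrow(monitoring$deltas) > 0L)
      fwrite(monitoring$deltas, file.path(out_dir, "monitoring_deltas.tsv"),
             sep = "\t")
    files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
    manifest$files <- lapply(stats::setNames(files, basename(files)),
                             function(f) unname(tools::md5sum(f)))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  list(scores = scores, roc = roc, loocv = loocv, dilution = dil,
       monitoring = monitoring,
       signatures = list(bundle = bundle, sites = sites), manifest = manifest)
}

## index of the first member of `b` overlapping each member of `a` (NA = none)
overlap_match <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(rep(NA_integer_, nrow(a)))
  hits <- findOverlaps(as_granges0(a), as_granges0(b), select = "first")
  as.integer(hits)
}
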