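#!/usr/bin/env Rscript
# Stage 2: derive the three cell-line-informed signatures.
#
# Reads the true site sets written by stage 1, simulates negative-binomial
# cell-line read counts over the consensus peak universe (4 tRCC vs 6 ccRCC
# lines), recovers tRCC-up sites by moderated differential analysis at the
# mark-specific thresholds (FDR-q < 0.01; log2FC > 2 for H3K4me3, > 1 for
# H3K27ac), intersects the known-TFBS catalog with fusion ChIP peaks, and
# removes TFBS shared with the H3K27ac up set so no signal is double
# counted. Signature BEDs go to results/02_signatures/.

suppressMessages(library(cfties))
suppressMessages(library(data.table))

seed <- 1
cfg <- cohort_config(seed = seed, n_fragments_per_sample = 2e4)
ind <- "results/01_cohort"
out <- "results/02_signatures"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

truth <- list(
  k4_up = read_bed(file.path(ind, "k4_up.bed"), mark = "H3K4me3", label = "tRCC-up"),
  k27_up = read_bed(file.path(ind, "k27_up.bed"), mark = "H3K27ac", label = "tRCC-up"),
  tfbs_raw = read_bed(file.path(ind, "tfbs_raw.bed"), mark = "TFBS",
                      label = "fusion-occupied"),
  ccrcc_up = read_bed(file.path(ind, "ccrcc_up.bed"), mark = "H3K27ac",
                      label = "ccRCC-up"),
  background = read_bed(file.path(ind, "background.bed"), label = "background"))

derive <- function(true_set, mark, lfc_min, key) {
  pool <- rbindlist(lapply(list(true_set, truth$ccrcc_up, truth$background),
                           function(x) as.data.table(x)[, .(chrom, start, end)]))
  consensus <- consensus_peaks(list(site_set(pool$chrom, pool$start, pool$end,
                                             mark = mark, label = "consensus")))
  true_idx <- which(!is.na(cfties:::overlap_match(consensus, true_set)))
  m <- simulate_cell_line_counts(cfg, consensus, true_idx, log2fc_true = 3,
                                 n_per_group = c(4L, 6L),
                                 seed = cfties:::derive_seed(seed, key))
  dp <- differential_peaks(m, lfc_min = lfc_min, q_max = 0.01)
  fwrite(dp$table, file.path(out, paste0("differential_", mark, ".tsv")),
         sep = "\t")
  up <- site_set(dp$up$chrom, dp$up$start, dp$up$end, mark = mark,
                 label = "tRCC-up")
  message(mark, ": ", nrow(up), " tRCC-up peaks of ", nrow(true_set),
          " truly enriched (", nrow(consensus), " consensus peaks tested)")
  up
}

k4_up <- derive(truth$k4_up, "H3K4me3", lfc_min = 2, key = "k4_counts")
k27_up <- derive(truth$k27_up, "H3K27ac", lfc_min = 1, key = "k27_counts")

bundle <- assemble_bundle(k4_up, k27_up, truth$tfbs_raw)
message("fusion-occupied TFBS: ", nrow(truth$tfbs_raw), " raw, ",
        bundle$n_shared, " shared with H3K27ac tRCC-up removed, ",
        nrow(bundle$tfbs), " kept")

write_bed(bundle$k4_up, file.path(out, "signature_k4_up.bed"))
write_bed(bundle$k27_up, file.path(out, "signature_k27_up.bed"))
write_bed(bundle$tfbs, file.path(out, "signature_tfbs.bed"))
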