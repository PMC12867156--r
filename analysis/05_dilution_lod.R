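#!/usr/bin/env Rscript
# Stage 5: in silico dilution limit of detection.
#
# Simulates a dilution arm (10 tumor samples with tumor fraction > 3%, 9
# healthy), mixes every tumor x healthy pair at eleven tumor-read fractions
# (0.9 ... 0.01), scores each mixture, bins by expected tumor fraction
# (0.4%-wide bins, open terminal bins) and tests each bin against the
# undiluted healthy scores by Wilcoxon rank-sum. Writes results/05_dilution/.

suppressMessages(library(cfties))
suppressMessages(library(data.table))

seed <- 1
cfg <- cohort_config(seed = cfties:::derive_seed(seed, "dilution_arm"),
                     n_fragments_per_sample = 2e4,
                     tf_log_range = c(0.035, 0.30))
sig <- "results/02_signatures"
ind <- "results/01_cohort"
out <- "results/05_dilution"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

bundle <- assemble_bundle(
  read_bed(file.path(sig, "signature_k4_up.bed"), mark = "H3K4me3", label = "tRCC-up"),
  read_bed(file.path(sig, "signature_k27_up.bed"), mark = "H3K27ac", label = "tRCC-up"),
  read_bed(file.path(sig, "signature_tfbs.bed"), mark = "TFBS", label = "fusion-occupied"))
dhs <- read_bed(file.path(ind, "dhs.bed"), mark = "DHS", label = "housekeeping")

# fragment placement must use the same genomic truth as stage 1
sites <- make_sites(cohort_config(seed = seed, n_fragments_per_sample = 2e4))
arm <- simulate_cohort(cfg, n_trcc = 10, n_ccrcc = 0, n_healthy = 9,
                       sites = sites)
tumors <- Filter(function(s) s$label == "tRCC", arm$samples)
healthies <- Filter(function(s) s$label == "healthy", arm$samples)

res <- dilution_experiment(tumors, healthies, dilution_spec(seed = seed),
                           bundle, dhs)
fwrite(res$mixtures, file.path(out, "mixtures.tsv"), sep = "\t")
fwrite(res$per_bin, file.path(out, "per_bin.tsv"), sep = "\t")
print(res)
message("limit of detection (lowest persistently significant TF bin): ",
        res$lod_label)
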