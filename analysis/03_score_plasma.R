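#!/usr/bin/env Rscript
# Stage 3: quantify the signatures in every plasma sample.
#
# Reads the fragment BEDs from stage 1 and the derived signature BEDs from
# stage 2, collapses fragments to midpoints, builds 3-kb/40-bp aggregate
# profiles with shoulder background subtraction, normalizes to the
# housekeeping DHS reference, and sums the three signals into the
# log-scale integrated score per sample. Writes results/03_scores/ties_scores.tsv.

suppressMessages(library(cfties))
suppressMessages(library(data.table))

ind <- "results/01_cohort"
sig <- "results/02_signatures"
out <- "results/03_scores"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

bundle <- assemble_bundle(
  read_bed(file.path(sig, "signature_k4_up.bed"), mark = "H3K4me3", label = "tRCC-up"),
  read_bed(file.path(sig, "signature_k27_up.bed"), mark = "H3K27ac", label = "tRCC-up"),
  read_bed(file.path(sig, "signature_tfbs.bed"), mark = "TFBS", label = "fusion-occupied"))
dhs <- read_bed(file.path(ind, "dhs.bed"), mark = "DHS", label = "housekeeping")

sheet <- fread(file.path(ind, "sample_sheet.tsv"))
scores <- rbindlist(lapply(seq_len(nrow(sheet)), function(i) {
  sid <- sheet$sample_id[i]
  sm <- list(
    sample_id = sid,
    k4 = read_fragments(file.path(ind, paste0(sid, "_H3K4me3.bed")), sid, "H3K4me3"),
    k27 = read_fragments(file.path(ind, paste0(sid, "_H3K27ac.bed")), sid, "H3K27ac"))
  sc <- score_sample(sm, bundle, dhs)
  cbind(sc, sheet[i, .(patient_id, label, tumor_fraction, draw_date, status)])
}))

fwrite(scores, file.path(out, "ties_scores.tsv"), sep = "\t")
message("scored ", nrow(scores), " samples")
print(scores[, .(median_ties = median(ties), n = .N), by = label])
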