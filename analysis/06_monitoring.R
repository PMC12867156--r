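#!/usr/bin/env Rscript
# Stage 6: longitudinal monitoring.
#
# For the longitudinal patients of stage 1, computes the percent change in
# the integrated score between consecutive draws and compares progression
# intervals against stable/response intervals (Wilcoxon rank-sum).
# Writes results/06_monitoring/.

suppressMessages(library(cfties))
suppressMessages(library(data.table))

out <- "results/06_monitoring"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
scores <- fread("results/03_scores/ties_scores.tsv")

series <- scores[grepl("^LP", patient_id),
                 .(patient_id, draw_date, ties, tumor_fraction, status)]
deltas <- consecutive_deltas(series)
fwrite(deltas, file.path(out, "deltas.tsv"), sep = "\t")
print(deltas)

prog <- deltas[status == "progression"]$delta_ties
rest <- deltas[status %in% c("stable", "response")]$delta_ties
cmp <- group_compare(prog, rest)
jsonlite::write_json(
  list(n_progression = length(prog), n_stable_or_response = length(rest),
       median_delta_progression = median(prog),
       median_delta_rest = median(rest), p_value = cmp$p_value),
  file.path(out, "progression_contrast.json"), auto_unbox = TRUE, digits = NA)
message(sprintf(
  "score change on progression (median %+.1f%%) vs stable/response (%+.1f%%): p = %.3g",
  median(prog), median(rest), cmp$p_value))
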