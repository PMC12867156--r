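#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Produces the cell-line-informed site sets (true tRCC-up H3K4me3/H3K27ac
# sites, fusion-occupied TFBS with 13% placed overlapping the H3K27ac set,
# housekeeping DHS sites, a ccRCC comparator set, and background consensus
# peaks) plus a plasma cohort: 10 tRCC, 8 ccRCC and 6 healthy samples, and
# two longitudinal patients whose tumor fraction tracks clinical status.
# Fragment BEDs and the sample sheet are written under results/01_cohort/.

suppressMessages(library(cfties))

seed <- 1
cfg <- cohort_config(seed = seed, n_fragments_per_sample = 2e4)
out <- "results/01_cohort"

longitudinal <- list(
  list(patient_id = "LP1", tf0 = 0.08,
       statuses = c("response", "stable", "progression", "progression")),
  list(patient_id = "LP2", tf0 = 0.10,
       statuses = c("progression", "response", "stable")),
  list(patient_id = "LP3", tf0 = 0.05,
       statuses = c("stable", "progression", "response")))

cohort <- simulate_cohort(cfg, n_trcc = 10, n_ccrcc = 8, n_healthy = 6,
                          longitudinal = longitudinal, out_dir = out)

message("wrote ", nrow(cohort$sheet), " samples (x2 marks) to ", out)
message("tumor fractions: tRCC ",
        paste(signif(cohort$sheet$tumor_fraction[cohort$sheet$label == "tRCC"], 2),
              collapse = " "))
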