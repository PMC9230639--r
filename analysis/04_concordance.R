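#!/usr/bin/env Rscript
# The analytical core: detection filtering (>= 5 samples per cohort),
# per-set direction tests (continuity-corrected two-proportion on up vs
# down members), magnitude tests (one-sample t of fold-changes against 1),
# global up/down proportion tests, and transcript-protein coupling calls.

library(concordia)

out <- "results/concordance"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

de_t <- utils::read.delim("results/diffexp/de_transcript.tsv")
de_p <- utils::read.delim("results/diffexp/de_protein.tsv")
sets <- read_gmt("results/simulated/functional_groups.gmt")

summ <- build_summary(de_t, de_p, sets, alpha = 0.05, min_detect = 5)

write_results_tables(
  list(global = summ$global,
       concordance_transcript = summ$concordance_transcript,
       concordance_protein = summ$concordance_protein,
       coupling = summ$coupling),
  out, params = list(alpha = 0.05, min_detect = 5,
                     up_cut = 1.1, down_cut = 0.9))

cat("global direction summary:\n")
print(summ$global, digits = 3)
cat("\ncoupling calls:\n")
print(summ$coupling)
cat("\ntables written to", out, "\n")
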