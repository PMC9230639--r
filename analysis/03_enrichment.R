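#!/usr/bin/env Rscript
# Over-representation of the significantly up- and downregulated lists
# against the detected-feature reference of each ome, with binomial tails
# and BH correction, followed by single-linkage merging of redundant terms
# (Jaccard >= 0.5 on reference-restricted membership).

library(concordia)

out <- "results/enrichment"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sets <- read_gmt("results/simulated/functional_groups.gmt")
tables <- list()

for (ome in c("transcript", "protein")) {
  de <- utils::read.delim(sprintf("results/diffexp/de_%s.tsv", ome))
  reference <- de$feature_id
  for (dir in c("up", "down")) {
    ids <- de$feature_id[de$direction == dir]
    rows <- binomial_ora(ids, reference, sets, correct_fdr = TRUE)
    merged <- merge_redundant_terms(rows, jaccard_min = 0.5)
    cat(sprintf("%s %s: %d in list, %d/%d sets enriched at FDR 0.05\n",
                ome, dir, length(ids),
                if (nrow(rows)) sum(rows$fdr <= 0.05) else 0L, nrow(rows)))
    rows$members <- NULL
    tables[[sprintf("enrichment_%s_%s", ome, dir)]] <- rows
    tables[[sprintf("enrichment_%s_%s_merged", ome, dir)]] <- merged
  }
}

write_results_tables(tables, out, params = list(jaccard = 0.5))
cat("tables written to", out, "\n")
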