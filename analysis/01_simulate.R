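#!/usr/bin/env Rscript
# Generate the paper-shaped synthetic cohort: 20 PD-like cases vs 20
# controls, measured as RNA-seq counts and label-free protein intensities,
# with the planted functional-group structure (OXPHOS CI-IV transcripts
# down / proteins up, Complex V and ribosome down in both omes, immune and
# sphingolipid sets up in both). Writes the four pipeline input files.

library(concordia)

out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

scenario <- default_paper_scenario(seed = 20260921)
cohort <- generate_cohort(scenario)

write_expression_matrix(cohort$transcripts, file.path(out, "counts.tsv"))
write_expression_matrix(cohort$proteins, file.path(out, "proteins.tsv"))
write_design(cohort$design, file.path(out, "design.tsv"))
write_gmt(cohort$sets, file.path(out, "functional_groups.gmt"))

cat(sprintf("simulated %d transcripts and %d proteins for %d samples\n",
            nrow(cohort$transcripts$values), nrow(cohort$proteins$values),
            length(cohort$design)))
cat(sprintf("protein matrix missingness: %.1f%% (intensity-dependent)\n",
            100 * mean(is.na(cohort$proteins$values))))
cat("inputs written to", out, "\n")
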