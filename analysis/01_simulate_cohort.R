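#!/usr/bin/env Rscript

# Step 1 — simulate the study inputs.
#
# Generates (a) a longitudinal infant cohort at the study's scale —
# 12 subjects sampled daily for the first week and every other day to day
# 29 (18 samples each, 216 in total), with three community regimes, a
# forward-biased daily regime chain, and gut-environment variables coupled
# to Bifidobacteriaceae abundance — and (b) a 29-strain panel with 2000
# homologous groups, one of which discriminates the growth phenotype up to
# a single exception strain. Everything downstream reads these files.

library(infantgut)

seed <- 20160624
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

coh <- generate_cohort(cohort_config(), seed = seed)
write_abundance_table(coh$table, "results/data/abundance.tsv")
write.table(coh$meta, "results/data/metadata.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(coh$env, "results/data/environment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(coh$truth, "results/data/true_regimes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

panel <- generate_strain_panel(panel_config(), seed = seed + 1)
write_ortholog_groups(panel$presence, "results/data/ortholog_groups.txt")
write.table(panel$curves, "results/data/growth_curves.csv", sep = ",",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(list(planted_group = panel$planted_group,
                          exception_strains = panel$exception_strains,
                          phenotype = as.list(panel$phenotype),
                          seed = seed + 1),
                     "results/data/panel_truth.json", auto_unbox = TRUE)

cat(sprintf("cohort: %d samples x %d taxa from %d subjects\n",
            nrow(coh$table), ncol(coh$table),
            length(unique(coh$meta$subject_id))))
cat(sprintf("panel: %d strains x %d homologous groups (planted: %s)\n",
            nrow(panel$presence), ncol(panel$presence), panel$planted_group))
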