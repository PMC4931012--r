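#!/usr/bin/env Rscript

# Step 3 — longitudinal state dynamics.
#
# Names each PAM cluster by its top mean family, maps every sample to a
# community state, exports the per-subject day grid, and counts directional
# transitions between consecutive observed samples. The forward fraction
# quantifies the Staphylococcaceae -> Enterobacteriaceae ->
# Bifidobacteriaceae succession.

library(infantgut)

tab <- read_abundance_table("results/data/abundance.tsv")
meta <- read_sample_table("results/data/metadata.tsv")
sol_json <- jsonlite::read_json("results/pam_solution.json", simplifyVector = TRUE)
sol <- structure(list(k = sol_json$k,
                      medoid_ids = sol_json$medoid_ids,
                      assignment = unlist(sol_json$assignment),
                      total_cost = sol_json$total_cost),
                 class = "pam_solution")

series <- assign_states(tab, meta, sol)
write_state_grid(series, "results/state_grid.tsv")

trans <- transition_counts(series)
write.table(trans$pairs, "results/transition_pairs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("transition counts (from rows to columns):\n")
print(trans$counts)

order <- c("Staphylococcaceae", "Enterobacteriaceae", "Bifidobacteriaceae")
dir <- directionality(trans, order = c(intersect(order, trans$states),
                                       setdiff(trans$states, order)))
cat(sprintf("forward transitions: %d, backward: %d, forward fraction: %s\n",
            dir$forward, dir$backward,
            ifelse(dir$defined, sprintf("%.3f", dir$forward_fraction), "undefined")))
jsonlite::write_json(dir, "results/directionality.json", auto_unbox = TRUE,
                     digits = NA)
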